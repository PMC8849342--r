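#' Construct an image stack
#'
#' The universal image container of the package: a 4-dimensional non-negative
#' intensity array indexed `(channel, plane, y, x)` together with acquisition
#' metadata.  The plane axis is either depth (`axis_kind = "z"`, one plane per
#' imaging depth, shallowest first) or time (`axis_kind = "t"`, one plane per
#' frame).  All indices are 1-based, following R convention.
#'
#' @param pixels Numeric array.  Accepted shapes: `(y, x)` (single plane,
#'   single channel), `(plane, y, x)` (single channel) or
#'   `(channel, plane, y, x)`.  Degenerate axes are added on the left.
#' @param axis_kind `"z"` for depth stacks, `"t"` for time lapses.
#' @param pixel_size_um Lateral pixel size in micrometres.
#' @param plane_step Plane spacing: micrometres per plane for `"z"`,
#'   seconds per frame for `"t"`.  Must be positive.
#' @param channel_names Character vector naming the channels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param meta Named list of acquisition metadata.  Recognised fields:
#'   `wavelength_nm`, `rep_rate_hz`, `per_plane_energy_nj` (excitation pulse
#'   energy at the sample surface, one value per plane), `immersion_path_mm`,
#'   `objective_energy_nj`.  Unknown fields are kept verbatim.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, axis_kind = c("z", "t"), pixel_size_um = 1,
                        plane_step = 1, channel_names = NULL, meta = list()) {
  axis_kind <- match.arg(axis_kind)
  d <- dim(pixels) %||% length(pixels)
  if (length(d) == 2L) dim(pixels) <- c(1L, 1L, d)
  if (length(dim(pixels)) == 3L) dim(pixels) <- c(1L, dim(pixels))
  if (length(dim(pixels)) != 4L) {
    abort("`pixels` must have 2 to 4 dimensions (channel, plane, y, x).")
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("All pixel intensities must be finite and non-negative.")
  }
  if (plane_step <= 0) abort("`plane_step` must be > 0.")
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0.")
  nc <- dim(pixels)[1L]
  channel_names <- channel_names %||% paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    abort("`channel_names` must have one entry per channel.")
  }
  e <- meta$per_plane_energy_nj
  if (!is.null(e)) {
    if (length(e) != dim(pixels)[2L] || any(e <= 0)) {
      abort("`meta$per_plane_energy_nj` needs one positive value per plane.")
    }
  }
  structure(
    list(pixels = pixels, axis_kind = axis_kind,
         pixel_size_um = pixel_size_um, plane_step = plane_step,
         channel_names = channel_names, meta = meta),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_stack> %d channel(s) x %d plane(s) (%s) x %d x %d px\n",
    d[1], d[2], x$axis_kind, d[3], d[4]))
  cat(sprintf("  pixel size %g um, plane step %g %s; channels: %s\n",
              x$pixel_size_um, x$plane_step,
              if (x$axis_kind == "z") "um" else "s",
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

#' Number of planes / channels in a stack
#' @param stack An `image_stack`.
#' @export
n_planes <- function(stack) dim(stack$pixels)[2L]

#' @rdname n_planes
#' @export
n_channels <- function(stack) dim(stack$pixels)[1L]

#' Extract a single plane as a y-by-x matrix
#'
#' @param stack An `image_stack`.
#' @param channel Channel index or name.
#' @param plane Plane index (1-based).
#' @export
get_plane <- function(stack, channel = 1L, plane = 1L) {
  channel <- resolve_channel(stack, channel)
  if (plane < 1L || plane > n_planes(stack)) {
    abort(sprintf("Plane %d outside stack (1..%d).", plane, n_planes(stack)))
  }
  stack$pixels[channel, plane, , ]
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) abort(sprintf("Unknown channel '%s'.", channel))
    return(i)
  }
  channel <- as.integer(channel)
  if (channel < 1L || channel > n_channels(stack)) {
    abort(sprintf("Channel %d outside stack (1..%d).", channel,
                  n_channels(stack)))
  }
  channel
}

#' Depth (or time) coordinate of every plane
#'
#' Plane 1 sits at coordinate 0 (sample surface, or recording start).
#' @param stack An `image_stack`.
#' @export
plane_coords <- function(stack) (seq_len(n_planes(stack)) - 1) * stack$plane_step

#' Read an image stack from a (OME-)TIFF file
#'
#' Pages are read in file order and reshaped to `(channel, plane, y, x)` with
#' channels interleaved fastest (page = (plane - 1) * n_channels + channel).
#' Acquisition metadata not expressible in baseline TIFF tags is supplied via
#' a YAML sidecar (by default `<path>.yaml`) with fields `axis_kind`,
#' `n_channels`, `channel_names`, `pixel_size_um`, `plane_step` and an
#' optional `meta` block; see [write_stack()] which emits the sidecar.
#'
#' @param path TIFF file path.
#' @param axis_kind Override for the plane-axis interpretation; defaults to
#'   the sidecar value, else `"z"`.
#' @param sidecar Path to the YAML sidecar; `NULL` to use `<path>.yaml`
#'   when present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, axis_kind = NULL, sidecar = NULL) {
  if (!file.exists(path)) abort(sprintf("Cannot read TIFF file '%s'.", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      abort(sprintf("Failed to read '%s': %s", path,
                                    conditionMessage(e)))
                    })
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- sidecar %||% paste0(path, ".yaml")
  cfg <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  nc <- as.integer(cfg$n_channels %||% 1L)
  np <- length(pages) / nc
  if (np != as.integer(np)) {
    abort(sprintf(
      "Page count %d is not a multiple of n_channels = %d in '%s'.",
      length(pages), nc, path))
  }
  np <- as.integer(np)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  px <- array(0, dim = c(nc, np, ny, nx))
  for (p in seq_len(np)) {
    for (ch in seq_len(nc)) {
      px[ch, p, , ] <- pages[[(p - 1L) * nc + ch]]
    }
  }
  ak <- axis_kind %||% cfg$axis_kind %||% "z"
  image_stack(px, axis_kind = ak,
              pixel_size_um = cfg$pixel_size_um %||% 1,
              plane_step = cfg$plane_step %||% 1,
              channel_names = unlist(cfg$channel_names) %||% NULL,
              meta = cfg$meta %||% list())
}

#' Write an image stack to TIFF plus a YAML metadata sidecar
#'
#' Pixel values are written as 16-bit unsigned integers (they must be
#' integral and lie in 0..65535); the round trip through [read_stack()] is
#' bit exact for such data.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the sidecar is written to `<path>.yaml`.
#' @export
write_stack <- function(stack, path) {
  px <- stack$pixels
  if (any(px != round(px)) || max(px) > 65535) {
    abort("write_stack() stores 16-bit data: pixels must be integers in 0..65535.")
  }
  nc <- n_channels(stack); np <- n_planes(stack)
  pages <- vector("list", nc * np)
  for (p in seq_len(np)) {
    for (ch in seq_len(nc)) {
      pages[[(p - 1L) * nc + ch]] <- px[ch, p, , ] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  cfg <- list(axis_kind = stack$axis_kind, n_channels = nc,
              channel_names = as.list(stack$channel_names),
              pixel_size_um = stack$pixel_size_um,
              plane_step = stack$plane_step, meta = stack$meta)
  yaml::write_yaml(cfg, paste0(path, ".yaml"))
  invisible(path)
}

#' Regions of interest
#'
#' An ROI is a boolean pixel mask over the `(y, x)` frame with a label.
#' `roi_rect()` builds a rectangular ROI, `roi_mask()` wraps an explicit
#' logical matrix.
#'
#' @param y,x 1-based top-left corner of the rectangle.
#' @param height,width Rectangle extent in pixels.
#' @param dim Frame dimensions `c(ny, nx)`.
#' @param label Free-text label.
#' @return An object of class `mp_roi`.
#' @export
roi_rect <- function(y, x, height, width, dim, label = "roi") {
  if (y < 1 || x < 1 || y + height - 1 > dim[1] || x + width - 1 > dim[2]) {
    abort("ROI rectangle extends outside the image.")
  }
  mask <- matrix(FALSE, dim[1], dim[2])
  mask[y:(y + height - 1), x:(x + width - 1)] <- TRUE
  roi_mask(mask, label)
}

#' @rdname roi_rect
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @export
roi_mask <- function(mask, label = "roi") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("`mask` must be a logical matrix.")
  }
  if (!any(mask)) abort("An ROI must contain at least one pixel.")
  structure(list(mask = mask, label = label), class = "mp_roi")
}

#' @export
print.mp_roi <- function(x, ...) {
  cat(sprintf("<mp_roi> '%s': %d px in a %d x %d frame\n",
              x$label, sum(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

check_roi_fits <- function(roi, ny, nx) {
  if (!inherits(roi, "mp_roi")) abort("Expected an `mp_roi` object.")
  if (nrow(roi$mask) != ny || ncol(roi$mask) != nx) {
    abort(sprintf("ROI mask is %d x %d but the image is %d x %d.",
                  nrow(roi$mask), ncol(roi$mask), ny, nx))
  }
  invisible(roi)
}
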