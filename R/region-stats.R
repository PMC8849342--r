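#' Median filter a 2-D image
#'
#' Square-window median filter of the given radius (window side
#' `2 * radius + 1`), the spatial pre-filter used before bright-pixel
#' selection.  Radius 0 returns the image unchanged.  Backed by
#' EBImage's constant-time median filter; borders are replicated.
#'
#' @param image Numeric matrix.
#' @param radius_px Integer radius in pixels, >= 0.
#' @export
median_filter <- function(image, radius_px) {
  stopifnot(is.matrix(image))
  radius_px <- as.integer(radius_px)
  if (radius_px <= 0L) return(image)
  hi <- max(image)
  if (hi == 0) return(image)
  # EBImage expects data in [0, 1] and works in a 16-bit integer
  # workspace; integer-valued images up to 65535 are filtered exactly by
  # scaling with the full 16-bit range, everything else by its maximum
  # (quantization ~ max/2^16, far below any noise floor)
  if (hi <= 65535 && all(image == round(image))) {
    EBImage::medianFilter(image / 65535, radius_px) * 65535
  } else {
    EBImage::medianFilter(image / hi, radius_px) * hi
  }
}

# normalized mean filter over a disc of the given radius (replicated borders)
mean_filter_disk <- function(image, radius_px) {
  if (radius_px <= 0) return(image)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  brush <- brush / sum(brush)
  as.matrix(EBImage::filter2(image, brush, boundary = "replicate"))
}

#' Statistics of the brightest pixels of an image
#'
#' Median-filters the image, then selects the `ceil(top_fraction * N)`
#' brightest pixels (ties at the cut broken by raster order) and returns
#' their mean, population standard deviation and count.  This implements the
#' brightest-percentile signal estimate used throughout the SNR and
#' attenuation analyses (top 1% for harmonic signals, 10% for nuclei, 40%
#' for cytosolic labels).
#'
#' @param image Numeric matrix.
#' @param top_fraction Fraction in (0, 1] of pixels to keep.
#' @param median_radius_px Median pre-filter radius; 0 disables filtering.
#' @return One-row tibble with `i_mean`, `sigma_i`, `area_px`.
#' @export
select_bright_pixels <- function(image, top_fraction, median_radius_px = 0L) {
  if (!is.matrix(image) || length(image) == 0L) {
    abort("`image` must be a non-empty matrix.")
  }
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must lie in (0, 1].")
  }
  filt <- median_filter(image, median_radius_px)
  v <- as.vector(t(filt))           # raster order: row-major
  k <- ceiling(top_fraction * length(v))
  idx <- order(-v, seq_along(v))[seq_len(k)]
  sel <- v[idx]
  tibble(i_mean = mean(sel), sigma_i = sd_pop(sel), area_px = k)
}

#' Background statistics over a dark ROI
#'
#' Mean and population SD of the *unfiltered* pixels inside the ROI, either
#' per plane or pooled over all planes of the stack.
#'
#' @param stack An [image_stack()].
#' @param channel Channel index or name.
#' @param roi An `mp_roi` over the frame.
#' @param per_plane If `TRUE` (default) one row per plane, else a single
#'   pooled row with `plane = NA`.
#' @return Tibble with columns `plane`, `b_mean`, `sigma_b`.
#' @export
background_stats <- function(stack, channel = 1L, roi, per_plane = TRUE) {
  channel <- resolve_channel(stack, channel)
  d <- dim(stack$pixels)
  check_roi_fits(roi, d[3], d[4])
  vals <- lapply(seq_len(d[2]), function(p) {
    stack$pixels[channel, p, , ][roi$mask]
  })
  if (per_plane) {
    tibble(plane = seq_len(d[2]),
           b_mean = map_dbl(vals, mean),
           sigma_b = map_dbl(vals, sd_pop))
  } else {
    pooled <- unlist(vals)
    tibble(plane = NA_integer_, b_mean = mean(pooled),
           sigma_b = sd_pop(pooled))
  }
}

#' Automatic threshold mask
#'
#' Histogram-based automatic thresholding (256 bins between the image
#' minimum and maximum) followed by optional binary erosion with a 3x3
#' square structuring element.  Methods follow the classical definitions:
#' Otsu (maximum between-class variance), Huang (minimum fuzzy entropy) and
#' IsoData (iterative intermeans).
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param method One of `"otsu"`, `"huang"`, `"isodata"`.
#' @param erode_steps Number of erosion passes, >= 0.
#' @return An `mp_roi` whose mask holds pixels above the threshold.  If
#'   erosion empties the mask the result carries attribute
#'   `degenerate = TRUE` (and an all-`FALSE` mask is not representable as an
#'   ROI, so the pre-erosion mask is returned with that flag).
#' @export
auto_threshold_mask <- function(image, method = c("otsu", "huang", "isodata"),
                                erode_steps = 0L) {
  method <- match.arg(method)
  if (diff(range(image)) == 0) {
    abort("Cannot threshold a constant image.")
  }
  thr <- threshold_value(image, method)
  mask <- image > thr
  if (!any(mask)) abort("Thresholding selected no pixels.")
  m0 <- mask
  degenerate <- FALSE
  if (erode_steps > 0L) {
    brush <- EBImage::makeBrush(3L, shape = "box")
    for (i in seq_len(erode_steps)) {
      eroded <- as.matrix(EBImage::erode(EBImage::Image(mask * 1), brush)) > 0
      if (!any(eroded)) { degenerate <- TRUE; break }
      mask <- eroded
    }
  }
  roi <- roi_mask(if (degenerate) m0 else mask,
                  label = sprintf("%s>%.4g", method, thr))
  attr(roi, "threshold") <- thr
  attr(roi, "degenerate") <- degenerate
  roi
}

#' Automatic threshold value
#'
#' The intensity cut used by [auto_threshold_mask()], on the original
#' intensity scale.
#'
#' @inheritParams auto_threshold_mask
#' @export
threshold_value <- function(image, method = c("otsu", "huang", "isodata")) {
  method <- match.arg(method)
  lo <- min(image); hi <- max(image)
  if (hi == lo) abort("Cannot threshold a constant image.")
  nbin <- 256L
  # bin index 0..255; counts over equal-width bins spanning [lo, hi]
  b <- pmin(floor((as.vector(image) - lo) / (hi - lo) * nbin), nbin - 1L)
  counts <- tabulate(b + 1L, nbins = nbin)
  t_bin <- switch(method,
    otsu = otsu_bin(counts),
    huang = huang_bin(counts),
    isodata = isodata_bin(counts))
  # mask = pixels in bins strictly above t_bin
  lo + (t_bin + 1) / nbin * (hi - lo)
}

# Otsu 1979: maximize between-class variance; threshold bin = last bin of
# the dark class
otsu_bin <- function(counts) {
  n <- length(counts)
  lev <- seq_len(n) - 1
  w <- cumsum(counts)
  m <- cumsum(counts * lev)
  tot_w <- w[n]; tot_m <- m[n]
  w0 <- w[-n]; w1 <- tot_w - w0
  mu0 <- ifelse(w0 > 0, m[-n] / w0, 0)
  mu1 <- ifelse(w1 > 0, (tot_m - m[-n]) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  which.max(bcv) - 1L
}

# IsoData / intermeans (Ridler & Calvard 1978): t = (mean below + mean
# above) / 2, iterated to a fixed point
isodata_bin <- function(counts) {
  n <- length(counts)
  lev <- seq_len(n) - 1
  t <- round(sum(counts * lev) / sum(counts))
  repeat {
    below <- lev <= t
    m0 <- if (any(counts[below] > 0)) {
      sum(counts[below] * lev[below]) / sum(counts[below])
    } else 0
    m1 <- if (any(counts[!below] > 0)) {
      sum(counts[!below] * lev[!below]) / sum(counts[!below])
    } else m0
    t_new <- floor((m0 + m1) / 2)
    if (t_new == t) break
    t <- t_new
  }
  as.integer(t)
}

# Huang & Wang 1995: minimize the Shannon fuzzy entropy of the membership
# function based on distances to the class means
huang_bin <- function(counts) {
  n <- length(counts)
  lev <- seq_len(n) - 1
  first <- min(which(counts > 0)) - 1L
  last <- max(which(counts > 0)) - 1L
  if (first == last) return(first)
  w <- cumsum(counts)
  m <- cumsum(counts * lev)
  c_inv <- 1 / (last - first)  # normalizing factor of the membership
  best_t <- first; best_e <- Inf
  for (t in first:last) {
    w0 <- w[t + 1L]; w1 <- w[n] - w0
    mu0 <- if (w0 > 0) m[t + 1L] / w0 else 0
    mu1 <- if (w1 > 0) (m[n] - m[t + 1L]) / w1 else 0
    mu <- ifelse(lev <= t, mu0, mu1)
    u <- 1 / (1 + c_inv * abs(lev - mu))   # membership in [0.5, 1]
    h <- -u * log(u) - (1 - u) * log(1 - u)
    h[u >= 1] <- 0
    e <- sum(counts * h)
    if (e < best_e) { best_e <- e; best_t <- t }
  }
  as.integer(best_t)
}
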