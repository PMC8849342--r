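#' Extract per-cell intensity traces from a time-lapse movie
#'
#' For every tracked point the trace value is the mean over a disc-shaped
#' pixel neighbourhood (default radius 2 px) centred on the coordinate,
#' clipped at the frame borders.  Coordinates outside the frame produce a
#' warning and a masked (`NA`) value.
#'
#' @param movie An [image_stack()] with `axis_kind = "t"`.
#' @param channel Channel index or name.
#' @param track_points Tibble with columns `frame`, `cell_id`,
#'   `compartment` (`"nucleus"` or `"cytosol"`), `y_px`, `x_px`
#'   (1-based pixel coordinates).
#' @param radius_px Neighbourhood radius in pixels.
#' @return An `intensity_traces` tibble with `cell_id`, `compartment`,
#'   `frame`, `time_s`, `value`.
#' @export
extract_traces <- function(movie, channel = 1L, track_points, radius_px = 2L) {
  channel <- resolve_channel(movie, channel)
  d <- dim(movie$pixels)
  tp <- as_tibble(track_points)
  stopifnot(all(c("frame", "cell_id", "compartment", "y_px", "x_px")
                %in% names(tp)))
  off <- disk_offsets(radius_px)
  outside <- tp$y_px < 1 | tp$y_px > d[3] | tp$x_px < 1 | tp$x_px > d[4] |
    tp$frame < 1 | tp$frame > d[2]
  if (any(outside)) {
    warn(sprintf("%d track point(s) outside the movie were masked.",
                 sum(outside)))
  }
  vals <- rep(NA_real_, nrow(tp))
  for (f in unique(tp$frame[!outside])) {
    fr <- movie$pixels[channel, f, , ]
    for (i in which(!outside & tp$frame == f)) {
      yy <- tp$y_px[i] + off[, 1]; xx <- tp$x_px[i] + off[, 2]
      keep <- yy >= 1 & yy <= d[3] & xx >= 1 & xx <= d[4]
      vals[i] <- mean(fr[cbind(yy[keep], xx[keep])])
    }
  }
  out <- tibble(cell_id = tp$cell_id, compartment = tp$compartment,
                frame = tp$frame,
                time_s = (tp$frame - 1) * movie$plane_step,
                value = vals)
  structure(arrange(out, .data$cell_id, .data$compartment, .data$frame),
            class = c("intensity_traces", class(out)))
}

disk_offsets <- function(radius_px) {
  g <- expand.grid(dy = -radius_px:radius_px, dx = -radius_px:radius_px)
  as.matrix(g[g$dy^2 + g$dx^2 <= radius_px^2, ])
}

#' Crosstalk-corrected Sytox trace
#'
#' The nuclear dead-cell-stain signal is contaminated by the cytosolic
#' calcium indicator (both emit in the same detection band).  Dividing the
#' background-subtracted nucleus trace by the background-subtracted cytosol
#' trace of the same cell cancels the shared indicator component, so the
#' ratio reports nuclear stain uptake: it stays near 1 in intact cells and
#' rises when the stain enters the nucleus.
#'
#' @param nucleus,cytosol Numeric vectors (same frames, same cell).
#' @param background Per-frame dark background (scalar or vector).
#' @return Numeric vector of ratios; frames with non-positive denominator
#'   are masked to `NA` with a warning.
#' @export
sytox_trace <- function(nucleus, cytosol, background = 0) {
  if (length(nucleus) != length(cytosol)) {
    abort("`nucleus` and `cytosol` must cover the same frames.")
  }
  den <- cytosol - background
  bad <- den <= 0
  if (any(bad)) {
    warn(sprintf("%d frame(s) with non-positive cytosol signal masked.",
                 sum(bad)))
  }
  ifelse(bad, NA_real_, (nucleus - background) / den)
}

#' Smooth and normalize an intensity trace
#'
#' Background subtraction, Savitzky-Golay smoothing (polynomial order 2
#' over a 10-point window by default; the window is widened to the next odd
#' length as the filter needs a centre point) and division by the maximum
#' of a reference trace (conventionally the smoothed cytosol trace of the
#' same cell).
#'
#' @param values Numeric trace.
#' @param window_pts Nominal smoothing window (points).
#' @param poly_order Polynomial order of the filter.
#' @param background Scalar or per-frame background to subtract.
#' @param norm_ref Reference trace whose (smoothed) maximum becomes 1;
#'   `NULL` normalizes to the trace's own smoothed maximum; `NA` skips
#'   normalization.
#' @return Numeric vector: the processed trace.
#' @export
smooth_normalize <- function(values, window_pts = 10L, poly_order = 2L,
                             background = 0, norm_ref = NULL) {
  n <- odd_window(window_pts)
  if (length(values) <= n) {
    abort(sprintf("Trace length %d must exceed the smoothing window %d.",
                  length(values), n))
  }
  sm <- signal::sgolayfilt(values - background, p = poly_order, n = n)
  if (length(norm_ref) == 1L && is.na(norm_ref)) return(sm)
  ref <- if (is.null(norm_ref)) sm else {
    signal::sgolayfilt(norm_ref - background, p = poly_order, n = n)
  }
  sm / max(ref)
}

odd_window <- function(window_pts) {
  n <- as.integer(window_pts)
  if (n %% 2L == 0L) n + 1L else n
}

#' Classify a cell as responder from its intensity trace
#'
#' The response threshold is `mean_baseline + 3 * SD_baseline`, computed
#' from the *unsmoothed* trace inside the baseline window (before
#' exposure onset).  A cell is a responder when its trace crosses that
#' threshold after the baseline; crossing detection is by default performed
#' on the Savitzky-Golay-smoothed trace (the threshold always comes from
#' the raw baseline).  Under a Gaussian null the per-sample probability of
#' exceeding the threshold is given by [responder_null_rate()].
#'
#' @param values Numeric trace (raw intensities).
#' @param baseline_window Integer frame indices forming the pre-exposure
#'   baseline (>= 5 frames, must precede all tested frames).
#' @param smooth Smooth the trace (window 10, order 2) before crossing
#'   detection; set `FALSE` to test the raw samples.
#' @param cell_id Identifier copied into the output.
#' @return One-row tibble `responder_call`: `cell_id`, `responder`,
#'   `threshold`, `first_crossing_frame` (`NA` for non-responders).
#' @export
classify_responder <- function(values, baseline_window, smooth = TRUE,
                               cell_id = NA) {
  bw <- sort(unique(as.integer(baseline_window)))
  if (length(bw) < 5L) abort("Baseline window must span at least 5 frames.")
  if (max(bw) >= length(values)) {
    abort("Baseline window must precede the tested frames.")
  }
  base <- values[bw]
  s <- sd_pop(base)
  if (s == 0) abort("Degenerate baseline: SD is zero.")
  thr <- mean(base) + 3 * s
  test_vals <- if (smooth) {
    smooth_normalize(values, window_pts = 10L, poly_order = 2L,
                     background = 0, norm_ref = NA)
  } else values
  post <- seq(max(bw) + 1L, length(values))
  above <- post[which(test_vals[post] > thr)]
  tibble(cell_id = cell_id,
         responder = length(above) > 0L,
         threshold = thr,
         first_crossing_frame = if (length(above)) min(above) else NA_integer_)
}

#' Null exceedance probability of the baseline threshold
#'
#' Exact per-sample probability that an i.i.d. Gaussian sample exceeds
#' `mean + 3 * SD` estimated from `n_baseline` baseline samples (population
#' SD).  Writing the studentized statistic shows this equals a Student-t
#' tail, `P(t_{n-1} > 3 * sqrt((n-1)/(n+1)))`; as the baseline grows it
#' converges to the one-tailed 3-sigma level `1 - pnorm(3) = 0.00135`
#' (often quoted rounded as p = 0.0015).
#'
#' @param n_baseline Number of baseline frames; `Inf` gives the asymptotic
#'   3-sigma tail.
#' @export
responder_null_rate <- function(n_baseline = Inf) {
  if (is.infinite(n_baseline)) return(pnorm(3, lower.tail = FALSE))
  nb <- as.integer(n_baseline)
  pt(3 * sqrt((nb - 1) / (nb + 1)), df = nb - 1, lower.tail = FALSE)
}

#' Image-area based response fraction
#'
#' Quantifies the fraction of the field responding to exposure without
#' tracking individual cells:
#' 1. a threshold `t = mean + 3 * SD` is derived over the 95% dimmest ROI
#'    pixels of a pre-exposure reference frame (ties at the 95th percentile
#'    included);
#' 2. every frame is median filtered (radius 1) and pixels above `t` inside
#'    the ROI form the response mask;
#' 3. the pre-exposure positive mask (last pre-exposure frame for
#'    time-lapses, union over all pre-exposure planes for z-stacks) is
#'    dilated (default 6 steps, 3x3 square) to absorb drift and expansion
#'    of pre-existing features;
#' 4. the dilated pre-mask is subtracted from every frame mask;
#' 5. the response fraction is the remaining positive area over the
#'    corrected ROI area: the ROI minus the pixels positive *prior to*
#'    exposure (the undilated pre-mask; the dilation only widens the
#'    subtraction in step 4, so that the fraction can never grow when the
#'    dilation margin is widened).
#'
#' @param movie An [image_stack()] (`axis_kind` `"t"` or `"z"`).
#' @param channel Channel index or name.
#' @param roi `mp_roi` drawn over the evaluated field.
#' @param pre_exposure Integer plane indices acquired before exposure.
#' @param dilate_steps Dilation passes applied to the pre-exposure mask.
#' @param median_radius_px Median filter radius for the per-frame masks.
#' @param dim_fraction Fraction of dimmest ROI pixels defining the
#'   threshold statistics (default 0.95).
#' @return An `area_response` tibble with `frame`, `fraction`, plus
#'   attributes `threshold_t`, `pre_mask` (dilated), `corrected_area_px`.
#' @export
area_response_fraction <- function(movie, channel = 1L, roi, pre_exposure,
                                   dilate_steps = 6L, median_radius_px = 1L,
                                   dim_fraction = 0.95) {
  channel <- resolve_channel(movie, channel)
  d <- dim(movie$pixels)
  check_roi_fits(roi, d[3], d[4])
  pre_exposure <- sort(unique(as.integer(pre_exposure)))
  if (length(pre_exposure) == 0L || any(pre_exposure < 1) ||
      any(pre_exposure > d[2])) {
    abort("`pre_exposure` must be a non-empty set of valid plane indices.")
  }
  # threshold from the designated pre-exposure reference frame
  ref_frame <- get_plane(movie, channel, max(pre_exposure))
  rv <- ref_frame[roi$mask]
  qcut <- quantile(rv, dim_fraction, names = FALSE)
  dim_px <- rv[rv <= qcut]
  thr <- mean(dim_px) + 3 * sd_pop(dim_px)

  frame_mask <- function(p) {
    f <- median_filter(get_plane(movie, channel, p), median_radius_px)
    (f > thr) & roi$mask
  }
  pre_src <- if (movie$axis_kind == "z") pre_exposure else max(pre_exposure)
  pre_mask0 <- Reduce(`|`, lapply(pre_src, frame_mask))
  pre_mask <- pre_mask0
  if (dilate_steps > 0L) {
    brush <- EBImage::makeBrush(3L, shape = "box")
    for (i in seq_len(dilate_steps)) {
      pre_mask <- as.matrix(
        EBImage::dilate(EBImage::Image(pre_mask * 1), brush)) > 0
    }
  }
  corrected_area <- sum(roi$mask) - sum(pre_mask0 & roi$mask)
  if (corrected_area <= 0L || all(pre_mask[roi$mask])) {
    abort("Pre-exposure positive mask covers the whole ROI.")
  }
  frac <- map_dbl(seq_len(d[2]), function(p) {
    m <- frame_mask(p) & !pre_mask
    sum(m) / corrected_area
  })
  out <- tibble(frame = seq_len(d[2]), fraction = frac)
  structure(out, class = c("area_response", class(out)),
            threshold_t = thr, pre_mask = pre_mask,
            corrected_area_px = corrected_area)
}

#' Peak response fraction during exposure
#'
#' The exposure-induced positive-cell fraction of a measurement is the
#' maximum per-frame response fraction reached inside the exposure window.
#'
#' @param response An `area_response` from [area_response_fraction()].
#' @param exposure_window Integer frame indices of the exposure period.
#' @return One-row tibble with `fraction_max` and `frame_at_max`.
#' @export
gcamp_fraction_summary <- function(response, exposure_window) {
  w <- intersect(as.integer(exposure_window), response$frame)
  if (length(w) == 0L) abort("Exposure window is empty.")
  f <- response$fraction[match(w, response$frame)]
  tibble(fraction_max = max(f), frame_at_max = w[which.max(f)])
}

#' Compare response fractions between exposure groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between two groups of
#' per-measurement response fractions, with box-plot summaries (median,
#' 25/75 and 5/95 percentiles).
#'
#' @param group_a,group_b Numeric vectors of response fractions (n >= 3
#'   each).
#' @return List with `p_value`, `test` (the `htest` object) and `summary`
#'   (one tibble row per group).
#' @export
compare_exposure_groups <- function(group_a, group_b) {
  if (length(group_a) < 3L || length(group_b) < 3L) {
    abort("Each group needs at least 3 measurements.")
  }
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided", exact = NULL))
  # fully tied samples give a 0/0 normal approximation; no evidence at all
  if (is.nan(ht$p.value)) ht$p.value <- 1
  qs <- function(x, g) {
    q <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    tibble(group = g, n = length(x), q05 = q[1], q25 = q[2],
           median = q[3], q75 = q[4], q95 = q[5])
  }
  list(p_value = ht$p.value, test = ht,
       summary = bind_rows(qs(group_a, "a"), qs(group_b, "b")))
}
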