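#' SNR-versus-depth profile of an image stack
#'
#' For every plane, the signal `I_mean` is the mean of the brightest
#' `top_fraction` of pixels in the median-filtered plane
#' ([select_bright_pixels()]); the background mean and SD come from a dark
#' ROI of the *unfiltered* stack ([background_stats()]); and
#' `SNR = (I_mean - B_mean) / sigma_B`.  Use `top_fraction = 0.01` for
#' harmonic-generation signals, `0.10` for nuclear labels and `0.40` for
#' cytosolic labels (with median radii 1 and 2, respectively).
#'
#' @param stack An [image_stack()] with `axis_kind = "z"`.
#' @param channel Channel index or name.
#' @param top_fraction Bright-pixel fraction for the signal estimate.
#' @param median_radius_px Median pre-filter radius.
#' @param background_roi `mp_roi` over a dark region.
#' @param per_plane_background If `TRUE` (default) background statistics are
#'   computed per plane, else pooled over the whole stack.
#' @param order_n Assumed order of the excitation process (2, 3 or 4),
#'   carried along for the attenuation analysis; may be `NA`.
#' @return A `depth_profile` tibble with columns `depth_um`, `i_mean`,
#'   `b_mean`, `sigma_b`, `snr`, `energy_nj`.
#' @export
snr_profile <- function(stack, channel = 1L, top_fraction = 0.1,
                        median_radius_px = 2L, background_roi,
                        per_plane_background = TRUE, order_n = NA) {
  channel <- resolve_channel(stack, channel)
  np <- n_planes(stack)
  sig <- map(seq_len(np), function(p) {
    select_bright_pixels(get_plane(stack, channel, p), top_fraction,
                         median_radius_px)
  })
  bg <- background_stats(stack, channel, background_roi,
                         per_plane = per_plane_background)
  b_mean <- if (per_plane_background) bg$b_mean else rep(bg$b_mean, np)
  sigma_b <- if (per_plane_background) bg$sigma_b else rep(bg$sigma_b, np)
  if (any(sigma_b == 0)) {
    abort("Degenerate background: sigma_B is zero in at least one plane.")
  }
  i_mean <- map_dbl(sig, "i_mean")
  if (any(b_mean > i_mean)) {
    warn("Background mean exceeds the signal mean at some depths; check the background ROI.")
  }
  energy <- stack$meta$per_plane_energy_nj %||% rep(NA_real_, np)
  out <- tibble(depth_um = plane_coords(stack),
                i_mean = i_mean, b_mean = b_mean, sigma_b = sigma_b,
                snr = (i_mean - b_mean) / sigma_b,
                energy_nj = energy)
  structure(out, class = c("depth_profile", class(out)),
            channel = stack$channel_names[channel], order_n = order_n)
}

#' SNR along a pixel path
#'
#' Elementwise `SNR = (I_line - B_mean) / sigma_B` along a line profile.
#'
#' @param image Numeric matrix.
#' @param line Two-column matrix or data frame of `(y, x)` pixel indices.
#' @param b_mean,sigma_b Background mean and SD.
#' @return Tibble with `y`, `x`, `intensity`, `snr`.
#' @export
snr_line_profile <- function(image, line, b_mean, sigma_b) {
  if (sigma_b == 0) abort("Degenerate background: sigma_B is zero.")
  line <- as.matrix(line)[, 1:2, drop = FALSE]
  if (any(line[, 1] < 1 | line[, 1] > nrow(image) |
          line[, 2] < 1 | line[, 2] > ncol(image))) {
    abort("Line path extends outside the image.")
  }
  vals <- image[cbind(line[, 1], line[, 2])]
  tibble(y = line[, 1], x = line[, 2], intensity = vals,
         snr = (vals - b_mean) / sigma_b)
}

#' SNR-limited imaging depth
#'
#' The depth of the last crossing of the SNR curve from at-or-above to
#' below the detection threshold (default `SNR = 3`), linearly interpolated
#' between the bracketing grid depths.
#'
#' @param profile A `depth_profile` (or tibble with `depth_um`, `snr`).
#' @param snr_threshold Detection threshold.
#' @return One-row tibble with `depth_limit_um` and `status`:
#'   `"crossed"` (interpolated limit), `"not_limited"` (SNR never drops
#'   below the threshold; the deepest measured depth is returned) or
#'   `"undetected"` (SNR never reaches the threshold; limit is `NA`).
#' @export
depth_limit <- function(profile, snr_threshold = 3) {
  z <- profile$depth_um; s <- profile$snr
  if (length(z) == 0) abort("Empty profile.")
  if (all(s < snr_threshold)) {
    return(tibble(depth_limit_um = NA_real_, status = "undetected"))
  }
  k <- length(z)
  cross <- which(s[-k] >= snr_threshold & s[-1] < snr_threshold)
  if (length(cross) == 0L) {
    return(tibble(depth_limit_um = z[k], status = "not_limited"))
  }
  i <- max(cross)
  zlim <- z[i] + (s[i] - snr_threshold) / (s[i] - s[i + 1]) * (z[i + 1] - z[i])
  tibble(depth_limit_um = zlim, status = "crossed")
}

#' Axial-resolution score from intensity z-profiles
#'
#' For each fixed-size feature ROI the mean-over-ROI intensity z-profile is
#' extracted, min-max normalized to `[0, 1]` and differentiated (central
#' finite differences in the interior, one-sided at the profile ends,
#' divided by the plane step).  The maximum absolute slope
#' `(dI/dz)_max` (1/um) is a relative measure of axial resolution: the
#' sharper the axial transition of a feature, the larger the slope.
#' Features with flat profiles are excluded with a warning.
#'
#' @param stack An [image_stack()] with `axis_kind = "z"`.
#' @param channel Channel index or name.
#' @param feature_rois List of `mp_roi`s, one per fluorescent feature.
#' @param depth_window_um Optional `c(min, max)` depth window to analyse.
#' @return A `resolution_summary` object; [tidy()] returns the per-feature
#'   slopes, [glance()] the median/SD summary.
#' @export
axial_resolution <- function(stack, channel = 1L, feature_rois,
                             depth_window_um = NULL) {
  channel <- resolve_channel(stack, channel)
  z <- plane_coords(stack)
  keep <- if (is.null(depth_window_um)) rep(TRUE, length(z)) else {
    z >= depth_window_um[1] & z <= depth_window_um[2]
  }
  if (sum(keep) < 5L) {
    abort("Need at least 5 planes inside the depth window.")
  }
  zw <- z[keep]
  slopes <- map_dbl(feature_rois, function(roi) {
    d <- dim(stack$pixels)
    check_roi_fits(roi, d[3], d[4])
    prof <- map_dbl(which(keep), function(p) {
      mean(stack$pixels[channel, p, , ][roi$mask])
    })
    rng <- range(prof)
    if (diff(rng) == 0) return(NA_real_)
    prof <- (prof - rng[1]) / diff(rng)
    max(abs(finite_diff(prof, stack$plane_step)))
  })
  if (anyNA(slopes)) {
    warn(sprintf("%d feature(s) with flat z-profiles excluded.",
                 sum(is.na(slopes))))
  }
  ok <- slopes[!is.na(slopes)]
  if (length(ok) < 11L || length(ok) > 17L) {
    inform(sprintf(
      "%d usable features; resolution summaries are typically derived from 11-17 features per channel.",
      length(ok)))
  }
  structure(
    list(per_feature_max_slope = ok,
         median = median(ok), sd = sd_pop(ok),
         depth_window_um = depth_window_um %||% range(zw),
         n_features = length(ok)),
    class = "resolution_summary")
}

# central differences in the interior, one-sided at the ends
finite_diff <- function(y, step) {
  k <- length(y)
  d <- numeric(k)
  if (k >= 3) d[2:(k - 1)] <- (y[3:k] - y[1:(k - 2)]) / (2 * step)
  d[1] <- (y[2] - y[1]) / step
  d[k] <- (y[k] - y[k - 1]) / step
  d
}

#' @export
print.resolution_summary <- function(x, ...) {
  cat(sprintf(
    "<resolution_summary> %d features, (dI/dz)_max median %.3f +/- %.3f 1/um in [%g, %g] um\n",
    x$n_features, x$median, x$sd, x$depth_window_um[1], x$depth_window_um[2]))
  invisible(x)
}

#' @export
tidy.resolution_summary <- function(x, ...) {
  tibble(feature = seq_along(x$per_feature_max_slope),
         max_slope_per_um = x$per_feature_max_slope)
}

#' @export
glance.resolution_summary <- function(x, ...) {
  tibble(median_slope = x$median, sd_slope = x$sd,
         n_features = x$n_features,
         window_min_um = x$depth_window_um[1],
         window_max_um = x$depth_window_um[2])
}

#' Power- and order-normalized attenuation signal
#'
#' Converts a depth profile into the normalized signal
#' `S(z) = N * ((I_mean - B_mean) / P^n)^(1/n)`:
#' background-subtracted intensities are divided by the n-th power of the
#' applied excitation energy and compressed by the `1/n` exponent, so that
#' ballistic attenuation of the *excitation* light appears as a single
#' exponential `exp(-z / l_e)` regardless of the applied power ramp.  `N`
#' is chosen so that the first in-window value equals 1 unless given.
#'
#' @param profile A `depth_profile` with a complete `energy_nj` column.
#' @param order_n Order of the excitation process (2, 3 or 4); defaults to
#'   the profile's `order_n` attribute.
#' @param b_mean Optional scalar background override.  The deepest-frame
#'   average ([last_frame_background()]) is the conventional choice for
#'   attenuation analysis; by default the profile's per-depth `b_mean` is
#'   used.
#' @param fit_window_um Optional `c(min, max)` depth window; points outside
#'   get `s_norm = NA`.
#' @param norm_const Optional explicit normalization constant `N`.
#' @return The profile with an added `s_norm` column (class
#'   `attenuation_profile`).  Points with `i_mean <= b_mean` inside the
#'   window are masked to `NA` with a warning.
#' @export
attenuation_signal <- function(profile, order_n = NULL, b_mean = NULL,
                               fit_window_um = NULL, norm_const = NULL) {
  order_n <- order_n %||% attr(profile, "order_n")
  if (is.null(order_n) || is.na(order_n) || !(order_n %in% 2:4)) {
    abort("`order_n` must be 2, 3 or 4.")
  }
  if (anyNA(profile$energy_nj)) {
    abort("`energy_nj` must be present for every depth.")
  }
  b <- b_mean %||% profile$b_mean
  z <- profile$depth_um
  inwin <- if (is.null(fit_window_um)) rep(TRUE, length(z)) else {
    z >= fit_window_um[1] & z <= fit_window_um[2]
  }
  net <- profile$i_mean - b
  bad <- inwin & net <= 0
  if (any(bad)) {
    warn(sprintf("%d point(s) with I_mean <= B_mean masked.", sum(bad)))
  }
  s_raw <- ifelse(inwin & net > 0,
                  (net / profile$energy_nj^order_n)^(1 / order_n),
                  NA_real_)
  nconst <- norm_const %||% (1 / s_raw[which(!is.na(s_raw))[1]])
  out <- mutate(as_tibble(profile), s_norm = nconst * s_raw)
  structure(out,
            class = c("attenuation_profile", "depth_profile", class(out)),
            order_n = order_n, channel = attr(profile, "channel"),
            norm_const = nconst)
}

#' Background estimate from the deepest frame
#'
#' Mean over all pixels of the last plane of the stack, the conventional
#' background for attenuation curves (at the deepest plane the signal has
#' decayed into the noise floor).
#'
#' @param stack An [image_stack()].
#' @param channel Channel index or name.
#' @export
last_frame_background <- function(stack, channel = 1L) {
  mean(get_plane(stack, channel, n_planes(stack)))
}

#' Fit the effective attenuation length
#'
#' Least-squares fit of `S(z) = A * exp(-z / l_e)` to a normalized
#' attenuation signal.  For an n-photon process the raw intensity then
#' decays as `exp(-n z / l_e)`: one effective attenuation length
#' corresponds to a 1/e^n drop of the n-photon-excited intensity (1/e^3 for
#' three-photon signals), because `S` carries the `1/n` exponent.
#'
#' @param s An `attenuation_profile` (or tibble with `depth_um`, `s_norm`).
#' @param fit_window_um Optional `c(min, max)` depth window.
#' @return An `attenuation_fit` with `l_e_um`, `l_e_se`, `a`, `n_used`,
#'   `fit_window_um`, `norm_const`.
#' @export
fit_attenuation <- function(s, fit_window_um = NULL) {
  dat <- as_tibble(s)
  stopifnot(all(c("depth_um", "s_norm") %in% names(dat)))
  if (!is.null(fit_window_um)) {
    dat <- dplyr::filter(dat, .data$depth_um >= fit_window_um[1],
                         .data$depth_um <= fit_window_um[2])
  }
  dat <- dplyr::filter(dat, is.finite(.data$s_norm), .data$s_norm > 0)
  if (nrow(dat) < 4L) abort("Need at least 4 points inside the fit window.")
  # log-linear start
  cf <- unname(stats::lm.fit(cbind(1, dat$depth_um),
                             log(dat$s_norm))$coefficients)
  le0 <- if (cf[2] < 0) -1 / cf[2] else diff(range(dat$depth_um))
  fit <- tryCatch(
    minpack.lm::nlsLM(s_norm ~ A * exp(-depth_um / le), data = dat,
                      start = list(A = exp(cf[1]), le = le0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf("Attenuation fit failed: %s", conditionMessage(e)))
    })
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  structure(
    list(l_e_um = unname(est["le"]), l_e_se = unname(se[2]),
         a = unname(est["A"]), a_se = unname(se[1]),
         n_used = attr(s, "order_n") %||% NA,
         fit_window_um = fit_window_um %||% range(dat$depth_um),
         norm_const = attr(s, "norm_const") %||% NA_real_,
         n_points = nrow(dat), data = dat),
    class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "<attenuation_fit> l_e = %.1f +/- %.1f um (A = %.3g, %d points in [%g, %g] um)\n",
    x$l_e_um, x$l_e_se, x$a, x$n_points,
    x$fit_window_um[1], x$fit_window_um[2]))
  invisible(x)
}

#' @export
tidy.attenuation_fit <- function(x, ...) {
  tibble(term = c("A", "l_e_um"),
         estimate = c(x$a, x$l_e_um),
         std.error = c(x$a_se, x$l_e_se))
}

#' @export
glance.attenuation_fit <- function(x, ...) {
  tibble(l_e_um = x$l_e_um, l_e_se = x$l_e_se, a = x$a,
         n_used = x$n_used, n_points = x$n_points)
}

#' Photobleaching curve of a time-lapse recording
#'
#' Per scan: mean filter (disc, radius `mean_radius_px`), selection of
#' bright cell pixels by automatic thresholding restricted to `roi`, their
#' mean intensity minus the background (mean over a user-designated dark
#' region), yielding the background-subtracted signal versus scan index and
#' the percentage decline relative to the first scan.
#'
#' @param timelapse An [image_stack()] with `axis_kind = "t"` (one plane
#'   per scan; z-projected upstream if the recording was 3-D).
#' @param channel Channel index or name.
#' @param roi `mp_roi` restricting the cell-pixel selection.
#' @param background_roi `mp_roi` over the darkest region.
#' @param threshold_method Automatic threshold method (`"huang"`,
#'   `"isodata"` or `"otsu"`).
#' @param mean_radius_px Mean pre-filter radius.
#' @return Tibble with `scan`, `signal`, `pct_decline`
#'   (`100 * (1 - S_k / S_1)`).
#' @export
bleaching_curve <- function(timelapse, channel = 1L, roi, background_roi,
                            threshold_method = c("huang", "isodata", "otsu"),
                            mean_radius_px = 2L) {
  threshold_method <- match.arg(threshold_method)
  channel <- resolve_channel(timelapse, channel)
  np <- n_planes(timelapse)
  if (np < 2L) abort("Need at least 2 time points.")
  d <- dim(timelapse$pixels)
  check_roi_fits(roi, d[3], d[4])
  check_roi_fits(background_roi, d[3], d[4])
  sig <- map_dbl(seq_len(np), function(p) {
    fr <- mean_filter_disk(get_plane(timelapse, channel, p), mean_radius_px)
    sel <- auto_threshold_mask(fr, threshold_method)$mask & roi$mask
    if (!any(sel)) abort(sprintf("Empty cell selection at scan %d.", p))
    bg <- mean(get_plane(timelapse, channel, p)[background_roi$mask])
    mean(fr[sel]) - bg
  })
  tibble(scan = seq_len(np), signal = sig,
         pct_decline = 100 * (1 - sig / sig[1]))
}
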