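#' Power-series recording
#'
#' An ordered set of single-plane images acquired at varying excitation
#' pulse energy, each immediately followed by a reference image taken at a
#' fixed low energy (`bleach_energy_nj`).  The reference images track
#' photobleaching so the energy dependence of the signal can be separated
#' from fluorophore loss.
#'
#' @param frames List of numeric matrices, one per excitation energy.
#' @param energies_nj Excitation pulse energy per frame, nJ (> 0).
#' @param bleach_frames List of reference matrices, paired with `frames`
#'   (reference k was recorded right after frame k).
#' @param bleach_energy_nj The fixed reference energy, nJ.
#' @param roi `mp_roi` selecting the bright (signal) pixels.
#' @param background_roi `mp_roi` over a dark region of the frames.
#' @return A `power_series` object.
#' @export
power_series <- function(frames, energies_nj, bleach_frames, bleach_energy_nj,
                         roi, background_roi) {
  if (length(frames) != length(energies_nj) ||
      length(frames) != length(bleach_frames)) {
    abort("`frames`, `energies_nj` and `bleach_frames` must have equal length.")
  }
  if (any(energies_nj <= 0) || bleach_energy_nj <= 0) {
    abort("All excitation energies must be > 0.")
  }
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  check_roi_fits(roi, ny, nx)
  check_roi_fits(background_roi, ny, nx)
  structure(list(frames = frames, energies_nj = energies_nj,
                 bleach_frames = bleach_frames,
                 bleach_energy_nj = bleach_energy_nj,
                 roi = roi, background_roi = background_roi),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf(
    "<power_series> %d frames, E in [%.3g, %.3g] nJ, reference at %.3g nJ\n",
    length(x$frames), min(x$energies_nj), max(x$energies_nj),
    x$bleach_energy_nj))
  invisible(x)
}

#' Normalize a power series for power-law fitting
#'
#' Computes, per frame k, the normalized, bleaching-corrected,
#' background-subtracted signal
#' `S_k = F_norm * (I_mean,k - B_mean,k) / (I_ref,k - B_ref,k)`,
#' where the numerator statistics come from frame k and the denominator from
#' its paired reference frame.  Because every frame is divided by a
#' reference acquired at the same bleaching state, fluorophore loss cancels
#' exactly for any bleaching kinetics that act multiplicatively on the
#' signal.  By default `F_norm` is chosen so that `max(S) = 1`.
#'
#' Signal uncertainties are propagated in quadrature from the standard
#' errors of the four region means; the energy uncertainty is a relative
#' measurement error (`rel_p_err`, default 3%).
#'
#' @param series A [power_series()].
#' @param f_norm Normalization constant; `NULL` (default) scales the
#'   maximum S to 1.
#' @param rel_p_err Relative uncertainty of the energy readings.
#' @param bleach_correct Set to `FALSE` to skip the reference division
#'   (used to demonstrate the bleaching bias; the result is then
#'   `F_norm * (I_mean - B_mean)`).
#' @return A `normalized_series` tibble with columns `energy_nj`, `s`,
#'   `s_err`, `p_err` and attributes `f_norm`, `bleach_energy_nj`.
#' @export
normalize_power_series <- function(series, f_norm = NULL, rel_p_err = 0.03,
                                   bleach_correct = TRUE) {
  stopifnot(inherits(series, "power_series"))
  sig <- roi_mean_se(series$frames, series$roi)
  bg <- roi_mean_se(series$frames, series$background_roi)
  num <- sig$mean - bg$mean
  var_num <- sig$se2 + bg$se2
  if (bleach_correct) {
    rsig <- roi_mean_se(series$bleach_frames, series$roi)
    rbg <- roi_mean_se(series$bleach_frames, series$background_roi)
    den <- rsig$mean - rbg$mean
    bad <- which(den <= 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "Bleach correction failed: non-positive reference signal in frame(s) %s.",
        paste(bad, collapse = ", ")))
    }
    var_den <- rsig$se2 + rbg$se2
    s_raw <- num / den
    # relative errors of numerator and denominator in quadrature
    s_err_raw <- abs(s_raw) * sqrt(var_num / num^2 + var_den / den^2)
  } else {
    s_raw <- num
    s_err_raw <- sqrt(var_num)
  }
  f <- f_norm %||% (1 / max(s_raw))
  out <- tibble(energy_nj = series$energies_nj,
                s = f * s_raw, s_err = f * s_err_raw,
                p_err = rel_p_err * series$energies_nj)
  structure(out, class = c("normalized_series", class(out)),
            f_norm = f, bleach_energy_nj = series$bleach_energy_nj)
}

# mean and squared standard error of the ROI pixels of each frame
roi_mean_se <- function(frames, roi) {
  m <- map_dbl(frames, function(fr) mean(fr[roi$mask]))
  se2 <- map_dbl(frames, function(fr) {
    v <- fr[roi$mask]
    sd_pop(v)^2 / length(v)
  })
  list(mean = m, se2 = se2)
}

#' Fit the excitation power law S = A * E^n
#'
#' Determines the order `n` of the nonlinear excitation process by fitting
#' the power law with orthogonal distance regression (ODR): both the energy
#' and the signal uncertainties enter the fit.  The chi-square that is
#' minimized over `A`, `n` and latent true energies `p_i` is
#' `sum((P_i - p_i)^2 / p_err_i^2 + (S_i - A p_i^n)^2 / s_err_i^2)`,
#' initialized from an ordinary log-log least-squares fit.  Standard errors
#' come from the curvature of the chi-square at the minimum, scaled by the
#' reduced chi-square (the ODRPACK convention).
#'
#' @param ns A `normalized_series` from [normalize_power_series()], or any
#'   tibble with columns `energy_nj`, `s`, `s_err`, `p_err`.
#' @param fit_range_nj Optional `c(min, max)` energy window; points outside
#'   (below a damage threshold, above a saturation limit) are excluded
#'   before fitting.
#' @return A `power_law_fit` object with elements `a`, `a_se`, `n`, `n_se`,
#'   `red_chisq`, `adj_r2`, `fit_range_nj`, `n_points` and the fitted data.
#' @export
fit_power_law <- function(ns, fit_range_nj = NULL) {
  dat <- as_tibble(ns)
  stopifnot(all(c("energy_nj", "s") %in% names(dat)))
  if (is.null(dat$s_err)) dat$s_err <- NA_real_
  if (is.null(dat$p_err)) dat$p_err <- NA_real_
  if (!is.null(fit_range_nj)) {
    dat <- dplyr::filter(dat, .data$energy_nj >= fit_range_nj[1],
                         .data$energy_nj <= fit_range_nj[2])
  }
  if (nrow(dat) < 4L) {
    abort("Need at least 4 points inside the fit range.")
  }
  if (any(dat$energy_nj <= 0) || any(dat$s <= 0)) {
    abort("All energies and signals inside the fit range must be > 0.")
  }
  P <- dat$energy_nj; S <- dat$s
  # uncertainty floors: zero/missing errors would make the chi-square
  # singular; fall back to a small relative scale
  sp <- ifelse(is.finite(dat$p_err) & dat$p_err > 0, dat$p_err, 1e-4 * P)
  ss0 <- ifelse(is.finite(dat$s_err) & dat$s_err > 0, dat$s_err, NA_real_)
  ss <- ifelse(is.na(ss0), 1e-4 * pmax(S, max(S) * 1e-3), ss0)

  # log-log OLS starting point
  ll <- stats::lm.fit(cbind(1, log(P)), log(S))
  th0 <- c(logA = unname(ll$coefficients[1]), n = unname(ll$coefficients[2]),
           log(P))
  negfun <- function(th) {
    a <- exp(th[1]); nn <- th[2]; p <- exp(th[-(1:2)])
    sum((P - p)^2 / sp^2 + (S - a * p^nn)^2 / ss^2)
  }
  opt <- optim(th0, negfun, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0) {
    abort(sprintf("ODR power-law fit did not converge (optim code %d).",
                  opt$convergence))
  }
  chisq <- opt$value
  k <- nrow(dat)
  dof <- k - 2L
  red_chisq <- chisq / dof
  # covariance of (logA, n) from the chi-square curvature
  H <- opt$hessian
  cov_all <- tryCatch(solve(H / 2), error = function(e) NULL)
  if (!is.null(cov_all)) {
    scale <- max(red_chisq, 0)
    logA_se <- sqrt(max(cov_all[1, 1], 0) * scale)
    n_se <- sqrt(max(cov_all[2, 2], 0) * scale)
  } else {
    logA_se <- n_se <- NA_real_
  }
  a <- unname(exp(opt$par[1])); n_hat <- unname(opt$par[2])
  a_se <- a * logA_se
  pred <- a * P^n_hat
  ss_res <- sum((S - pred)^2)
  ss_tot <- sum((S - mean(S))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (k - 1) / (k - 2)
  structure(
    list(a = a, a_se = a_se, n = n_hat, n_se = unname(n_se),
         red_chisq = red_chisq, adj_r2 = adj_r2,
         fit_range_nj = fit_range_nj %||% range(P),
         n_points = k, data = dat),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> S = A * E^n: n = %.3f +/- %.3f, A = %.4g +/- %.3g\n",
    x$n, x$n_se, x$a, x$a_se))
  cat(sprintf("  %d points in [%.3g, %.3g] nJ; red. chi-sq %.3g, adj. R2 %.5f\n",
              x$n_points, x$fit_range_nj[1], x$fit_range_nj[2],
              x$red_chisq, x$adj_r2))
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("A", "n"),
         estimate = c(x$a, x$n),
         std.error = c(x$a_se, x$n_se))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(n = x$n, n_se = x$n_se, a = x$a, a_se = x$a_se,
         red_chisq = x$red_chisq, adj_r2 = x$adj_r2, n_points = x$n_points)
}

#' Quality gate for power-law fits
#'
#' A fit is accepted when its reduced chi-square is below `max_red_chisq`
#' and its adjusted R-square is above `min_adj_r2` (defaults 2 and 0.995).
#'
#' @param fit A `power_law_fit`.
#' @param max_red_chisq Upper bound on the reduced chi-square.
#' @param min_adj_r2 Lower bound on the adjusted R-square.
#' @return One-row tibble with `pass` (logical) and `reasons` (comma-joined
#'   failing criteria, empty when passing).
#' @export
qc_fit <- function(fit, max_red_chisq = 2, min_adj_r2 = 0.995) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (!is.finite(fit$red_chisq) || !is.finite(fit$adj_r2)) {
    abort("Fit statistics must be finite.")
  }
  reasons <- character()
  if (!(fit$red_chisq < max_red_chisq)) reasons <- c(reasons, "red_chisq")
  if (!(fit$adj_r2 > min_adj_r2)) reasons <- c(reasons, "adj_r2")
  tibble(pass = length(reasons) == 0L,
         reasons = paste(reasons, collapse = ","))
}
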