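test_that("SNR profile reproduces hand arithmetic", {
  # plane with bright block 40, background 10, sigma_B forced via two values
  px <- array(10, dim = c(1, 1, 8, 8))
  px[1, 1, 1:2, ] <- 40
  px[1, 1, 7, 1:2] <- c(7, 13)   # background ROI pixels {7,13,10,10}: sd 2.12
  s <- image_stack(px)
  roi <- roi_rect(7, 1, 1, 4, c(8, 8))
  prof <- suppressWarnings(
    snr_profile(s, 1, top_fraction = 0.25, median_radius_px = 0,
                background_roi = roi))
  b <- c(7, 13, 10, 10)
  expect_equal(prof$i_mean, 40)
  expect_equal(prof$b_mean, mean(b))
  expect_equal(prof$sigma_b, sqrt(mean((b - mean(b))^2)))
  expect_equal(prof$snr, (40 - 10) / sqrt(4.5))
  # pure background plane gives SNR 0
  px0 <- array(10, dim = c(1, 1, 8, 8))
  px0[1, 1, 7, 1:2] <- c(7, 13)
  prof0 <- suppressWarnings(
    snr_profile(image_stack(px0), 1, top_fraction = 1, median_radius_px = 0,
                background_roi = roi_rect(1, 1, 8, 8, c(8, 8))))
  expect_equal(prof0$snr, 0, tolerance = 1e-12)
  # degenerate background errors
  expect_error(
    snr_profile(s, 1, background_roi = roi_rect(8, 5, 1, 4, c(8, 8))),
    "sigma_B")
})

test_that("line-profile SNR is elementwise", {
  img <- matrix(10, 6, 6)
  img[3, 1:5] <- c(10, 13, 16, 10, 25)
  line <- cbind(3, 1:5)
  out <- snr_line_profile(img, line, b_mean = 10, sigma_b = 3)
  expect_equal(out$snr, c(0, 1, 2, 0, 5))
  expect_error(snr_line_profile(img, line, 10, 0), "sigma_B")
  expect_error(snr_line_profile(img, cbind(9, 1), 10, 3), "outside")
})

test_that("depth limit interpolates the last threshold crossing", {
  prof <- tibble::tibble(depth_um = c(0, 100, 200), snr = c(10, 5, 2))
  lim <- depth_limit(prof, 3)
  expect_equal(lim$depth_limit_um, 100 + 2 / 3 * 100, tolerance = 1e-9)
  expect_equal(lim$status, "crossed")
  # all above threshold: deepest depth with flag
  above <- tibble::tibble(depth_um = c(0, 50, 100), snr = c(9, 8, 7))
  la <- depth_limit(above, 3)
  expect_equal(la$depth_limit_um, 100)
  expect_equal(la$status, "not_limited")
  # never detected
  below <- tibble::tibble(depth_um = c(0, 50), snr = c(2, 1))
  expect_equal(depth_limit(below, 3)$status, "undetected")
  # raising the threshold never deepens the limit
  set.seed(5)
  snr <- 30 * exp(-(0:20) / 6) + rnorm(21, 0, 0.1)
  p <- tibble::tibble(depth_um = (0:20) * 10, snr = snr)
  lims <- vapply(c(2, 3, 5, 8), function(t) {
    depth_limit(p, t)$depth_limit_um
  }, numeric(1))
  expect_true(all(diff(lims) <= 0))
})

test_that("axial resolution scores match finite-difference oracles", {
  # step 0 -> 1 across one 2.5 um step at the profile end: one-sided
  # difference gives 1 / 2.5 = 0.4 per um
  s <- uniform_plane_stack(c(0, 0, 0, 0, 1), plane_step = 2.5)
  roi <- roi_rect(2, 2, 3, 3, c(8, 8))
  res <- suppressMessages(axial_resolution(s, 1, list(roi)))
  expect_equal(res$per_feature_max_slope, 0.4)
  # normalized Gaussian profile: max slope ~ exp(-1/2)/sigma on fine grids
  zz <- seq(0, 40, by = 0.5)
  sig_z <- 4
  sg <- uniform_plane_stack(exp(-(zz - 20)^2 / (2 * sig_z^2)),
                            plane_step = 0.5)
  resg <- suppressMessages(axial_resolution(sg, 1, list(roi)))
  expect_equal(resg$per_feature_max_slope, exp(-0.5) / sig_z,
               tolerance = 0.05)
  # constant profiles are excluded with a warning
  sc <- uniform_plane_stack(rep(3, 6))
  expect_warning(suppressMessages(axial_resolution(sc, 1, list(roi, roi))),
                 "flat")
  expect_error(suppressMessages(
    axial_resolution(s, 1, list(roi), depth_window_um = c(0, 4))),
    "at least 5 planes")
})

test_that("axial slopes shrink as the generative axial PSF broadens", {
  meds <- vapply(c(1.5, 3, 6), function(sz) {
    sim <- make_depth_stack(scene_config(
      depths_um = seq(0, 60, by = 1), psf_sigma_axial_um = sz,
      n_features = 12, schedule = power_schedule(c(0, 60), c(1, 1)),
      l_e_um = 1e6, shot_noise = FALSE, read_sd = 0, seed = 31))
    rois <- lapply(seq_len(nrow(sim$truth$layout)), function(i) {
      roi_rect(round(sim$truth$layout$y[i]) - 1,
               round(sim$truth$layout$x[i]) - 1, 3, 3,
               dim(sim$stack$pixels)[3:4])
    })
    suppressMessages(axial_resolution(sim$stack, 1, rois))$median
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("attenuation signal linearizes the n-th order decay", {
  z <- seq(0, 300, by = 20)
  # constant P, I = exp(-3 z / 200) + B  ->  S proportional to exp(-z/200)
  prof <- profile_tbl(z, i_mean = 5 + 100 * exp(-3 * z / 200), b_mean = 5)
  s <- attenuation_signal(prof, order_n = 3)
  expect_equal(s$s_norm, exp(-z / 200), tolerance = 1e-10)
  # invariance to the excitation schedule given correct P^n division
  ramp <- exp(z / 150)
  prof2 <- profile_tbl(z, i_mean = 5 + 100 * ramp^3 * exp(-3 * z / 200),
                       b_mean = 5, energy_nj = ramp)
  s2 <- attenuation_signal(prof2, order_n = 3)
  expect_equal(s2$s_norm, s$s_norm, tolerance = 1e-10)
  # masked points and missing energies raise conditions
  prof3 <- profile_tbl(z, i_mean = c(rep(50, length(z) - 1), 1), b_mean = 5)
  expect_warning(attenuation_signal(prof3, order_n = 3), "masked")
  prof4 <- profile_tbl(z, 100, energy_nj = NA)
  expect_error(attenuation_signal(prof4, order_n = 3), "energy_nj")
})

test_that("attenuation fits recover l_e exactly and match the raw-decay fit", {
  z <- seq(0, 400, by = 10)
  s <- tibble::tibble(depth_um = z, s_norm = exp(-z / 200))
  fit <- fit_attenuation(s)
  expect_equal(fit$l_e_um, 200, tolerance = 1e-6)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  # generative: I = P^3 exp(-3 z / 150) + B through the full pipeline
  P <- exp(z / 300)
  prof <- profile_tbl(z, i_mean = 8 + 50 * P^3 * exp(-3 * z / 150),
                      b_mean = 8, energy_nj = P)
  fit2 <- fit_attenuation(attenuation_signal(prof, order_n = 3))
  expect_equal(fit2$l_e_um, 150, tolerance = 1e-6)
  # equivalence: fitting raw (I-B)/P^3 with A exp(-3 z / l_e) yields the
  # same l_e; on noiseless data the log-linear slope is an exact oracle
  raw <- (prof$i_mean - prof$b_mean) / prof$energy_nj^3
  le_oracle <- -3 / unname(coef(stats::lm(log(raw) ~ z))[2])
  expect_equal(fit2$l_e_um, le_oracle, tolerance = 1e-6)
  # two-layer tissue with per-layer windows (l_e 300 then 80)
  sim <- make_depth_stack(scene_config(
    l_e_um = c(300, 80), layer_boundaries_um = 150,
    depths_um = seq(0, 320, by = 5), seed = 17))
  prof2 <- snr_profile(sim$stack, background_roi = sim$truth$background_roi,
                       order_n = 3)
  s2 <- attenuation_signal(prof2, 3)
  f_top <- fit_attenuation(s2, fit_window_um = c(0, 145))
  f_bot <- fit_attenuation(s2, fit_window_um = c(155, 320))
  expect_equal(f_top$l_e_um, 300, tolerance = 0.1)
  expect_equal(f_bot$l_e_um, 80, tolerance = 0.1)
})

test_that("bleaching curves report percent decline and are scale invariant", {
  ny <- 24; nx <- 24
  r <- 1 - 0.75^(1 / 24)     # mono-exponential fade: 25% down at scan 25
  scans <- 30
  px <- array(0, dim = c(1, scans, ny, nx))
  for (k in seq_len(scans)) {
    fr <- matrix(10, ny, nx)
    fr[6:17, 6:17] <- 10 + 100 * (1 - r)^(k - 1)
    px[1, k, , ] <- fr
  }
  tl <- image_stack(px, axis_kind = "t", plane_step = 60)
  roi <- roi_rect(9, 9, 6, 6, c(ny, nx))        # block interior
  bg <- roi_rect(1, 1, 3, 3, c(ny, nx))
  curve <- bleaching_curve(tl, 1, roi, bg, threshold_method = "huang")
  expect_equal(curve$pct_decline[1], 0)
  expect_equal(curve$pct_decline[25], 25, tolerance = 1e-6)
  # constant movie: zero decline everywhere
  pxc <- array(0, dim = c(1, 5, ny, nx))
  for (k in 1:5) pxc[1, k, , ] <- px[1, 1, , ]
  cc <- bleaching_curve(image_stack(pxc, axis_kind = "t"), 1, roi, bg)
  expect_equal(cc$pct_decline, rep(0, 5))
  # two-fold intensity scaling leaves the percent decline unchanged
  tl2 <- tl; tl2$pixels <- tl$pixels * 2
  curve2 <- bleaching_curve(tl2, 1, roi, bg, threshold_method = "huang")
  expect_equal(curve2$pct_decline, curve$pct_decline, tolerance = 1e-9)
  expect_error(bleaching_curve(image_stack(px[, 1, , , drop = FALSE],
                                           axis_kind = "t"), 1, roi, bg),
               "at least 2")
})
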