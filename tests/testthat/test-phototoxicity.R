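test_that("trace extraction averages a disc neighbourhood", {
  # uniform frame: value equals the constant at any coordinate
  px <- array(7, dim = c(1, 2, 10, 10))
  mv <- image_stack(px, axis_kind = "t")
  tp <- tibble::tibble(frame = 1:2, cell_id = 1, compartment = "cytosol",
                       y_px = 5, x_px = 5)
  tr <- extract_traces(mv, 1, tp)
  expect_equal(tr$value, c(7, 7))
  # single bright pixel: the disc mean is below the pixel value
  px2 <- array(0, dim = c(1, 1, 11, 11))
  px2[1, 1, 6, 6] <- 130
  mv2 <- image_stack(px2, axis_kind = "t")
  tp2 <- tibble::tibble(frame = 1, cell_id = 1, compartment = "nucleus",
                        y_px = 6, x_px = 6)
  v <- extract_traces(mv2, 1, tp2)$value
  expect_equal(v, 130 / 13)    # 13 pixels in a radius-2 disc
  expect_lt(v, 130)
  # out-of-frame coordinates are masked with a warning
  tp3 <- tibble::tibble(frame = 1, cell_id = 1, compartment = "nucleus",
                        y_px = 50, x_px = 6)
  expect_warning(tr3 <- extract_traces(mv2, 1, tp3), "masked")
  expect_true(is.na(tr3$value))
})

test_that("extracted traces follow the generative intensity series", {
  vm <- make_viability_movie(viability_config(
    n_cells = 9, n_frames = 60, exposure_window = 21:50,
    weights = c(quiet = 1, spontaneous = 0, steep = 0, gradual = 0),
    seed = 5))
  tr <- extract_traces(vm$movie, "green", vm$tracks)
  cyt <- dplyr::filter(tr, compartment == "cytosol", cell_id == 1)
  expect_equal(mean(cyt$value), 40 + 5, tolerance = 0.05)  # level + bg
  expect_lt(sd(cyt$value), 3 * vm$truth$sd_eff)
})

test_that("sytox ratio cancels the shared indicator signal", {
  expect_equal(sytox_trace(c(50, 60), c(50, 60), 0), c(1, 1))
  expect_equal(sytox_trace(120, 70, 20), 2)
  # influx: nucleus ramp over constant cytosol is monotone
  nuc <- 50 + c(0, 0, 5, 15, 30, 50)
  cyt <- rep(50, 6)
  r <- sytox_trace(nuc, cyt, 10)
  expect_true(all(diff(r) >= 0))
  expect_warning(r2 <- sytox_trace(c(5, 5), c(5, 30), 10), "masked")
  expect_true(is.na(r2[1]))
})

test_that("Savitzky-Golay smoothing reproduces quadratics and normalizes", {
  x <- seq_len(40)
  quad <- 2 + 0.5 * x - 0.01 * x^2
  sm <- smooth_normalize(quad, window_pts = 10, poly_order = 2,
                         norm_ref = NA)
  inner <- 7:34   # away from the filter start-up region
  expect_equal(sm[inner], quad[inner], tolerance = 1e-8)
  cons <- smooth_normalize(rep(4, 30), norm_ref = NULL)
  expect_equal(cons, rep(1, 30), tolerance = 1e-8)
  expect_error(smooth_normalize(1:5), "exceed")
})

test_that("responder calls use the mean + 3 SD baseline threshold", {
  base <- c(95, 105, 100, 95, 105, 100, 95, 105, 100, 100)  # mean 100
  s <- sqrt(mean((base - mean(base))^2))
  post_hit <- c(rep(100, 10), 120)
  call <- classify_responder(c(base, post_hit), 1:10, smooth = FALSE)
  expect_equal(call$threshold, 100 + 3 * s)
  expect_true(call$responder)          # 120 > 112.1
  expect_equal(call$first_crossing_frame, 21)
  miss <- classify_responder(c(base, rep(100, 10), 111), 1:10,
                             smooth = FALSE)
  expect_false(miss$responder)         # 111 < 112.1
  expect_true(is.na(miss$first_crossing_frame))
  expect_error(classify_responder(c(rep(5, 20), 9), 1:20, smooth = FALSE),
               "Degenerate baseline")
  expect_error(classify_responder(1:10, 1:3), "at least 5")
})

test_that("the analytic null rate is the finite-baseline t tail", {
  expect_equal(responder_null_rate(Inf), 1 - pnorm(3))
  # converges to the 3-sigma level from above as the baseline grows
  rates <- vapply(c(10, 50, 200, 5000), responder_null_rate, numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_equal(rates[4], 1 - pnorm(3), tolerance = 0.02)
  # simulation check at n_baseline = 20
  set.seed(99)
  hits <- 0; tot <- 0
  for (i in 1:4000) {
    b <- rnorm(20); p <- rnorm(10)
    thr <- mean(b) + 3 * sqrt(mean((b - mean(b))^2))
    hits <- hits + sum(p > thr); tot <- tot + 10
  }
  p0 <- responder_null_rate(20)
  expect_lt(abs(hits / tot - p0), 3 * sqrt(p0 * (1 - p0) / tot))
})

test_that("area fractions match hand-enumerated mask arithmetic", {
  # 24 x 24 field; 4 x 4 cell A bright before exposure, disjoint 4 x 4
  # cell B appears after.  Median radius 1 turns each 4 x 4 block into a
  # 12-px block-minus-corners shape, so the pre-exposure positive area is
  # 12 px and the corrected ROI is 576 - 12 = 564.  The pre-mask dilated
  # 6x covers the 12 x 12 corner square minus its far corner (143 px) and
  # does not reach cell B, whose 12 px are the only new positives.
  pre <- matrix(10, 24, 24);  pre[3:6, 3:6] <- 200
  post <- pre;                post[17:20, 17:20] <- 200
  px <- array(0, dim = c(1, 3, 24, 24))
  px[1, 1, , ] <- pre; px[1, 2, , ] <- pre; px[1, 3, , ] <- post
  mv <- image_stack(px, axis_kind = "t")
  roi <- roi_rect(1, 1, 24, 24, c(24, 24))
  ar <- area_response_fraction(mv, 1, roi, pre_exposure = 1:2,
                               dilate_steps = 6)
  expect_equal(ar$fraction[1:2], c(0, 0))     # identical to pre-exposure
  expect_equal(ar$fraction[3], 12 / 564)
  expect_equal(attr(ar, "corrected_area_px"), 564)
  expect_equal(sum(attr(ar, "pre_mask")), 143)
  # 95% dimmest of 560 x value-10 and 16 x value-200 pixels are all 10
  expect_equal(attr(ar, "threshold_t"), 10)
})

test_that("area fractions shrink with dilation and survive affine rescaling", {
  set.seed(11)
  pre <- matrix(rpois(576, 10), 24, 24); pre[3:6, 3:6] <- 200
  post <- pre; post[15:19, 14:18] <- 180
  px <- array(0, dim = c(1, 2, 24, 24))
  px[1, 1, , ] <- pre; px[1, 2, , ] <- post
  mv <- image_stack(px, axis_kind = "t")
  roi <- roi_rect(1, 1, 24, 24, c(24, 24))
  fr <- vapply(c(0, 2, 4, 6, 8), function(k) {
    area_response_fraction(mv, 1, roi, 1, dilate_steps = k)$fraction[2]
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  # global affine rescaling re-derives the threshold: identical fractions
  mv2 <- mv; mv2$pixels <- 3 * mv$pixels + 40
  a1 <- area_response_fraction(mv, 1, roi, 1)
  a2 <- area_response_fraction(mv2, 1, roi, 1)
  expect_equal(a2$fraction, a1$fraction)
  # fractions always within [0, 1]
  expect_true(all(a1$fraction >= 0 & a1$fraction <= 1))
})

test_that("peak fraction summaries and group comparisons behave", {
  ar <- structure(tibble::tibble(frame = 1:10,
                                 fraction = c(0, 0, .1, .4, .2, .5, .3,
                                              0, 0, 0)),
                  class = c("area_response", "tbl_df", "tbl", "data.frame"))
  expect_equal(gcamp_fraction_summary(ar, 3:7)$fraction_max, 0.5)
  expect_equal(gcamp_fraction_summary(ar, 3:7)$frame_at_max, 6)
  expect_equal(gcamp_fraction_summary(ar, 8:10)$fraction_max, 0)
  expect_error(gcamp_fraction_summary(ar, 11:12), "empty")
  # completely separated groups of 4: exact two-sided p = 2/70
  res <- compare_exposure_groups(c(.01, .02, .03, .04), c(.2, .3, .4, .5))
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-9)
  # identical tied groups: no evidence
  res2 <- compare_exposure_groups(rep(.1, 4), rep(.1, 4))
  expect_gt(res2$p_value, 0.99)
  expect_named(res$summary,
               c("group", "n", "q05", "q25", "median", "q75", "q95"))
  expect_error(compare_exposure_groups(1:2, 1:5), "at least 3")
})

test_that("steep responders are detected near their true onset and Sytox lags", {
  vm <- make_viability_movie(viability_config(
    n_cells = 40, n_frames = 150, exposure_window = 51:130,
    weights = c(quiet = 0.3, spontaneous = 0, steep = 0.7, gradual = 0),
    response_amplitude_sd = 5, seed = 23))
  tr <- extract_traces(vm$movie, "green", vm$tracks)
  bw <- vm$truth$baseline_window
  steep <- dplyr::filter(vm$truth$cells, population == "steep")
  calls <- purrr::map_dfr(steep$cell_id, function(id) {
    v <- dplyr::filter(tr, cell_id == id, compartment == "cytosol")$value
    classify_responder(v, bw, cell_id = id)
  })
  expect_true(all(calls$responder))
  dev <- abs(calls$first_crossing_frame - steep$ca_onset_frame)
  expect_gte(mean(dev <= 2), 0.9)
  # Sytox onset from the nucleus / cytosol ratio lags by the configured delay
  meas_delay <- purrr::map_dbl(steep$cell_id, function(id) {
    nuc <- dplyr::filter(tr, cell_id == id, compartment == "nucleus")$value
    cyt <- dplyr::filter(tr, cell_id == id, compartment == "cytosol")$value
    ratio <- sytox_trace(nuc, cyt, vm$truth$background)
    classify_responder(ratio, bw)$first_crossing_frame - 50
  })
  true_delay <- steep$sytox_onset_frame - 50
  expect_lte(abs(median(meas_delay - true_delay, na.rm = TRUE)), 3)
})
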