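#' Scene configuration for synthetic depth stacks
#'
#' Describes a ground-truthed tissue scene for [make_depth_stack()]: an
#' n-th order focal excitation whose ballistic excitation light attenuates
#' exponentially with depth, so the expected focal signal scales as
#' `P(z)^n * exp(-n * z / l_e)`.  Fluorescent features are Gaussian blobs on
#' a uniform background; noise is Poisson shot noise plus Gaussian read
#' noise.  The defaults emulate the deep-tumor profiling conditions this
#' package targets: a third-order process, `l_e = 220` um, a 0-400 um depth
#' range in 5 um steps, an excitation ramp compensating the attenuation
#' (held so the emission stays roughly constant with depth) and a surface
#' SNR of 50.
#'
#' @param order_n Order of the excitation process (2, 3 or 4).
#' @param l_e_um Effective attenuation length(s), um.  A vector of length
#'   `length(layer_boundaries_um) + 1` models layered tissue.
#' @param layer_boundaries_um Depths at which `l_e` changes (strictly
#'   increasing), or `NULL` for homogeneous tissue.
#' @param depths_um Depth grid of the stack, um.
#' @param schedule A [power_schedule()], or `NULL` for the default
#'   attenuation-compensating ramp `E(z) = exp(z / l_e)` nJ.
#' @param img_px Frame side length, pixels.
#' @param n_features Number of Gaussian blob features.
#' @param feature_sigma_px Lateral blob SD, pixels.
#' @param psf_sigma_axial_um Axial envelope SD of the features, um;
#'   `NA` makes features span all depths (the attenuation-profiling
#'   geometry), a finite value gives each feature a Gaussian axial profile
#'   centred at a feature-specific depth (the resolution-scoring geometry).
#' @param background Uniform background level, counts.
#' @param surface_snr Targeted `(I_mean - B_mean)/sigma_B` of the
#'   brightest-decile signal estimate at the surface plane; fixes the
#'   feature amplitude.
#' @param shot_noise,read_sd Poisson shot noise flag and Gaussian read
#'   noise SD.
#' @param bleach_rate Fractional fluorophore loss per plane scan.
#' @param pixel_size_um Lateral pixel size, um.
#' @param seed Integer random seed.
#' @export
scene_config <- function(order_n = 3, l_e_um = 220,
                         layer_boundaries_um = NULL,
                         depths_um = seq(0, 400, by = 5),
                         schedule = NULL,
                         img_px = 48L, n_features = 6L,
                         feature_sigma_px = 2.5,
                         psf_sigma_axial_um = NA,
                         background = 10, surface_snr = 50,
                         shot_noise = TRUE, read_sd = 1,
                         bleach_rate = 0, pixel_size_um = 0.7,
                         seed = 1L) {
  if (!(order_n %in% 2:4)) abort("`order_n` must be 2, 3 or 4.")
  if (any(l_e_um <= 0)) abort("`l_e_um` must be > 0.")
  if (length(l_e_um) != length(layer_boundaries_um) + 1L) {
    abort("Need one `l_e_um` per tissue layer (boundaries + 1).")
  }
  if (read_sd < 0 || bleach_rate < 0 || bleach_rate >= 1) {
    abort("`read_sd` must be >= 0 and `bleach_rate` in [0, 1).")
  }
  if (is.null(schedule)) {
    tau <- optical_depth(depths_um, l_e_um, layer_boundaries_um)
    schedule <- power_schedule(depths_um, exp(tau))
  }
  structure(list(order_n = order_n, l_e_um = l_e_um,
                 layer_boundaries_um = layer_boundaries_um,
                 depths_um = depths_um, schedule = schedule,
                 img_px = as.integer(img_px),
                 n_features = as.integer(n_features),
                 feature_sigma_px = feature_sigma_px,
                 psf_sigma_axial_um = psf_sigma_axial_um,
                 background = background, surface_snr = surface_snr,
                 shot_noise = shot_noise, read_sd = read_sd,
                 bleach_rate = bleach_rate, pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# cumulative optical depth integral(dz / l_e(z)) for piecewise-constant l_e
optical_depth <- function(z, l_e_um, boundaries) {
  if (is.null(boundaries)) return(z / l_e_um)
  edges <- c(0, boundaries, Inf)
  tau <- numeric(length(z))
  for (i in seq_along(l_e_um)) {
    lo <- edges[i]; hi <- edges[i + 1]
    seg <- pmax(pmin(z, hi) - lo, 0)
    tau <- tau + seg / l_e_um[i]
  }
  tau
}

# local RNG scope: seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# mean-preserving shot noise: exact Poisson below 20 counts, Gaussian
# approximation (variance = mean) above
rshot <- function(lambda) {
  out <- numeric(length(lambda))
  lo <- lambda < 20
  if (any(lo)) out[lo] <- rpois(sum(lo), lambda[lo])
  if (any(!lo)) {
    out[!lo] <- pmax(rnorm(sum(!lo), lambda[!lo], sqrt(lambda[!lo])), 0)
  }
  out
}

#' Simulate a depth stack with known ground truth
#'
#' Renders, per plane `z`, the deterministic expected image
#' `background + amplitude * f(z) * blobs(y, x)` with
#' `f(z) = (E(z)/E(0))^n * exp(-n * tau(z))` (and the optional per-plane
#' bleach factor), then applies shot and read noise under the configured
#' seed.  The feature amplitude is calibrated so the noiseless surface
#' plane reaches the configured `surface_snr` under the brightest-decile
#' signal estimate.  The top-left corner of every frame is kept free of
#' features as a dark background region.
#'
#' @param cfg A [scene_config()].
#' @return List with `stack` (an [image_stack()] carrying the energy
#'   schedule in its metadata), `truth` (generative parameters including
#'   the per-plane expected signal factor and the reserved background ROI).
#' @export
make_depth_stack <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  np <- length(cfg$depths_um)
  sz <- cfg$img_px
  energies <- schedule_at(cfg$schedule, cfg$depths_um)
  tau <- optical_depth(cfg$depths_um, cfg$l_e_um, cfg$layer_boundaries_um)
  fz <- (energies / energies[1])^cfg$order_n * exp(-cfg$order_n * tau) *
    (1 - cfg$bleach_rate)^(seq_len(np) - 1)

  # feature layout: keep the top-left corner (background ROI) dark
  bg_px <- max(10L, sz %/% 4L)
  margin <- ceiling(3 * cfg$feature_sigma_px)
  # keep features clear of borders and the dark corner; on small frames
  # fall back to a tighter margin
  ylo <- bg_px + margin; yhi <- sz - margin
  if (ylo >= yhi) { ylo <- min(bg_px + 2, sz - 3); yhi <- sz - 2 }
  xlo <- margin; xhi <- sz - margin
  if (xlo >= xhi) { xlo <- 3; xhi <- sz - 2 }
  truth_layout <- with_seed(cfg$seed, {
    tibble(
      y = runif(cfg$n_features, ylo, yhi),
      x = runif(cfg$n_features, xlo, xhi),
      brightness = runif(cfg$n_features, 0.6, 1),
      z_center_um = if (is.na(cfg$psf_sigma_axial_um)) NA_real_ else {
        runif(cfg$n_features, min(cfg$depths_um) + 2 * cfg$psf_sigma_axial_um,
              max(cfg$depths_um) - 2 * cfg$psf_sigma_axial_um)
      })
  })
  yy <- matrix(seq_len(sz), sz, sz)
  xx <- t(yy)
  unit <- matrix(0, sz, sz)
  for (i in seq_len(cfg$n_features)) {
    unit <- unit + truth_layout$brightness[i] *
      exp(-((yy - truth_layout$y[i])^2 + (xx - truth_layout$x[i])^2) /
            (2 * cfg$feature_sigma_px^2))
  }
  # calibrate amplitude: brightest decile of the noiseless unit image
  stats <- select_bright_pixels(unit, 0.1, 0L)
  sigma_b <- sqrt(cfg$background + cfg$read_sd^2)
  amplitude <- cfg$surface_snr * sigma_b / stats$i_mean

  axial <- function(p) {
    if (is.na(cfg$psf_sigma_axial_um)) return(rep(1, cfg$n_features))
    exp(-(cfg$depths_um[p] - truth_layout$z_center_um)^2 /
          (2 * cfg$psf_sigma_axial_um^2))
  }
  px <- array(0, dim = c(1L, np, sz, sz))
  with_seed(cfg$seed + 1L, {
    for (p in seq_len(np)) {
      img <- matrix(cfg$background, sz, sz)
      ax <- axial(p)
      if (is.na(cfg$psf_sigma_axial_um)) {
        img <- img + amplitude * fz[p] * unit
      } else {
        for (i in seq_len(cfg$n_features)) {
          img <- img + amplitude * fz[p] * ax[i] * truth_layout$brightness[i] *
            exp(-((yy - truth_layout$y[i])^2 + (xx - truth_layout$x[i])^2) /
                  (2 * cfg$feature_sigma_px^2))
        }
      }
      if (cfg$shot_noise) img <- matrix(rshot(img), sz, sz)
      if (cfg$read_sd > 0) {
        img <- pmax(img + matrix(rnorm(sz * sz, 0, cfg$read_sd), sz, sz), 0)
      }
      px[1L, p, , ] <- img
    }
  })
  step <- if (np > 1) diff(cfg$depths_um[1:2]) else 1
  stack <- image_stack(px, axis_kind = "z",
                       pixel_size_um = cfg$pixel_size_um,
                       plane_step = step,
                       channel_names = "synthetic",
                       meta = list(per_plane_energy_nj = energies))
  truth <- list(order_n = cfg$order_n, l_e_um = cfg$l_e_um,
                layer_boundaries_um = cfg$layer_boundaries_um,
                depths_um = cfg$depths_um, energies_nj = energies,
                plane_signal_factor = fz, amplitude = amplitude,
                background = cfg$background,
                sigma_b = sigma_b, layout = truth_layout,
                background_roi = roi_rect(1, 1, bg_px, bg_px, c(sz, sz),
                                          label = "dark corner"),
                seed = cfg$seed)
  list(stack = stack, truth = truth)
}

#' Simulate a bleach-referenced power series
#'
#' Frame k carries the expected signal
#' `a * (1 - bleach_rate)^(2 (k - 1)) * P_k^n` on a uniform disc (every
#' scan, measurement or reference, bleaches the fluorophore), and its
#' paired reference frame the analogous signal at the fixed reference
#' energy.  Because measurement and reference frames are one scan apart,
#' the reference ratio cancels the bleaching exactly.  The default energy
#' sequence follows the stepwise decreasing-then-increasing acquisition
#' protocol.
#'
#' @param a Proportionality constant; `NULL` derives it from
#'   `signal_at_min` (expected counts at the lowest energy).
#' @param n True order of the process.
#' @param energies_nj Energy sequence in acquisition order, nJ.
#' @param bleach_rate Fractional fluorophore loss per scan.
#' @param bleach_energy_nj Fixed reference energy, nJ.
#' @param noise List with `shot` (flag), `read_sd` (counts) and `rel_sd`
#'   (per-frame multiplicative illumination noise).
#' @param img_px Frame side length.
#' @param background Background level, counts.
#' @param signal_at_min Expected signal at the lowest energy when `a` is
#'   derived (counts; 400 gives shot-noise SNR 20 at the dimmest frame).
#' @param seed Integer seed.
#' @return List with `series` (a [power_series()]) and `truth`.
#' @export
make_power_series <- function(a = NULL, n = 3,
                              energies_nj = default_energy_protocol(),
                              bleach_rate = 0, bleach_energy_nj = 1,
                              noise = list(shot = TRUE, read_sd = 1,
                                           rel_sd = 0),
                              img_px = 24L, background = 5,
                              signal_at_min = 400, seed = 1L) {
  if (any(energies_nj <= 0) || bleach_energy_nj <= 0) {
    abort("All energies must be > 0.")
  }
  a <- a %||% (signal_at_min / min(energies_nj)^n)
  sz <- as.integer(img_px)
  ctr <- (sz + 1) / 2
  yy <- matrix(seq_len(sz), sz, sz); xx <- t(yy)
  r2 <- (yy - ctr)^2 + (xx - ctr)^2
  cell <- r2 <= (sz / 3)^2           # uniform disc feature
  roi <- roi_mask(r2 <= (sz / 4)^2, "cell core")
  bgsz <- max(3L, sz %/% 6L)
  background_roi <- roi_rect(1, 1, bgsz, bgsz, c(sz, sz), "dark corner")
  k <- length(energies_nj)
  shot <- isTRUE(noise$shot); read_sd <- noise$read_sd %||% 0
  rel_sd <- noise$rel_sd %||% 0
  render <- function(energy, residual, amp_noise) {
    img <- matrix(background, sz, sz)
    img[cell] <- img[cell] + a * residual * energy^n * amp_noise
    if (shot) img <- matrix(rshot(img), sz, sz)
    if (read_sd > 0) img <- pmax(img + rnorm(sz * sz, 0, read_sd), 0)
    img
  }
  frames <- vector("list", k); bleach_frames <- vector("list", k)
  with_seed(seed, {
    for (i in seq_len(k)) {
      amp_i <- if (rel_sd > 0) 1 + rnorm(1, 0, rel_sd) else 1
      amp_r <- if (rel_sd > 0) 1 + rnorm(1, 0, rel_sd) else 1
      frames[[i]] <- render(energies_nj[i],
                            (1 - bleach_rate)^(2 * (i - 1)), amp_i)
      bleach_frames[[i]] <- render(bleach_energy_nj,
                                   (1 - bleach_rate)^(2 * i - 1), amp_r)
    }
  })
  series <- power_series(frames, energies_nj, bleach_frames,
                         bleach_energy_nj, roi, background_roi)
  truth <- list(a = a, n = n, bleach_rate = bleach_rate,
                background = background, seed = seed)
  list(series = series, truth = truth)
}

#' Default stepwise decreasing-then-increasing energy protocol
#'
#' Ten distinct energies geometrically spaced over a factor of 3 (2 to 6
#' nJ), visited high-to-low then low-to-high as in the acquisition
#' protocol the power-series analysis assumes.
#' @export
default_energy_protocol <- function() {
  e <- 2 * 3^(seq(0, 1, length.out = 10))
  c(rev(e), e[-1])
}

#' Viability-movie configuration
#'
#' Parameters of the synthetic two-channel cell movie produced by
#' [make_viability_movie()]: a green channel carrying the calcium-indicator
#' signal of every cell (plus nuclear dead-cell-stain crosstalk) and a red
#' channel carrying a nuclear label with optional photobleaching.  The cell
#' population is a mixture of quiet cells, cells with a spontaneous
#' reversible transient, steep responders (near-instantaneous sustained
#' calcium rise at exposure onset, later becoming stain-positive with a
#' delayed nuclear uptake) and gradual responders (slow sustained rise).
#' The default mixture mirrors the composition observed at a toxic exposure
#' dose in vivo (about 12% spontaneous, 11% steep, 61% gradual).
#'
#' @param n_cells Number of cells.
#' @param weights Named mixture weights over
#'   `quiet`, `spontaneous`, `steep`, `gradual`; must sum to 1.
#' @param response_amplitude_sd Exposure-response amplitude in units of the
#'   baseline trace SD.  The default of 30 corresponds to a multi-fold
#'   intensity rise (dF/F of roughly 2-3 at the default levels), as
#'   calcium indicators show for sustained stress responses; use 5 for the
#'   near-threshold regime probed by classifier sensitivity analyses.
#' @param spont_amplitude_sd Amplitude of spontaneous reversible
#'   transients, in baseline-SD units.
#' @param sytox_delay_mean,sytox_delay_sd Nuclear-stain onset lag after
#'   exposure start (frames).
#' @param n_frames Movie length, frames.
#' @param exposure_window Frame indices of the exposure period.
#' @param frame_s Frame interval, seconds.
#' @param cytosol_level,nucleus_level Baseline intensities, counts.
#' @param baseline_sd Cell-wide baseline fluctuation SD, counts.
#' @param sytox_amplitude Saturating nuclear-stain intensity, counts.
#' @param mcherry_bleach_rate Red-channel fractional loss per frame.
#' @param background Dark background level, counts.
#' @param shot_noise,read_sd Pixel noise model.
#' @param seed Integer seed.
#' @export
viability_config <- function(n_cells = 60L,
                             weights = c(quiet = 0.16, spontaneous = 0.12,
                                         steep = 0.11, gradual = 0.61),
                             response_amplitude_sd = 30,
                             spont_amplitude_sd = 5,
                             sytox_delay_mean = 30, sytox_delay_sd = 10,
                             n_frames = 200L, exposure_window = 51:150,
                             frame_s = 3.3,
                             cytosol_level = 40, nucleus_level = 50,
                             baseline_sd = 3, sytox_amplitude = 80,
                             mcherry_bleach_rate = 0.002,
                             background = 5, shot_noise = TRUE, read_sd = 1,
                             seed = 1L) {
  if (n_cells < 1L) abort("`n_cells` must be >= 1.")
  req <- c("quiet", "spontaneous", "steep", "gradual")
  if (!setequal(names(weights), req) || abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be named quiet/spontaneous/steep/gradual and sum to 1.")
  }
  structure(
    list(n_cells = as.integer(n_cells), weights = weights[req],
         response_amplitude_sd = response_amplitude_sd,
         spont_amplitude_sd = spont_amplitude_sd,
         sytox_delay_mean = sytox_delay_mean,
         sytox_delay_sd = sytox_delay_sd,
         n_frames = as.integer(n_frames),
         exposure_window = as.integer(exposure_window), frame_s = frame_s,
         cytosol_level = cytosol_level, nucleus_level = nucleus_level,
         baseline_sd = baseline_sd, sytox_amplitude = sytox_amplitude,
         mcherry_bleach_rate = mcherry_bleach_rate,
         background = background, shot_noise = shot_noise,
         read_sd = read_sd, seed = as.integer(seed)),
    class = "viability_config")
}

#' Simulate a two-channel cell viability movie
#'
#' Static cells on a regular grid; each cell is a cytosol disc with a
#' nuclear core.  Per-cell scalar intensity time series (baseline
#' fluctuation plus the population-specific response shape) are rendered
#' into frames and degraded with shot and read noise.  A tracks table
#' compatible with [extract_traces()] and a ground-truth record (per-cell
#' population label, calcium onset frame, stain onset frame, analytic
#' baseline trace SD) are returned alongside the movie.
#'
#' @param cfg A [viability_config()].
#' @return List with `movie` (an [image_stack()], channels `green`, `red`),
#'   `tracks` (tibble), `truth` (list).
#' @export
make_viability_movie <- function(cfg) {
  stopifnot(inherits(cfg, "viability_config"))
  nc <- cfg$n_cells; nf <- cfg$n_frames
  exp_start <- min(cfg$exposure_window)
  ncol_grid <- ceiling(sqrt(nc))
  nrow_grid <- ceiling(nc / ncol_grid)
  spacing <- 16L
  ny <- nrow_grid * spacing + 8L
  nx <- ncol_grid * spacing + 8L
  cy <- ((seq_len(nc) - 1) %/% ncol_grid) * spacing + spacing / 2 + 4
  cx <- ((seq_len(nc) - 1) %% ncol_grid) * spacing + spacing / 2 + 4

  # analytic baseline trace SD of the extracted (13-px disc mean) trace
  npx <- nrow(disk_offsets(2L))
  pix_var <- (cfg$cytosol_level + cfg$background) * cfg$shot_noise +
    cfg$read_sd^2
  sd_eff <- sqrt(cfg$baseline_sd^2 + pix_var / npx)
  amp <- cfg$response_amplitude_sd * sd_eff

  truth <- with_seed(cfg$seed, {
    pop <- sample(names(cfg$weights), nc, replace = TRUE,
                  prob = cfg$weights)
    onset <- ifelse(pop %in% c("steep", "gradual"),
                    exp_start + sample(0:2, nc, replace = TRUE), NA_integer_)
    sp_center <- ifelse(pop == "spontaneous",
                        sample(seq(10L, nf - 10L), nc, replace = TRUE),
                        NA_integer_)
    sy_delay <- ifelse(pop == "steep",
                       pmax(round(rnorm(nc, cfg$sytox_delay_mean,
                                        cfg$sytox_delay_sd)), 5),
                       NA_real_)
    tibble(cell_id = seq_len(nc), population = pop,
           ca_onset_frame = as.integer(onset),
           spont_center_frame = as.integer(sp_center),
           sytox_onset_frame = as.integer(exp_start + sy_delay),
           y = cy, x = cx)
  })

  tvec <- seq_len(nf)
  resp <- matrix(0, nc, nf)       # additive calcium response, counts
  sytox <- matrix(0, nc, nf)      # additive nuclear stain, counts
  fluct <- with_seed(cfg$seed + 1L, {
    matrix(rnorm(nc * nf, 0, cfg$baseline_sd), nc, nf)
  })
  exp_end <- max(cfg$exposure_window)
  for (i in seq_len(nc)) {
    p <- truth$population[i]
    if (p == "steep") {
      resp[i, ] <- amp / (1 + exp(-(tvec - truth$ca_onset_frame[i])))
      k0 <- truth$sytox_onset_frame[i]
      # stain influx saturates within ~10 frames once the membrane fails
      sytox[i, ] <- cfg$sytox_amplitude * pmin(pmax(tvec - k0, 0) / 10, 1)
    } else if (p == "gradual") {
      ramp <- pmin(pmax(tvec - truth$ca_onset_frame[i], 0) /
                     (exp_end - truth$ca_onset_frame[i]), 1)
      resp[i, ] <- amp * ramp
    } else if (p == "spontaneous") {
      resp[i, ] <- cfg$spont_amplitude_sd * sd_eff *
        exp(-(tvec - truth$spont_center_frame[i])^2 / (2 * 4^2))
    }
  }
  cyt <- cfg$cytosol_level + resp + fluct
  nuc_green <- cfg$nucleus_level + resp + fluct + sytox
  nuc_red <- cfg$nucleus_level *
    matrix(rep((1 - cfg$mcherry_bleach_rate)^(tvec - 1), each = nc), nc, nf)

  # pixel index maps
  yy <- matrix(seq_len(ny), ny, nx); xx <- matrix(seq_len(nx), ny, nx,
                                                  byrow = TRUE)
  cyt_idx <- vector("list", nc); nuc_idx <- vector("list", nc)
  for (i in seq_len(nc)) {
    d2 <- (yy - cy[i])^2 + (xx - cx[i])^2
    nuc_idx[[i]] <- which(d2 <= 2.5^2)
    cyt_idx[[i]] <- which(d2 <= 7^2 & d2 > 2.5^2)
  }
  px <- array(0, dim = c(2L, nf, ny, nx))
  with_seed(cfg$seed + 2L, {
    for (k in seq_len(nf)) {
      g <- matrix(cfg$background, ny, nx)
      r <- matrix(cfg$background, ny, nx)
      for (i in seq_len(nc)) {
        g[cyt_idx[[i]]] <- cfg$background + cyt[i, k]
        g[nuc_idx[[i]]] <- cfg$background + nuc_green[i, k]
        r[nuc_idx[[i]]] <- cfg$background + nuc_red[i, k]
      }
      g <- pmax(g, 0); r <- pmax(r, 0)
      if (cfg$shot_noise) {
        g <- matrix(rshot(g), ny, nx); r <- matrix(rshot(r), ny, nx)
      }
      if (cfg$read_sd > 0) {
        g <- pmax(g + rnorm(ny * nx, 0, cfg$read_sd), 0)
        r <- pmax(r + rnorm(ny * nx, 0, cfg$read_sd), 0)
      }
      px[1L, k, , ] <- g
      px[2L, k, , ] <- r
    }
  })
  movie <- image_stack(px, axis_kind = "t", plane_step = cfg$frame_s,
                       channel_names = c("green", "red"))
  tracks <- tidyr::crossing(frame = tvec, cell_id = seq_len(nc),
                            compartment = c("nucleus", "cytosol"))
  tracks <- mutate(tracks,
                   y_px = round(cy[.data$cell_id]),
                   x_px = round(cx[.data$cell_id]) +
                     ifelse(.data$compartment == "cytosol", 5L, 0L))
  truth_all <- list(cells = truth, amplitude = amp, sd_eff = sd_eff,
                    exposure_window = cfg$exposure_window,
                    baseline_window = seq_len(exp_start - 1L),
                    background = cfg$background, seed = cfg$seed)
  list(movie = movie, tracks = tracks, truth = truth_all)
}
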