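# Fixtures are built in code; no binary test data.

# single-channel z-stack whose planes are uniform at the given values
uniform_plane_stack <- function(values, plane_step = 2.5, ny = 8, nx = 8,
                                energy_nj = NULL) {
  px <- array(0, dim = c(1, length(values), ny, nx))
  for (p in seq_along(values)) px[1, p, , ] <- values[p]
  meta <- if (is.null(energy_nj)) list() else
    list(per_plane_energy_nj = energy_nj)
  image_stack(px, axis_kind = "z", plane_step = plane_step, meta = meta)
}

# two-region frame: a bright rectangle on a dark background
two_level_frame <- function(ny = 16, nx = 16, bright = 100, dark = 0,
                            rows = 3:6, cols = 3:6) {
  m <- matrix(dark, ny, nx)
  m[rows, cols] <- bright
  m
}

# depth profile tibble for attenuation tests
profile_tbl <- function(depth_um, i_mean, b_mean = 0, energy_nj = 1,
                        sigma_b = 1) {
  tibble::tibble(depth_um = depth_um, i_mean = i_mean, b_mean = b_mean,
                 sigma_b = sigma_b, snr = (i_mean - b_mean) / sigma_b,
                 energy_nj = energy_nj)
}

# minimal power series with uniform-by-region frames; signal region holds
# `sig`, background region `bg`
series_from_values <- function(sig, energies, ref_sig, bleach_energy = 1,
                               bg = 10, ny = 6, nx = 6) {
  roi <- roi_rect(1, 1, 3, nx, c(ny, nx), "sig")
  bgroi <- roi_rect(ny - 1, 1, 2, nx, c(ny, nx), "bg")
  mk <- function(v) {
    m <- matrix(bg, ny, nx)
    m[1:3, ] <- v
    m
  }
  power_series(lapply(sig, mk), energies, lapply(ref_sig, mk),
               bleach_energy, roi, bgroi)
}
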