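#' Excitation setting
#'
#' Bundles the quantities needed to convert the pulse energy measured under
#' the objective (`e_obj_nj`) into the pulse energy at the sample surface,
#' correcting for absorption in the immersion liquid with a Beer-Lambert
#' factor.  The absorption coefficient is wavelength dependent and
#' instrument specific; it is supplied by the user (natural-log units per
#' millimetre), typically from a calibration table.
#'
#' @param wavelength_nm Excitation wavelength.
#' @param rep_rate_hz Pulse repetition rate in Hz.
#' @param e_obj_nj Pulse energy under the objective, nJ.
#' @param immersion_path_mm Immersion-liquid path length, mm.
#' @param absorption_per_mm Immersion attenuation coefficient at this
#'   wavelength, 1/mm.
#' @export
excitation_setting <- function(wavelength_nm, rep_rate_hz, e_obj_nj,
                               immersion_path_mm = 0, absorption_per_mm = 0) {
  if (rep_rate_hz <= 0) abort("`rep_rate_hz` must be > 0.")
  if (e_obj_nj < 0 || immersion_path_mm < 0 || absorption_per_mm < 0) {
    abort("Energies, path lengths and absorption coefficients must be >= 0.")
  }
  structure(list(wavelength_nm = wavelength_nm, rep_rate_hz = rep_rate_hz,
                 e_obj_nj = e_obj_nj, immersion_path_mm = immersion_path_mm,
                 absorption_per_mm = absorption_per_mm),
            class = "excitation_setting")
}

#' Pulse energy at the sample surface
#'
#' `E = E_obj * exp(-absorption_per_mm * immersion_path_mm)`: the
#' under-objective pulse energy attenuated by single-pass Beer-Lambert
#' absorption in the immersion medium.  `E` is the reference energy quoted
#' for every measurement in this package.
#'
#' @param setting An [excitation_setting()].
#' @return Pulse energy at the sample surface, nJ.
#' @export
surface_pulse_energy <- function(setting) {
  stopifnot(inherits(setting, "excitation_setting"))
  setting$e_obj_nj *
    exp(-setting$absorption_per_mm * setting$immersion_path_mm)
}

#' Average excitation power at the sample surface
#'
#' Pulse energy times repetition rate; with energy in nJ and the rate in Hz
#' the result is returned in mW (nJ x MHz = mW).
#'
#' @param e_surface_nj Pulse energy at the sample surface, nJ.
#' @param rep_rate_hz Pulse repetition rate, Hz.
#' @return Average power in mW.
#' @export
average_power <- function(e_surface_nj, rep_rate_hz) {
  if (any(e_surface_nj <= 0) || any(rep_rate_hz <= 0)) {
    abort("`e_surface_nj` and `rep_rate_hz` must be > 0.")
  }
  e_surface_nj * rep_rate_hz * 1e-6
}

#' Depth-dependent excitation-power schedule
#'
#' Represents the pulse-energy ramp applied while descending into the
#' sample (energy is raised with depth to hold the emission roughly
#' constant).  `schedule_at()` evaluates the schedule by linear
#' interpolation; it is exact at the grid depths and errors outside the
#' grid.
#'
#' @param depths_um Strictly increasing depth grid, um.
#' @param e_surface_nj Pulse energy at the sample surface per depth, nJ.
#' @return A `power_schedule` object (a tibble with attributes).
#' @export
power_schedule <- function(depths_um, e_surface_nj) {
  if (length(depths_um) != length(e_surface_nj)) {
    abort("`depths_um` and `e_surface_nj` must have equal length.")
  }
  if (any(diff(depths_um) <= 0)) {
    abort("`depths_um` must be strictly increasing.")
  }
  if (any(e_surface_nj <= 0)) abort("All energies must be > 0.")
  structure(tibble(depth_um = depths_um, e_surface_nj = e_surface_nj),
            class = c("power_schedule", "tbl_df", "tbl", "data.frame"))
}

#' @rdname power_schedule
#' @param schedule A `power_schedule`.
#' @param z_um Depth(s) at which to evaluate, um.
#' @export
schedule_at <- function(schedule, z_um) {
  stopifnot(inherits(schedule, "power_schedule"))
  rng <- range(schedule$depth_um)
  if (any(z_um < rng[1] | z_um > rng[2])) {
    abort(sprintf("Depth outside the schedule grid [%g, %g] um.",
                  rng[1], rng[2]))
  }
  approx(schedule$depth_um, schedule$e_surface_nj, xout = z_um,
         method = "linear", ties = "ordered")$y
}
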