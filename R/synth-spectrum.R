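#' Specification for a synthetic two-band emission spectrum
#'
#' A spectrum built from two Gaussian emission bands (blue and red) whose
#' amplitudes are solved so that the band-integrated GP — computed with
#' [spectrum_gp()] on the same sampled grid and the same band windows —
#' equals `target_gp` exactly in the noiseless case.
#'
#' @param wavelength_range `c(lo, hi)` nm of the sampled grid.
#' @param step Grid step (nm).
#' @param blue_center,red_center Band centres (nm), `blue_center <
#'   red_center`, both inside `wavelength_range`.
#' @param band_sd Gaussian band SD (nm).
#' @param total_intensity Integral of the noiseless spectrum (a.u. * nm).
#' @param target_gp Target band-integrated GP in `[-1, 1]`.
#' @param noise_sd Additive Gaussian noise SD per grid point (a.u.).
#' @param bands The [band_pair()] used both to solve the amplitudes and
#'   expected for downstream [spectrum_gp()] calls.
#' @param seed Integer RNG seed (used only when `noise_sd > 0`).
#' @return An object of class `SpectrumSpec`.
#' @export
spectrum_spec <- function(wavelength_range = c(450, 780), step = 1,
                          blue_center = 540, red_center = 670,
                          band_sd = 15, total_intensity = 1000,
                          target_gp = 0, noise_sd = 0,
                          bands = band_pair(), seed = 1L) {
  if (blue_center >= red_center) stop("blue_center must be < red_center")
  if (abs(target_gp) > 1) stop("target_gp must lie in [-1, 1]")
  if (blue_center < wavelength_range[1] || red_center > wavelength_range[2])
    stop("band centers must lie inside wavelength_range")
  structure(list(wavelength_range = wavelength_range, step = step,
                 blue_center = blue_center, red_center = red_center,
                 band_sd = band_sd, total_intensity = total_intensity,
                 target_gp = target_gp, noise_sd = noise_sd,
                 bands = bands, seed = as.integer(seed)),
            class = "SpectrumSpec")
}

#' Generate a synthetic emission spectrum with known GP
#'
#' Solves the two band amplitudes `A_blue`, `A_red` from the linear system
#' fixing the band-integrated GP and total signal, using the identical
#' trapezoidal quadrature as [integrate_band()] so the noiseless
#' round-trip through [spectrum_gp()] is exact to machine precision.
#' A `target_gp` that would require a negative amplitude (possible only
#' through band overlap) is accepted when clamping that amplitude to zero
#' still reproduces the target within 1e-6, and is an error otherwise.
#'
#' @param spec A [spectrum_spec()].
#' @return A list with `spectrum` (an [emission_spectrum()]) and `truth`
#'   (`spectrum_gp` = the target, plus the solved band amplitudes).
#' @export
make_spectrum <- function(spec) {
  stopifnot(inherits(spec, "SpectrumSpec"))
  w <- seq(spec$wavelength_range[1], spec$wavelength_range[2], by = spec$step)
  shape_b <- stats::dnorm(w, spec$blue_center, spec$band_sd)
  shape_r <- stats::dnorm(w, spec$red_center, spec$band_sd)
  sp_b <- emission_spectrum(w, shape_b)
  sp_r <- emission_spectrum(w, shape_r)
  bb <- spec$bands$blue_band; rb <- spec$bands$red_band
  # band integrals of the unit shapes, same quadrature as spectrum_gp
  u_b <- integrate_band(sp_b, bb); v_b <- integrate_band(sp_b, rb)
  u_r <- integrate_band(sp_r, bb); v_r <- integrate_band(sp_r, rb)
  g <- spec$target_gp
  m <- rbind(c(u_b - v_b, u_r - v_r), c(u_b + v_b, u_r + v_r))
  amps <- solve(m, c(g, 1))
  if (any(amps < 0)) {
    amps <- pmax(amps, 0)
    i_b <- amps[1] * u_b + amps[2] * u_r
    i_r <- amps[1] * v_b + amps[2] * v_r
    achieved <- compute_gp(i_b, i_r)
    if (!is.finite(achieved) || abs(achieved - g) > 1e-6)
      stop(sprintf(
        "target_gp = %g infeasible with these bands (closest achievable %g)",
        g, achieved))
  }
  y <- amps[1] * shape_b + amps[2] * shape_r
  # rescale the total signal; GP is scale invariant
  area <- sum(diff(w) * (y[-length(y)] + y[-1]) / 2)
  sc <- if (area > 0) spec$total_intensity / area else 1
  y <- y * sc
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    y <- y + stats::rnorm(length(y), sd = spec$noise_sd)
  }
  list(spectrum = emission_spectrum(w, y),
       truth = list(spectrum_gp = g, amplitudes = amps * sc))
}
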