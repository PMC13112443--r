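#' Generalized polarization of a blue/red intensity pair
#'
#' GP = (I_blue - I_red) / (I_blue + I_red), the standard ratiometric index
#' used for Laurdan-family and ANEP-family environment-sensitive dyes.
#' Higher GP means a less hydrated (more ordered) probe environment.
#'
#' @param i_blue,i_red Nonnegative intensities (scalars or arrays of equal
#'   shape), blue- and red-edge emission respectively.
#' @return GP values in `[-1, 1]`; `NA` where both channels are zero (the
#'   undefined case, consumed by the validity mask in [gp_map()]).
#' @examples
#' compute_gp(3, 1)   # 0.5
#' compute_gp(1, 1)   # 0
#' @export
compute_gp <- function(i_blue, i_red) {
  if (any(i_blue < 0, na.rm = TRUE) || any(i_red < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  tot <- i_blue + i_red
  gp <- (i_blue - i_red) / tot
  gp[tot == 0] <- NA_real_
  gp
}

#' Emission spectrum container
#'
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param intensities Intensities (a.u.), same length, finite.
#' @param excitation_wavelength Excitation wavelength (nm), metadata only.
#' @return An object of class `EmissionSpectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities,
                              excitation_wavelength = 488) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least 2 points")
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 excitation_wavelength = excitation_wavelength),
            class = "EmissionSpectrum")
}

#' @export
print.EmissionSpectrum <- function(x, ...) {
  cat(sprintf("EmissionSpectrum: %d points, %.1f-%.1f nm, ex %.0f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$excitation_wavelength))
  invisible(x)
}

#' Blue/red integration windows
#'
#' Default windows follow common di-4-ANEPPDHQ practice (the exact detector
#' windows are instrument settings and are always overridable).
#'
#' @param blue_band,red_band Length-2 numeric `[lo, hi]` in nm.
#' @return An object of class `BandPair`.
#' @export
band_pair <- function(blue_band = c(500, 580), red_band = c(620, 750)) {
  for (b in list(blue_band, red_band))
    if (length(b) != 2L || b[1] >= b[2])
      stop("each band must be [lo, hi] with lo < hi")
  if (isTRUE(all(blue_band == red_band)))
    stop("blue and red bands must differ")
  structure(list(blue_band = as.numeric(blue_band),
                 red_band = as.numeric(red_band)), class = "BandPair")
}

#' Trapezoidal band integral of a spectrum
#'
#' Integrates intensity over `[band[1], band[2]]` by the trapezoid rule,
#' linearly interpolating the spectrum at the band edges.
#'
#' @param spectrum An [emission_spectrum()].
#' @param band Length-2 numeric window (nm), inside the spectrum's span.
#' @return Integrated intensity (a.u. * nm).
#' @export
integrate_band <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "EmissionSpectrum"))
  w <- spectrum$wavelengths; y <- spectrum$intensities
  if (band[1] < w[1] || band[2] > w[length(w)])
    stop(sprintf("band [%g, %g] outside spectrum span [%g, %g]",
                 band[1], band[2], w[1], w[length(w)]))
  inside <- w > band[1] & w < band[2]
  xs <- c(band[1], w[inside], band[2])
  ys <- c(stats::approx(w, y, xout = band[1])$y, y[inside],
          stats::approx(w, y, xout = band[2])$y)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

#' Spectral GP from band integrals
#'
#' GP of the blue- and red-window band integrals of one emission spectrum,
#' the quantity obtained from spectrofluorometer scans of dye-stained cell
#' suspensions.
#'
#' @inheritParams integrate_band
#' @param bands A [band_pair()].
#' @return Scalar GP in `[-1, 1]`.
#' @export
spectrum_gp <- function(spectrum, bands = band_pair()) {
  stopifnot(inherits(bands, "BandPair"))
  compute_gp(integrate_band(spectrum, bands$blue_band),
             integrate_band(spectrum, bands$red_band))
}

#' Two-channel image container
#'
#' @param blue,red Numeric matrices of identical shape (blue/red emission
#'   intensity), nonnegative.
#' @param pixel_size Optional pixel size in micrometres (metadata).
#' @return An object of class `TwoChannelImage`.
#' @export
two_channel_image <- function(blue, red, pixel_size = NULL) {
  blue <- as.matrix(blue); red <- as.matrix(red)
  if (!identical(dim(blue), dim(red)))
    stop("blue and red channels must have identical shape")
  if (any(blue < 0) || any(red < 0))
    stop("channel intensities must be nonnegative")
  structure(list(blue = blue, red = red, pixel_size = pixel_size),
            class = "TwoChannelImage")
}

#' @export
print.TwoChannelImage <- function(x, ...) {
  cat(sprintf("TwoChannelImage: %d x %d px, total intensity %.3g\n",
              nrow(x$blue), ncol(x$blue), sum(x$blue) + sum(x$red)))
  invisible(x)
}

#' Constant background subtraction
#'
#' Subtracts a constant background per channel and clips negatives to zero.
#' Background handling is optional and must be explicit; the applied values
#' are recorded in the returned object.
#'
#' @param image A [two_channel_image()].
#' @param blue_bg,red_bg Constant background per channel (intensity units).
#' @return A `TwoChannelImage` with attribute `background` recording the
#'   subtracted constants.
#' @export
subtract_background <- function(image, blue_bg = 0, red_bg = blue_bg) {
  stopifnot(inherits(image, "TwoChannelImage"))
  out <- two_channel_image(pmax(image$blue - blue_bg, 0),
                           pmax(image$red - red_bg, 0),
                           pixel_size = image$pixel_size)
  attr(out, "background") <- c(blue = blue_bg, red = red_bg)
  out
}

#' Otsu threshold of the summed-channel image
#'
#' Parameter-free default for the GP validity threshold: Otsu's method on
#' the blue+red intensity image (256 levels over the observed range).
#'
#' @param image A [two_channel_image()].
#' @return Scalar threshold in the intensity units of the input.
#' @export
otsu_threshold <- function(image) {
  stopifnot(inherits(image, "TwoChannelImage"))
  tot <- image$blue + image$red
  rng <- range(tot)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image((tot - rng[1]) / diff(rng))) *
    diff(rng) + rng[1]
}

#' Pixel-wise GP map with validity mask
#'
#' Computes GP on every pixel whose summed intensity strictly exceeds the
#' threshold; all other pixels are marked invalid and carry `NA`.
#'
#' @param image A [two_channel_image()] (registered channels).
#' @param intensity_threshold Numeric threshold on blue+red, or `NULL`
#'   (default) for Otsu's threshold on the summed image.
#' @return An object of class `GPMap` with fields `gp` (matrix, `NA` where
#'   invalid), `valid` (logical matrix), `intensity_threshold`.
#' @export
gp_map <- function(image, intensity_threshold = NULL) {
  stopifnot(inherits(image, "TwoChannelImage"))
  if (is.null(intensity_threshold))
    intensity_threshold <- otsu_threshold(image)
  tot <- image$blue + image$red
  valid <- is.finite(tot) & tot > intensity_threshold
  gp <- matrix(NA_real_, nrow(tot), ncol(tot))
  gp[valid] <- (image$blue[valid] - image$red[valid]) / tot[valid]
  structure(list(gp = gp, valid = valid,
                 intensity_threshold = intensity_threshold),
            class = "GPMap")
}

#' @export
print.GPMap <- function(x, ...) {
  cat(sprintf("GPMap: %d x %d px, %d valid (threshold %.4g)\n",
              nrow(x$gp), ncol(x$gp), sum(x$valid), x$intensity_threshold))
  if (any(x$valid))
    cat(sprintf("  GP on valid pixels: median %.3f [%.3f, %.3f]\n",
                stats::median(x$gp[x$valid]), min(x$gp[x$valid]),
                max(x$gp[x$valid])))
  invisible(x)
}
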