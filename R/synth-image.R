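#' Specification for a synthetic two-channel cell image
#'
#' Describes a field of non-overlapping disc "cells" with bright annular
#' membranes, imaged in a blue and a red emission channel whose split
#' encodes a per-cell generalized polarization: on a cell's pixels the
#' expected blue fraction of the total signal is `(1 + GP) / 2`, which
#' inverts the GP definition exactly. Photon (Poisson) noise and additive
#' Gaussian read noise are optional.
#'
#' @param image_shape Integer `c(rows, cols)` in pixels.
#' @param n_cells Number of cells to place.
#' @param cell_radius_range `c(min, max)` disc radius in pixels.
#' @param membrane_width Annulus width in pixels (>= 1).
#' @param membrane_intensity,interior_intensity,background_intensity
#'   Expected total (blue+red) photons per pixel on the membrane annulus,
#'   the cell interior and the background.
#' @param per_cell_gp Numeric of length `n_cells` (or length 1, recycled),
#'   each in `[-1, 1]`: the true GP of each cell's pixels. Background
#'   pixels have GP 0 (equal channel split).
#' @param read_noise_sd Gaussian read noise SD (intensity units) added per
#'   channel when `noise = TRUE`.
#' @param noise If `FALSE`, return the noiseless expectation image.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param noise_seed Optional separate seed for the noise draw (defaults
#'   to `seed`); holding `seed` fixed while varying `noise_seed` yields
#'   independent noise realizations over an identical cell placement.
#' @return An object of class `ImageSpec`.
#' @export
image_spec <- function(image_shape = c(256L, 256L), n_cells = 10L,
                       cell_radius_range = c(12, 18), membrane_width = 2,
                       membrane_intensity = 600, interior_intensity = 120,
                       background_intensity = 20,
                       per_cell_gp = 0.3, read_noise_sd = 3,
                       noise = TRUE, seed = 1L, noise_seed = NULL) {
  per_cell_gp <- rep_len(as.numeric(per_cell_gp), n_cells)
  if (any(abs(per_cell_gp) > 1))
    stop("every per_cell_gp must lie in [-1, 1]")
  if (membrane_width < 1) stop("membrane_width must be >= 1")
  if (cell_radius_range[1] > cell_radius_range[2] ||
      cell_radius_range[1] <= membrane_width)
    stop("cell_radius_range must be increasing and exceed membrane_width")
  structure(list(image_shape = as.integer(image_shape),
                 n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 membrane_width = membrane_width,
                 membrane_intensity = membrane_intensity,
                 interior_intensity = interior_intensity,
                 background_intensity = background_intensity,
                 per_cell_gp = per_cell_gp,
                 read_noise_sd = read_noise_sd,
                 noise = isTRUE(noise), seed = as.integer(seed),
                 noise_seed = if (is.null(noise_seed)) as.integer(seed)
                              else as.integer(noise_seed)),
            class = "ImageSpec")
}

# Non-overlapping disc placement by rejection sampling; bounded retries.
place_cells <- function(spec, max_tries = 200L * spec$n_cells, gap = 2) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  centers <- matrix(NA_real_, spec$n_cells, 2)
  radii <- numeric(spec$n_cells)
  placed <- 0L; tries <- 0L
  while (placed < spec$n_cells && tries < max_tries) {
    tries <- tries + 1L
    r <- stats::runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
    cy <- stats::runif(1, r + 1, nr - r)
    cx <- stats::runif(1, r + 1, nc - r)
    ok <- placed == 0L ||
      all(sqrt((centers[seq_len(placed), 1] - cy)^2 +
               (centers[seq_len(placed), 2] - cx)^2) >=
            radii[seq_len(placed)] + r + gap)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- c(cy, cx); radii[placed] <- r
    }
  }
  if (placed < spec$n_cells)
    stop(sprintf(
      "could not place non-overlapping cells: requested %d, placed %d",
      spec$n_cells, placed))
  list(centers = centers, radii = radii)
}

#' Generate a synthetic two-channel cell image with ground truth
#'
#' Renders the discs described by an [image_spec()] into a noiseless
#' expectation image, splits it into blue/red channels from each cell's
#' true GP, then (optionally) applies Poisson photon noise plus Gaussian
#' read noise per channel (negative values clipped to zero).
#'
#' @param spec An [image_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{A [two_channel_image()].}
#'     \item{truth}{Ground truth: `cell_label_map` (integer matrix, 0 =
#'       background, 1..N in placement order), `membrane_masks` (list of
#'       pixel index vectors, pairwise disjoint), `per_cell_gp`, `centers`
#'       (0-based `(row, col)` disc centers, usable as watershed seeds),
#'       `radii`, and the noiseless channels `blue0`/`red0`.}
#'   }
#' @export
make_cell_image <- function(spec) {
  stopifnot(inherits(spec, "ImageSpec"))
  set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  pl <- place_cells(spec)

  total <- matrix(spec$background_intensity, nr, nc)
  gp_img <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)
  membrane_masks <- vector("list", spec$n_cells)
  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(spec$n_cells)) {
    d <- sqrt((row_idx - pl$centers[k, 1])^2 + (col_idx - pl$centers[k, 2])^2)
    r <- pl$radii[k]
    inside <- d <= r
    ring <- inside & d > r - spec$membrane_width
    total[inside & !ring] <- spec$interior_intensity
    total[ring] <- spec$membrane_intensity
    gp_img[inside] <- spec$per_cell_gp[k]
    labels[inside] <- k
    membrane_masks[[k]] <- which(ring)
  }
  blue0 <- total * (1 + gp_img) / 2
  red0 <- total * (1 - gp_img) / 2
  if (spec$noise) {
    set.seed(spec$noise_seed)
    blue <- stats::rpois(length(blue0), blue0) +
      stats::rnorm(length(blue0), sd = spec$read_noise_sd)
    red <- stats::rpois(length(red0), red0) +
      stats::rnorm(length(red0), sd = spec$read_noise_sd)
    blue <- matrix(pmax(blue, 0), nr, nc)
    red <- matrix(pmax(red, 0), nr, nc)
  } else {
    blue <- blue0; red <- red0
  }
  list(image = two_channel_image(blue, red),
       truth = list(cell_label_map = labels,
                    membrane_masks = membrane_masks,
                    per_cell_gp = spec$per_cell_gp,
                    centers = pl$centers - 1,   # 0-based (row, col)
                    radii = pl$radii,
                    blue0 = blue0, red0 = red0))
}

#' Watershed seeds from image ground truth
#'
#' Perfect seeds for [seeded_watershed()]: each true cell centre as a cell
#' seed and the darkest background corner pixel as the background seed.
#'
#' @param truth The `truth` element returned by [make_cell_image()].
#' @return A [seed_set()].
#' @export
truth_seeds <- function(truth) {
  bg <- which(truth$cell_label_map == 0, arr.ind = TRUE)[1, ] - 1L
  seed_set(cell_seeds = round(truth$centers),
           background_seeds = matrix(bg, 1))
}
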