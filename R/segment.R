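#' Watershed seed set
#'
#' Seed coordinates for the manually seeded watershed. In the original
#' workflow these are clicked by the analyst; here they come from a CSV
#' file ([read_seeds_csv()]) or from the synthetic generator's ground
#' truth ([truth_seeds()]), keeping the algorithm itself identical.
#'
#' @param cell_seeds Matrix (or 2-column data frame) of 0-based
#'   `(row, col)` pixel coordinates, one per cell, pairwise distinct.
#' @param background_seeds Same format, at least one seed, marking
#'   background.
#' @return An object of class `SeedSet`.
#' @export
seed_set <- function(cell_seeds, background_seeds) {
  cell_seeds <- matrix(as.integer(round(as.matrix(cell_seeds))), ncol = 2)
  background_seeds <-
    matrix(as.integer(round(as.matrix(background_seeds))), ncol = 2)
  if (nrow(cell_seeds) < 1L || nrow(background_seeds) < 1L)
    stop("need at least one cell seed and one background seed")
  if (anyDuplicated(cell_seeds))
    stop("cell seeds must be pairwise distinct")
  structure(list(cell_seeds = cell_seeds,
                 background_seeds = background_seeds),
            class = "SeedSet")
}

check_seed_bounds <- function(seeds, dm) {
  all_seeds <- rbind(seeds$cell_seeds, seeds$background_seeds)
  if (any(all_seeds < 0L) || any(all_seeds[, 1] >= dm[1]) ||
      any(all_seeds[, 2] >= dm[2]))
    stop("seed coordinates outside image bounds")
}

# Gradient magnitude by central differences (one-sided at the borders).
gradient_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gr <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  gr <- gr / ifelse(matrix(seq_len(nr) %in% c(1L, nr), nr, nc), 1, 2)
  gc <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  gc <- gc / ifelse(matrix(seq_len(nc) %in% c(1L, nc), nr, nc,
                           byrow = TRUE), 1, 2)
  sqrt(gr^2 + gc^2)
}

#' Manually seeded watershed segmentation
#'
#' Floods the gradient magnitude of a Gaussian-smoothed intensity image
#' from the supplied seeds. The region grown from the background seeds
#' becomes label 0; each cell seed produces one label, numbered in seed
#' order. Every pixel receives exactly one label (8-connectivity; ties in
#' the flood are broken by first-in-queue order with a fixed seed
#' insertion order, so the partition is deterministic). If two cell
#' regions first meet at a flood level no higher than either seed's own
#' gradient value, the seeds likely share a catchment basin: both labels
#' are still emitted but a warning is raised (no silent merge).
#'
#' @param intensity 2-D numeric matrix (typically the summed blue+red
#'   channel); all finite.
#' @param seeds A [seed_set()].
#' @param sigma Gaussian smoothing SD in pixels applied before the
#'   gradient (0 disables smoothing). The default of 1 px matches the
#'   apparent membrane thickness of diffraction-limited rings; larger
#'   values shift the gradient crest of a thin bright ring outward and
#'   inflate the labels.
#' @param gradient `"intensity"` (default) computes the gradient on the
#'   smoothed intensities; `"rank"` replaces intensities by their ranks
#'   first, which makes the segmentation invariant under any strictly
#'   increasing intensity transform.
#' @return An object of class `CellLabelMap`: `labels` (integer matrix,
#'   0 = background), `n_cells`.
#' @export
seeded_watershed <- function(intensity, seeds, sigma = 1,
                             gradient = c("intensity", "rank")) {
  gradient <- match.arg(gradient)
  intensity <- as.matrix(intensity)
  if (!all(is.finite(intensity)))
    stop("intensity must be finite everywhere")
  stopifnot(inherits(seeds, "SeedSet"))
  check_seed_bounds(seeds, dim(intensity))

  img <- intensity
  if (gradient == "rank")
    img <- matrix(rank(img, ties.method = "average"), nrow(img))
  if (sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = sigma))
  grad <- gradient_magnitude(img)

  seed_tab <- rbind(
    cbind(seeds$background_seeds, 0L),
    cbind(seeds$cell_seeds, seq_len(nrow(seeds$cell_seeds))))
  res <- .flood_watershed(grad, seed_tab)

  n_cells <- nrow(seeds$cell_seeds)
  if (length(res$pass_a)) {
    sg <- grad[seeds$cell_seeds + 1L]   # gradient at each cell seed
    low <- res$pass_height <= pmax(sg[res$pass_a], sg[res$pass_b]) + 1e-12
    if (any(low))
      warning(sprintf(
        "cell seeds may share a catchment basin (label pairs: %s)",
        paste(res$pass_a[low], res$pass_b[low], sep = "-",
              collapse = ", ")))
  }
  structure(list(labels = res$labels, n_cells = n_cells),
            class = "CellLabelMap")
}

#' @export
print.CellLabelMap <- function(x, ...) {
  cat(sprintf("CellLabelMap: %d x %d px, %d cells (%.1f%% background)\n",
              nrow(x$labels), ncol(x$labels), x$n_cells,
              100 * mean(x$labels == 0L)))
  invisible(x)
}

#' Extract per-cell plasma-membrane pixels
#'
#' For each cell, takes the band of pixels within `band_width` of the
#' label boundary on the inner side (the label region minus its box
#' erosion), then keeps the pixels whose total intensity is at or above
#' the `refinement_quantile` quantile within that band (the bright
#' membrane ring dominates the band's intensity distribution). Bands are
#' strictly inside their cell's label region, so per-cell masks are
#' pairwise disjoint by construction.
#'
#' @param labels A [seeded_watershed()] result (`CellLabelMap`).
#' @param total_intensity 2-D matrix of summed channel intensity, same
#'   shape as the label map.
#' @param band_width Band depth in pixels (>= 1).
#' @param refinement_quantile Fraction in `[0, 1)`; 0 keeps the whole
#'   band. The quantile is closed: pixels equal to the quantile value are
#'   retained.
#' @return An object of class `MembraneMask`: `masks` (per-cell vectors
#'   of pixel indices into the image), `band_width`,
#'   `refinement_quantile`, `dim`, and `excluded` (cells whose band was
#'   empty, also reported via a warning).
#' @export
extract_membrane <- function(labels, total_intensity, band_width = 3,
                             refinement_quantile = 0.5) {
  stopifnot(inherits(labels, "CellLabelMap"))
  if (band_width < 1) stop("band_width must be >= 1")
  if (refinement_quantile < 0 || refinement_quantile >= 1)
    stop("refinement_quantile must lie in [0, 1)")
  total_intensity <- as.matrix(total_intensity)
  if (!identical(dim(total_intensity), dim(labels$labels)))
    stop("total_intensity and label map shapes differ")

  brush <- EBImage::makeBrush(2 * band_width + 1, "box")
  masks <- vector("list", labels$n_cells)
  excluded <- integer(0)
  for (k in seq_len(labels$n_cells)) {
    mask <- labels$labels == k
    if (!any(mask)) { excluded <- c(excluded, k); next }
    core <- as.matrix(EBImage::erode(mask + 0, brush)) > 0.5
    band <- which(mask & !core)
    if (!length(band)) { excluded <- c(excluded, k); next }
    thr <- stats::quantile(total_intensity[band], refinement_quantile,
                           names = FALSE)
    masks[[k]] <- band[total_intensity[band] >= thr]
  }
  if (length(excluded))
    warning(sprintf("cells with empty membrane band excluded: %s",
                    paste(excluded, collapse = ", ")))
  structure(list(masks = masks, band_width = band_width,
                 refinement_quantile = refinement_quantile,
                 dim = dim(labels$labels), excluded = excluded),
            class = "MembraneMask")
}

#' Per-cell median GP over plasma-membrane pixels
#'
#' The per-cell readout: for each cell, the median of the GP map over the
#' intersection of its membrane pixels with the map's validity mask.
#' Cells with fewer than `min_pixels` valid membrane pixels are excluded
#' and reported (small pixel sets give unstable medians).
#'
#' @param gp A [gp_map()] result (`GPMap`).
#' @param membranes An [extract_membrane()] result (`MembraneMask`),
#'   same image shape.
#' @param min_pixels Minimum number of valid membrane pixels per cell.
#' @param treatment Optional treatment label attached to every record.
#' @return A data frame with columns `cell_id`, `treatment`, `median_gp`,
#'   `n_membrane_pixels`, one row per surviving cell, plus attribute
#'   `excluded` (integer vector of dropped cell ids). An empty result
#'   (no surviving cell) is returned as a zero-row data frame with a
#'   warning.
#' @export
per_cell_median_gp <- function(gp, membranes, min_pixels = 20,
                               treatment = NA_character_) {
  stopifnot(inherits(gp, "GPMap"), inherits(membranes, "MembraneMask"))
  if (!identical(dim(gp$gp), membranes$dim))
    stop("GP map and membrane masks have different image shapes")
  out <- lapply(seq_along(membranes$masks), function(k) {
    px <- membranes$masks[[k]]
    px <- px[gp$valid[px]]
    if (length(px) < min_pixels) return(NULL)
    data.frame(cell_id = k, treatment = treatment,
               median_gp = stats::median(gp$gp[px]),
               n_membrane_pixels = length(px))
  })
  keep <- !vapply(out, is.null, logical(1))
  excluded <- which(!keep)
  res <- if (any(keep)) do.call(rbind, out[keep]) else
    data.frame(cell_id = integer(0), treatment = character(0),
               median_gp = numeric(0), n_membrane_pixels = integer(0))
  if (!nrow(res))
    warning("no cell retained at least min_pixels valid membrane pixels")
  attr(res, "excluded") <- excluded
  res
}
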