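# Readers and writers shared by all stages. CSV dialect: comma-separated,
# UTF-8, header row, "." decimal, floats at 9 significant digits.

fmt9 <- function(x) {
  if (is.double(x)) formatC(x, digits = 9, format = "g") else x
}

write_csv9 <- function(df, path) {
  df[] <- lapply(df, fmt9)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Read / write emission spectra as CSV
#'
#' Columns `wavelength_nm,intensity`.
#'
#' @param path File path.
#' @param excitation_wavelength Excitation wavelength (nm) attached on
#'   read.
#' @return `read_spectrum_csv()` returns an [emission_spectrum()].
#' @export
read_spectrum_csv <- function(path, excitation_wavelength = 488) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop("spectrum CSV needs columns wavelength_nm,intensity")
  emission_spectrum(df$wavelength_nm, df$intensity,
                    excitation_wavelength = excitation_wavelength)
}

#' @rdname read_spectrum_csv
#' @param spectrum An [emission_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "EmissionSpectrum"))
  write_csv9(data.frame(wavelength_nm = spectrum$wavelengths,
                        intensity = spectrum$intensities), path)
  invisible(path)
}

#' Read / write watershed seeds as CSV
#'
#' Columns `row,col,kind` with 0-based coordinates and
#' `kind %in% c("cell", "background")`.
#'
#' @param path File path.
#' @return `read_seeds_csv()` returns a [seed_set()].
#' @export
read_seeds_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("row", "col", "kind") %in% names(df)))
    stop("seeds CSV needs columns row,col,kind")
  if (!all(df$kind %in% c("cell", "background")))
    stop("seed kind must be 'cell' or 'background'")
  seed_set(cell_seeds = as.matrix(df[df$kind == "cell", c("row", "col")]),
           background_seeds =
             as.matrix(df[df$kind == "background", c("row", "col")]))
}

#' @rdname read_seeds_csv
#' @param seeds A [seed_set()].
#' @export
write_seeds_csv <- function(seeds, path) {
  stopifnot(inherits(seeds, "SeedSet"))
  df <- rbind(
    data.frame(row = seeds$cell_seeds[, 1], col = seeds$cell_seeds[, 2],
               kind = "cell"),
    data.frame(row = seeds$background_seeds[, 1],
               col = seeds$background_seeds[, 2], kind = "background"))
  write_csv9(df, path)
  invisible(path)
}

# Intensities are stored normalized to [0, 1] as 32-bit float TIFF pages
# (the tiff package clamps samples outside [0, 1]); the scale factor and
# channel order live in a JSON sidecar restored on read. Declared
# round-trip precision: 32-bit float (~1e-6 relative).
tiff_sidecar <- function(path) paste0(path, ".json")

#' Read / write two-channel images as multichannel TIFF
#'
#' The image is written as a two-page 32-bit float TIFF (declared channel
#' order, default blue then red) normalized by a single scale factor that
#' is recorded in a JSON sidecar `<path>.json` and reapplied on read.
#'
#' @param image A [two_channel_image()].
#' @param path Output TIFF path.
#' @param channel_order Page order, a permutation of `c("blue", "red")`;
#'   on read it is overridden by the sidecar when one is present.
#' @return `read_two_channel_tiff()` returns a [two_channel_image()].
#' @export
write_two_channel_tiff <- function(image, path,
                                   channel_order = c("blue", "red")) {
  stopifnot(inherits(image, "TwoChannelImage"))
  scale <- max(image$blue, image$red, 1)
  pages <- lapply(channel_order, function(ch) image[[ch]] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = scale, channel_order = channel_order,
         pixel_size = image$pixel_size),
    tiff_sidecar(path), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_two_channel_tiff
#' @export
read_two_channel_tiff <- function(path, channel_order = c("blue", "red")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L)
    stop(sprintf("expected a 2-page TIFF, found %d pages", length(pages)))
  scale <- 1
  pixel_size <- NULL
  sc <- tiff_sidecar(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    scale <- meta$scale
    channel_order <- meta$channel_order
    pixel_size <- meta$pixel_size
  }
  names(pages) <- channel_order
  two_channel_image(pages[["blue"]] * scale, pages[["red"]] * scale,
                    pixel_size = pixel_size)
}

#' Write a GP map as float TIFF plus validity-mask TIFF
#'
#' The GP page stores `(gp + 1) / 2` (32-bit float in `[0, 1]`; invalid
#' pixels 0) and the mask page stores validity as 0/1; the affine
#' transform is recorded in a JSON sidecar and undone by the reader.
#'
#' @param gp A [gp_map()] result.
#' @param path Output TIFF path for the GP values; the mask goes to
#'   `<path base>_mask.tif`.
#' @return `read_gp_map_tiff()` returns a `GPMap`.
#' @export
write_gp_map_tiff <- function(gp, path) {
  stopifnot(inherits(gp, "GPMap"))
  enc <- (gp$gp + 1) / 2
  enc[!gp$valid] <- 0
  mask_path <- sub("(\\.[Tt][Ii][Ff]+)?$", "_mask.tif", path)[1]
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  tiff::writeTIFF(gp$valid + 0, mask_path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(encoding = "gp = 2 * stored - 1", mask = basename(mask_path),
         intensity_threshold = gp$intensity_threshold),
    tiff_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp_map_tiff
#' @export
read_gp_map_tiff <- function(path) {
  enc <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(tiff_sidecar(path), simplifyVector = TRUE)
  mask <- tiff::readTIFF(file.path(dirname(path), meta$mask)) > 0.5
  g <- 2 * enc - 1
  g[!mask] <- NA_real_
  structure(list(gp = g, valid = mask,
                 intensity_threshold = meta$intensity_threshold),
            class = "GPMap")
}

#' Write a cell label map as 16-bit TIFF
#'
#' @param labels A `CellLabelMap`.
#' @param path Output path.
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(inherits(labels, "CellLabelMap"))
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  m <- round(tiff::readTIFF(path) * 65535)
  structure(list(labels = matrix(as.integer(m), nrow(m)),
                 n_cells = max(m)),
            class = "CellLabelMap")
}

#' Read / write per-cell GP records as CSV
#'
#' Columns `cell_id,treatment,median_gp,n_membrane_pixels`.
#'
#' @param records Data frame from [per_cell_median_gp()].
#' @param path File path.
#' @export
write_cell_records_csv <- function(records, path) {
  write_csv9(records[, c("cell_id", "treatment", "median_gp",
                         "n_membrane_pixels")], path)
  invisible(path)
}

#' @rdname write_cell_records_csv
#' @export
read_cell_records_csv <- function(path) {
  utils::read.csv(path)
}

#' Read / write bilayer trajectories as plain CSV coordinate dumps
#'
#' Long format, one row per atom per frame: columns
#' `frame,time_ns,atom,name,x,y,z` (Angstrom).
#'
#' @param trajectory A `BilayerTrajectory`.
#' @param path File path.
#' @param p_name Phosphate atom name used to recover the leaflet atom
#'   indices on read.
#' @return `read_trajectory_csv()` returns a `BilayerTrajectory`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "BilayerTrajectory"))
  nf <- length(trajectory$times)
  na <- length(trajectory$atom_names)
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    time_ns = rep(trajectory$times, each = na),
    atom = rep(seq_len(na), nf),
    name = rep(trajectory$atom_names, nf),
    x = as.vector(trajectory$coords[, 1, ]),
    y = as.vector(trajectory$coords[, 2, ]),
    z = as.vector(trajectory$coords[, 3, ]))
  write_csv9(df, path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, p_name = "P") {
  df <- utils::read.csv(path)
  need <- c("frame", "time_ns", "atom", "name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("trajectory CSV needs columns ", paste(need, collapse = ","))
  frames <- sort(unique(df$frame))
  df <- df[order(df$frame, df$atom), ]
  na <- sum(df$frame == frames[1])
  coords <- array(NA_real_, c(na, 3, length(frames)))
  coords[, 1, ] <- df$x; coords[, 2, ] <- df$y; coords[, 3, ] <- df$z
  atom_names <- df$name[seq_len(na)]
  p_idx <- which(atom_names == p_name)
  structure(list(times = df$time_ns[!duplicated(df$frame)],
                 coords = coords, atom_names = atom_names,
                 p_atom_indices = p_idx,
                 dye_atom_indices = setdiff(seq_len(na), p_idx),
                 dye_heavy_indices = setdiff(seq_len(na), p_idx),
                 box = NULL),
            class = "BilayerTrajectory")
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL per frame (a standard trajectory container readable by any
#' MD tool and by `bio3d::read.pdb(multi = TRUE)`). Phosphates get
#' residue name `POP`, dye atoms `DYE`; atom names are the trajectory's.
#'
#' @inheritParams write_trajectory_csv
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "BilayerTrajectory"))
  na <- length(trajectory$atom_names)
  nf <- length(trajectory$times)
  xyz <- t(apply(trajectory$coords, 3, function(m) as.vector(t(m))))
  if (nf == 1L) xyz <- matrix(xyz, nrow = 1)
  resid <- ifelse(seq_len(na) %in% trajectory$p_atom_indices, "POP", "DYE")
  bio3d::write.pdb(file = path, xyz = xyz,
                   elety = trajectory$atom_names, resid = resid,
                   resno = seq_len(na))
  invisible(path)
}
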