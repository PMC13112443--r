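#' Default pipeline configuration
#'
#' Full configuration template for [run_pipeline()]: every tunable
#' parameter of the image pipeline with its default. Unknown keys in a
#' user configuration are rejected against this template, and the full
#' configuration is echoed verbatim into the run report.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    input = list(image = NULL, seeds = NULL, treatment = NA),
    background = list(blue = 0, red = 0),
    gp = list(intensity_threshold = NULL),   # NULL = Otsu on blue+red
    segment = list(sigma = 1, gradient = "intensity",
                   band_width = 3, refinement_quantile = 0.5,
                   min_pixels = 20),
    seed = 1L,
    out_dir = NULL)
}

merge_config <- function(user, template, path = "") {
  unknown <- setdiff(names(user), names(template))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      template[[k]] <- merge_config(
        if (is.list(user[[k]])) user[[k]] else
          stop(sprintf("config key %s%s must be a mapping", path, k)),
        template[[k]], paste0(path, k, "."))
    } else {
      template[k] <- user[k]
    }
  }
  template
}

#' Validate and complete a pipeline configuration
#'
#' @param config Nested list (e.g. from `yaml::read_yaml()`) or a path
#'   to a YAML file. Keys not present in [default_config()] are rejected
#'   by name; missing keys take their defaults.
#' @return The completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  merge_config(config, default_config())
}

#' Run the image pipeline end to end
#'
#' Orchestrates the per-image workflow: read the two-channel image and
#' the seed list, optional constant background subtraction, pixel-wise GP
#' with validity masking, seeded watershed, plasma-membrane extraction,
#' and per-cell median GP. Intermediate artifacts (GP map, label map,
#' per-cell records) and a machine-readable run report are written to
#' `out_dir` when one is configured. The run is deterministic given the
#' configuration and seed.
#'
#' @param config Configuration ([validate_config()] is applied). Instead
#'   of file paths, `input$image` may be a [two_channel_image()] and
#'   `input$seeds` a [seed_set()] directly.
#' @return A list with `records` (per-cell data frame) and `report`
#'   (class `RunReport`), invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  if (is.null(config$input$image) || is.null(config$input$seeds))
    stop("config must name input$image and input$seeds")

  checksums <- list()
  if (is.character(config$input$image)) {
    if (!file.exists(config$input$image))
      stop("input image not found: ", config$input$image)
    checksums$image <- unname(tools::md5sum(config$input$image))
    image <- read_two_channel_tiff(config$input$image)
  } else image <- config$input$image
  if (is.character(config$input$seeds)) {
    if (!file.exists(config$input$seeds))
      stop("seed file not found: ", config$input$seeds)
    checksums$seeds <- unname(tools::md5sum(config$input$seeds))
    seeds <- read_seeds_csv(config$input$seeds)
  } else seeds <- config$input$seeds
  stopifnot(inherits(image, "TwoChannelImage"), inherits(seeds, "SeedSet"))

  warnings <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  set.seed(config$seed)
  if (config$background$blue > 0 || config$background$red > 0)
    image <- subtract_background(image, config$background$blue,
                                 config$background$red)
  gp <- gp_map(image, intensity_threshold = config$gp$intensity_threshold)
  total <- image$blue + image$red
  labels <- collect(seeded_watershed(total, seeds,
                                     sigma = config$segment$sigma,
                                     gradient = config$segment$gradient))
  membranes <- collect(extract_membrane(
    labels, total, band_width = config$segment$band_width,
    refinement_quantile = config$segment$refinement_quantile))
  records <- collect(per_cell_median_gp(
    gp, membranes, min_pixels = config$segment$min_pixels,
    treatment = config$input$treatment))

  report <- structure(list(
    tool = "gpmembrane",
    version = as.character(utils::packageVersion("gpmembrane")),
    config = config_echo(config),
    input_checksums = checksums,
    counts = list(
      pixels_total = length(gp$valid),
      pixels_valid = sum(gp$valid),
      pixels_masked = sum(!gp$valid),
      intensity_threshold = gp$intensity_threshold,
      cells_seeded = labels$n_cells,
      cells_excluded = length(attr(records, "excluded")),
      cells_reported = nrow(records)),
    warnings = warnings), class = "RunReport")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gp_map_tiff(gp, file.path(config$out_dir, "gp_map.tif"))
    write_labels_tiff(labels, file.path(config$out_dir, "labels.tif"))
    write_cell_records_csv(records,
                           file.path(config$out_dir, "cell_records.csv"))
    write_run_report(report, file.path(config$out_dir, "run_report.json"))
  }
  invisible(list(records = records, report = report,
                 gp = gp, labels = labels, membranes = membranes))
}

# config values serializable for the JSON report (in-memory inputs are
# described, not embedded)
config_echo <- function(config) {
  ech <- config
  if (!is.character(ech$input$image) && !is.null(ech$input$image))
    ech$input$image <- "<in-memory TwoChannelImage>"
  if (!is.character(ech$input$seeds) && !is.null(ech$input$seeds))
    ech$input$seeds <- "<in-memory SeedSet>"
  ech
}

#' Write a run report as JSON
#'
#' @param report A `RunReport`.
#' @param path Output path.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "RunReport"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("gpmembrane run report (v%s)\n", x$version))
  cat(sprintf("  pixels valid: %d / %d (threshold %.4g)\n",
              x$counts$pixels_valid, x$counts$pixels_total,
              x$counts$intensity_threshold))
  cat(sprintf("  cells: %d seeded, %d reported, %d excluded\n",
              x$counts$cells_seeded, x$counts$cells_reported,
              x$counts$cells_excluded))
  if (length(x$warnings))
    cat("  warnings:\n", paste("   -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
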