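# End-to-end batch runs from a config: load images, build the difference
# matrix, weight, score, persist. Every parameter actually used (including
# defaults) is echoed to the run log so results are auditable.

#' Assemble and validate a run configuration
#'
#' @param camouflage Character vector of image paths, or a single directory
#'   (all PNG/TIFF/JPEG files inside, sorted by name).
#' @param backgrounds Same, for the background images.
#' @param geometry A [viewing_geometry()], or a list with either `spd` or
#'   `distance_mm` + `pixel_pitch_mm`. Default: 35 samples per degree.
#' @param equalize_policy `"resize"` or `"crop"`.
#' @param gms_c GMS stability constant.
#' @param channel_policy Gradient plane policy (see
#'   [gradient_magnitude()]).
#' @param orientation Score orientation (see [aggregate_scores()]).
#' @param out_dir Output directory for `scores.csv`,
#'   `difference_matrix.csv`, `report.json` and `run_log.txt`; `NULL`
#'   skips writing.
#' @param subjective Optional path to a CSV with columns
#'   `pattern_id,hit_rate,detection_time,difficulty` for the correlation
#'   analysis.
#' @return A validated `run_config`.
#' @export
run_config <- function(camouflage, backgrounds,
                       geometry = list(spd = 35),
                       equalize_policy = "resize", gms_c = 0.0026,
                       channel_policy = "luminance",
                       orientation = "per_camouflage",
                       out_dir = NULL, subjective = NULL) {
  camo_paths <- resolve_image_paths(camouflage, "camouflage")
  bg_paths <- resolve_image_paths(backgrounds, "background")
  geom <- if (inherits(geometry, "viewing_geometry")) {
    geometry
  } else {
    do.call(viewing_geometry, geometry)
  }
  if (!is.null(subjective) && !file.exists(subjective)) {
    stop("subjective response file does not exist: ", subjective)
  }
  structure(list(camo_paths = camo_paths, bg_paths = bg_paths, geom = geom,
                 equalize_policy = equalize_policy, gms_c = gms_c,
                 channel_policy = channel_policy, orientation = orientation,
                 out_dir = out_dir, subjective = subjective),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Accepts the same fields as [run_config()]; `geometry` may be a mapping
#' with `spd` or `distance_mm`/`pixel_pitch_mm`. Relative image paths are
#' resolved against the config file's directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rebase <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  args <- list(camouflage = rebase(unlist(raw$camouflage)),
               backgrounds = rebase(unlist(raw$backgrounds)))
  if (!is.null(raw$geometry)) args$geometry <- raw$geometry
  for (f in c("equalize_policy", "gms_c", "channel_policy", "orientation")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$out_dir)) args$out_dir <- rebase(raw$out_dir)
  if (!is.null(raw$subjective)) args$subjective <- rebase(raw$subjective)
  do.call(run_config, args)
}

resolve_image_paths <- function(x, what) {
  if (length(x) == 0L) stop("no ", what, " images specified")
  if (length(x) == 1L && dir.exists(x)) {
    x <- sort(list.files(x, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                         ignore.case = TRUE, full.names = TRUE))
    if (length(x) == 0L) stop("no images found in ", what, " directory")
  }
  missing <- x[!file.exists(x)]
  if (length(missing) > 0L) {
    stop("missing ", what, " images: ", paste(missing, collapse = ", "))
  }
  x
}

#' Run a full camouflage-effectiveness assessment
#'
#' Loads all images, computes the ICSI/GMSD difference matrix, derives
#' entropy weights, aggregates conspicuousness scores and (when `out_dir`
#' is set) persists `scores.csv`, `difference_matrix.csv`, `report.json`
#' and a parameter log. Outputs are deterministic: the same config yields
#' byte-identical CSV files.
#'
#' @param cfg A [run_config()] or path to a YAML config.
#' @return List with `report` (a `score_report`), `matrix`
#'   (`difference_matrix`), `weights`, and `correlations` when a
#'   subjective table was supplied.
#' @export
run_compute <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) stop("expected a run_config")
  camos <- lapply(cfg$camo_paths, load_image)
  names(camos) <- tools::file_path_sans_ext(basename(cfg$camo_paths))
  bgs <- lapply(cfg$bg_paths, load_image)
  names(bgs) <- tools::file_path_sans_ext(basename(cfg$bg_paths))
  config <- pair_config(equalize_policy = cfg$equalize_policy,
                        gms_c = cfg$gms_c,
                        channel_policy = cfg$channel_policy)
  x <- build_difference_matrix(camos, bgs, cfg$geom, config)
  w <- entropy_weights(x)
  report <- aggregate_scores(x, w, orientation = cfg$orientation)
  out <- list(report = report, matrix = x, weights = w)
  if (!is.null(cfg$subjective)) {
    subj <- utils::read.csv(cfg$subjective, stringsAsFactors = FALSE)
    out$correlations <- correlate_with_subjective(report, subj)
  }
  if (!is.null(cfg$out_dir)) persist_run(cfg, out)
  out
}

persist_run <- function(cfg, out) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(out$report),
                   file.path(cfg$out_dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  write_difference_matrix(out$matrix,
                          file.path(cfg$out_dir, "difference_matrix.csv"))
  payload <- list(
    weights = as.list(out$weights),
    orientation = attr(out$report, "orientation"),
    polarity = attr(out$report, "polarity"),
    scores = as.data.frame(out$report)
  )
  if (!is.null(out$correlations)) {
    payload$correlations <- as.list(out$correlations)
  }
  jsonlite::write_json(payload, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    "camoscore run parameters",
    sprintf("camouflage images (%d): %s", length(cfg$camo_paths),
            paste(cfg$camo_paths, collapse = ", ")),
    sprintf("background images (%d): %s", length(cfg$bg_paths),
            paste(cfg$bg_paths, collapse = ", ")),
    sprintf("samples_per_degree: %.6f", samples_per_degree(cfg$geom)),
    sprintf("equalize_policy: %s", cfg$equalize_policy),
    sprintf("gms_c: %g", cfg$gms_c),
    sprintf("channel_policy: %s", cfg$channel_policy),
    sprintf("orientation: %s", cfg$orientation),
    sprintf("white_point: %s", paste(white_d65(), collapse = " ")),
    sprintf("filter_params: %s",
            system.file("extdata", "scielab-filters.yaml",
                        package = "camoscore"))
  )
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(NULL)
}
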