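# End-to-end orchestration: strict YAML config validation with a single
# defaults table holding every numeric constant of the imaging procedure,
# and a deterministic simulate/segment/classify/quantify/summarize run that
# writes per-cell tables, a slide summary and a manifest.

# Every procedural constant in one auditable place.
pipeline_defaults <- function() {
  list(
    segmentation = list(min_filter_size = 50, sat_low_pct = 5, sat_high_pct = 95,
                        nuc_threshold = 0.4, min_area = 10, split_area = 200,
                        max_single_area = NULL, connectivity = 8,
                        marker_merge_dist = 3, watershed_tolerance = 1),
    quantification = list(expansion_radius = 10, min_overlap = 5,
                          positivity_region = "cell", combine = "region_means",
                          elongation_markers = list(),
                          elongation = list(min_area = 20, min_ratio = 0.5,
                                            perimeter = "steps"),
                          double_positive_pairs = list()),
    classifier = list(model = NULL),
    ihc = list(positive_threshold = 0.1, bins = c(0.2, 0.4, 0.6)),
    expression = list(efficiency = 2, fold_cut = 2, p_cut = 0.05),
    seed = 1,
    log_level = "info")
}

# recursive strict merge: unknown keys error with their full path
merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    if (is.null(user[[k]])) next   # explicit null keeps the default
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], key)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent list), checks it against a strict
#' schema — unknown keys, missing DAPI mapping, duplicate channel names and
#' invalid numeric settings are keyed errors — and fills every default from
#' the package's single defaults table. No partial configs escape.
#'
#' @param config path to a YAML file, or a list.
#' @return a normalized `run_config` list with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  if (is.null(config$input)) stop("missing config key 'input'", call. = FALSE)
  if (is.null(config$input$image)) stop("missing config key 'input.image'", call. = FALSE)
  channels <- config$input$channels
  if (is.null(channels)) stop("missing config key 'input.channels'", call. = FALSE)
  ch_names <- names(channels)
  if (anyDuplicated(ch_names))
    stop(sprintf("duplicate channel name '%s' in input.channels",
                 ch_names[duplicated(ch_names)][1]), call. = FALSE)
  if (!"DAPI" %in% ch_names)
    stop("input.channels must map a 'DAPI' channel", call. = FALSE)
  pages <- unlist(channels)
  if (anyDuplicated(pages))
    stop("input.channels maps two channels to the same page", call. = FALSE)

  user <- config
  user$input <- NULL
  output <- user$output; user$output <- NULL
  full <- merge_config(pipeline_defaults(), user)
  full$input <- list(image = config$input$image, channels = channels)
  full$output <- output

  seg <- full$segmentation
  if (seg$min_area <= 0) stop("segmentation.min_area must be > 0", call. = FALSE)
  # constructor re-checks the joint constraints
  do.call(seg_config, seg)
  q <- full$quantification
  if (q$expansion_radius <= 0) stop("quantification.expansion_radius must be > 0", call. = FALSE)
  if (q$min_overlap < 0) stop("quantification.min_overlap must be >= 0", call. = FALSE)
  known <- setdiff(ch_names, "DAPI")
  for (m in unlist(q$elongation_markers))
    if (!m %in% known)
      stop(sprintf("quantification.elongation_markers names unknown channel '%s'", m), call. = FALSE)
  for (pr in q$double_positive_pairs) {
    pr <- unlist(pr)
    if (length(pr) != 2 || !all(pr %in% known))
      stop("quantification.double_positive_pairs must be pairs of known marker channels", call. = FALSE)
  }
  # canonical forms that survive YAML serialization
  full$quantification$elongation_markers <- as.character(unlist(q$elongation_markers))
  full$quantification$double_positive_pairs <-
    lapply(q$double_positive_pairs, function(pr) as.character(unlist(pr)))
  structure(full, class = "run_config")
}

#' Run the full quantification pipeline on one image
#'
#' Stages: read image -> segment nuclei -> compute features -> classify ->
#' CAM exclusion -> cytoplasm assignment -> marker quantification -> slide
#' summary. Writes `per_cell.csv`, `slide_summary.csv`,
#' `double_positive.csv`, `nuclei.csv` and `manifest.json` into the output
#' directory. Identical config and inputs give identical output CSVs.
#'
#' @param config a `run_config` from [validate_config()] (or something
#'   coercible by it).
#' @param output_dir overrides `config$output`.
#' @return the `slide_summary`, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- if (!is.null(output_dir)) output_dir else config$output
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  log_msg <- function(stage, ...) {
    if (identical(config$log_level, "quiet")) return(invisible())
    message(sprintf("[camquant:%s] %s", stage, sprintf(...)))
  }
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  loaded <- stage("read", {
    pages <- tiff::readTIFF(config$input$image, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    chmap <- config$input$channels
    chans <- lapply(chmap, function(p) {
      if (p > length(pages)) stop(sprintf("channel page %d beyond TIFF page count", p))
      m <- pages[[p]]; mode(m) <- "integer"; m
    })
    structure(list(channels = chans, height = nrow(chans[[1]]),
                   width = ncol(chans[[1]]), bit_depth = 8L),
              class = "image_scene")
  })
  log_msg("read", "%d channels, %dx%d px", length(loaded$channels), loaded$height, loaded$width)

  seg_cfg <- do.call(seg_config, config$segmentation)
  labels <- stage("segment", segment_nuclei(loaded, seg_cfg))
  log_msg("segment", "%d nuclei", max(labels))
  if (max(labels) == 0L) stop("stage 'segment' found no nuclei", call. = FALSE)

  records <- stage("classify", {
    feats <- compute_features(labels)
    model <- if (is.null(config$classifier$model)) default_classifier()
             else read_model(config$classifier$model)
    classify_nuclei(feats, model)
  })
  parts <- exclude_cam(records)
  log_msg("classify", "%d human-analysis, %d CAM-excluded",
          nrow(parts$human_analysis), nrow(parts$excluded))

  q <- config$quantification
  regions <- stage("cytoplasm", assign_cytoplasm(labels, q$expansion_radius))
  meas <- stage("quantify", quantify_markers(
    loaded, regions, records,
    elongation_markers = unlist(q$elongation_markers),
    min_overlap = q$min_overlap,
    min_filter_size = config$segmentation$min_filter_size,
    positivity_region = q$positivity_region,
    elongation = q$elongation,
    combine = q$combine))
  pairs <- lapply(q$double_positive_pairs, unlist)
  summary <- stage("summarize", summarize_slide(meas, pairs))

  stage("write", {
    utils::write.csv(meas, file.path(out_dir, "per_cell.csv"), row.names = FALSE)
    utils::write.csv(records, file.path(out_dir, "nuclei.csv"), row.names = FALSE)
    utils::write.csv(summary$markers, file.path(out_dir, "slide_summary.csv"), row.names = FALSE)
    utils::write.csv(summary$double_positive, file.path(out_dir, "double_positive.csv"),
                     row.names = FALSE)
    TRUE
  })

  cfg_for_hash <- unclass(config)
  cfg_for_hash$output <- NULL
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_for_hash, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(
    package = "camquant",
    version = as.character(utils::packageVersion("camquant")),
    config = cfg_for_hash,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    n_nuclei = max(labels),
    timings_s = timings)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  log_msg("done", "outputs in %s", out_dir)
  invisible(summary)
}
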