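# Configuration, reporting and end-to-end subcommands
# (simulate / annotate / profile / fullrun).

#' Default run configuration
#'
#' One structured document holding every tunable of the pipeline; flags
#' or code may override individual fields, and the full configuration is
#' echoed (with a hash) into every report so runs are reproducible.
#'
#' @param parent parent compound id (see [parent_compound()]).
#' @param seed RNG seed; all randomness flows from it.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(parent = "5F-ADB-PINACA", seed = 1L) {
  structure(list(
    parent = parent,
    ms1_tolerance_ppm = 5,
    ms2_tolerance_ppm = 10,
    depth_limit = 3L,
    ruleset_path = NULL,
    correlation_threshold = 0.8,
    normalization = "global_max",
    trend_thresholds = default_trend_thresholds(),
    noise = list(sigma_lognormal = 0.2, ppm_jitter = 1, replicates = 3L),
    seed = as.integer(seed),
    input = list(peaks = NULL, ms2 = NULL, intensity = NULL),
    output_dir = NULL
  ), class = "run_config")
}

#' Load a run configuration from JSON
#'
#' Fields present in the file override the defaults; unknown fields are
#' rejected.
#' @param path JSON file.
#' @param base configuration to override (default [default_config()]).
#' @return A validated `run_config`.
#' @export
load_config <- function(path, base = default_config()) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(doc), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(doc)) {
    if (nm %in% c("trend_thresholds", "noise", "input")) {
      base[[nm]][names(doc[[nm]])] <- doc[[nm]]
    } else base[[nm]] <- doc[[nm]]
  }
  validate_config(base)
}

#' Validate a run configuration
#' @param config a `run_config`.
#' @return The config, invisibly classed, or an error of class
#'   `config_error`.
#' @export
validate_config <- function(config) {
  fail <- function(...) stop(structure(
    class = c("config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))))
  if (!config$parent %in% c("5F-ADB-PINACA", "5F-ADBICA"))
    fail("unknown parent: ", config$parent)
  if (config$ms1_tolerance_ppm <= 0 || config$ms2_tolerance_ppm <= 0)
    fail("tolerances must be positive")
  if (!config$normalization %in% c("global_max", "per_metabolite"))
    fail("unknown normalization mode: ", config$normalization)
  if (config$correlation_threshold <= 0 || config$correlation_threshold >= 1)
    fail("correlation threshold must be in (0, 1)")
  if (config$depth_limit < 1) fail("depth_limit must be >= 1")
  structure(config, class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

.version_string <- function() {
  as.character(utils::packageVersion("biotransformr"))
}

.report_header <- function(config) {
  list(tool = "biotransformr", version = .version_string(),
       config_hash = config_hash(config),
       config = unclass(config))
}

.ruleset_from_config <- function(config, scaffold) {
  rs <- if (!is.null(config$ruleset_path)) read_ruleset(config$ruleset_path)
        else default_ruleset(scaffold)
  rs$depth_limit <- as.integer(config$depth_limit)
  rs
}

#' Run the annotation stage
#'
#' Reads the configured peak list (and optional MS2 table), annotates it
#' against the enumerated candidates of the configured parent, and, when
#' `output_dir` is set, writes `annotation.csv` and `annotation_report.json`.
#'
#' @param config a `run_config` (see [default_config()], [load_config()]).
#' @return List with `table` (annotation data.frame), `result`
#'   (`annotation_result`), `report` (the JSON payload).
#' @export
run_annotate <- function(config) {
  config <- validate_config(config)
  if (is.null(config$input$peaks))
    stop(structure(class = c("input_error", "error", "condition"),
                   list(message = "config$input$peaks is required",
                        call = sys.call())))
  if (!file.exists(config$input$peaks))
    stop(structure(class = c("input_error", "error", "condition"),
                   list(message = paste0("missing input file: ",
                                         config$input$peaks),
                        call = sys.call())))
  peaks <- load_peaklist(config$input$peaks)
  ms2 <- if (!is.null(config$input$ms2)) load_ms2(config$input$ms2)
  p <- parent_compound(config$parent)
  rs <- .ruleset_from_config(config, p$scaffold)
  res <- annotate_dataset(peaks, ms2, p, rs,
                          tolerance_ppm = config$ms1_tolerance_ppm,
                          ms2_tolerance_ppm = config$ms2_tolerance_ppm)
  tab <- annotation_table(res)
  report <- c(.report_header(config),
              list(summary = res$summary, n_records = nrow(tab)))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$output_dir, "annotation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report,
                         file.path(config$output_dir,
                                   "annotation_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(table = tab, result = res, report = report)
}

#' Run the temporal profiling stage
#'
#' Aggregates replicates, normalizes, classifies trends, clusters by
#' correlation, categorizes, nominates biomarkers; when `output_dir` is
#' set writes `trends.csv`, `correlation.csv`, `clusters.csv`,
#' `heatmap_matrix.csv` and `biomarkers.json`.
#'
#' @param config a `run_config` with `input$intensity` set.
#' @return List with `aggregated`, `normalized`, `trends`, `correlation`,
#'   `clusters`, `categories`, `nomination`, `report`.
#' @export
run_profile <- function(config) {
  config <- validate_config(config)
  if (is.null(config$input$intensity) ||
      !file.exists(config$input$intensity))
    stop(structure(class = c("input_error", "error", "condition"),
                   list(message = "missing intensity input",
                        call = sys.call())))
  im <- read_intensity_csv(config$input$intensity)
  agg <- aggregate_replicates(im)
  norm <- normalize_matrix(agg, config$normalization)
  trends <- classify_trends(norm, config$trend_thresholds)
  cm <- correlation_matrix(agg)
  clusters <- threshold_clusters(cm, config$correlation_threshold)
  categories <- categorize(trends, clusters, norm)
  nomination <- nominate_biomarkers(categories, norm, cm, clusters)
  report <- c(.report_header(config), list(
    categories = as.list(categories),
    top_biomarker = nomination$top,
    top_per_category = nomination$top_per_category,
    components = clusters$components
  ))
  if (!is.null(config$output_dir)) {
    d <- config$output_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trends, file.path(d, "trends.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cm), file.path(d, "correlation.csv"))
    utils::write.csv(
      data.frame(metabolite_id = names(clusters$membership),
                 component = clusters$membership,
                 category = categories[names(clusters$membership)]),
      file.path(d, "clusters.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(norm),
                     file.path(d, "heatmap_matrix.csv"))
    jsonlite::write_json(c(report,
                           list(ranking = nomination$ranking)),
                         file.path(d, "biomarkers.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(aggregated = agg, normalized = norm, trends = trends,
       correlation = cm, clusters = clusters, categories = categories,
       nomination = nomination, report = report)
}

#' Run the simulation stage
#'
#' Generates the default reference-like study for the configured parent
#' and seed; when `output_dir` is set, writes the study files (see
#' [write_study()]).
#'
#' @param config a `run_config`.
#' @return The `synthetic_study`.
#' @export
run_simulate <- function(config) {
  config <- validate_config(config)
  noise <- noise_spec(config$noise$sigma_lognormal,
                      config$noise$ppm_jitter,
                      config$noise$replicates,
                      seed = config$seed)
  study <- default_paper_like_study(config$parent, noise = noise)
  if (!is.null(config$output_dir))
    write_study(study, config$output_dir)
  study
}

#' Simulate, annotate, profile, and consolidate
#'
#' Full pipeline on the default reference-like study: generates the study
#' from the config seed, annotates its peak list, profiles its intensity
#' table, computes annotation recall against the planted ground truth,
#' and (when `output_dir` is set) writes `fullrun_report.json` plus all
#' stage outputs.
#'
#' @param config a `run_config`.
#' @return List with `study`, `annotation`, `profile`, `recall`, `report`.
#' @export
run_fullrun <- function(config) {
  config <- validate_config(config)
  study <- run_simulate(config)
  p <- parent_compound(config$parent)
  rs <- .ruleset_from_config(config, p$scaffold)
  ann <- annotate_dataset(study$peaks, study$ms2, p, rs,
                          tolerance_ppm = config$ms1_tolerance_ppm,
                          ms2_tolerance_ppm = config$ms2_tolerance_ppm)
  planted <- study$ground_truth$id[!study$ground_truth$is_parent]
  matched <- vapply(ann$records, `[[`, "", "peak_id")
  recall <- if (length(planted))
    length(intersect(planted, matched)) / length(planted) else 1
  # profile from the study's intensity table
  agg <- aggregate_replicates(intensity_matrix(study$intensity))
  norm <- normalize_matrix(agg, config$normalization)
  trends <- classify_trends(norm, config$trend_thresholds)
  cm <- correlation_matrix(agg)
  clusters <- threshold_clusters(cm, config$correlation_threshold)
  categories <- categorize(trends, clusters, norm)
  nomination <- nominate_biomarkers(categories, norm, cm, clusters)
  report <- c(.report_header(config), list(
    recall = recall,
    n_planted = length(planted),
    n_matched = ann$summary$n_matched,
    categories = as.list(categories),
    trend_classes = stats::setNames(as.list(trends$class),
                                    trends$metabolite_id),
    top_biomarker = nomination$top
  ))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_study(study, config$output_dir)
    utils::write.csv(annotation_table(ann),
                     file.path(config$output_dir, "annotation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report,
                         file.path(config$output_dir,
                                   "fullrun_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(study = study, annotation = ann,
       profile = list(trends = trends, correlation = cm,
                      clusters = clusters, categories = categories,
                      nomination = nomination),
       recall = recall, report = report)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `annotate`, `profile`,
#' `fullrun`. Arguments: `<subcommand> [--config path.json] [--parent id]
#' [--seed n] [--out dir] [--peaks csv] [--ms2 csv] [--intensity csv]`.
#' Flags override config-file fields. Returns (rather than calls
#' `quit()` with) the exit status: 0 on success, 2 for configuration
#' errors, 3 for input errors, 1 otherwise — the installed script
#' `inst/cli/biotransformr` forwards it to the shell.
#'
#' @param args character vector (default `commandArgs(TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: biotransformr <simulate|annotate|profile|fullrun>",
    "[--config cfg.json] [--parent id] [--seed n] [--out dir]",
    "[--peaks csv] [--ms2 csv] [--intensity csv]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args)) {
      message("bad argument: ", args[i]); return(invisible(2L))
    }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    config <- if (!is.null(opt$config)) load_config(opt$config)
              else default_config()
    if (!is.null(opt$parent)) config$parent <- opt$parent
    if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
    if (!is.null(opt$out)) config$output_dir <- opt$out
    if (!is.null(opt$peaks)) config$input$peaks <- opt$peaks
    if (!is.null(opt$ms2)) config$input$ms2 <- opt$ms2
    if (!is.null(opt$intensity)) config$input$intensity <- opt$intensity
    if (is.null(config$seed)) {
      config$seed <- sample.int(1e6, 1)
      message("seed not given; drew seed ", config$seed)
    }
    res <- switch(cmd,
      simulate = run_simulate(config),
      annotate = run_annotate(config),
      profile  = run_profile(config),
      fullrun  = run_fullrun(config),
      { message("unknown subcommand: ", cmd, "\n", usage)
        return(invisible(2L)) })
    0L
  },
  config_error = function(e) { message("config error: ",
                                       conditionMessage(e)); 2L },
  input_error = function(e) { message("input error: ",
                                      conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
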