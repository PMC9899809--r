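# File-based pipeline: simulate -> analyze -> stats, driven by a single
# config (YAML/JSON or an R list). A thin command-line wrapper over these
# functions ships in inst/scripts/ucm_pipeline.R.

# 32-bit polynomial rolling hash of the canonicalized config, embedded in
# every artifact header (stable fingerprint, not cryptographic)
.config_hash <- function(config) {
  config <- config[setdiff(names(config), c("out_dir", "input_dir"))]
  s <- utf8ToInt(paste(deparse(config[order(names(config))]), collapse = ""))
  h <- 5381
  for (b in s) h <- (h * 33 + b) %% 4294967296
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

.header_lines <- function(config) {
  c(sprintf("# config_hash: %s", .config_hash(config)),
    sprintf("# seed: %d", config$seed))
}

#' Load and validate a pipeline run configuration
#'
#' @param config A named list, or path to a YAML/JSON file. Recognised
#'   fields: `out_dir` (required for the file-based stages), `seed`,
#'   `cutoff_hz`, `order`, `sharing_floor_n`, `trim_s`, `outcome`, `alpha`,
#'   and a `cohort` sub-list of [cohort_spec()] arguments.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, cutoff_hz = 4, order = 4L,
                   sharing_floor_n = 0.5, trim_s = 0,
                   outcome = "delta_v", alpha = 0.05, cohort = list())
  config <- utils::modifyList(defaults, config)
  config$seed <- as.integer(config$seed)
  if (!is.null(config$cohort$sharing) &&
      abs(sum(config$cohort$sharing) - 1) > 1e-12)
    stop("invalid config field 'cohort$sharing': must sum to 1")
  structure(config, class = c("run_config", "list"))
}

.cohort_from_config <- function(config) {
  args <- config$cohort
  args$seed <- config$seed
  do.call(cohort_spec, args)
}

#' Simulate a cohort to disk
#'
#' Writes one trial CSV per trial under `out_dir/trials/`, plus
#' `subjects.tsv` and `ground_truth.tsv`. Every file embeds the config hash
#' and seed in `#`-comment header lines; the same config and seed reproduce
#' the files byte for byte.
#'
#' @param config A [run_config()] (list or path) with `out_dir` set.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config) {
  config <- run_config(config)
  if (is.null(config$out_dir)) stop("config must set out_dir")
  trial_dir <- file.path(config$out_dir, "trials")
  dir.create(trial_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- simulate_cohort(.cohort_from_config(config))
  hdr <- .header_lines(config)
  paths <- character(0)
  for (tr in coh$trials) {
    p <- file.path(trial_dir, sprintf("%s_trial%02d.csv",
                                      tr$meta$subject, tr$meta$trial))
    tr$meta <- c(tr$meta, list(config_hash = .config_hash(config)))
    write_trial_csv(tr, p)
    paths <- c(paths, p)
  }
  write_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    con <- file(p, "w"); on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(paths, write_tsv(coh$subjects, "subjects.tsv"),
             write_tsv(coh$ground_truth$trials, "ground_truth.tsv"))
  invisible(paths)
}

#' Analyse trial CSVs on disk into a results TSV
#'
#' Reads every `*.csv` under `out_dir/trials/`, runs [analyze_trials()], and
#' writes `results.tsv` (one row per trial) and `subject_summary.tsv`.
#'
#' @param config A [run_config()] with `out_dir` set.
#' @return Invisibly, the results data frame.
#' @export
run_analyze <- function(config) {
  config <- run_config(config)
  trial_dir <- file.path(config$out_dir, "trials")
  files <- sort(list.files(trial_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no trial CSVs found under ", trial_dir)
  trials <- lapply(files, read_trial_csv)
  res <- analyze_trials(trials, cutoff_hz = config$cutoff_hz,
                        order = config$order, trim_s = config$trim_s,
                        sharing_floor_n = config$sharing_floor_n)
  hdr <- .header_lines(config)
  for (nm in c("results.tsv", "subject_summary.tsv")) {
    df <- if (nm == "results.tsv") res else summarize_subjects(res)
    p <- file.path(config$out_dir, nm)
    con <- file(p, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(res)
}

#' Run model selection on a results TSV
#'
#' Reads `out_dir/subject_summary.tsv`, runs [select_synergy_model()] on the
#' configured outcome, and writes `selection.json` plus a readable
#' `selection.txt`.
#'
#' @param config A [run_config()] with `out_dir` set.
#' @return Invisibly, the `synergy_selection` object.
#' @export
run_stats <- function(config) {
  config <- run_config(config)
  p <- file.path(config$out_dir, "subject_summary.tsv")
  if (!file.exists(p)) stop("missing ", p, "; run run_analyze() first")
  tab <- utils::read.delim(p, comment.char = "#")
  if (!config$outcome %in% names(tab))
    stop("outcome column '", config$outcome, "' not present in ", p)
  sel <- select_synergy_model(tab, outcome = config$outcome,
                              alpha = config$alpha)
  out <- list(config_hash = .config_hash(config), seed = config$seed,
              outcome = sel$outcome,
              aic_by_random = as.list(sel$aic_by_random),
              random_subject = sel$random_subject,
              bic_by_fixed = as.list(sel$bic_by_fixed),
              selected = sel$selected, terms = sel$terms)
  jsonlite::write_json(out, file.path(config$out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(config$out_dir, "selection.txt"), "w")
  sink(con); print(sel); sink()
  close(con)
  invisible(sel)
}
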