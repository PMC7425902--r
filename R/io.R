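# Trial-table column registry: name -> required? Stable column order for
# writing. generating_process is simulation ground truth and optional.
TRIAL_COLUMNS <- c(subject = TRUE, group = TRUE, frame = TRUE,
                   session = TRUE, block = FALSE, trial = TRUE,
                   tp_code = TRUE, tot_code = TRUE,
                   P = TRUE, a = TRUE, A = TRUE,
                   choice = TRUE, rt_ms = TRUE, generating_process = FALSE)

#' Validate a trial table against the project schema
#'
#' Checks column presence, choice coding (0/1/NA), positive RTs,
#' probabilities in (0, 1), and TP/ToT codes in \{-1, 0, 1\} (NA allowed for
#' self-paced priming rows). Violations are reported with the offending
#' line numbers (header = line 1, so data row i is line i + 1).
#'
#' @param trials A data frame.
#' @return `trials`, invisibly, if valid.
#' @export
validate_trials <- function(trials) {
  required <- names(TRIAL_COLUMNS)[TRIAL_COLUMNS]
  missing <- setdiff(required, names(trials))
  if (length(missing))
    stop("trial-table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(trials) == 0)
    stop("trial-table schema error: no data rows", call. = FALSE)
  line <- function(i) paste(i + 1L, collapse = ", ")
  bad <- which(!(trials$choice %in% c(0, 1) | is.na(trials$choice)))
  if (length(bad))
    stop("trial-table schema error: choice must be 0, 1 or NA on line(s) ",
         line(bad), call. = FALSE)
  bad <- which(!is.na(trials$rt_ms) & trials$rt_ms <= 0)
  if (length(bad))
    stop("trial-table schema error: rt_ms must be positive on line(s) ",
         line(bad), call. = FALSE)
  bad <- which(!is.finite(trials$P) | trials$P <= 0 | trials$P >= 1)
  if (length(bad))
    stop("trial-table schema error: P must lie in (0, 1) on line(s) ",
         line(bad), call. = FALSE)
  for (cc in c("tp_code", "tot_code")) {
    bad <- which(!(trials[[cc]] %in% c(-1, 0, 1) | is.na(trials[[cc]])))
    if (length(bad))
      stop("trial-table schema error: ", cc,
           " must be -1, 0, 1 or NA on line(s) ", line(bad), call. = FALSE)
  }
  invisible(trials)
}

#' Write a trial table to CSV
#'
#' Comma-separated, UTF-8, "." decimal, header always present, stable
#' column order. Numeric values round-trip through [read_trials()] to at
#' least 1e-9.
#'
#' @param trials A schema-valid trial table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  cols <- intersect(names(TRIAL_COLUMNS), names(trials))
  utils::write.csv(trials[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path A comma-separated UTF-8 file with a header row.
#' @return A schema-validated trial table.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trials <- tryCatch(
    utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  validate_trials(trials)
  trials
}

#' Pipeline configuration
#'
#' A single structured configuration for [run_pipeline()]: either a named
#' list or the path of a YAML file holding one. Recognized fields (all
#' optional except where noted):
#' \describe{
#'   \item{seed}{master seed for every source of randomness (default 1).}
#'   \item{trials_file}{load an existing trial table instead of simulating.}
#'   \item{hypothesis, frame, n_subjects}{simulation settings (defaults
#'     `"none"`, `"gain"`, 19 per group).}
#'   \item{alpha}{selection threshold (default 0.05).}
#'   \item{fixed_point_factors}{character vector, default `c("TP", "ToT")`.}
#'   \item{analyses}{subset of `c("choices", "fixed_point")`.}
#'   \item{random_effects, fast}{passed to the regression spec.}
#'   \item{out_dir}{required: where reports are written.}
#' }
#' @param config Named list or YAML path.
#' @return Normalized config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  defaults <- list(seed = 1L, trials_file = NULL, hypothesis = "none",
                   frame = "gain", n_subjects = 19L, alpha = 0.05,
                   fixed_point_factors = c("TP", "ToT"),
                   analyses = c("choices", "fixed_point"),
                   random_effects = "slopes", fast = FALSE,
                   out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir", call. = FALSE)
  cfg
}

pipeline_log <- function(con, stage, seed, cfg_hash, msg) {
  line <- sprintf("[%s] stage=%s seed=%d config=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, seed, cfg_hash, msg)
  writeLines(line, con)
  message(line)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a trial table, run the choice analyses (priming
#' proportion tests, RT manipulation check, backward model selection) and
#' the fixed-point tests, and write JSON reports plus a log to the output
#' directory. Fully reproducible under a fixed seed; any stage error aborts
#' with the stage name, leaving no partial report file behind.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, the report bundle (named list also written as JSON).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  cfg_hash <- substr(digest_config(cfg), 1, 8)
  stage <- "setup"
  tmp_dir <- tempfile("pipeline")
  dir.create(tmp_dir)
  log_path <- file.path(tmp_dir, "pipeline.log")
  con <- file(log_path, open = "wt")
  bundle <- tryCatch({
    res <- list(config = cfg[setdiff(names(cfg), "out_dir")])
    stage <- "simulate"
    if (!is.null(cfg$trials_file)) {
      pipeline_log(con, stage, cfg$seed, cfg_hash,
                   paste("loading", cfg$trials_file))
      trials <- read_trials(cfg$trials_file)
    } else {
      pipeline_log(con, stage, cfg$seed, cfg_hash,
                   paste("simulating hypothesis", cfg$hypothesis))
      trials <- simulate_experiment(
        design_spec(n_subjects = cfg$n_subjects, frame = cfg$frame),
        scenario_spec(cfg$hypothesis), seed = cfg$seed)
      write_trials(trials, file.path(tmp_dir, "trials.csv"))
    }
    if ("choices" %in% cfg$analyses) {
      stage <- "analyze-choices"
      pipeline_log(con, stage, cfg$seed, cfg_hash, "priming + selection")
      res$priming <- lapply(
        c(safe_default = "greater", risky_default = "less"),
        function(side) {
          g <- if (side == "greater") "safe_default" else "risky_default"
          priming_proportion_test(safe_choice_proportions(trials, group = g),
                                  side = side)
        })
      spec <- regression_spec("choice", random = cfg$random_effects,
                              fast = cfg$fast)
      tr <- backward_select(trials, spec, alpha = cfg$alpha)
      res$selection <- list(steps = tr$steps, final_terms = tr$final_terms,
                            final_coefficients = tr$final$coefficients)
      rtfit <- rt_manipulation_check(trials, random = cfg$random_effects)
      res$rt_check <- rtfit$coefficients
    }
    if ("fixed_point" %in% cfg$analyses) {
      stage <- "fixed-point"
      for (f in cfg$fixed_point_factors) {
        pipeline_log(con, stage, cfg$seed, cfg_hash, paste("factor", f))
        fp <- fixed_point_test(trials, factor = f)
        res[[paste0("fixed_point_", f)]] <- list(
          BF01 = fp$BF01, pair_means = as.list(fp$pair_means),
          pair_ses = as.list(fp$pair_ses),
          n_participants = fp$n_participants, excluded = fp$excluded)
      }
    }
    stage <- "report"
    pipeline_log(con, stage, cfg$seed, cfg_hash, "writing reports")
    res
  }, error = function(e) {
    close(con)
    unlink(tmp_dir, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  close(con)
  # atomic publish: reports appear only on full success
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(bundle, file.path(tmp_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  for (f in list.files(tmp_dir, full.names = TRUE))
    file.copy(f, file.path(cfg$out_dir, basename(f)), overwrite = TRUE)
  unlink(tmp_dir, recursive = TRUE)
  invisible(bundle)
}

# Small stable polynomial hash over the serialized config, used to stamp
# log lines; avoids a digest dependency.
digest_config <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
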