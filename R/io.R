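TRIAL_LOG_SCHEMA <- "scmforage trial_log v1"
TRIAL_LOG_COLUMNS <- c("trial_index", "subsession", "context", "trial_type",
                       "option_left", "option_right", "planned_iti_s",
                       "subject", "latency_s", "chosen_option", "rewarded",
                       "peck_times")

#' Read and write trial logs as versioned CSV
#'
#' Trial logs are stored as plain CSV with a one-line schema header
#' (`# scmforage trial_log v1`).  `read_trial_log()` rejects files whose
#' schema line or columns do not match, and refuses rows violating basic
#' invariants (non-positive latency, unknown trial type, missing option),
#' reporting the offending row numbers.
#'
#' @param log a `trial_log` data frame from [simulate_subject()].
#' @param path file path.
#' @return `read_trial_log()` returns a `trial_log` data frame;
#'   `write_trial_log()` returns `path` invisibly.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(all(TRIAL_LOG_COLUMNS %in% names(log)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", TRIAL_LOG_SCHEMA), con)
  utils::write.csv(as.data.frame(log)[TRIAL_LOG_COLUMNS], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (!identical(header, paste0("# ", TRIAL_LOG_SCHEMA))) {
    stop("unknown trial-log schema in ", path, ": '", header,
         "' (expected '# ", TRIAL_LOG_SCHEMA, "')")
  }
  df <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                        colClasses = c(peck_times = "character"))
  if (nrow(df) == 0L) stop("trial log ", path, " is empty")
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(df))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df$peck_times[is.na(df$peck_times)] <- ""
  bad <- character(0)
  flag <- function(rows, why) {
    if (any(rows)) bad <<- c(bad, paste0(why, " at row(s) ",
                                         paste(which(rows), collapse = ", ")))
  }
  flag(!df$trial_type %in% c("single", "peak", "choice"),
       "unknown trial_type")
  flag(!is.finite(df$latency_s) | df$latency_s <= 0, "non-positive latency")
  known <- c(NA_character_, unique(c(df$option_left, df$option_right)))
  flag(df$trial_type != "choice" &
         is.na(df$option_left) & is.na(df$option_right),
       "no option offered")
  flag(df$trial_type == "choice" &
         (!df$chosen_option %in% c(df$option_left, df$option_right) |
            is.na(df$chosen_option)),
       "chosen option not among offered")
  if (length(bad)) stop("invalid trial log ", path, ":\n  ",
                        paste(bad, collapse = "\n  "))
  structure(df, class = c("trial_log", "data.frame"))
}

#' Serialise a design/value/timing configuration bundle as JSON
#'
#' One JSON document with namespaces `design`, `value`, `timing`, `scm`,
#' `analysis`, covering every tunable in the pipeline.
#'
#' @param config a [design_config()].
#' @param vparams a [value_params()].
#' @param tparams a [timing_params()].
#' @param scm list of SCM settings (`n_trials`, `n_experiments`).
#' @param analysis list of analysis settings (stability thresholds).
#' @param path file path for `write_config`; for `read_config` the file to
#'   load.
#' @return `read_config()` returns a list with elements `design`, `value`,
#'   `timing`, `scm`, `analysis`, reconstructed with their proper classes.
#' @export
write_config <- function(path, config = design_config(),
                         vparams = value_params(),
                         tparams = timing_params(),
                         scm = list(n_trials = 96L, n_experiments = 10000L),
                         analysis = list(sd_threshold = 10,
                                         trend_threshold = 5)) {
  doc <- list(
    schema = "scmforage config v1",
    design = c(list(options = as.data.frame(config$options)),
               unclass(config)[setdiff(names(config), "options")]),
    value = unclass(vparams),
    timing = unclass(tparams),
    scm = scm,
    analysis = analysis
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "scmforage config v1")) {
    stop("unknown config schema: ", doc$schema)
  }
  design_args <- doc$design
  design_args$options <- option_set(
    id = doc$design$options$id, delay = doc$design$options$delay,
    context = doc$design$options$context, rank = doc$design$options$rank
  )
  cfg <- do.call(design_config, design_args)
  list(design = cfg,
       value = do.call(value_params, as.list(doc$value)),
       timing = do.call(timing_params, as.list(doc$timing)),
       scm = doc$scm,
       analysis = doc$analysis)
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a pipeline run: the configuration
#' snapshot, root seed, package version, per-stage wall-clock timings, and
#' MD5 digests of every output file.  Identical manifests imply identical
#' outputs.
#'
#' @param config,vparams,tparams configuration objects of the run.
#' @param seed root seed.
#' @param timings named numeric vector of per-stage seconds.
#' @param files character vector of output file paths to digest.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(config, vparams, tparams, seed, timings = NULL,
                         files = character(0)) {
  digests <- if (length(files)) tools::md5sum(files) else character(0)
  structure(list(
    package_version = as.character(utils::packageVersion("scmforage")),
    seed = seed,
    design = unclass(config), value = unclass(vparams),
    timing = unclass(tparams),
    stage_timings_s = timings,
    file_digests = digests
  ), class = "run_manifest")
}
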