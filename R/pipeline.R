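#' Desk-scale reproduction of the full experiment
#'
#' Orchestrates the whole design on synthetic subjects: training sessions,
#' stability-gated testing with both cross-context pairings
#' (counterbalanced order across subjects), Sequential Choice Model
#' predictions from each subject's single-option latencies, the
#' observed-versus-predicted comparison (the model-fit diagonal), latency
#' shortening analyses, and peak-timing fits.
#'
#' Observed choice proportions and the latency samples feeding the SCM are
#' both taken from the last three testing sessions of each pairing — the
#' sessions that satisfied the stability criterion — mirroring the rule
#' that only data collected at stability are analysed.
#'
#' @param seed integer root seed; with the configuration it determines
#'   every output.
#' @param config a [design_config()].
#' @param vparams,tparams generator parameters ([value_params()],
#'   [timing_params()]).
#' @param n_subjects number of synthetic subjects (default 7).
#' @param training_days training sessions per subject (default 2; subjects
#'   are generated at stability, so training only accumulates latency and
#'   peak data).
#' @param max_testing_days cap on testing sessions per pairing
#'   (default 8).
#' @param n_experiments,n_trials SCM Monte Carlo size (defaults 10000 and
#'   96).
#' @param focal option whose choice proportion is reported (default `"C"`,
#'   the option common to both pairings).
#' @param pairings list of two cross-context pairings (default A:C and
#'   B:C).
#' @param out_dir if non-NULL, per-subject trial logs, result tables and
#'   the manifest are written there as CSV/JSON.
#' @param progress print one line per stage (default FALSE).
#' @return a list of class `scm_pipeline`: `preferences` (per
#'   subject-by-pairing observed and predicted proportions for the focal
#'   option, with SEs), `regression` (observed ~ predicted lm), `group`
#'   (per-pairing means and tests against indifference), `stability`,
#'   `shortening`, `peak_fits`, `peak_comparison` (equal-delay options),
#'   `logs`, `manifest`.
#' @examples
#' \donttest{
#' res <- run_experiment_pipeline(seed = 1, n_subjects = 3, n_experiments = 200)
#' res$group
#' }
#' @export
run_experiment_pipeline <- function(seed,
                                    config = design_config(),
                                    vparams = value_params(),
                                    tparams = timing_params(),
                                    n_subjects = 7L,
                                    training_days = 2L,
                                    max_testing_days = 8L,
                                    n_experiments = 10000L,
                                    n_trials = 96L,
                                    focal = "C",
                                    pairings = list(c("A", "C"),
                                                    c("B", "C")),
                                    out_dir = NULL,
                                    progress = FALSE) {
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage, t0) {
    timings[stage] <<- proc.time()[["elapsed"]] - t0
    if (progress) message(sprintf("[%s] %.1f s", stage, timings[stage]))
  }
  subjects <- sprintf("s%02d", seq_len(n_subjects))

  ## ---- simulate: training then stability-gated testing -------------------
  t0 <- proc.time()[["elapsed"]]
  logs <- list()
  stability_rows <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    vp <- subject_params(vparams, derive_seed(seed, "subject", s))
    train <- lapply(seq_len(training_days), function(day) {
      sched <- build_training_session(config, day_parity = day %% 2L,
                                      seed = derive_seed(seed, "sched", s,
                                                         "train", day))
      simulate_subject(sched, vp, tparams,
                       seed = derive_seed(seed, "sim", s, "train", day),
                       subject = s)
    })
    # counterbalance pairing order across subjects
    order_idx <- if (si %% 2L == 1L) c(1L, 2L) else c(2L, 1L)
    testing <- list()
    for (pi in order_idx) {
      pairing <- pairings[[pi]]
      key <- paste(pairing, collapse = "")
      days <- list()
      pcts <- numeric(0)
      for (day in seq_len(max_testing_days)) {
        sched <- build_testing_session(config, pairing,
                                       day_parity = day %% 2L,
                                       seed = derive_seed(seed, "sched", s,
                                                          key, day))
        log <- simulate_subject(sched, vp, tparams,
                                seed = derive_seed(seed, "sim", s, key, day),
                                subject = s)
        days[[day]] <- log
        ch <- log[log$trial_type == "choice", ]
        pcts[day] <- 100 * mean(ch$chosen_option == focal)
        if (day >= 3L && stability_check(pcts)$stable) break
      }
      verdict <- stability_check(pcts)
      stability_rows[[paste(s, key)]] <- data.frame(
        subject = s, pairing = key, n_sessions = length(pcts),
        sd = verdict$sd, slope = verdict$slope, stable = verdict$stable)
      testing[[key]] <- days
    }
    logs[[s]] <- list(training = train, testing = testing)
  }
  stability <- do.call(rbind, stability_rows)
  rownames(stability) <- NULL
  tick("simulate", t0)

  ## ---- SCM predictions vs observed choice, at stability ------------------
  t0 <- proc.time()[["elapsed"]]
  pref_rows <- list()
  shortening_rows <- list()
  for (s in subjects) {
    for (pairing in pairings) {
      key <- paste(pairing, collapse = "")
      days <- logs[[s]]$testing[[key]]
      at_stability <- utils::tail(days, 3L)
      pooled <- do.call(rbind, lapply(at_stability, as.data.frame))
      singles <- lapply(pairing, function(o) log_latencies(pooled, o))
      names(singles) <- pairing
      pred <- predict_preference(singles[[1]], singles[[2]],
                                 n_trials = n_trials,
                                 n_experiments = n_experiments,
                                 seed = derive_seed(seed, "scm", s, key))
      ch <- pooled[pooled$trial_type == "choice", ]
      obs <- mean(ch$chosen_option == focal)
      pred_focal <- unname(pred$preference[focal])
      pref_rows[[paste(s, key)]] <- data.frame(
        subject = s, pairing = key,
        observed = obs, predicted = pred_focal,
        predicted_mc_se = pred$se,
        n_choice_trials = nrow(ch),
        n_single_a = length(singles[[1]]$latencies),
        n_single_b = length(singles[[2]]$latencies))
      # shortening: ECDF-area difference, observed (chosen-in-choice vs
      # single) and predicted (race winner latencies vs single)
      for (o in pairing) {
        chosen <- ch[!is.na(ch$chosen_option) & ch$chosen_option == o, ]
        if (nrow(chosen) == 0L) next
        obs_choice <- latency_sample(o, chosen$latency_s,
                                     condition = "chosen_in_choice",
                                     subject = s)
        g <- decile_grid(singles[[o]], obs_choice)
        sh_obs <- shortening(singles[[o]], obs_choice, grid = g)
        winners <- pred$winners[[o]]
        sh_pred <- if (length(winners)) {
          gp <- decile_grid(singles[[o]], winners)
          ecdf_score(winners, gp)$score -
            ecdf_score(singles[[o]], gp)$score
        } else NA_real_
        shortening_rows[[paste(s, key, o)]] <- data.frame(
          subject = s, pairing = key, option = o,
          observed_shortening = sh_obs$shortening,
          predicted_shortening = sh_pred)
      }
    }
  }
  preferences <- do.call(rbind, pref_rows)
  rownames(preferences) <- NULL
  shortening_tab <- do.call(rbind, shortening_rows)
  rownames(shortening_tab) <- NULL
  regression <- stats::lm(observed ~ predicted, data = preferences)
  group <- do.call(rbind, lapply(split(preferences, preferences$pairing),
    function(d) {
      tt <- preference_test(d$observed)
      data.frame(pairing = d$pairing[1],
                 mean_observed = mean(d$observed),
                 mean_predicted = mean(d$predicted),
                 t_vs_indifference = tt$t, df = tt$df, p = tt$p)
    }))
  rownames(group) <- NULL
  tick("scm", t0)

  ## ---- peak-timing control ----------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  peak_rows <- list()
  for (s in subjects) {
    all_logs <- c(logs[[s]]$training,
                  unlist(logs[[s]]$testing, recursive = FALSE))
    pooled <- do.call(rbind, lapply(all_logs, as.data.frame))
    pk <- pooled[pooled$trial_type == "peak", ]
    for (o in config$options$id) {
      rows <- pk[offered_option(pk) == o, ]
      if (nrow(rows) == 0L) next
      trains <- parse_peck_times(rows$peck_times)
      curve <- bin_responses(trains, window = config$peak_duration,
                             option = o)
      fit <- fit_peak(curve)
      peak_rows[[paste(s, o)]] <- data.frame(
        subject = s, option = o,
        delay = config$options$delay[config$options$id == o],
        n_trials = curve$n_trials, peak_time = fit$peak_time,
        peak_rate = fit$peak_rate, spread = fit$spread,
        peak_time_argmax = fit$peak_time_argmax)
    }
  }
  peak_fits <- do.call(rbind, peak_rows)
  rownames(peak_fits) <- NULL
  peak_comparison <- local({
    same_delay <- c("B", "C")
    if (all(same_delay %in% peak_fits$option)) {
      a <- peak_fits[peak_fits$option == same_delay[1], ]
      b <- peak_fits[peak_fits$option == same_delay[2], ]
      a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
      c(list(options = same_delay),
        compare_peak_times(a$peak_time, b$peak_time))
    } else NULL
  })
  tick("peaks", t0)

  ## ---- outputs -----------------------------------------------------------
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) {
      all_logs <- c(logs[[s]]$training,
                    unlist(logs[[s]]$testing, recursive = FALSE))
      pooled <- do.call(rbind, lapply(all_logs, as.data.frame))
      f <- file.path(out_dir, paste0("trials_", s, ".csv"))
      write_trial_log(pooled, f)
      files <- c(files, f)
    }
    for (nm in c("preferences", "stability", "peak_fits")) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(get(nm), f, row.names = FALSE)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "shortening.csv")
    utils::write.csv(shortening_tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  timings["total"] <- proc.time()[["elapsed"]] - t_start
  manifest <- run_manifest(config, vparams, tparams, seed,
                           timings = timings, files = files)
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(
    preferences = preferences, regression = regression, group = group,
    stability = stability, shortening = shortening_tab,
    peak_fits = peak_fits, peak_comparison = peak_comparison,
    logs = logs, manifest = manifest
  ), class = "scm_pipeline")
}

parse_peck_times <- function(strings) {
  lapply(strings, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' @export
print.scm_pipeline <- function(x, ...) {
  cat("<scm_pipeline>\n")
  cat(sprintf("  %d subjects, %d subject-by-pairing preference points\n",
              length(x$logs), nrow(x$preferences)))
  print(x$group)
  sl <- stats::coef(x$regression)[2]
  cat(sprintf("  observed ~ predicted regression slope: %.3f\n", sl))
  invisible(x)
}

#' @export
plot.scm_pipeline <- function(x, ...) {
  d <- x$preferences
  pch <- ifelse(d$pairing == unique(d$pairing)[1], 19, 1)
  plot(d$predicted, d$observed, pch = pch, xlim = 0:1, ylim = 0:1,
       xlab = "SCM-predicted preference for focal option",
       ylab = "observed preference", ...)
  abline(0, 1, lty = 2)
  abline(x$regression, col = 2)
  legend("topleft", legend = unique(d$pairing), pch = c(19, 1), bty = "n")
  invisible(x)
}
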