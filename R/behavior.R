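#' Parameters of the value-to-latency map
#'
#' Subjective value of an option is a weighted sum of its immediacy (1/delay)
#' and its within-context rank; latency to respond is a reaction-time floor
#' plus a lognormal whose log-median decreases linearly in value:
#' \deqn{v = w_{imm}/delay + w_{rank} \cdot r, \quad r = +1 (better), -1 (worse)}
#' \deqn{L = t_0 + \mathrm{LogNormal}(\mu = a - b v, \sigma)}
#' so the median latency is \eqn{t_0 + e^{a - b v}}, strictly decreasing in
#' value.
#'
#' The defaults are calibrated in closed form against four anchors: median
#' latencies of 0.565 s (option A) and 0.654 s (option C), a median for D
#' more than twice that of B (the strong B-vs-D separation), and a 70\%
#' race-model preference for C over B.  Under this calibration the latency
#' distributions of the two short-delay options (A, C) sit just above the
#' reaction-time floor — the "floor effect" regime in which latency
#' differences compress while large preference differences remain possible.
#' Derived values: `w_rank = qnorm(0.7) * sigma_log * sqrt(2) / (2 *
#' scale_b)`, floor and intercept solved from the two median anchors.
#'
#' @param w_imm weight on immediacy, dimensionless (default 1).
#' @param w_rank weight on within-context rank (default 0.0046350895, from
#'   the 70\% race calibration above).
#' @param floor_t0 reaction-time floor, seconds (default 0.5633394949).
#' @param scale_a intercept of the log-median map (default 1.7847701169).
#' @param scale_b slope of the log-median map per unit value; `> 0` so
#'   higher value means shorter latency (default 40).
#' @param sigma_log lognormal dispersion on the log scale (default 0.5).
#' @param subject_sd between-subject SD of `scale_a` (default 0.1).
#' @param extra_route_p probability that a choice trial bypasses the race
#'   and is decided by a value softmax instead; default 0 (pure race).  A
#'   demonstrative knob for choice routes beyond the race, not a fitted
#'   model.
#' @param extra_route_beta softmax inverse temperature for the extra route
#'   (default 50).
#' @return a list of class `value_params`.
#' @examples
#' vp <- value_params()
#' opts <- default_options()
#' v <- subjective_value(opts, vp)
#' median_latency(v, vp) # A 0.565, C 0.654, B 0.69, D 1.53
#' @export
value_params <- function(w_imm = 1,
                         w_rank = 0.0046350895,
                         floor_t0 = 0.5633394949,
                         scale_a = 1.7847701169,
                         scale_b = 40,
                         sigma_log = 0.5,
                         subject_sd = 0.1,
                         extra_route_p = 0,
                         extra_route_beta = 50) {
  stopifnot(floor_t0 > 0, sigma_log > 0, scale_b > 0, subject_sd >= 0,
            extra_route_p >= 0, extra_route_p <= 1)
  structure(list(w_imm = w_imm, w_rank = w_rank, floor_t0 = floor_t0,
                 scale_a = scale_a, scale_b = scale_b, sigma_log = sigma_log,
                 subject_sd = subject_sd, extra_route_p = extra_route_p,
                 extra_route_beta = extra_route_beta),
            class = "value_params")
}

#' Parameters of peak-trial timing behaviour
#'
#' Pecking during an unrewarded peak trial is an inhomogeneous Poisson
#' process with intensity
#' \deqn{\lambda(t) = baseline + rate_{max} \exp\{-(t - delay)^2 /
#'   (2 (cv \cdot delay)^2)\}}
#' i.e. a Gaussian bump centred on the remembered delay whose width grows
#' proportionally with the delay (scalar timing; `cv` is the Weber
#' fraction).  `decay` optionally attenuates the post-peak limb
#' (multiplies the bump by `exp(-decay * (t - delay))` for `t > delay`);
#' default 0 keeps the bump symmetric.
#'
#' @param cv Weber fraction: spread/delay ratio (default 0.3).
#' @param rate_max peak pecking rate above baseline, pecks/s (default 3).
#' @param baseline background pecking rate, pecks/s (default 0.2).
#' @param decay post-peak attenuation, 1/s (default 0).
#' @return a list of class `timing_params`.
#' @export
timing_params <- function(cv = 0.3, rate_max = 3, baseline = 0.2,
                          decay = 0) {
  stopifnot(cv > 0, rate_max > baseline, baseline >= 0, decay >= 0)
  structure(list(cv = cv, rate_max = rate_max, baseline = baseline,
                 decay = decay),
            class = "timing_params")
}

#' Subjective value of options
#'
#' `subjective_value()` maps each option to
#' `w_imm / delay + w_rank * rank_term`, with `rank_term` +1 for the
#' better-ranked option of its context and -1 for the worse.  It is strictly
#' increasing in immediacy and in rank.  `median_latency()` gives the
#' corresponding median of the latency law, `floor_t0 + exp(scale_a -
#' scale_b * value)`.
#'
#' @param option an [option_set()] (or one row of one).
#' @param params a [value_params()].
#' @param value numeric value score(s) as returned by `subjective_value`.
#' @return named numeric vector of values (or median latencies), one per
#'   option.
#' @examples
#' subjective_value(default_options(), value_params())
#' @export
subjective_value <- function(option, params) {
  stopifnot(all(c("delay", "rank", "id") %in% names(option)))
  rank_term <- ifelse(option$rank == 1L, 1, -1)
  v <- params$w_imm / option$delay + params$w_rank * rank_term
  names(v) <- option$id
  v
}

#' @rdname subjective_value
#' @export
median_latency <- function(value, params) {
  params$floor_t0 + exp(params$scale_a - params$scale_b * value)
}

#' Draw response latencies for a given value score
#'
#' Shifted-lognormal draws: `floor_t0 + rlnorm(n, scale_a - scale_b * value,
#' sigma_log)`.  Every draw exceeds the reaction-time floor by construction.
#' Uses the current RNG state; wrap in a seeded context for reproducibility.
#'
#' @param value a value score from [subjective_value()].
#' @param params a [value_params()].
#' @param n number of draws.
#' @return numeric vector of latencies, seconds, all `> floor_t0`.
#' @export
draw_latency <- function(value, params, n = 1L) {
  params$floor_t0 +
    stats::rlnorm(n, meanlog = params$scale_a - params$scale_b * value,
                  sdlog = params$sigma_log)
}

#' Per-subject parameter perturbation
#'
#' Draws a subject-specific `scale_a` from
#' `Normal(scale_a, subject_sd)` — the only between-subject heterogeneity in
#' the generator — and returns the perturbed parameter set.  A common shift
#' of `scale_a` rescales all of a subject's above-floor latencies by the
#' same factor, so race probabilities are unchanged while latency medians
#' differ across subjects.
#'
#' @param params a [value_params()].
#' @param seed integer seed identifying the subject.
#' @return a `value_params` with subject-specific `scale_a` and
#'   `subject_sd = 0`.
#' @export
subject_params <- function(params, seed) {
  params$scale_a <- with_seed(seed, stats::rnorm(1, params$scale_a,
                                                 params$subject_sd))
  params$subject_sd <- 0
  params
}

#' Simulate peck timestamps for one peak trial
#'
#' Thinned Poisson process in `dt`-second steps over the peak window, with
#' the scalar-timing intensity described in [timing_params()].  The
#' noiseless intensity has its mode exactly at the programmed delay.
#'
#' @param delay programmed delay to food, seconds; must be shorter than the
#'   window.
#' @param tparams a [timing_params()].
#' @param window peak-trial duration, seconds (default 60).
#' @param dt time step, seconds (default 0.01).
#' @return numeric vector of peck timestamps in `[0, window]`.
#' @export
generate_peak_curve <- function(delay, tparams, window = 60, dt = 0.01) {
  stopifnot(delay > 0, delay < window)
  t <- seq(dt / 2, window - dt / 2, by = dt)
  lambda <- peak_intensity(t, delay, tparams)
  # thinning: at most one event per 10-ms step; p = lambda*dt stays << 1
  hit <- stats::runif(length(t)) < lambda * dt
  t[hit]
}

peak_intensity <- function(t, delay, tparams) {
  bump <- tparams$rate_max *
    exp(-(t - delay)^2 / (2 * (tparams$cv * delay)^2))
  if (tparams$decay > 0) {
    post <- t > delay
    bump[post] <- bump[post] * exp(-tparams$decay * (t[post] - delay))
  }
  tparams$baseline + bump
}

#' Simulate one subject through one session schedule
#'
#' Realises a [build_training_session()] or [build_testing_session()]
#' schedule as a trial log:
#' \itemize{
#'   \item single-option trials draw one latency from the offered option's
#'     law and end in reward;
#'   \item peak trials draw a latency, then a peck train from the
#'     scalar-timing intensity, and end unrewarded;
#'   \item choice trials draw one latency per offered option and record the
#'     shorter as the choice with its latency — the generative process is
#'     itself the race, which makes the Sequential Choice Model exactly
#'     self-consistent on this synthetic world (unless the optional
#'     extra-route knob diverts a fraction of choices to a value softmax);
#'   \item ITI slots left `NA` by the scheduler are filled with
#'     [adjust_iti()] from the preceding window of single-option delays.
#' }
#'
#' @param schedule a valid `session_schedule`; schedules failing
#'   [validate_schedule()] are refused.
#' @param vparams a [value_params()] (already subject-specific if desired;
#'   see [subject_params()]).
#' @param tparams a [timing_params()].
#' @param seed integer seed; the log is deterministic given the seed.
#' @param subject id recorded in the log (default `"s1"`).
#' @return a data frame of class `trial_log`: the schedule columns plus
#'   `subject`, `latency_s`, `chosen_option`, `rewarded`, `peck_times`
#'   (semicolon-joined seconds, peak trials only).
#' @examples
#' cfg <- design_config()
#' log <- simulate_subject(build_training_session(cfg, seed = 1),
#'                         value_params(), timing_params(), seed = 1)
#' table(log$rewarded) # 16 FALSE (peak trials), 160 TRUE
#' @export
simulate_subject <- function(schedule, vparams, tparams, seed,
                             subject = "s1") {
  config <- attr(schedule, "config")
  if (is.null(config)) stop("schedule lacks its design_config attribute")
  bad <- validate_schedule(schedule, config)
  if (length(bad)) {
    stop("refusing to simulate an invalid schedule:\n  ",
         paste(bad, collapse = "\n  "))
  }
  values <- subjective_value(config$options, vparams)
  delays <- stats::setNames(config$options$delay, config$options$id)

  n <- nrow(schedule)
  latency <- numeric(n)
  chosen <- rep(NA_character_, n)
  rewarded <- logical(n)
  pecks <- rep("", n)
  iti <- schedule$planned_iti_s

  with_seed(seed, {
    for (ss in unique(schedule$subsession)) {
      idx <- which(schedule$subsession == ss)
      recent <- numeric(0) # single-option delays seen this sub-session
      for (i in idx) {
        type <- schedule$trial_type[i]
        if (type == "choice") {
          a <- schedule$option_left[i]; b <- schedule$option_right[i]
          la <- draw_latency(values[[a]], vparams)
          lb <- draw_latency(values[[b]], vparams)
          if (vparams$extra_route_p > 0 &&
              stats::runif(1) < vparams$extra_route_p) {
            pa <- 1 / (1 + exp(-vparams$extra_route_beta *
                                 (values[[a]] - values[[b]])))
            pick_a <- stats::runif(1) < pa
            chosen[i] <- if (pick_a) a else b
            latency[i] <- if (pick_a) la else lb
          } else {
            race <- race_trial(la, lb, id_a = a, id_b = b)
            chosen[i] <- race$winner
            latency[i] <- race$latency
          }
          rewarded[i] <- TRUE
        } else {
          opt <- offered_option(schedule[i, ])
          latency[i] <- draw_latency(values[[opt]], vparams)
          if (type == "peak") {
            train <- generate_peak_curve(delays[[opt]], tparams,
                                         window = config$peak_duration)
            pecks[i] <- paste(sprintf("%.3f", train), collapse = ";")
            rewarded[i] <- FALSE
          } else {
            rewarded[i] <- TRUE
            recent <- c(recent, delays[[opt]])
            if (is.na(iti[i])) {
              iti[i] <- adjust_iti(utils::tail(recent, config$iti_window),
                                   config)
            }
          }
        }
      }
    }
  })

  log <- as.data.frame(schedule)
  log$planned_iti_s <- iti
  log$subject <- subject
  log$latency_s <- latency
  log$chosen_option <- chosen
  log$rewarded <- rewarded
  log$peck_times <- pecks
  structure(log, class = c("trial_log", "data.frame"),
            phase = attr(schedule, "phase"),
            pairing = attr(schedule, "pairing"))
}

#' Extract per-option latency samples from a trial log
#'
#' Filters a [simulate_subject()] log (or anything read back by
#' [read_trial_log()]) to one option under one condition and wraps the
#' latencies as a [latency_sample()].
#'
#' @param log a `trial_log` data frame.
#' @param option option id.
#' @param condition `"single_option"` (latencies from single-option trials)
#'   or `"chosen_in_choice"` (latencies on choice trials where this option
#'   was taken).
#' @return a [latency_sample()].
#' @export
log_latencies <- function(log, option,
                          condition = c("single_option",
                                        "chosen_in_choice")) {
  condition <- match.arg(condition)
  if (condition == "single_option") {
    rows <- log$trial_type == "single" &
      !is.na(offered_option(log)) & offered_option(log) == option
  } else {
    rows <- log$trial_type == "choice" & !is.na(log$chosen_option) &
      log$chosen_option == option
  }
  subject <- if ("subject" %in% names(log)) log$subject[1] else NA_character_
  latency_sample(option, log$latency_s[rows], condition = condition,
                 subject = subject)
}
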