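#' Define a set of foraging options
#'
#' An option set is a data frame with one row per option: an identifier, the
#' programmed delay to food (s), the context in which the option is
#' encountered, and its rank within that context (1 = better, 2 = worse).
#' Exactly two options per context are required, with distinct ranks.
#'
#' @param id character vector of option identifiers.
#' @param delay numeric vector of delays to food, seconds; all `> 0`.
#' @param context character vector of context identifiers.
#' @param rank integer vector, rank within context: 1 (better) or 2 (worse).
#' @return a data frame of class `option_set`.
#' @examples
#' default_options()
#' @export
option_set <- function(id, delay, context, rank) {
  stopifnot(
    length(id) == length(delay), length(id) == length(context),
    length(id) == length(rank), !anyDuplicated(id),
    all(delay > 0), all(rank %in% c(1L, 2L))
  )
  opts <- data.frame(
    id = as.character(id), delay = as.numeric(delay),
    context = as.character(context), rank = as.integer(rank),
    stringsAsFactors = FALSE
  )
  for (ctx in unique(opts$context)) {
    rows <- opts[opts$context == ctx, ]
    if (nrow(rows) != 2L) {
      stop("context '", ctx, "' must contain exactly two options, has ",
           nrow(rows))
    }
    if (anyDuplicated(rows$rank)) {
      stop("ranks within context '", ctx, "' must be distinct")
    }
  }
  class(opts) <- c("option_set", "data.frame")
  opts
}

#' The default two-context option set
#'
#' Four options in two contexts: in context AB, option A (5-s delay, better)
#' and B (10 s, worse); in context CD, option C (10 s, better) and D (20 s,
#' worse).  B and C share the same delay but differ in within-context rank,
#' which is the critical comparison of the design.
#'
#' @return an [option_set()] with options A, B, C, D.
#' @export
default_options <- function() {
  option_set(
    id      = c("A", "B", "C", "D"),
    delay   = c(5, 10, 10, 20),
    context = c("AB", "AB", "CD", "CD"),
    rank    = c(1L, 2L, 1L, 2L)
  )
}

#' Design configuration for a two-context operant session
#'
#' Holds the per-sub-session trial counts, inter-trial-interval (ITI)
#' parameters, and reward metadata for the session schedulers.  Defaults
#' reproduce the reference design: four 44-trial sub-sessions per day (40
#' single-option trials — 20 per option — plus 4 peak trials — 2 per
#' option), 30-s base ITI adjusted every fifth single-option trial so that
#' the delay-plus-ITI total per five-trial block is constant across
#' contexts, two 20-mg pellets per reward, and during testing two pairs of
#' choice trials per context visit (16 choice trials per day).
#'
#' @param options an [option_set()]; default [default_options()].
#' @param singles_per_option single-option trials per option per
#'   sub-session (default 20).
#' @param peaks_per_option peak trials per option per sub-session
#'   (default 2).
#' @param base_iti base inter-trial interval, seconds (default 30).
#' @param iti_window number of single-option trials between ITI adjustments
#'   (default 5).
#' @param iti_max_sum theoretical maximum of the summed delays over one
#'   window, seconds; default `iti_window * max(delay)` (100 s for the
#'   default options).
#' @param subsessions_per_day sub-sessions (context visits) per day
#'   (default 4, alternating contexts).
#' @param peak_duration length of the unrewarded peak-trial window, seconds
#'   (default 60).
#' @param pellets_per_reward pellets delivered per rewarded trial
#'   (default 2).
#' @param pellet_mass mass of one pellet, grams (default 0.020).
#' @param choice_pairs_per_context_visit pairs of choice trials substituted
#'   at the beginning and end of each sub-session during testing
#'   (default 2, i.e. 4 choice trials per sub-session).
#' @param session_cap_h maximum session length in hours; schedule metadata
#'   only, never enforced by the simulator (default 6.5).
#' @param context_intervals_min minutes separating consecutive sub-sessions;
#'   metadata only (default `c(45, 60, 45)`).
#' @return a list of class `design_config`.
#' @examples
#' cfg <- design_config()
#' trials_per_subsession(cfg) # 44
#' trials_per_day(cfg)        # 176
#' @export
design_config <- function(options = default_options(),
                          singles_per_option = 20L,
                          peaks_per_option = 2L,
                          base_iti = 30,
                          iti_window = 5L,
                          iti_max_sum = NULL,
                          subsessions_per_day = 4L,
                          peak_duration = 60,
                          pellets_per_reward = 2L,
                          pellet_mass = 0.020,
                          choice_pairs_per_context_visit = 2L,
                          session_cap_h = 6.5,
                          context_intervals_min = c(45, 60, 45)) {
  if (!inherits(options, "option_set")) {
    options <- do.call(option_set, as.list(options))
  }
  counts <- c(
    singles_per_option = singles_per_option,
    peaks_per_option = peaks_per_option, iti_window = iti_window,
    subsessions_per_day = subsessions_per_day,
    pellets_per_reward = pellets_per_reward,
    choice_pairs_per_context_visit = choice_pairs_per_context_visit
  )
  if (any(counts != round(counts)) || any(counts[names(counts) != "peaks_per_option"] <= 0) ||
      peaks_per_option < 0) {
    stop("count parameters must be positive integers (peaks_per_option may be 0)")
  }
  stopifnot(base_iti > 0, peak_duration > 0, pellet_mass > 0, session_cap_h > 0)
  if (is.null(iti_max_sum)) iti_max_sum <- iti_window * max(options$delay)
  cfg <- list(
    options = options,
    singles_per_option = as.integer(singles_per_option),
    peaks_per_option = as.integer(peaks_per_option),
    base_iti = base_iti,
    iti_window = as.integer(iti_window),
    iti_max_sum = iti_max_sum,
    subsessions_per_day = as.integer(subsessions_per_day),
    peak_duration = peak_duration,
    pellets_per_reward = as.integer(pellets_per_reward),
    pellet_mass = pellet_mass,
    choice_pairs_per_context_visit = as.integer(choice_pairs_per_context_visit),
    session_cap_h = session_cap_h,
    context_intervals_min = context_intervals_min
  )
  class(cfg) <- "design_config"
  cfg
}

#' @export
print.design_config <- function(x, ...) {
  cat("Two-context operant design\n")
  cat("  options:",
      paste0(x$options$id, " (", x$options$delay, " s, ", x$options$context,
             ifelse(x$options$rank == 1L, ", better", ", worse"), ")",
             collapse = "; "), "\n")
  cat(sprintf("  per sub-session: %d single + %d peak trials (%d total)\n",
              2L * x$singles_per_option, 2L * x$peaks_per_option,
              trials_per_subsession(x)))
  cat(sprintf("  %d sub-sessions/day -> %d trials/day\n",
              x$subsessions_per_day, trials_per_day(x)))
  cat(sprintf("  ITI: base %g s, adjusted every %d single trials (delay-sum max %g s)\n",
              x$base_iti, x$iti_window, x$iti_max_sum))
  invisible(x)
}

#' Design arithmetic helpers
#'
#' Trial-count and food-intake quantities implied by a [design_config()]:
#' trials per sub-session and per day, choice trials per testing day, and
#' the daily food maximum.  The food maximum is computed on an all-trials
#' basis by default (every scheduled trial counted as rewarded, matching the
#' printed arithmetic of the reference design: 176 trials x 2 pellets x
#' 0.020 g = 7.04 g); peak trials are unrewarded, so
#' `basis = "rewarded_only"` gives the strictly attainable maximum.
#'
#' @param config a [design_config()].
#' @param basis for `food_maximum`: `"all_trials"` (default) or
#'   `"rewarded_only"`.
#' @return a number: trials (integer) or grams.
#' @examples
#' food_maximum(design_config())                    # 7.04
#' food_maximum(design_config(), "rewarded_only")   # 6.4
#' @export
trials_per_subsession <- function(config) {
  2L * (config$singles_per_option + config$peaks_per_option)
}

#' @rdname trials_per_subsession
#' @export
trials_per_day <- function(config) {
  config$subsessions_per_day * trials_per_subsession(config)
}

#' @rdname trials_per_subsession
#' @export
choice_trials_per_day <- function(config) {
  config$subsessions_per_day * 2L * config$choice_pairs_per_context_visit
}

#' @rdname trials_per_subsession
#' @export
food_maximum <- function(config, basis = c("all_trials", "rewarded_only")) {
  basis <- match.arg(basis)
  n <- trials_per_day(config)
  if (basis == "rewarded_only") {
    n <- n - config$subsessions_per_day * 2L * config$peaks_per_option
  }
  n * config$pellets_per_reward * config$pellet_mass
}

#' Reward-rate equalising ITI adjustment
#'
#' Every `iti_window`-th single-option trial, the inter-trial interval is
#' lengthened by the shortfall between the theoretical maximum delay sum
#' (`iti_max_sum`, 100 s by default: five delays of 20 s) and the realised
#' sum of delays over the preceding `iti_window` single-option trials.  This
#' equates reward rate across contexts: over each window the total of delays
#' plus ITIs is constant regardless of which options were met.
#'
#' @param recent_delays numeric vector of the preceding `iti_window`
#'   single-option delays, seconds.
#' @param config a [design_config()].
#' @return the adjusted ITI in seconds, `>= base_iti`.
#' @examples
#' cfg <- design_config()
#' adjust_iti(c(20, 20, 20, 20, 20), cfg) # 30: delays already at maximum
#' adjust_iti(c(5, 5, 5, 5, 5), cfg)      # 105
#' @export
adjust_iti <- function(recent_delays, config) {
  if (length(recent_delays) != config$iti_window) {
    stop("recent_delays must have length iti_window (",
         config$iti_window, "), got ", length(recent_delays))
  }
  if (!all(recent_delays %in% config$options$delay)) {
    stop("recent_delays contains a delay not in the configured option set")
  }
  config$base_iti + (config$iti_max_sum - sum(recent_delays))
}
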