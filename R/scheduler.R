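#' Session schedules for the two-context design
#'
#' `build_training_session()` lays out one day of training: alternating
#' context visits (sub-sessions), each a pseudo-random interleaving of
#' single-option and peak trials with the constraint that no two peak trials
#' are consecutive.  `build_testing_session()` additionally substitutes the
#' first and last single-option slots of every sub-session with simultaneous
#' choice trials offering a cross-context pairing.
#'
#' Pseudo-randomisation is a uniform shuffle resampled until the
#' no-consecutive-peaks constraint holds; side assignment alternates per
#' option across presentations from a seeded starting side.  The planned ITI
#' is the base ITI everywhere except the slots subject to the reward-rate
#' adjustment (every `iti_window`-th single-option trial within a
#' sub-session), which are left `NA` and filled at simulation time by
#' [adjust_iti()].
#'
#' @param config a [design_config()].
#' @param day_parity 0 or 1: which context opens the day.  Parity 0 starts
#'   with the first context of the option set (AB by default); parity 1 with
#'   the second.  Alternating parity across days reproduces the
#'   ABAB / BABA alternation of the reference design.
#' @param seed integer seed; the same seed always yields the same schedule.
#' @param pairing for testing sessions, the two option ids offered in choice
#'   trials, as `c("A", "C")` or a string `"A:C"` / `"AC"`.  Must be
#'   cross-context.
#' @return a data frame of class `session_schedule` with columns
#'   `trial_index`, `subsession`, `context`, `trial_type`
#'   (`single`/`peak`/`choice`), `option_left`, `option_right`,
#'   `planned_iti_s`, and attributes `phase`, `pairing`, `day_parity`,
#'   `config`.
#' @examples
#' cfg <- design_config()
#' sched <- build_training_session(cfg, day_parity = 0, seed = 1)
#' nrow(sched)                      # 176
#' table(sched$trial_type)
#' test <- build_testing_session(cfg, pairing = "A:C", seed = 1)
#' sum(test$trial_type == "choice") # 16
#' @export
build_training_session <- function(config, day_parity = 0L, seed = 1L) {
  build_session(config, phase = "training", pairing = NULL,
                day_parity = day_parity, seed = seed)
}

#' @rdname build_training_session
#' @export
build_testing_session <- function(config, pairing, day_parity = 0L,
                                  seed = 1L) {
  pairing <- parse_pairing(pairing, config$options)
  build_session(config, phase = "testing", pairing = pairing,
                day_parity = day_parity, seed = seed)
}

parse_pairing <- function(pairing, options) {
  if (length(pairing) == 1L) {
    pairing <- strsplit(gsub(":", "", pairing), "")[[1]]
  }
  pairing <- as.character(pairing)
  if (length(pairing) != 2L || !all(pairing %in% options$id)) {
    stop("pairing must name two options from the option set, got: ",
         paste(pairing, collapse = ", "))
  }
  ctx <- options$context[match(pairing, options$id)]
  if (ctx[1] == ctx[2]) {
    stop("pairing must be cross-context; ", pairing[1], " and ", pairing[2],
         " both belong to context ", ctx[1])
  }
  pairing
}

build_session <- function(config, phase, pairing, day_parity, seed) {
  stopifnot(day_parity %in% c(0L, 1L))
  if (2L * config$peaks_per_option > 2L * config$singles_per_option + 1L) {
    stop("scheduling error: too many peak trials to avoid consecutive peaks")
  }
  contexts <- unique(config$options$context)
  if (length(contexts) != 2L) stop("design requires exactly two contexts")
  if (day_parity == 1L) contexts <- rev(contexts)
  ctx_seq <- rep_len(contexts, config$subsessions_per_day)

  side_state <- new.env(parent = emptyenv()) # per-option side alternation
  rows <- with_seed(seed, {
    for (o in config$options$id) {
      assign(o, sample(c("L", "R"), 1L), envir = side_state)
    }
    assign(".pair", sample(c(TRUE, FALSE), 1L), envir = side_state)
    do.call(rbind, lapply(seq_along(ctx_seq), function(ss) {
      build_subsession(config, ss, ctx_seq[ss], phase, pairing, side_state)
    }))
  })
  rows$trial_index <- seq_len(nrow(rows))
  rows <- rows[c("trial_index", "subsession", "context", "trial_type",
                 "option_left", "option_right", "planned_iti_s")]
  structure(rows,
            class = c("session_schedule", "data.frame"),
            phase = phase, pairing = pairing,
            day_parity = as.integer(day_parity), seed = as.integer(seed),
            config = config)
}

# One context visit: shuffle singles + peaks until no two peaks adjoin,
# then (testing) replace the first/last single slots with choice trials.
build_subsession <- function(config, ss, ctx, phase, pairing, side_state) {
  opts <- config$options[config$options$context == ctx, ]
  types <- c(rep("single", 2L * config$singles_per_option),
             rep("peak", 2L * config$peaks_per_option))
  ids <- c(rep(opts$id, each = config$singles_per_option),
           rep(opts$id, each = config$peaks_per_option))
  repeat {
    ord <- sample(length(types))
    if (!any(types[ord][-1] == "peak" & types[ord][-length(ord)] == "peak")) {
      break
    }
  }
  type <- types[ord]
  opt <- ids[ord]

  if (phase == "testing") {
    k <- config$choice_pairs_per_context_visit
    singles <- which(type == "single")
    if (length(singles) < 2L * k) {
      stop("scheduling error: not enough single-option slots to substitute ",
           2L * k, " choice trials")
    }
    swap <- c(utils::head(singles, k), utils::tail(singles, k))
    type[swap] <- "choice"
    opt[swap] <- NA_character_
  }

  n <- length(type)
  left <- right <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (type[i] == "choice") {
      first_left <- get(".pair", envir = side_state)
      assign(".pair", !first_left, envir = side_state)
      if (first_left) {
        left[i] <- pairing[1]; right[i] <- pairing[2]
      } else {
        left[i] <- pairing[2]; right[i] <- pairing[1]
      }
    } else {
      side <- get(opt[i], envir = side_state)
      assign(opt[i], if (side == "L") "R" else "L", envir = side_state)
      if (side == "L") left[i] <- opt[i] else right[i] <- opt[i]
    }
  }

  iti <- rep(config$base_iti, n)
  single_idx <- which(type == "single")
  adj <- single_idx[seq_along(single_idx) %% config$iti_window == 0L]
  iti[adj] <- NA_real_ # filled by adjust_iti() at simulation time

  data.frame(
    trial_index = NA_integer_, subsession = ss, context = ctx,
    trial_type = type, option_left = left, option_right = right,
    planned_iti_s = iti, stringsAsFactors = FALSE
  )
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule> %s day, %d trials, %d sub-sessions\n",
              attr(x, "phase"), nrow(x), length(unique(x$subsession))))
  if (!is.null(attr(x, "pairing"))) {
    cat("  choice pairing:", paste(attr(x, "pairing"), collapse = " vs "), "\n")
  }
  print(as.data.frame(utils::head(x, 5)))
  if (nrow(x) > 5) cat("  ... and", nrow(x) - 5, "more trials\n")
  invisible(x)
}

# Option offered on a non-choice trial (exactly one side lit).
offered_option <- function(schedule) {
  ifelse(is.na(schedule$option_left), schedule$option_right,
         schedule$option_left)
}

#' Check a session schedule against its design invariants
#'
#' Structural validation: per-sub-session trial counts, the
#' no-consecutive-peaks constraint, context alternation, option/context
#' membership, and (testing) the placement of choice trials at the first and
#' last single-option slots of each sub-session.  Violations are returned as
#' data, one message per problem; an empty character vector means the
#' schedule is valid.
#'
#' @param schedule a `session_schedule`.
#' @param config the [design_config()] it should conform to.
#' @return character vector of violation messages (empty if valid).
#' @examples
#' cfg <- design_config()
#' validate_schedule(build_training_session(cfg, seed = 7), cfg) # character(0)
#' @export
validate_schedule <- function(schedule, config) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  phase <- attr(schedule, "phase")
  if (is.null(phase)) {
    phase <- if (any(schedule$trial_type == "choice")) "testing" else "training"
  }
  k <- config$choice_pairs_per_context_visit
  contexts <- unique(config$options$context)

  ctx_by_ss <- vapply(split(schedule$context, schedule$subsession),
                      function(x) x[1], character(1))
  if (length(ctx_by_ss) != config$subsessions_per_day) {
    say("expected %d sub-sessions, found %d", config$subsessions_per_day,
        length(ctx_by_ss))
  }
  if (any(ctx_by_ss[-1] == ctx_by_ss[-length(ctx_by_ss)])) {
    say("contexts do not alternate across sub-sessions")
  }

  for (ss in unique(schedule$subsession)) {
    sub <- schedule[schedule$subsession == ss, ]
    ctx <- sub$context[1]
    opts <- config$options$id[config$options$context == ctx]
    if (!all(sub$context == ctx)) say("sub-session %s mixes contexts", ss)

    n_single_exp <- 2L * config$singles_per_option -
      if (phase == "testing") 2L * k else 0L
    tt <- table(factor(sub$trial_type,
                       levels = c("single", "peak", "choice")))
    if (tt[["single"]] != n_single_exp) {
      say("sub-session %s: %d single trials, expected %d", ss,
          tt[["single"]], n_single_exp)
    }
    if (tt[["peak"]] != 2L * config$peaks_per_option) {
      say("sub-session %s: %d peak trials, expected %d", ss, tt[["peak"]],
          2L * config$peaks_per_option)
    }
    if (tt[["choice"]] != (if (phase == "testing") 2L * k else 0L)) {
      say("sub-session %s: %d choice trials, expected %d", ss, tt[["choice"]],
          if (phase == "testing") 2L * k else 0L)
    }

    pk <- which(sub$trial_type == "peak")
    adjacent <- pk[which(diff(pk) == 1L)]
    for (i in adjacent) {
      say("sub-session %s: consecutive peak trials at indices %d and %d",
          ss, sub$trial_index[i], sub$trial_index[i + 1L])
    }

    non_peak <- sub[sub$trial_type != "peak", ]
    for (i in seq_len(nrow(sub))) {
      if (sub$trial_type[i] == "choice") next
      o <- offered_option(sub[i, ])
      if (is.na(o) || !(o %in% opts)) {
        say("trial %d: option %s not in context %s", sub$trial_index[i],
            o, ctx)
      }
    }
    if (phase == "testing" && nrow(non_peak) >= 2L * k) {
      pos <- which(non_peak$trial_type == "choice")
      want <- c(seq_len(k), nrow(non_peak) - k + seq_len(k) - 0L)
      if (!identical(sort(pos), sort(unique(want)))) {
        say(paste0("sub-session %s: choice trials misplaced (positions %s ",
                   "among non-peak trials, expected first and last %d)"),
            ss, paste(pos, collapse = ","), k)
      }
    }
  }
  v
}
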