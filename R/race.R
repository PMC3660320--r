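#' A labelled sample of response latencies
#'
#' The unit of input to the Sequential Choice Model: all latencies recorded
#' for one option under one condition (alone in single-option trials, or
#' when chosen in choice trials), for one subject.
#'
#' @param option option id.
#' @param latencies numeric vector of latencies, seconds; non-empty, all
#'   positive.
#' @param condition `"single_option"` or `"chosen_in_choice"`.
#' @param subject subject id (optional).
#' @return a list of class `latency_sample`.
#' @export
latency_sample <- function(option, latencies,
                           condition = c("single_option",
                                         "chosen_in_choice"),
                           subject = NA_character_) {
  condition <- match.arg(condition)
  latencies <- as.numeric(latencies)
  if (length(latencies) == 0L) stop("latency sample for option ", option,
                                    " is empty")
  if (any(!is.finite(latencies)) || any(latencies <= 0)) {
    stop("latencies must be positive and finite")
  }
  structure(list(option = as.character(option), condition = condition,
                 latencies = latencies, subject = subject),
            class = "latency_sample")
}

#' @export
print.latency_sample <- function(x, ...) {
  cat(sprintf("<latency_sample> option %s, %s, n = %d, median %.3f s\n",
              x$option, x$condition, length(x$latencies),
              stats::median(x$latencies)))
  invisible(x)
}

as_latencies <- function(x) {
  if (inherits(x, "latency_sample")) x$latencies else as.numeric(x)
}

#' One race between two latency realisations
#'
#' The SCM choice rule: the option whose latency process finishes first is
#' taken, at its own latency.  Exact ties are broken by a fair coin (a
#' measure-zero event for continuous latencies; relevant for discretised
#' logs).
#'
#' @param lat_a,lat_b latencies in seconds, both positive.
#' @param id_a,id_b identifiers returned as the winner.
#' @return list with `winner` (id) and `latency` (the winning, i.e. smaller,
#'   latency).
#' @examples
#' race_trial(0.5, 0.9) # a wins at 0.5 s
#' @export
race_trial <- function(lat_a, lat_b, id_a = "a", id_b = "b") {
  if (!is.finite(lat_a) || !is.finite(lat_b) || lat_a <= 0 || lat_b <= 0) {
    stop("latencies must be positive and finite")
  }
  if (lat_a < lat_b) {
    list(winner = id_a, latency = lat_a)
  } else if (lat_b < lat_a) {
    list(winner = id_b, latency = lat_b)
  } else if (stats::runif(1) < 0.5) {
    list(winner = id_a, latency = lat_a)
  } else {
    list(winner = id_b, latency = lat_b)
  }
}

#' SCM Monte Carlo prediction of simultaneous-choice preference
#'
#' Runs the Sequential Choice Model on two empirical latency samples: in
#' each of `n_experiments` simulated experiments, `n_trials` choice trials
#' are resolved by drawing one latency per option (resampling with
#' replacement from the observed single-option latencies) and taking the
#' option with the shorter draw.  Returns the mean predicted preference,
#' its dispersion across experiments, and the pooled winner-latency samples
#' — the censored latencies the model predicts for choice trials.
#'
#' Each experiment runs on its own child RNG stream derived from `seed`, so
#' enlarging `n_experiments` never perturbs earlier experiments.
#'
#' @param sample_a,sample_b [latency_sample()]s (or bare numeric vectors)
#'   of single-option latencies for the two options.
#' @param n_trials choice trials per experiment (default 96, i.e. 48 + 48
#'   in the reference design).
#' @param n_experiments number of simulated experiments (default 10000).
#' @param seed integer root seed.
#' @return a list of class `preference_prediction`: `pairing`, `preference`
#'   (named proportions summing to 1), `se` (Monte Carlo standard error of
#'   the mean preference), `sd` (SD of per-experiment preference),
#'   `per_experiment` (vector of per-experiment preferences for option a),
#'   `winners` (list of winning-latency vectors per option), `n_trials`,
#'   `n_experiments`.
#' @examples
#' a <- latency_sample("A", c(0.4, 0.5))
#' b <- latency_sample("B", c(0.6, 0.7))
#' predict_preference(a, b, n_trials = 10, n_experiments = 50,
#'                    seed = 1)$preference # A = 1: supports are disjoint
#' @export
predict_preference <- function(sample_a, sample_b, n_trials = 96L,
                               n_experiments = 10000L, seed = 1L) {
  id_a <- if (inherits(sample_a, "latency_sample")) sample_a$option else "a"
  id_b <- if (inherits(sample_b, "latency_sample")) sample_b$option else "b"
  xa <- as_latencies(sample_a)
  xb <- as_latencies(sample_b)
  if (!length(xa) || !length(xb)) stop("latency samples must be non-empty")
  stopifnot(n_trials > 0, n_experiments > 0)

  prop_a <- numeric(n_experiments)
  win_a <- vector("list", n_experiments)
  win_b <- vector("list", n_experiments)
  for (e in seq_len(n_experiments)) {
    with_seed(derive_seed(seed, "experiment", e), {
      la <- xa[sample.int(length(xa), n_trials, replace = TRUE)]
      lb <- xb[sample.int(length(xb), n_trials, replace = TRUE)]
      a_wins <- la < lb
      tie <- la == lb
      if (any(tie)) {
        a_wins[tie] <- stats::runif(sum(tie)) < 0.5
      }
      prop_a[e] <- mean(a_wins)
      win_a[[e]] <- la[a_wins]
      win_b[[e]] <- lb[!a_wins]
    })
  }

  pref <- c(mean(prop_a), 1 - mean(prop_a))
  names(pref) <- c(id_a, id_b)
  structure(list(
    pairing = c(id_a, id_b),
    preference = pref,
    sd = stats::sd(prop_a),
    se = stats::sd(prop_a) / sqrt(n_experiments),
    per_experiment = prop_a,
    winners = stats::setNames(list(unlist(win_a), unlist(win_b)),
                              c(id_a, id_b)),
    n_trials = as.integer(n_trials),
    n_experiments = as.integer(n_experiments),
    seed = as.integer(seed)
  ), class = "preference_prediction")
}

#' @export
print.preference_prediction <- function(x, ...) {
  cat(sprintf("<preference_prediction> %s vs %s (%d experiments x %d trials)\n",
              x$pairing[1], x$pairing[2], x$n_experiments, x$n_trials))
  cat(sprintf("  P(%s) = %.3f, P(%s) = %.3f  (MC SE %.2g)\n",
              x$pairing[1], x$preference[1], x$pairing[2], x$preference[2],
              x$se))
  invisible(x)
}

#' Analytic race-model preference for parametric latency laws
#'
#' The continuous-law oracle for [predict_preference()]: the probability
#' that a draw from law A undercuts an independent draw from law B,
#' \deqn{P(A \prec B) = \int_0^\infty f_A(t)\, S_B(t)\, dt,}
#' computed by adaptive quadrature.  Point masses are handled exactly
#' (ties split 0.5, mirroring the race's fair coin).
#'
#' @param dist_a,dist_b latency laws built with [dist_exponential()],
#'   [dist_lognormal()] or [dist_point()], or any list with elements
#'   `d` (density) and `p` (CDF), plus optional `point` (an atom location).
#' @param rel_tol quadrature relative tolerance (default 1e-8).
#' @return probability that option A wins the race.
#' @examples
#' analytic_preference(dist_exponential(2), dist_exponential(1)) # 2/3
#' analytic_preference(dist_point(0.5), dist_point(0.7))         # 1
#' @export
analytic_preference <- function(dist_a, dist_b, rel_tol = 1e-8) {
  pa <- dist_a$point
  pb <- dist_b$point
  if (!is.null(pa) && !is.null(pb)) {
    return(if (pa < pb) 1 else if (pa > pb) 0 else 0.5)
  }
  if (!is.null(pa)) return(1 - dist_b$p(pa)) # P(B > a)
  if (!is.null(pb)) return(dist_a$p(pb))     # P(A < b)
  integrand <- function(t) dist_a$d(t) * (1 - dist_b$p(t))
  res <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = Inf,
                     rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) stop("quadrature failed: ", conditionMessage(e))
  )
  if (res$message != "OK") stop("quadrature did not converge: ", res$message)
  min(max(res$value, 0), 1)
}

#' Parametric latency laws for the analytic race oracle
#'
#' Thin wrappers pairing a density with its CDF (and, for `dist_point`, an
#' atom) in the form [analytic_preference()] consumes.  `shift` adds a
#' constant offset (a reaction-time floor) to the lognormal.
#'
#' @param rate exponential rate, 1/s.
#' @param meanlog,sdlog lognormal parameters.
#' @param shift additive offset, seconds (default 0).
#' @param x location of a point mass, seconds.
#' @return a list with elements `d`, `p` (and `point` for `dist_point`).
#' @export
dist_exponential <- function(rate) {
  list(d = function(t) stats::dexp(t, rate),
       p = function(t) stats::pexp(t, rate))
}

#' @rdname dist_exponential
#' @export
dist_lognormal <- function(meanlog, sdlog, shift = 0) {
  list(d = function(t) stats::dlnorm(t - shift, meanlog, sdlog),
       p = function(t) stats::plnorm(t - shift, meanlog, sdlog))
}

#' @rdname dist_exponential
#' @export
dist_point <- function(x) {
  list(d = function(t) ifelse(t == x, Inf, 0),
       p = function(t) as.numeric(t >= x), point = x)
}

#' Summaries of an option's censored (winning) choice latencies
#'
#' In the race, an option's choice latencies are its latency draws
#' conditioned on beating the rival — slow realisations are censored by the
#' other option winning.  This returns the median and ECDF-area score of
#' the winner latencies pooled across experiments; by construction they are
#' stochastically no longer than the unconditional sample.
#'
#' @param prediction a [predict_preference()] result.
#' @param option one of the two option ids in the prediction.
#' @param grid latency cut points for the ECDF score; defaults to the
#'   pooled deciles of the winner latencies.
#' @return list with `option`, `n`, `median`, `ecdf_score`, and `empty`
#'   (`TRUE` when the option never won — a dominated option, flagged rather
#'   than an error).
#' @export
censored_latency_summary <- function(prediction, option, grid = NULL) {
  if (!option %in% prediction$pairing) {
    stop("option ", option, " did not participate in this prediction")
  }
  w <- prediction$winners[[option]]
  if (length(w) == 0L) {
    return(list(option = option, n = 0L, median = NA_real_,
                ecdf_score = NA_real_, empty = TRUE))
  }
  if (is.null(grid)) grid <- decile_grid(w)
  list(option = option, n = length(w), median = stats::median(w),
       ecdf_score = ecdf_score(w, grid)$score, empty = FALSE)
}
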