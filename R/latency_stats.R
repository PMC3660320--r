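#' Cumulative-frequency (ECDF-area) score of a latency sample
#'
#' Summarises a latency distribution by the mean height of its empirical
#' CDF over a fixed grid of cut points:
#' \deqn{score = \frac{1}{|G|} \sum_{g \in G} \hat F(g) \in [0, 1].}
#' The greater the score (area below the cumulative curve), the shorter the
#' latencies overall.  Comparisons are only meaningful on a shared grid;
#' [decile_grid()] builds one from the pooled deciles of all samples under
#' comparison.
#'
#' @param latencies a [latency_sample()] or numeric vector, seconds.
#' @param grid strictly increasing cut points, seconds.
#' @return list of class `ecdf_score`: `option`, `condition`, `grid`,
#'   `score`.
#' @examples
#' ecdf_score(c(0.5, 1.5), grid = c(1, 2))$score # (0.5 + 1)/2 = 0.75
#' @export
ecdf_score <- function(latencies, grid) {
  x <- as_latencies(latencies)
  if (!length(x)) stop("empty latency sample")
  if (!length(grid)) stop("empty grid")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  Fhat <- stats::ecdf(x)
  structure(list(
    option = if (inherits(latencies, "latency_sample")) latencies$option
             else NA_character_,
    condition = if (inherits(latencies, "latency_sample"))
                  latencies$condition else NA_character_,
    grid = grid,
    score = mean(Fhat(grid))
  ), class = "ecdf_score")
}

#' @rdname ecdf_score
#' @param ... latency samples or numeric vectors to pool.
#' @param probs quantile probabilities for the grid (default the nine
#'   interior deciles).
#' @export
decile_grid <- function(..., probs = seq(0.1, 0.9, by = 0.1)) {
  pooled <- unlist(lapply(list(...), as_latencies))
  g <- unique(stats::quantile(pooled, probs = probs, names = FALSE,
                              type = 7))
  if (length(g) < 2L) g <- unique(c(g, g + 1e-9))
  g
}

#' Latency shortening between single-option and choice conditions
#'
#' The SCM predicts that latencies on choice trials (censored minima) are
#' shorter than on single-option trials, and more so for the less-preferred
#' (more-censored) option.  Shortening is quantified as the difference in
#' ECDF-area scores, choice minus single, on a grid pooled from both
#' conditions: positive values mean shorter choice latencies.  When lists
#' of per-subject samples are supplied the difference is computed per
#' subject and a paired t test is added.
#'
#' @param single,choice [latency_sample()]s for one option under the two
#'   conditions, or lists of such samples (one per subject, in matching
#'   order).
#' @param grid optional shared grid; defaults to pooled deciles across both
#'   conditions (per subject when paired).
#' @return for single samples, a list with `shortening` (the score
#'   difference), `score_single`, `score_choice`; for per-subject lists,
#'   additionally `per_subject` (data frame) and `t`, `df`, `p` from the
#'   paired test.
#' @export
shortening <- function(single, choice, grid = NULL) {
  if (inherits(single, "latency_sample") &&
      inherits(choice, "latency_sample")) {
    if (!identical(single$option, choice$option)) {
      stop("conditions belong to different options: ", single$option,
           " vs ", choice$option)
    }
    g <- if (is.null(grid)) decile_grid(single, choice) else grid
    s1 <- ecdf_score(single, g)$score
    s2 <- ecdf_score(choice, g)$score
    return(list(option = single$option, shortening = s2 - s1,
                score_single = s1, score_choice = s2))
  }
  if (!is.list(single) || !is.list(choice) ||
      length(single) != length(choice)) {
    stop("supply two latency_samples or two equal-length lists of them")
  }
  per <- mapply(function(s, c) shortening(s, c, grid = grid)$shortening,
                single, choice)
  tt <- degenerate_safe_t(per, mu = 0)
  list(option = single[[1]]$option,
       per_subject = data.frame(
         subject = vapply(single, function(s) as.character(s$subject),
                          character(1)),
         shortening = per),
       shortening = mean(per), t = tt$t, df = tt$df, p = tt$p,
       degenerate = tt$degenerate)
}

#' Arcsine-square-root transform of proportions
#'
#' `asin(sqrt(p))`: the classical variance-stabilising transform for
#' proportions, mapping `[0, 1]` monotonically onto `[0, pi/2]`.
#'
#' @param p proportions in `[0, 1]`.
#' @return transformed values, radians.
#' @examples
#' arcsine_sqrt(c(0, 0.5, 1)) # 0, pi/4, pi/2
#' @export
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  asin(sqrt(p))
}

# One-sample t robust to zero variance: degenerate samples are flagged,
# not raised.
degenerate_safe_t <- function(x, mu) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 2L) stop("need at least two observations")
  if (s == 0) {
    return(list(t = if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf,
                df = n - 1L, p = if (mean(x) == mu) 1 else 0,
                degenerate = TRUE))
  }
  t <- (mean(x) - mu) / (s / sqrt(n))
  list(t = t, df = n - 1L, p = 2 * stats::pt(-abs(t), df = n - 1L),
       degenerate = FALSE)
}

#' One-sample test of preference against indifference
#'
#' Applies the arcsine-square-root transform to per-subject choice
#' proportions and to the null proportion, then performs a standard
#' one-sample t test (two-tailed, df = n - 1).  Zero-variance inputs are
#' flagged degenerate rather than raising.
#'
#' @param per_subject_proportions choice proportions in `[0, 1]`, one per
#'   subject (at least two).
#' @param null the indifference point (default 0.5).
#' @return list with `t`, `df`, `p`, `mean_proportion`, `degenerate`.
#' @examples
#' preference_test(c(0.55, 0.7, 0.62, 0.71, 0.66, 0.58, 0.75))
#' @export
preference_test <- function(per_subject_proportions, null = 0.5) {
  p <- per_subject_proportions
  if (length(p) < 2L) stop("need at least two subjects")
  tt <- degenerate_safe_t(arcsine_sqrt(p), mu = arcsine_sqrt(null))
  c(list(mean_proportion = mean(p)), tt)
}

#' Stability criterion on session-wise choice percentages
#'
#' A preference series is stable when, over the last three sessions, the
#' standard deviation of the choice percentages is below `sd_threshold`
#' (default 10 points) and the least-squares trend is below
#' `trend_threshold` in absolute value.  "No visible trend" has no numeric
#' definition in the source design; the default of 5 points/session is a
#' configurable operationalisation.
#'
#' @param choice_pcts per-session choice percentages (0–100); at least
#'   three, the last three are used.
#' @param sd_threshold SD threshold, percentage points (default 10).
#' @param trend_threshold absolute OLS slope threshold, points/session
#'   (default 5).
#' @return list of class `stability_verdict`: `last_three`, `sd`, `slope`,
#'   `stable`.
#' @examples
#' stability_check(c(40, 60, 80))$stable # FALSE: SD 20, slope 20
#' stability_check(c(60, 61, 59))$stable # TRUE
#' @export
stability_check <- function(choice_pcts, sd_threshold = 10,
                            trend_threshold = 5) {
  if (length(choice_pcts) < 3L) stop("need at least three sessions")
  last3 <- utils::tail(choice_pcts, 3L)
  s <- stats::sd(last3)
  # closed-form OLS slope on session index: exact at threshold boundaries
  x <- seq_along(last3)
  slope <- sum((x - mean(x)) * (last3 - mean(last3))) / sum((x - mean(x))^2)
  structure(list(last_three = last3, sd = s, slope = slope,
                 stable = s < sd_threshold && abs(slope) < trend_threshold),
            class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf("<stability_verdict> last three: %s | SD %.2f, slope %.2f -> %s\n",
              paste(round(x$last_three, 1), collapse = ", "), x$sd, x$slope,
              if (x$stable) "stable" else "not stable"))
  invisible(x)
}

#' Paired comparison of latency central tendency across conditions
#'
#' Paired t test on natural-log-transformed per-subject median latencies
#' (single-option vs chosen-in-choice), the standard test for a
#' deliberation-time lengthening (positive difference) or a race-censoring
#' shortening (negative difference).
#'
#' @param single_medians,choice_medians per-subject median latencies,
#'   seconds, in matching subject order; all positive.
#' @return list with `t`, `df`, `p`, `mean_log_ratio`
#'   (mean of `log(choice) - log(single)`), `degenerate`.
#' @export
compare_latency_conditions <- function(single_medians, choice_medians) {
  if (length(single_medians) != length(choice_medians)) {
    stop("unpaired input: lengths differ")
  }
  if (any(single_medians <= 0) || any(choice_medians <= 0)) {
    stop("medians must be positive")
  }
  d <- log(choice_medians) - log(single_medians)
  tt <- degenerate_safe_t(d, mu = 0)
  c(list(mean_log_ratio = mean(d)), tt)
}
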