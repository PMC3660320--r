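test_that("race_trial takes the minimum and splits ties fairly", {
  r <- race_trial(0.5, 0.9, id_a = "A", id_b = "C")
  expect_equal(r$winner, "A")
  expect_equal(r$latency, 0.5)
  expect_error(race_trial(-1, 0.5), "positive")
  expect_error(race_trial(0.5, 0), "positive")
  wins_a <- scmforage:::with_seed(17, {
    mean(vapply(1:4000, function(i) race_trial(0.7, 0.7)$winner == "a",
                logical(1)))
  })
  expect_lt(abs(wins_a - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("race on exponential draws matches the closed form", {
  # P(A wins) = rate_a / (rate_a + rate_b) for Exponential racers
  races <- scmforage:::with_seed(23, {
    la <- rexp(1e5, 1); lb <- rexp(1e5, 2)
    mean(la < lb)
  })
  expect_lt(abs(races - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / 1e5))
})

test_that("predict_preference: symmetry, dominance, normalisation, determinism", {
  x <- scmforage:::with_seed(3, rlnorm(400, -0.5, 0.5))
  same <- predict_preference(latency_sample("A", x), latency_sample("B", x),
                             n_experiments = 2000, seed = 31)
  # identical lists: conditional win probability is exactly 1/2, only
  # Monte Carlo error remains
  expect_lt(abs(same$preference[1] - 0.5), 3 * same$se)
  expect_equal(sum(same$preference), 1)

  disjoint <- predict_preference(latency_sample("A", c(0.4, 0.5)),
                                 latency_sample("B", c(0.6, 0.7)),
                                 n_experiments = 200, seed = 5)
  expect_equal(unname(disjoint$preference["A"]), 1)
  expect_length(disjoint$winners$B, 0)

  p1 <- predict_preference(latency_sample("A", x),
                           latency_sample("B", x * 1.1),
                           n_experiments = 300, seed = 77)
  p2 <- predict_preference(latency_sample("A", x),
                           latency_sample("B", x * 1.1),
                           n_experiments = 300, seed = 77)
  expect_identical(p1$per_experiment, p2$per_experiment)
  # per-experiment child streams: enlarging the run keeps early experiments
  p3 <- predict_preference(latency_sample("A", x),
                           latency_sample("B", x * 1.1),
                           n_experiments = 600, seed = 77)
  expect_identical(p1$per_experiment, p3$per_experiment[1:300])
  expect_error(predict_preference(latency_sample("A", 1), numeric(0)),
               "non-empty")
})

test_that("resampling agrees with the quadrature oracle on parametric laws", {
  # two-layer check: the resampling mean equals the sample's exact race
  # probability (a Mann-Whitney U statistic) up to MC error, and the U
  # statistic equals the analytic integral up to sampling error.
  cases <- list(
    list(ra = function(n) rexp(n, 1), rb = function(n) rexp(n, 2),
         da = dist_exponential(1), db = dist_exponential(2),
         truth = 1 / 3),
    list(ra = function(n) rlnorm(n, -0.5, 0.4),
         rb = function(n) rlnorm(n, -0.2, 0.6),
         da = dist_lognormal(-0.5, 0.4), db = dist_lognormal(-0.2, 0.6),
         truth = NA)
  )
  for (case in cases) {
    n <- 2000
    xa <- scmforage:::with_seed(41, case$ra(n))
    xb <- scmforage:::with_seed(42, case$rb(n))
    u <- mean(outer(xa, xb, "<")) # exact race probability given the samples
    pred <- predict_preference(latency_sample("a", xa),
                               latency_sample("b", xb),
                               n_experiments = 2000, seed = 8)
    expect_lt(abs(pred$preference[1] - u), 3 * pred$se)
    analytic <- analytic_preference(case$da, case$db)
    if (!is.na(case$truth)) expect_equal(analytic, case$truth,
                                         tolerance = 1e-7)
    se_u <- sqrt(analytic * (1 - analytic) * (1 / n + 1 / n))
    expect_lt(abs(u - analytic), 3 * se_u)
  }
})

test_that("analytic_preference handles symmetry and point masses", {
  expect_equal(analytic_preference(dist_exponential(1), dist_exponential(1)),
               0.5, tolerance = 1e-8)
  expect_equal(analytic_preference(dist_exponential(2), dist_exponential(1)),
               2 / 3, tolerance = 1e-7)
  expect_equal(analytic_preference(dist_point(0.5), dist_point(0.7)), 1)
  expect_equal(analytic_preference(dist_point(0.7), dist_point(0.7)), 0.5)
  expect_equal(analytic_preference(dist_point(0.5), dist_exponential(1)),
               exp(-0.5))
})

test_that("upward shifts never increase a racer's preference", {
  x <- scmforage:::with_seed(51, rlnorm(300, -0.3, 0.5))
  y <- scmforage:::with_seed(52, rlnorm(300, -0.3, 0.5))
  base <- predict_preference(latency_sample("A", x), latency_sample("B", y),
                             n_experiments = 500, seed = 9)$preference["A"]
  for (shift in c(0.05, 0.2, 1)) {
    shifted <- predict_preference(latency_sample("A", x + shift),
                                  latency_sample("B", y),
                                  n_experiments = 500,
                                  seed = 9)$preference["A"]
    expect_lte(shifted, base)
  }
})

test_that("winner latencies are censored: ECDF dominance at every grid point", {
  for (seed in c(2, 12, 22)) {
    xa <- option_draws("B", 400, seed = seed)
    xb <- option_draws("C", 400, seed = seed + 1000)
    pred <- predict_preference(latency_sample("B", xa),
                               latency_sample("C", xb),
                               n_experiments = 500, seed = seed)
    for (o in c("B", "C")) {
      uncond <- if (o == "B") xa else xb
      w <- pred$winners[[o]]
      g <- decile_grid(uncond, w)
      expect_true(all(ecdf(w)(g) >= ecdf(uncond)(g) - 1e-12))
    }
  }
})

test_that("censored summaries shorten, more so for the less preferred option", {
  xb <- option_draws("B", 500, seed = 71)
  xc <- option_draws("C", 500, seed = 72)
  pred <- predict_preference(latency_sample("B", xb),
                             latency_sample("C", xc),
                             n_experiments = 1000, seed = 73)
  expect_lt(pred$preference["B"], 0.5) # B is the less preferred option
  sb <- censored_latency_summary(pred, "B")
  sc <- censored_latency_summary(pred, "C")
  expect_lte(sb$median, median(xb))
  expect_lte(sc$median, median(xc))
  shorten <- function(uncond, w) {
    g <- decile_grid(uncond, w)
    ecdf_score(w, g)$score - ecdf_score(uncond, g)$score
  }
  expect_gt(shorten(xb, pred$winners$B), shorten(xc, pred$winners$C))
  # dominated option: empty winner set is flagged, not an error
  dom <- predict_preference(latency_sample("A", c(0.4, 0.5)),
                            latency_sample("B", c(0.6, 0.7)),
                            n_experiments = 100, seed = 1)
  expect_true(censored_latency_summary(dom, "B")$empty)
  expect_error(censored_latency_summary(dom, "Z"), "did not participate")
})

test_that("raw resampling and nonparametric-ECDF sampling agree", {
  x <- option_draws("B", 600, seed = 81)
  y <- option_draws("C", 600, seed = 82)
  raw <- predict_preference(latency_sample("B", x), latency_sample("C", y),
                            n_experiments = 2000, seed = 83)
  # sampling the nonparametric ECDF estimate = inverse-CDF draws
  ecdf_draws <- function(s, n) {
    quantile(s, probs = runif(n), type = 1, names = FALSE)
  }
  xe <- scmforage:::with_seed(84, ecdf_draws(x, 600))
  ye <- scmforage:::with_seed(85, ecdf_draws(y, 600))
  np <- predict_preference(latency_sample("B", xe), latency_sample("C", ye),
                           n_experiments = 2000, seed = 83)
  se <- sqrt(raw$preference[1] * (1 - raw$preference[1]) * (2 / 600)) +
    raw$se + np$se
  expect_lt(abs(raw$preference[1] - np$preference[1]), 3 * se)
})
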