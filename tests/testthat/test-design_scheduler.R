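test_that("option_set enforces two distinctly ranked options per context", {
  expect_s3_class(default_options(), "option_set")
  expect_error(option_set("A", 5, "AB", 1L), "exactly two options")
  expect_error(
    option_set(c("A", "B"), c(5, 10), c("AB", "AB"), c(1L, 1L)),
    "distinct"
  )
  expect_error(option_set(c("A", "B"), c(-5, 10), c("AB", "AB"), 1:2))
})

test_that("default training schedule reproduces the design arithmetic", {
  cfg <- default_cfg()
  sched <- build_training_session(cfg, day_parity = 0, seed = 11)
  expect_equal(nrow(sched), 176L)
  expect_equal(as.vector(table(sched$subsession)), rep(44L, 4))
  for (ss in 1:4) {
    sub <- sched[sched$subsession == ss, ]
    singles <- sub[sub$trial_type == "single", ]
    peaks <- sub[sub$trial_type == "peak", ]
    expect_equal(as.vector(table(scmforage:::offered_option(singles))),
                 c(20L, 20L))
    expect_equal(as.vector(table(scmforage:::offered_option(peaks))),
                 c(2L, 2L))
  }
  # context alternation flips with parity
  expect_equal(unique(sched$context[sched$subsession == 1]), "AB")
  flipped <- build_training_session(cfg, day_parity = 1, seed = 11)
  expect_equal(unique(flipped$context[flipped$subsession == 1]), "CD")
})

test_that("schedules are deterministic in the seed and degenerate configs work", {
  cfg <- default_cfg()
  expect_identical(build_training_session(cfg, seed = 5),
                   build_training_session(cfg, seed = 5))
  expect_false(identical(build_training_session(cfg, seed = 5),
                         build_training_session(cfg, seed = 6)))
  no_peaks <- design_config(peaks_per_option = 0L)
  sched <- build_training_session(no_peaks, seed = 3)
  expect_equal(nrow(sched), 160L)
  expect_equal(sum(sched$trial_type == "peak"), 0L)
  expect_length(validate_schedule(sched, no_peaks), 0)
})

test_that("unsatisfiable peak constraint raises a scheduling error", {
  bad <- design_config(singles_per_option = 1L, peaks_per_option = 3L)
  expect_error(build_training_session(bad, seed = 1), "scheduling error")
})

test_that("testing schedules substitute choice trials correctly", {
  cfg <- default_cfg()
  sched <- build_testing_session(cfg, pairing = "A:C", seed = 21)
  expect_equal(sum(sched$trial_type == "choice"), 16L)
  # 40 - 4 substituted single-option slots per sub-session
  for (ss in 1:4) {
    sub <- sched[sched$subsession == ss, ]
    expect_equal(sum(sub$trial_type == "single"), 36L)
    expect_equal(nrow(sub), 44L)
  }
  one_visit <- design_config(subsessions_per_day = 1L)
  expect_equal(
    sum(build_testing_session(one_visit, c("B", "C"),
                              seed = 2)$trial_type == "choice"),
    4L
  )
  expect_error(build_testing_session(cfg, pairing = c("A", "B"), seed = 1),
               "cross-context")
  expect_error(build_testing_session(cfg, pairing = c("A", "Z"), seed = 1),
               "pairing")
})

test_that("adjust_iti implements the rate-equalisation rule", {
  cfg <- default_cfg()
  expect_equal(adjust_iti(c(20, 20, 20, 20, 20), cfg), 30)
  expect_equal(adjust_iti(c(5, 5, 5, 5, 5), cfg), 105)   # 30 + (100 - 25)
  expect_equal(adjust_iti(c(5, 10, 20, 10, 5), cfg), 80) # 30 + (100 - 50)
  expect_error(adjust_iti(c(5, 5, 5), cfg), "length")
  expect_error(adjust_iti(c(5, 5, 5, 5, 7), cfg), "not in the configured")
  # bounds: never below base, equality only when all delays are maximal
  for (seed in 1:20) {
    d <- scmforage:::with_seed(seed,
      sample(default_options()$delay, 5, replace = TRUE))
    out <- adjust_iti(d, cfg)
    expect_gte(out, cfg$base_iti)
    if (!all(d == max(default_options()$delay))) {
      expect_gt(out, cfg$base_iti)
    }
  }
})

test_that("generated schedules validate cleanly across seeds and phases", {
  cfg <- default_cfg()
  for (seed in c(1, 7, 42, 99)) {
    expect_length(
      validate_schedule(build_training_session(cfg, seed %% 2, seed), cfg), 0)
    expect_length(
      validate_schedule(build_testing_session(cfg, "B:C", seed %% 2, seed),
                        cfg), 0)
  }
  qc <- quick_cfg()
  for (seed in 1:5) {
    expect_length(
      validate_schedule(build_testing_session(qc, "A:D", seed = seed), qc), 0)
  }
})

test_that("validator catches seeded faults", {
  cfg <- default_cfg()
  sched <- build_training_session(cfg, seed = 8)
  # force two adjacent peaks inside sub-session 1
  sub1 <- which(sched$subsession == 1)
  pk <- sub1[sched$trial_type[sub1] == "peak"][1]
  nxt <- pk + 1L # a single trial, since the fresh schedule is valid
  victim <- sub1[sched$trial_type[sub1] == "peak"][2]
  save <- sched[nxt, ]
  sched[nxt, ] <- sched[victim, ]
  sched[victim, ] <- save
  v <- validate_schedule(sched, cfg)
  expect_true(any(grepl("consecutive peak", v)))
  expect_true(any(grepl(as.character(pk), v))) # violation names the index

  # choice trial moved mid-session in a testing schedule
  test_sched <- build_testing_session(cfg, "A:C", seed = 8)
  sub1 <- which(test_sched$subsession == 1)
  ch <- sub1[test_sched$trial_type[sub1] == "choice"][1]
  mid <- sub1[test_sched$trial_type[sub1] == "single"][10]
  save <- test_sched[mid, ]
  test_sched[mid, ] <- test_sched[ch, ]
  test_sched[ch, ] <- save
  expect_true(any(grepl("misplaced", validate_schedule(test_sched, cfg))))
})

test_that("food maximum follows the printed all-trials arithmetic", {
  cfg <- default_cfg()
  expect_equal(food_maximum(cfg), 7.04)
  # peak trials are unrewarded: the strictly attainable maximum is lower
  expect_equal(food_maximum(cfg, "rewarded_only"), 6.4)
})

test_that("reward rate is equalised across contexts in simulated runs", {
  cfg <- default_cfg()
  log <- simulate_subject(build_training_session(cfg, seed = 31),
                          value_params(), timing_params(), seed = 32)
  delays <- with(default_options(), setNames(delay, id))
  block_totals <- list()
  for (ss in unique(log$subsession)) {
    singles <- log[log$subsession == ss & log$trial_type == "single", ]
    d <- delays[scmforage:::offered_option(singles)]
    blocks <- split(seq_len(nrow(singles)),
                    (seq_len(nrow(singles)) - 1) %/% cfg$iti_window)
    tot <- vapply(blocks, function(i) {
      sum(d[i]) + sum(singles$planned_iti_s[i])
    }, numeric(1))
    block_totals[[as.character(ss)]] <- tot
  }
  # delay + ITI per 5-trial block is the same constant in every context
  all_tot <- unlist(block_totals)
  expect_equal(max(all_tot), min(all_tot))
  expect_equal(unname(all_tot[1]),
               cfg$iti_max_sum + cfg$iti_window * cfg$base_iti)
})
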