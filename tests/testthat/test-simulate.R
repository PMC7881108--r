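test_that("generator config validates its stated world", {
  cfg <- generator_config()
  expect_identical(cfg$n_participants, 16L)
  expect_identical(cfg$conditions, c("MD", "HAD"))
  expect_equal(cfg$noise_rate, 0.15)
  expect_equal(cfg$sub80_rate, 0.05)
  expect_equal(cfg$visits_mean, 103)
  # rounding slack: the HAD shares sum to 1.0001 and must be accepted
  expect_equal(sum(default_class_mixture()$HAD), 1, tolerance = 1e-3)

  bad <- default_class_mixture()
  bad$MD["guidance"] <- 0.9
  expect_error(generator_config(class_mixture = bad), "sums to")
  expect_error(generator_config(noise_rate = 1), "noise_rate")
  expect_error(generator_config(class_mixture = list(MD = c(nope = 0.5)),
                                conditions = "MD"), "unknown class")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_participants = 3, seed = 99)
  a <- simulate_fixations(cfg)
  b <- simulate_fixations(cfg)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$ledger, b$ledger)
  c <- simulate_fixations(generator_config(n_participants = 3, seed = 100))
  expect_false(identical(a$fixations, c$fixations))
  # generation does not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulate_fixations(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a pure single-class mixture closes the loop through classification", {
  cfg <- generator_config(
    n_participants = 2, visits_mean = 150, noise_rate = 0, seed = 8,
    conditions = "MD",
    class_mixture = list(MD = c(guidance = 1.0)))
  sim <- simulate_fixations(cfg)
  seqs <- visit_sequences(sim$fixations)
  tri <- scanpath_distributions(seqs, 3, condition = "MD")
  cf <- class_frequencies(tri, scope = "full_dataset")
  expect_equal(cf$summary$mean_freq[cf$summary$class == "guidance"], 1)
  # guidance bouts alternate AOIs 1 and 3 exclusively
  expect_true(all(unlist(lapply(seqs, `[[`, "visits")) %in% c(1L, 3L)))
})

test_that("generated fixations survive the filter with their visit structure", {
  cfg <- generator_config(n_participants = 2, visits_mean = 80, seed = 17)
  sim <- simulate_fixations(cfg)
  expect_identical(sim$fixations, validate_fixations(sim$fixations))
  # sub-80 ms contamination is present by construction...
  expect_gt(sum(sim$fixations$duration_ms < 80), 0)
  # ...but each planted visit keeps a fixation >= 80 ms: collapsing after the
  # filter gives the same visit sequence as collapsing without it
  with_filter <- visit_sequences(sim$fixations, min_ms = 80)
  without <- visit_sequences(sim$fixations, min_ms = NULL)
  for (i in seq_along(with_filter))
    expect_identical(with_filter[[i]]$visits, without[[i]]$visits)
  # round trip: generated visit sequences satisfy the no-repeat invariant
  for (s in with_filter)
    expect_false(any(s$visits[-1] == s$visits[-length(s$visits)]))
})

test_that("ledger accounts for planted class mass and converges with size", {
  cfg <- generator_config(n_participants = 2, visits_mean = 60, seed = 4)
  sim <- simulate_fixations(cfg)
  led <- sim$ledger
  expect_setequal(unique(led$class), c(scanpath_classes(), "noise"))
  # planted visits per stream sum to the stream's visit count
  seqs <- visit_sequences(sim$fixations, min_ms = NULL)
  for (s in seqs) {
    planted <- sum(led$visits[led$participant == s$participant &
                                led$condition == s$condition])
    expect_identical(as.integer(planted), length(s$visits))
  }
  mx <- ledger_mixture(sim, "MD")
  expect_equal(sum(mx), 1, tolerance = 1e-9)
  expect_equal(unname(mx["supervision"]), 0)

  # consistency: recovered frequencies approach the ledger as size grows
  err_at <- function(visits_mean, seed) {
    cfg <- generator_config(n_participants = 4, visits_mean = visits_mean,
                            noise_rate = 0, seed = seed, conditions = "MD",
                            class_mixture = default_class_mixture()["MD"])
    sim <- simulate_fixations(cfg)
    dists <- scanpath_distributions(visit_sequences(sim$fixations), 4,
                                    condition = "MD")
    cf <- class_frequencies(dists, scope = "full_dataset")
    rec <- cf$pooled_counts / sum(cf$pooled_counts)
    max(abs(rec - ledger_mixture(sim, "MD")))
  }
  expect_lt(err_at(800, 6), err_at(60, 6))
})

test_that("markov baseline mode produces unstructured sequences", {
  cfg <- generator_config(n_participants = 2, visits_mean = 300,
                          mode = "markov", seed = 30, conditions = "MD")
  sim <- simulate_fixations(cfg)
  expect_true(all(sim$ledger$visits[sim$ledger$class != "noise"] == 0))
  seqs <- visit_sequences(sim$fixations)
  tri <- scanpath_distributions(seqs, 3, condition = "MD")
  cf <- suppressWarnings(class_frequencies(tri, scope = "full_dataset"))
  # under uniform transitions every catalogue triplet is equally likely:
  # classified mass should roughly follow catalogue sizes, e.g. scenery (9)
  # outweighing guidance (2)
  s <- stats::setNames(cf$summary$mean_freq, cf$summary$class)
  expect_gt(s[["right_scenery"]], s[["guidance"]])
})

test_that("the worked example matches its committed fixture files", {
  we <- make_worked_example()
  csv <- system.file("extdata", "worked_example_fixations.csv",
                     package = "scanpathr")
  expect_identical(read_fixations(csv), we$fixations)
  exp_file <- jsonlite::read_json(
    system.file("extdata", "worked_example_expected.json", package = "scanpathr"),
    simplifyVector = TRUE)
  expect_identical(as.integer(exp_file$visits), we$expected$visits)
  expect_identical(exp_file$quad_classes, we$expected$quad_classes)

  # every stage reproduces the hand-verified expectations
  fix <- filter_min_duration(we$fixations)
  expect_identical(nrow(we$fixations) - nrow(fix), 3L)  # three sub-80 ms events
  v <- collapse_to_visits(fix)
  expect_identical(v$visits, we$expected$visits)
  # the filter matters: without it a left-scenery visit appears
  v_raw <- collapse_to_visits(we$fixations)
  expect_true(5L %in% v_raw$visits && !(5L %in% v$visits))

  d <- extract_scanpaths(v, 4)
  expect_identical(d$total_windows, we$expected$total_windows)
  expect_identical(sum(d$counts == 1L), as.integer(we$expected$singletons))
  windows <- we$expected$quad_windows
  expect_setequal(names(d$counts), windows)
  expect_identical(classify_quad(windows, "MD"), we$expected$quad_classes)
  expect_identical(classify_triplet(we$expected$triplet_windows),
                   we$expected$triplet_classes)
  # all five manual-driving classes are represented
  expect_setequal(setdiff(we$expected$quad_classes, "unclassified"),
                  setdiff(scanpath_classes(), "supervision"))
})
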