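test_that("triplet catalogue has 28 valid, distinct entries with the right sizes", {
  cat <- triplet_catalogue()
  expect_identical(nrow(cat), 28L)
  expect_identical(anyDuplicated(cat$triplet), 0L)
  sizes <- catalogue_size()
  expect_identical(sizes$total, 28L)
  expect_identical(unname(sizes$per_class[scanpath_classes()]),
                   c(4L, 2L, 4L, 9L, 5L, 4L))
  for (t in cat$triplet) {
    v <- as.integer(strsplit(t, "")[[1]])
    expect_true(all(v %in% 0:6))
    expect_false(any(v[-1] == v[-3]))
  }
})

test_that("triplet classification is exact catalogue lookup", {
  expect_identical(classify_triplet("141"), "forward_polling")
  expect_identical(classify_triplet("040"), "supervision")
  expect_identical(classify_triplet("565"), "unclassified")
  expect_error(classify_triplet("12"), "length-3")
  # brute force: equality with the literal table over all 252 valid triplets
  cat <- triplet_catalogue()
  lookup <- stats::setNames(cat$class, cat$triplet)
  all3 <- enumerate_norepeat(7, 3)
  got <- classify_triplet(all3)
  want <- ifelse(all3 %in% names(lookup), lookup[all3], "unclassified")
  expect_identical(got, unname(want))
})

test_that("length-4 rules classify the canonical examples", {
  expect_identical(classify_quad("1414", "MD"), "forward_polling")
  expect_identical(classify_quad("1212", "MD"), "backwards_polling")
  expect_identical(classify_quad("1313", "MD"), "guidance")
  expect_identical(classify_quad("0120", "MD"), "speed_monitoring")
  expect_identical(classify_quad("1616", "MD"), "right_scenery")
  # residual is condition-gated
  expect_identical(classify_quad("2424", "HAD"), "supervision")
  expect_identical(classify_quad("2424", "MD"), "unclassified")
  # both forward and guidance predicates fire for 1341; precedence resolves
  expect_identical(classify_quad("1341", "MD"), "forward_polling")
  expect_error(classify_quad("121", "MD"), "length-4")
  expect_error(classify_quad("1214", "MD", precedence = c("guidance")),
               "permutation")
})

test_that("classify_quad is total and deterministic over all 1512 valid quads", {
  all4 <- enumerate_norepeat(7, 4)
  expect_identical(length(all4), 1512L)
  for (cond in c("MD", "HAD")) {
    cls <- classify_quad(all4, cond)
    expect_identical(length(cls), 1512L)
    allowed <- c(scanpath_classes(), "unclassified")
    expect_true(all(cls %in% allowed))
    expect_identical(cls, classify_quad(all4, cond))  # deterministic
    if (cond == "MD") expect_false(any(cls == "supervision"))
    if (cond == "HAD") expect_false(any(cls == "unclassified"))
  }
})

test_that("catalogue/rule consistency audit reports the known exceptions", {
  audit <- audit_catalogue_consistency("HAD")
  expect_identical(sort(unique(audit$triplet)), sort(triplet_catalogue()$triplet))
  # the road-structure triplets embed consistently in every length-4 window
  road <- c("141", "143", "343", "341", "131", "313",
            "121", "123", "323", "321")
  for (t in road)
    expect_true(all(audit$consistent[audit$triplet == t]), label = t)
  # known exceptions exist and are reported, not hidden: AOI-3 partners of
  # the scenery pivot and the 0-2 supervision triplets cannot be expressed
  # by the length-4 rules in every context
  for (t in c("363", "402", "204"))
    expect_false(all(audit$consistent[audit$triplet == t]), label = t)
  # every generator emission motif embeds consistently on at least one side
  for (t in c("161", "162", "261", "262", "303", "101", "301", "103",
              "202", "242", "040"))
    expect_true(any(audit$consistent[audit$triplet == t]), label = t)
})

test_that("class frequencies are per participant then averaged", {
  d1 <- extract_scanpaths(visits_obj(rep(c(1, 2), 10), participant = "a"), 4)
  t1 <- class_frequencies(list(d1))
  expect_equal(t1$summary$mean_freq[t1$summary$class == "backwards_polling"], 1)
  expect_equal(sum(t1$summary$mean_freq), 1)

  d2 <- extract_scanpaths(visits_obj(rep(c(1, 3), 10), participant = "b"), 4)
  t2 <- class_frequencies(list(d1, d2))
  s <- t2$summary
  expect_equal(s$mean_freq[s$class == "backwards_polling"], 0.5)
  expect_equal(s$mean_freq[s$class == "guidance"], 0.5)

  # invariance to participant relabeling
  d1b <- d1; d1b$participant <- "zz"
  t3 <- class_frequencies(list(d2, d1b))
  expect_equal(sort(t3$summary$mean_freq), sort(s$mean_freq))

  # a participant with no classifiable scan path is excluded with a warning
  d_null <- extract_scanpaths(visits_obj(rep(c(5, 0), 8), participant = "c"), 4)
  expect_warning(t4 <- class_frequencies(list(d1, d_null)), "excluded")
  expect_identical(t4$excluded, "c")

  expect_error(class_frequencies(list(d1, extract_scanpaths(visits_obj(1:5), 3))),
               "one condition and one scan-path length")
})

test_that("generator mixture ranking is recovered through classification", {
  cfg <- generator_config(
    n_participants = 6, visits_mean = 500, seed = 12,
    class_mixture = list(
      MD = c(forward_polling = 0.12, guidance = 0.19,
             backwards_polling = 0.49, right_scenery = 0.04,
             speed_monitoring = 0.16, supervision = 0)),
    conditions = "MD")
  sim <- simulate_fixations(cfg)
  dists <- scanpath_distributions(visit_sequences(sim$fixations), 4,
                                  condition = "MD")
  cf <- class_frequencies(dists, scope = "full_dataset")
  m <- stats::setNames(cf$summary$mean_freq, cf$summary$class)
  expect_true(m["backwards_polling"] > m["guidance"])
  expect_true(m["guidance"] > m["forward_polling"])
  expect_true(m["speed_monitoring"] > m["right_scenery"])
})

test_that("classified_table mirrors the per-scan-path listing", {
  set.seed(2)
  dists <- lapply(1:3, function(i)
    extract_scanpaths(visits_obj(random_visits(150), participant = paste0("p", i)), 4))
  pool <- pooled_distribution(dists)
  tab <- classified_table(pool, cutoff = 0.004, condition = "MD")
  expect_true(all(tab$class %in% c(scanpath_classes(), "unclassified")))
  expect_equal(sum(tab$rel_freq_in_subset), 1, tolerance = 1e-9)
  expect_true(all(tab$rel_freq_overall >= 0.004))
})
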