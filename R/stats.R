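# Inferential battery: chi-squared goodness of fit vs uniform, chi-squared
# homogeneity between conditions, Fisher's exact fallback for small expected
# counts, and Benjamini-Hochberg correction across a per-class test family.
# Pearson statistics are computed without continuity correction.

new_test_result <- function(method, statistic, df, p_raw, expected_min,
                            estimate = NA_real_) {
  tibble::tibble(method = method, statistic = statistic, df = df,
                 p_raw = p_raw, expected_min = expected_min,
                 estimate = estimate)
}

#' Chi-squared goodness of fit against a uniform distribution
#'
#' Pearson chi-squared of k observed category counts against equal expected
#' counts, df = k - 1.
#'
#' @param counts Integer vector of category counts (k >= 2, total > 0).
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_raw`,
#'   `expected_min`.
#' @examples
#' chi2_gof_uniform(c(8, 2))  # statistic 3.6, df 1
#' @export
chi2_gof_uniform <- function(counts) {
  if (length(counts) < 2) stop("need at least 2 categories", call. = FALSE)
  if (any(is.na(counts) | counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  k <- length(counts)
  res <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / k, k), correct = FALSE))
  new_test_result("chi2_gof", unname(res$statistic), unname(res$parameter),
                  res$p.value, total / k)
}

#' Chi-squared homogeneity test for one class between two conditions
#'
#' Builds the 2x2 table {class, not class} x {condition A, condition B}
#' and computes the Pearson chi-squared without continuity correction
#' (df = 1), recording the smallest expected cell count.
#'
#' @param count_a,total_a Class count and total count under condition A.
#' @param count_b,total_b Class count and total count under condition B.
#' @return A one-row tibble as in [chi2_gof_uniform()], method
#'   `"chi2_homogeneity"`.
#' @examples
#' chi2_homogeneity(5, 50, 10, 100)  # identical proportions: statistic 0
#' @export
chi2_homogeneity <- function(count_a, total_a, count_b, total_b) {
  if (total_a <= 0 || total_b <= 0)
    stop("totals must be positive", call. = FALSE)
  if (count_a > total_a || count_b > total_b || count_a < 0 || count_b < 0)
    stop("counts must satisfy 0 <= count <= total", call. = FALSE)
  m <- rbind(A = c(count_a, total_a - count_a),
             B = c(count_b, total_b - count_b))
  if (any(colSums(m) == 0) || any(rowSums(m) == 0))
    stop("degenerate margin in the 2x2 table", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_test_result("chi2_homogeneity", unname(res$statistic),
                  unname(res$parameter), res$p.value, min(res$expected))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing hypergeometric probabilities of
#' tables as extreme as or more extreme than the observed one (fixed
#' margins). Used in place of the chi-squared homogeneity test when the
#' smallest expected count is 5 or less.
#'
#' @param table A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A one-row tibble as in [chi2_gof_uniform()], method
#'   `"fisher_exact"`; `estimate` carries the conditional odds-ratio
#'   estimate and `statistic`/`df` are `NA`.
#' @examples
#' fisher_exact_2x2(matrix(c(1, 9, 9, 1), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("`table` must be a 2x2 matrix", call. = FALSE)
  if (any(is.na(table) | table < 0))
    stop("cells must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate margin in the 2x2 table", call. = FALSE)
  res <- stats::fisher.test(table)
  exp_min <- min(outer(rowSums(table), colSums(table)) / sum(table))
  new_test_result("fisher_exact", NA_real_, NA_real_, res$p.value, exp_min,
                  estimate = unname(res$estimate))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure: the adjusted p-value of the i-th smallest raw p is
#' `min over j >= i of (m / j) * p_(j)`, capped at 1, returned in the
#' original order.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param alpha Rejection level for the returned flags, default 0.05.
#' @return A tibble: `p_raw`, `p_adj`, `rejected`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.04))
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_raw = p_values, p_adj = adj, rejected = adj <= alpha)
}

#' Compare class frequencies between two conditions
#'
#' Runs the full between-condition battery on pooled class counts: an
#' overall k-class homogeneity chi-squared (df = k - 1), then one 2x2 test
#' per class ({class, not class} x {A, B}), substituting Fisher's exact
#' test whenever the smallest expected count is 5 or less, with
#' Benjamini-Hochberg correction across the per-class family. Classes with
#' zero pooled counts in both conditions are dropped from the overall test
#' (their expected counts would be zero) but reported per class as `NA`.
#'
#' @param x_a,x_b Either `class_frequency_table` objects (their
#'   `pooled_counts` are used) or named numeric vectors of counts sharing
#'   the same names.
#' @param labels Length-2 character vector naming the two conditions.
#' @param alpha BH rejection level, default 0.05.
#' @return A list with `overall` (one-row tibble) and `per_class` (tibble:
#'   `class`, counts and proportions per condition, `method`, `statistic`,
#'   `df`, `p_raw`, `p_adj`, `significant`, `direction` = sign of the B - A
#'   proportion difference).
#' @examples
#' a <- c(x = 30, y = 70); b <- c(x = 10, y = 90)
#' compare_conditions(a, b, labels = c("MD", "HAD"))$per_class
#' @export
compare_conditions <- function(x_a, x_b, labels = c("MD", "HAD"),
                               alpha = 0.05) {
  counts_a <- if (inherits(x_a, "class_frequency_table")) x_a$pooled_counts else x_a
  counts_b <- if (inherits(x_b, "class_frequency_table")) x_b$pooled_counts else x_b
  if (!setequal(names(counts_a), names(counts_b)))
    stop("the two conditions do not share the same class set", call. = FALSE)
  counts_b <- counts_b[names(counts_a)]
  total_a <- sum(counts_a); total_b <- sum(counts_b)
  if (total_a <= 0 || total_b <= 0)
    stop("each condition needs a positive total count", call. = FALSE)

  live <- names(counts_a)[counts_a + counts_b > 0]
  m <- rbind(counts_a[live], counts_b[live])
  overall <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  overall_row <- new_test_result("chi2_homogeneity",
                                 unname(overall$statistic),
                                 unname(overall$parameter),
                                 overall$p.value, min(overall$expected))

  rows <- lapply(names(counts_a), function(cl) {
    ca <- counts_a[[cl]]; cb <- counts_b[[cl]]
    if (ca + cb == 0) {
      return(tibble::tibble(class = cl, method = NA_character_,
                            statistic = NA_real_, df = NA_real_,
                            p_raw = NA_real_, expected_min = NA_real_))
    }
    chi <- chi2_homogeneity(ca, total_a, cb, total_b)
    if (chi$expected_min <= 5) {
      tab <- rbind(c(ca, total_a - ca), c(cb, total_b - cb))
      fis <- fisher_exact_2x2(tab)
      tibble::tibble(class = cl, method = fis$method, statistic = fis$statistic,
                     df = fis$df, p_raw = fis$p_raw,
                     expected_min = chi$expected_min)
    } else {
      tibble::tibble(class = cl, method = chi$method, statistic = chi$statistic,
                     df = chi$df, p_raw = chi$p_raw,
                     expected_min = chi$expected_min)
    }
  })
  per <- do.call(rbind, rows)
  tested <- !is.na(per$p_raw)
  per$p_adj <- NA_real_; per$significant <- NA
  if (any(tested)) {
    bh <- benjamini_hochberg(per$p_raw[tested], alpha)
    per$p_adj[tested] <- bh$p_adj
    per$significant[tested] <- bh$rejected
  }
  prop_a <- counts_a / total_a; prop_b <- counts_b / total_b
  per <- tibble::tibble(
    class = per$class,
    count_a = as.numeric(counts_a), count_b = as.numeric(counts_b),
    prop_a = as.numeric(prop_a), prop_b = as.numeric(prop_b),
    method = per$method, statistic = per$statistic, df = per$df,
    expected_min = per$expected_min,
    p_raw = per$p_raw, p_adj = per$p_adj, significant = per$significant,
    direction = sign(as.numeric(prop_b) - as.numeric(prop_a)))
  names(per)[names(per) == "count_a"] <- paste0("count_", labels[1])
  names(per)[names(per) == "count_b"] <- paste0("count_", labels[2])
  names(per)[names(per) == "prop_a"] <- paste0("prop_", labels[1])
  names(per)[names(per) == "prop_b"] <- paste0("prop_", labels[2])
  list(overall = overall_row, per_class = per, labels = labels, alpha = alpha)
}
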