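# Rule-based functional taxonomy of scan paths.
#
# Length-4 rules operate on a pivot AOI in window position 2 or 3 with
# qualifying AOIs required somewhere before and somewhere after the pivot
# (existential over the window, not adjacency). Length-3 scan paths are
# classified by exact membership in a 28-triplet catalogue.

#' The 28-triplet catalogue
#'
#' The predefined back-and-forth scan paths of length three and their
#' functional class: forward polling (141, 143, 343, 341), guidance
#' (131, 313), backwards polling (121, 123, 323, 321), right scenery
#' (363, 161, 361, 163, 262, 263, 261, 362, 162), speed monitoring
#' (303, 101, 301, 103, 202) and supervision (242, 040, 402, 204).
#'
#' @return A tibble with columns `triplet` and `class` (28 rows).
#' @examples
#' table(triplet_catalogue()$class)
#' @export
triplet_catalogue <- function() {
  cat <- .triplet_catalogue_list()
  tibble::tibble(
    triplet = unlist(cat, use.names = FALSE),
    class = rep(names(cat), lengths(cat)))
}

.triplet_catalogue_list <- function() {
  list(
    forward_polling   = c("141", "143", "343", "341"),
    guidance          = c("131", "313"),
    backwards_polling = c("121", "123", "323", "321"),
    right_scenery     = c("363", "161", "361", "163", "262", "263", "261",
                          "362", "162"),
    speed_monitoring  = c("303", "101", "301", "103", "202"),
    supervision       = c("242", "040", "402", "204"))
}

#' Catalogue size and per-class sizes
#'
#' @return A list with `total` (28) and `per_class` (named integer vector
#'   of class sizes).
#' @export
catalogue_size <- function() {
  cat <- .triplet_catalogue_list()
  list(total = sum(lengths(cat)),
       per_class = vapply(cat, length, integer(1)))
}

#' Classify length-3 scan paths by catalogue membership
#'
#' Exact lookup in the 28-triplet catalogue; non-members are
#' `"unclassified"`.
#'
#' @param x Character vector of length-3 scan-path strings.
#' @return Character vector of class names.
#' @examples
#' classify_triplet(c("141", "040", "565"))
#' @export
classify_triplet <- function(x) {
  lookup <- .triplet_lookup()
  vapply(x, function(sp) {
    v <- sp_codes(sp)
    if (length(v) != 3)
      stop("classify_triplet() expects length-3 scan paths, got '", sp, "'",
           call. = FALSE)
    cl <- lookup[[sp]]
    if (is.null(cl)) "unclassified" else cl
  }, character(1), USE.NAMES = FALSE)
}

.triplet_lookup <- function() {
  cat <- .triplet_catalogue_list()
  out <- list()
  for (cl in names(cat)) for (t in cat[[cl]]) out[[t]] <- cl
  out
}

# --- length-4 rules ------------------------------------------------------

# TRUE if some pivot position p in {2,3} has value `pivot` with at least one
# code from `before` at a position < p and one from `after` at a position > p
.pivot_rule <- function(v, pivot, before, after) {
  for (p in 2:3) {
    if (v[p] == pivot &&
        any(v[seq_len(p - 1)] %in% before) &&
        any(v[(p + 1):4] %in% after)) return(TRUE)
  }
  FALSE
}

.quad_rule_fns <- list(
  # look-ahead pivot (AOI 4) framed by guiding AOIs 1/3
  forward_polling = function(v) .pivot_rule(v, 4L, c(1L, 3L), c(1L, 3L)),
  # (i) near-road pivot framed by 1/3; (ii) AOI 1 pivot framed by near road;
  # (iii) X13X / X31X framed by near road
  backwards_polling = function(v) {
    .pivot_rule(v, 2L, c(1L, 3L), c(1L, 3L)) ||
      .pivot_rule(v, 1L, 2L, 2L) ||
      ((identical(v[2:3], c(1L, 3L)) || identical(v[2:3], c(3L, 1L))) &&
         v[1] == 2L && v[4] == 2L)
  },
  # guiding pivot (AOI 1 or 3) framed by further guiding fixations
  guidance = function(v) {
    .pivot_rule(v, 1L, c(1L, 3L), c(1L, 3L)) ||
      .pivot_rule(v, 3L, c(1L, 3L), c(1L, 3L))
  },
  # right-scenery pivot framed by AOI 1 or 2
  right_scenery = function(v) .pivot_rule(v, 6L, c(1L, 2L), c(1L, 2L)),
  # (i) speedometer pivot framed by AOIs 1/2/3; (ii) 0XX0 with 1/2/3 inside
  speed_monitoring = function(v) {
    .pivot_rule(v, 0L, c(1L, 2L, 3L), c(1L, 2L, 3L)) ||
      (v[1] == 0L && v[4] == 0L && all(v[2:3] %in% c(1L, 2L, 3L)))
  })

#' Default rule precedence for length-4 classification
#'
#' When several rule sets fire for the same scan path, the first class in
#' this order wins. The road-structure classes outrank the auxiliary-AOI
#' classes; forward polling outranks guidance.
#'
#' @return Character vector of the five rule-based classes in precedence
#'   order.
#' @export
default_precedence <- function() {
  c("forward_polling", "backwards_polling", "guidance",
    "right_scenery", "speed_monitoring")
}

#' Classify length-4 scan paths by positional rules
#'
#' Applies the five rule sets in precedence order. A scan path matching no
#' rule is `"unclassified"` under manual driving (MD) and `"supervision"`
#' under highly automated driving (HAD), where the residual class captures
#' automation-monitoring sequences.
#'
#' @param x Character vector of length-4 scan-path strings.
#' @param condition `"MD"` or `"HAD"`; gates the supervision residual.
#' @param precedence Order in which rules are evaluated; must be a
#'   permutation of [default_precedence()].
#' @return Character vector of class names.
#' @examples
#' classify_quad(c("1414", "1212", "1313", "0120"), "MD")
#' classify_quad("2424", "HAD")
#' @export
classify_quad <- function(x, condition = c("MD", "HAD"),
                          precedence = default_precedence()) {
  condition <- match.arg(condition)
  if (!setequal(precedence, default_precedence()))
    stop("`precedence` must be a permutation of default_precedence()",
         call. = FALSE)
  residual <- if (condition == "HAD") "supervision" else "unclassified"
  vapply(x, function(sp) {
    v <- sp_codes(sp)
    if (length(v) != 4)
      stop("classify_quad() expects length-4 scan paths, got '", sp, "'",
           call. = FALSE)
    for (cl in precedence) if (.quad_rule_fns[[cl]](v)) return(cl)
    residual
  }, character(1), USE.NAMES = FALSE)
}

#' Audit catalogue/rule consistency
#'
#' Embeds each catalogue triplet as the middle of every compatible length-4
#' window (one extra AOI prepended or appended, respecting the no-repeat
#' invariant) and checks whether [classify_quad()] assigns the same class.
#' Known exceptions exist: the length-4 right-scenery rule admits only
#' AOIs 1/2 around the pivot while the catalogue lists AOI-3 partners, and
#' the supervision triplets 402/204 contain a 0-2 adjacency that fires the
#' speed rule. Exceptions are reported, not hidden.
#'
#' @param condition Condition under which to classify, default `"HAD"` so
#'   the supervision residual is reachable.
#' @return A tibble: `triplet`, `class`, `embedding`, `quad_class`,
#'   `consistent`.
#' @export
audit_catalogue_consistency <- function(condition = "HAD") {
  cat <- triplet_catalogue()
  rows <- list()
  for (i in seq_len(nrow(cat))) {
    t <- cat$triplet[i]; cl <- cat$class[i]
    v <- sp_codes(t)
    pre <- setdiff(aoi_codes(), v[1])
    post <- setdiff(aoi_codes(), v[3])
    embeds <- c(paste0(pre, t), paste0(t, post))
    qc <- classify_quad(embeds, condition = condition)
    rows[[i]] <- tibble::tibble(triplet = t, class = cl, embedding = embeds,
                                quad_class = qc, consistent = qc == cl)
  }
  do.call(rbind, rows)
}

# --- class frequency aggregation ----------------------------------------

#' Class frequencies per participant, then averaged
#'
#' Classifies the scan paths of each participant's distribution and
#' aggregates class relative frequencies over classified occurrences
#' (unclassified windows are excluded from the denominator). Frequencies
#' are computed participant per participant and then averaged, so each
#' participant contributes equally; pooled class counts are returned
#' alongside for chi-squared use.
#'
#' For length-4 distributions the default scope is the analysis of the
#' frequent subset (types at or above `cutoff` pooled relative frequency);
#' `scope = "full_dataset"` classifies every window, with the supervision
#' residual still gated on frequent-subset membership (the residual class
#' is defined among the frequent types; ungated it would absorb arbitrary
#' rare junction patterns). Length-3 distributions are always classified
#' against the 28-triplet catalogue over the full dataset.
#'
#' @param dists List of `scanpath_distribution` objects, one condition,
#'   one length (3 or 4).
#' @param scope `"frequent_subset"` or `"full_dataset"` (length 4 only).
#' @param subset Optional character vector of frequent scan-path types; if
#'   `NULL` it is derived from the pooled distribution with `cutoff`.
#' @param cutoff Relative-frequency cutoff used when `subset` is `NULL`.
#' @param precedence Rule precedence passed to [classify_quad()].
#' @return A `class_frequency_table`: list with `condition`, `length`,
#'   `scope`, `per_participant` (tibble: participant, class, freq),
#'   `summary` (tibble: class, mean_freq, se, n_participants),
#'   `pooled_counts` (named numeric, all six classes) and `excluded`
#'   (participants with no classified scan path, dropped with a warning).
#' @examples
#' sim <- simulate_fixations(generator_config(n_participants = 2, seed = 1))
#' seqs <- visit_sequences(sim$fixations)
#' dists <- scanpath_distributions(seqs, 4, condition = "MD")
#' class_frequencies(dists)$summary
#' @export
class_frequencies <- function(dists,
                              scope = c("frequent_subset", "full_dataset"),
                              subset = NULL, cutoff = 0.004,
                              precedence = default_precedence()) {
  scope <- match.arg(scope)
  lens <- unique(vapply(dists, `[[`, integer(1), "length"))
  conds <- unique(vapply(dists, `[[`, character(1), "condition"))
  if (length(lens) != 1 || length(conds) != 1)
    stop("`dists` must share one condition and one scan-path length",
         call. = FALSE)
  if (!lens %in% c(3L, 4L))
    stop("class frequencies are defined for scan-path lengths 3 and 4",
         call. = FALSE)
  classes <- scanpath_classes()

  if (lens == 4L && is.null(subset)) {
    pool <- pooled_distribution(dists)
    subset <- if (nrow(pool)) frequent_subset(pool, cutoff)$scanpaths else character(0)
  }

  # classify each distinct type once
  types <- unique(unlist(lapply(dists, function(d) names(d$counts))))
  if (is.null(types)) types <- character(0)
  if (lens == 3L) {
    type_class <- stats::setNames(classify_triplet(types), types)
  } else {
    type_class <- stats::setNames(
      classify_quad(types, condition = if (conds == "HAD") "HAD" else "MD",
                    precedence = precedence), types)
    # the supervision residual is defined among the frequent types
    type_class[type_class == "supervision" & !(types %in% subset)] <- "unclassified"
  }

  per_rows <- list(); pooled <- stats::setNames(numeric(length(classes)), classes)
  excluded <- character(0)
  for (d in dists) {
    counts <- d$counts
    if (lens == 4L && scope == "frequent_subset")
      counts <- counts[names(counts) %in% subset]
    cls <- type_class[names(counts)]
    keep <- !is.na(cls) & cls != "unclassified"
    class_counts <- tapply(as.numeric(counts[keep]),
                           factor(cls[keep], levels = classes), sum)
    class_counts[is.na(class_counts)] <- 0
    tot <- sum(class_counts)
    pooled <- pooled + class_counts
    if (tot == 0) {
      excluded <- c(excluded, d$participant)
      next
    }
    per_rows[[length(per_rows) + 1L]] <- tibble::tibble(
      participant = d$participant, class = classes,
      freq = as.numeric(class_counts) / tot)
  }
  if (length(excluded))
    warning("participant(s) excluded from class frequencies (no classified ",
            "scan path): ", paste(excluded, collapse = ", "), call. = FALSE)
  if (!length(per_rows))
    stop("no participant has any classified scan path", call. = FALSE)
  per <- do.call(rbind, per_rows)
  n <- length(unique(per$participant))
  m <- tapply(per$freq, factor(per$class, levels = classes), mean)
  s <- tapply(per$freq, factor(per$class, levels = classes), stats::sd)
  summ <- tibble::tibble(class = classes, mean_freq = as.numeric(m),
                         se = if (n > 1) as.numeric(s) / sqrt(n) else NA_real_,
                         n_participants = n)
  structure(list(condition = conds, length = lens, scope = scope,
                 per_participant = per, summary = summ,
                 pooled_counts = pooled, excluded = excluded),
            class = "class_frequency_table")
}

#' @export
print.class_frequency_table <- function(x, ...) {
  cat("<class_frequency_table>", x$condition, "| L =", x$length,
      "| scope =", x$scope, "\n")
  print(x$summary)
  invisible(x)
}

#' Classified scan-path table for a condition
#'
#' Convenience table mirroring the per-scan-path classification listings:
#' each frequent scan path with its class, relative frequency in the entire
#' dataset and within the analysed subset.
#'
#' @param pool Pooled distribution from [pooled_distribution()] (length 4).
#' @param cutoff Relative-frequency cutoff for the analysed subset.
#' @param condition `"MD"` or `"HAD"`.
#' @param precedence Rule precedence passed to [classify_quad()].
#' @return A tibble: `scanpath`, `class`, `rel_freq_overall`,
#'   `rel_freq_in_subset`.
#' @export
classified_table <- function(pool, cutoff = 0.004, condition = c("MD", "HAD"),
                             precedence = default_precedence()) {
  condition <- match.arg(condition)
  sub <- frequent_subset(pool, cutoff)$table
  tibble::tibble(
    scanpath = sub$scanpath,
    class = classify_quad(sub$scanpath, condition, precedence),
    rel_freq_overall = sub$rel_freq,
    rel_freq_in_subset = sub$rel_freq / sum(sub$rel_freq))
}
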