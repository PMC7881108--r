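#' Number of scan-path permutations without immediate repeats
#'
#' The theoretical number of distinct scan paths of a given length over a
#' set of AOIs, counting sequences with no two adjacent equal codes:
#' `n_aois * (n_aois - 1)^(length - 1)`. With 7 AOIs this gives 42 at
#' length 2 and 1,959,552 at length 8.
#'
#' @param n_aois Number of AOIs (>= 1).
#' @param length Scan-path length (>= 2).
#' @return The permutation count as a double (counts grow fast).
#' @examples
#' count_permutations(7, 2)  # 42
#' count_permutations(7, 8)  # 1959552
#' @export
count_permutations <- function(n_aois, length) {
  stopifnot_scalar_count(n_aois, "n_aois", min = 1)
  stopifnot_scalar_count(length, "length", min = 2)
  n_aois * (n_aois - 1)^(length - 1)
}

#' Extract sliding-window scan paths from a visit sequence
#'
#' A scan path of length L is any window of L consecutive AOI visits; every
#' start position is used, so a sequence of N visits yields
#' `max(0, N - L + 1)` windows. Scan-path identity is the ordered tuple,
#' written as the digit string (e.g. `"1214"`).
#'
#' @param seq An `aoi_visits` object.
#' @param length Scan-path length L (>= 2), default 4.
#' @return A `scanpath_distribution`: list with `participant`, `condition`,
#'   `length`, `counts` (named integer vector, scan-path string -> count,
#'   sorted by decreasing count then string) and `total_windows`.
#' @examples
#' v <- structure(list(participant = "p", condition = "MD",
#'                     visits = c(1L, 2L, 1L, 3L)), class = "aoi_visits")
#' extract_scanpaths(v, 2)$counts
#' @export
extract_scanpaths <- function(seq, length = 4) {
  stopifnot_scalar_count(length, "length", min = 2)
  v <- seq$visits
  n <- base::length(v)
  total <- max(0L, n - length + 1L)
  if (total == 0L) {
    counts <- integer(0)
  } else {
    idx <- vapply(seq_len(total), function(i)
      paste(v[i:(i + length - 1L)], collapse = ""), character(1))
    tab <- table(idx)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    ord <- order(-counts, names(counts))
    counts <- counts[ord]
  }
  structure(list(participant = seq$participant, condition = seq$condition,
                 length = as.integer(length), counts = counts,
                 total_windows = as.integer(total)),
            class = "scanpath_distribution")
}

#' @export
print.scanpath_distribution <- function(x, ...) {
  cat("<scanpath_distribution> participant", x$participant, "|", x$condition,
      "| L =", x$length, "|", x$total_windows, "windows,",
      length(x$counts), "types\n")
  print(utils::head(x$counts, 10))
  invisible(x)
}

#' Scan-path distributions for a set of visit sequences
#'
#' @param seqs List of `aoi_visits` objects.
#' @param length Scan-path length, default 4.
#' @param condition Optional condition label to keep only matching sequences.
#' @return List of `scanpath_distribution` objects.
#' @export
scanpath_distributions <- function(seqs, length = 4, condition = NULL) {
  if (!is.null(condition)) {
    seqs <- Filter(function(s) identical(s$condition, condition), seqs)
    if (!length(seqs)) stop("no sequences for condition ", condition, call. = FALSE)
  }
  lapply(seqs, extract_scanpaths, length = length)
}

#' Pool per-participant scan-path distributions within a condition
#'
#' Sums counts across participants and derives relative and cumulative
#' relative frequencies, with scan-path types sorted by decreasing
#' frequency (ties broken by the scan-path string so the ordering is
#' deterministic).
#'
#' @param dists List of `scanpath_distribution` objects of the same
#'   condition and length.
#' @return A tibble with columns `rank`, `scanpath`, `count`, `rel_freq`,
#'   `cum_rel_freq`, and attributes `condition`, `length`,
#'   `total_windows`.
#' @export
pooled_distribution <- function(dists) {
  if (!length(dists)) stop("no distributions supplied", call. = FALSE)
  lens <- unique(vapply(dists, `[[`, integer(1), "length"))
  if (length(lens) != 1)
    stop("distributions mix scan-path lengths: ",
         paste(lens, collapse = ", "), call. = FALSE)
  conds <- unique(vapply(dists, `[[`, character(1), "condition"))
  if (length(conds) != 1)
    stop("distributions mix conditions: ",
         paste(conds, collapse = ", "), call. = FALSE)
  all_counts <- unlist(lapply(dists, `[[`, "counts"))
  if (is.null(all_counts) || !length(all_counts)) {
    out <- tibble::tibble(rank = integer(0), scanpath = character(0),
                          count = integer(0), rel_freq = numeric(0),
                          cum_rel_freq = numeric(0))
  } else {
    agg <- tapply(all_counts, names(all_counts), sum)
    counts <- as.integer(agg)
    names(counts) <- names(agg)
    ord <- order(-counts, names(counts))
    counts <- counts[ord]
    total <- sum(counts)
    rel <- counts / total
    out <- tibble::tibble(rank = seq_along(counts),
                          scanpath = names(counts),
                          count = counts,
                          rel_freq = as.numeric(rel),
                          cum_rel_freq = cumsum(as.numeric(rel)))
  }
  attr(out, "condition") <- conds
  attr(out, "length") <- lens
  attr(out, "total_windows") <- sum(vapply(dists, `[[`, integer(1), "total_windows"))
  out
}

#' Most frequent scan paths above a relative-frequency cutoff
#'
#' Selects the scan-path types whose pooled relative frequency is at least
#' `cutoff` (inclusive; a type at exactly the cutoff is retained). The
#' default 0.004 (0.4%) is the threshold separating stereotyped sequences
#' from the long tail of rare ones.
#'
#' @param pool A pooled distribution from [pooled_distribution()].
#' @param cutoff Relative-frequency cutoff, strictly between 0 and 1.
#' @return A list with `scanpaths` (character vector, sorted by decreasing
#'   frequency), `coverage` (their summed relative frequency) and `table`
#'   (the corresponding rows of `pool`).
#' @export
frequent_subset <- function(pool, cutoff = 0.004) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
      cutoff <= 0 || cutoff >= 1)
    stop("`cutoff` must be a single number strictly between 0 and 1",
         call. = FALSE)
  if (!nrow(pool)) stop("empty scan-path distribution", call. = FALSE)
  keep <- pool$rel_freq >= cutoff
  sub <- pool[keep, , drop = FALSE]
  list(scanpaths = sub$scanpath,
       coverage = sum(sub$rel_freq),
       table = sub)
}

#' Observed vs theoretical scan-path diversity by length
#'
#' For each scan-path length, counts the distinct scan-path types pooled
#' across participants within each condition and relates them to the
#' theoretical permutation count [count_permutations()]. The elbow of the
#' resulting curve guides the choice of scan-path length.
#'
#' @param seqs List of `aoi_visits` objects.
#' @param lengths Integer vector of lengths, default `2:8`.
#' @param n_aois Number of AOIs for the theoretical count, default 7.
#' @return A tibble: `condition`, `length`, `observed_distinct`,
#'   `theoretical`, `percent_observed`.
#' @seealso [suggest_elbow()]
#' @export
length_selection_curve <- function(seqs, lengths = 2:8, n_aois = 7) {
  conds <- sort(unique(vapply(seqs, `[[`, character(1), "condition")))
  rows <- list()
  for (cc in conds) {
    sub <- Filter(function(s) identical(s$condition, cc), seqs)
    for (L in lengths) {
      types <- unique(unlist(lapply(sub, function(s) {
        d <- extract_scanpaths(s, L)
        names(d$counts)
      })))
      theo <- count_permutations(n_aois, L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cc, length = as.integer(L),
        observed_distinct = length(types),
        theoretical = theo,
        percent_observed = 100 * length(types) / theo)
    }
  }
  do.call(rbind, rows)
}

#' Advisory elbow suggestion for the length-selection curve
#'
#' A second-difference knee heuristic on the log10 percent-observed curve.
#' The elbow in the original analysis is a visual judgment; this heuristic
#' is advisory only and the scan-path length remains a user parameter
#' (default 4 throughout the package).
#'
#' @param curve Output of [length_selection_curve()] for one condition (or
#'   pooled; if several conditions are present the per-condition suggestions
#'   are returned).
#' @return A tibble: `condition`, `elbow_length`.
#' @export
suggest_elbow <- function(curve) {
  conds <- unique(curve$condition)
  rows <- lapply(conds, function(cc) {
    sub <- curve[curve$condition == cc, , drop = FALSE]
    sub <- sub[order(sub$length), , drop = FALSE]
    y <- log10(pmax(sub$percent_observed, .Machine$double.eps))
    if (nrow(sub) < 3) return(tibble::tibble(condition = cc, elbow_length = NA_integer_))
    d2 <- diff(y, differences = 2)
    tibble::tibble(condition = cc,
                   elbow_length = sub$length[which.max(abs(d2)) + 1L])
  })
  do.call(rbind, rows)
}

#' Composition of length-4 scan paths by number of distinct AOIs
#'
#' @param types Character vector of length-4 scan-path strings.
#' @return A tibble with `n_distinct` (2, 3, 4) and `proportion` (summing
#'   to 1 over the supplied set).
#' @examples
#' composition_profile(c("1212", "1213", "1234"))
#' @export
composition_profile <- function(types) {
  if (!length(types)) stop("no scan-path types supplied", call. = FALSE)
  nd <- vapply(types, function(x) {
    v <- sp_codes(x)
    if (length(v) != 4)
      stop("composition_profile() expects length-4 scan paths, got '",
           x, "'", call. = FALSE)
    length(unique(v))
  }, integer(1))
  tab <- table(factor(nd, levels = 2:4))
  tibble::tibble(n_distinct = 2:4,
                 proportion = as.numeric(tab) / length(types))
}

#' Scan-path totals and singletons for one participant
#'
#' @param dist A `scanpath_distribution`.
#' @return A list with `total` (number of scan paths, i.e. windows) and
#'   `singletons` (number of types occurring exactly once).
#' @export
participant_totals <- function(dist) {
  list(total = dist$total_windows,
       singletons = sum(dist$counts == 1L))
}

#' Per-condition summary of scan-path totals and singletons
#'
#' Mean and standard deviation, across participants, of the total number of
#' scan paths performed and of the number of scan-path types appearing only
#' once.
#'
#' @param dists List of `scanpath_distribution` objects (may mix conditions).
#' @return A tibble: `condition`, `n_participants`, `mean_total`, `sd_total`,
#'   `mean_singletons`, `sd_singletons`.
#' @export
totals_summary <- function(dists) {
  conds <- sort(unique(vapply(dists, `[[`, character(1), "condition")))
  rows <- lapply(conds, function(cc) {
    sub <- Filter(function(d) identical(d$condition, cc), dists)
    tot <- vapply(sub, function(d) participant_totals(d)$total, numeric(1))
    sing <- vapply(sub, function(d) participant_totals(d)$singletons, numeric(1))
    tibble::tibble(condition = cc, n_participants = length(sub),
                   mean_total = mean(tot), sd_total = stats::sd(tot),
                   mean_singletons = mean(sing), sd_singletons = stats::sd(sing))
  })
  do.call(rbind, rows)
}
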