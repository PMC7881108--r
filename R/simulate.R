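# Seeded synthetic fixation-event generator.
#
# Visit sequences are built as a mixture of functional gaze strategies:
# a class is sampled from the condition's mixture, then a *bout* of
# back-and-forth catalogue motifs of that class is emitted (consecutive
# motifs overlap on the shared visit), with unstructured noise visits
# interleaved at the configured rate. Visits are then expanded into 1-3
# fixation records with log-normal durations, including a sub-80 ms
# contamination fraction so the minimum-duration filter has work to do.

# Motifs the generator plants, per class. These are the catalogue triplets
# that the length-4 rules classify back into their own class when chained;
# the scenery triplets with AOI-3 partners and the supervision triplets
# with a 0-2 adjacency are excluded from *emission* (they would classify
# elsewhere or not at all at length 4) but remain in the classification
# catalogue.
.emission_pools <- function() {
  list(
    forward_polling   = c("141", "143", "343", "341"),
    guidance          = c("131", "313"),
    backwards_polling = c("121", "123", "323", "321"),
    right_scenery     = c("161", "162", "261", "262"),
    speed_monitoring  = c("303", "101", "301", "103", "202"),
    supervision       = c("242", "040"))
}

#' Configuration for the synthetic fixation generator
#'
#' Defaults describe the emulated study: 16 participants observed under
#' manual driving (MD) and highly automated driving (HAD), with class
#' mixtures matching the reported class frequencies per condition, a mean
#' of about 103 AOI visits per participant and condition (negative-binomial
#' dispersion chosen so the between-participant spread matches the reported
#' +/- 49 scan paths), a 15% rate of unstructured noise visits, and
#' log-normal fixation durations with a 5% sub-80 ms contamination
#' fraction. Left scenery (AOI 5) appears only as noise.
#'
#' @param n_participants Number of participants (default 16).
#' @param conditions Condition labels (default `c("MD", "HAD")`).
#' @param class_mixture Named list (one element per condition) of named
#'   class probability vectors over [scanpath_classes()]; each must sum to
#'   at most 1 (up to rounding tolerance 1e-3); any remainder behaves as
#'   additional noise.
#' @param noise_rate Probability of inserting an unstructured AOI visit
#'   after each emitted motif (default 0.15); noise AOIs are uniform over
#'   0-6 minus the previous visit.
#' @param visits_mean,visits_dispersion Negative-binomial mean and size for
#'   the number of AOI visits per participant and condition (defaults 103
#'   and 5).
#' @param bout_mean Mean number of motifs per class bout (geometric,
#'   default 4); gaze strategies persist over several back-and-forths
#'   rather than single triplets.
#' @param duration_meanlog,duration_sdlog Log-normal parameters for
#'   fixation durations in ms (defaults log(250) and 0.45), floored at
#'   80 ms before contamination.
#' @param sub80_rate Fraction of fixations replaced by a sub-80 ms duration
#'   (uniform 30-79 ms, default 0.05); each visit keeps at least one
#'   fixation at or above 80 ms so the planted visit structure survives
#'   filtering.
#' @param mode `"motif"` (default) or `"markov"`, a structureless
#'   first-order baseline (uniform transitions without immediate repeats)
#'   for null comparisons.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_participants = 16,
                             conditions = c("MD", "HAD"),
                             class_mixture = default_class_mixture(),
                             noise_rate = 0.15,
                             visits_mean = 103,
                             visits_dispersion = 5,
                             bout_mean = 4,
                             duration_meanlog = log(250),
                             duration_sdlog = 0.45,
                             sub80_rate = 0.05,
                             mode = c("motif", "markov"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot_scalar_count(n_participants, "n_participants")
  if (!is.character(conditions) || !length(conditions))
    stop("`conditions` must be a character vector", call. = FALSE)
  if (!all(conditions %in% names(class_mixture)))
    stop("`class_mixture` must have one entry per condition", call. = FALSE)
  for (cc in conditions) {
    mx <- class_mixture[[cc]]
    if (!all(names(mx) %in% scanpath_classes()))
      stop("unknown class in mixture for ", cc, call. = FALSE)
    if (any(mx < 0) || any(mx > 1))
      stop("mixture probabilities must lie in [0, 1]", call. = FALSE)
    if (sum(mx) > 1 + 1e-3)
      stop("mixture for ", cc, " sums to ", round(sum(mx), 4), " > 1",
           call. = FALSE)
  }
  if (noise_rate < 0 || noise_rate >= 1)
    stop("`noise_rate` must lie in [0, 1)", call. = FALSE)
  if (sub80_rate < 0 || sub80_rate >= 1)
    stop("`sub80_rate` must lie in [0, 1)", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 conditions = conditions, class_mixture = class_mixture,
                 noise_rate = noise_rate, visits_mean = visits_mean,
                 visits_dispersion = visits_dispersion, bout_mean = bout_mean,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog, sub80_rate = sub80_rate,
                 mode = mode, seed = as.integer(seed)),
            class = "generator_config")
}

#' Default class mixtures per condition
#'
#' The per-class scan-path shares observed under manual and highly
#' automated driving: MD — forward polling 11.75%, guidance 18.85%,
#' backwards polling 48.58%, right scenery 3.96%, speed monitoring 16.85%,
#' supervision 0; HAD — 14.61%, 34.23%, 28.69%, 7.25%, 8.40%, 6.83%.
#' (The HAD percentages sum to 100.01 by rounding; the generator
#' normalises internally.)
#'
#' @return Named list with elements `MD` and `HAD`.
#' @export
default_class_mixture <- function() {
  list(
    MD = c(forward_polling = 0.1175, guidance = 0.1885,
           backwards_polling = 0.4858, right_scenery = 0.0396,
           speed_monitoring = 0.1685, supervision = 0),
    HAD = c(forward_polling = 0.1461, guidance = 0.3423,
            backwards_polling = 0.2869, right_scenery = 0.0725,
            speed_monitoring = 0.0840, supervision = 0.0683))
}

# sample one motif of `cls`, preferring motifs that overlap-chain on `start`
.sample_motif <- function(cls, start = NULL) {
  pool <- .emission_pools()[[cls]]
  if (!is.null(start)) {
    cand <- pool[substr(pool, 1, 1) == as.character(start)]
    if (length(cand)) {
      m <- sp_codes(sample(cand, 1))
      return(m[-1])                       # first visit already emitted
    }
  }
  m <- sp_codes(sample(pool, 1))
  if (!is.null(start) && m[1] == start) m <- m[-1]
  m
}

# one participant-condition visit sequence + planted-class ledger
.generate_visits <- function(n_target, mixture, config) {
  classes <- names(mixture)
  planted <- stats::setNames(numeric(length(classes) + 1),
                             c(classes, "noise"))
  s <- integer(0)
  if (config$mode == "markov") {
    s <- integer(n_target)
    s[1] <- sample(aoi_codes(), 1)
    for (i in seq_len(n_target - 1))
      s[i + 1] <- sample(setdiff(aoi_codes(), s[i]), 1)
    planted["noise"] <- n_target
    return(list(visits = s, planted = planted))
  }
  psum <- sum(mixture)
  while (length(s) < n_target) {
    u <- stats::runif(1)
    if (u > psum) {                       # mixture remainder behaves as noise
      last <- if (length(s)) s[length(s)] else -1L
      s <- c(s, sample(setdiff(aoi_codes(), last), 1))
      planted["noise"] <- planted["noise"] + 1
      next
    }
    cls <- classes[findInterval(u, cumsum(mixture), left.open = TRUE) + 1L]
    n_motifs <- 1L + stats::rgeom(1, 1 / config$bout_mean)
    n0 <- length(s)
    for (k in seq_len(n_motifs)) {
      last <- if (length(s)) s[length(s)] else NULL
      s <- c(s, .sample_motif(cls, start = last))
      if (stats::runif(1) < config$noise_rate) {
        v <- sample(setdiff(aoi_codes(), s[length(s)]), 1)
        s <- c(s, v)
        planted["noise"] <- planted["noise"] + 1
        planted[cls] <- planted[cls] - 1   # noise visit is not class mass
      }
    }
    planted[cls] <- planted[cls] + (length(s) - n0)
  }
  list(visits = s, planted = planted)
}

# expand a visit sequence into fixation records
.expand_fixations <- function(visits, participant, condition, config) {
  n_fix <- sample(1:3, length(visits), replace = TRUE, prob = c(0.6, 0.3, 0.1))
  total <- sum(n_fix)
  dur <- pmax(80, stats::rlnorm(total, config$duration_meanlog,
                                config$duration_sdlog))
  contam <- stats::runif(total) < config$sub80_rate
  # each visit keeps at least one fixation >= 80 ms
  first_of_visit <- cumsum(c(1, n_fix[-length(n_fix)]))
  all_contam <- vapply(seq_along(visits), function(i) {
    idx <- first_of_visit[i] + seq_len(n_fix[i]) - 1L
    all(contam[idx])
  }, logical(1))
  contam[first_of_visit[all_contam]] <- FALSE
  dur[contam] <- stats::runif(sum(contam), 30, 79)
  dur <- round(dur)
  gaps <- round(stats::runif(total, 20, 80))
  onset <- cumsum(c(0, (dur + gaps)[-total]))
  tibble::tibble(participant = participant, condition = condition,
                 onset_ms = onset, duration_ms = dur,
                 aoi = rep(visits, n_fix))
}

#' Generate a synthetic fixation-event table
#'
#' Produces, for every participant and condition, an AOI visit sequence
#' planted with class motifs per the configured mixture, expands it into
#' fixation records, and returns the table together with a ground-truth
#' ledger of the planted class mass. Deterministic for a fixed config
#' (including its seed).
#'
#' @param config A [generator_config()].
#' @return A `scanpath_simulation`: list with `fixations` (tibble in the
#'   [read_fixations()] dialect), `ledger` (tibble: participant, condition,
#'   class, visits — planted visit counts, with `"noise"` as an extra row
#'   per stream) and `config`.
#' @examples
#' sim <- simulate_fixations(generator_config(n_participants = 2, seed = 7))
#' head(sim$fixations)
#' ledger_mixture(sim, "MD")
#' @export
simulate_fixations <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop("`config` must come from generator_config()", call. = FALSE)
  withr::with_seed(config$seed, {
    fix_rows <- list(); led_rows <- list()
    ids <- sprintf("P%02d", seq_len(config$n_participants))
    for (pid in ids) for (cc in config$conditions) {
      mixture <- config$class_mixture[[cc]]
      mixture <- mixture / max(1, sum(mixture))  # absorb rounding above 1
      n_target <- max(20L, stats::rnbinom(1, mu = config$visits_mean,
                                          size = config$visits_dispersion))
      g <- .generate_visits(n_target, mixture, config)
      fix_rows[[length(fix_rows) + 1L]] <-
        .expand_fixations(g$visits, pid, cc, config)
      led_rows[[length(led_rows) + 1L]] <- tibble::tibble(
        participant = pid, condition = cc,
        class = names(g$planted), visits = as.numeric(g$planted))
    }
    structure(list(fixations = validate_fixations(do.call(rbind, fix_rows)),
                   ledger = do.call(rbind, led_rows),
                   config = config),
              class = "scanpath_simulation")
  })
}

#' @export
print.scanpath_simulation <- function(x, ...) {
  cat("<scanpath_simulation>", x$config$n_participants, "participants x",
      length(x$config$conditions), "conditions |",
      nrow(x$fixations), "fixations | seed", x$config$seed, "\n")
  invisible(x)
}

#' Realized planted class mixture from the ledger
#'
#' The share of planted visits per class actually emitted for a condition
#' (noise excluded), i.e. the ground truth against which pipeline-recovered
#' class frequencies are compared.
#'
#' @param sim A `scanpath_simulation`.
#' @param condition Condition label.
#' @return Named numeric vector over [scanpath_classes()], summing to 1.
#' @export
ledger_mixture <- function(sim, condition) {
  led <- sim$ledger
  led <- led[led$condition == condition & led$class != "noise", , drop = FALSE]
  agg <- tapply(led$visits, factor(led$class, levels = scanpath_classes()), sum)
  agg[is.na(agg)] <- 0
  agg / sum(agg)
}

#' A tiny hand-verifiable worked example
#'
#' One manual-driving participant with 27 fixations whose every pipeline
#' stage was verified by hand: three sub-80 ms fixations that the duration
#' filter removes (one of which would otherwise create a spurious left
#' scenery visit and one a spurious far-road visit), 13 AOI visits after
#' collapsing, and ten length-4 windows covering all five manual-driving
#' classes. The same data and expected values ship as plain-text files
#' under `inst/extdata` (`worked_example_fixations.csv`,
#' `worked_example_expected.json`).
#'
#' @return A list with `fixations` (tibble) and `expected` (list:
#'   `visits`, `quad_windows`, `quad_classes`, `triplet_windows`,
#'   `triplet_classes`, `total_windows`, `singletons`).
#' @export
make_worked_example <- function() {
  aoi <- c(1, 1, 4, 4, 5, 1, 2, 2, 1, 1, 2, 2, 6, 6,
           2, 0, 0, 0, 1, 1, 3, 4, 1, 1, 3, 3, 3)
  dur <- c(250, 180, 300, 150, 60, 220, 150, 90, 400, 130, 200, 120, 90, 110,
           310, 100, 75, 95, 260, 140, 190, 70, 210, 85, 330, 150, 95)
  onset <- cumsum(c(0, (dur + 40)[-length(dur)]))
  fixations <- tibble::tibble(participant = "P01", condition = "MD",
                              onset_ms = onset, duration_ms = dur,
                              aoi = as.integer(aoi))
  expected <- list(
    visits = c(1L, 4L, 1L, 2L, 1L, 2L, 6L, 2L, 0L, 1L, 3L, 1L, 3L),
    quad_windows = c("1412", "4121", "1212", "2126", "1262",
                     "2620", "6201", "2013", "0131", "1313"),
    quad_classes = c("forward_polling", "backwards_polling",
                     "backwards_polling", "backwards_polling",
                     "right_scenery", "right_scenery",
                     "speed_monitoring", "speed_monitoring",
                     "guidance", "guidance"),
    triplet_windows = c("141", "412", "121", "212", "126", "262",
                        "620", "201", "013", "131", "313"),
    triplet_classes = c("forward_polling", "unclassified",
                        "backwards_polling", "unclassified", "unclassified",
                        "right_scenery", "unclassified", "unclassified",
                        "unclassified", "guidance", "guidance"),
    total_windows = 10L,
    singletons = 10L)
  list(fixations = fixations, expected = expected)
}
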