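#' Read a fixation event table
#'
#' Reads a CSV of fixation events with columns `participant`, `condition`,
#' `onset_ms`, `duration_ms` and `aoi` (comma-separated, UTF-8, header
#' mandatory, `.` decimal separator). Records are validated (AOI codes in
#' 0-6, positive durations, no overlapping fixations within a
#' participant-condition stream) and returned sorted by participant,
#' condition and onset.
#'
#' @param path Path to the CSV file.
#' @return A tibble of fixation records with the five columns above,
#'   `participant` and `condition` as character, `aoi` as integer.
#' @seealso [filter_min_duration()], [collapse_to_visits()]
#' @examples
#' csv <- system.file("extdata", "worked_example_fixations.csv",
#'                    package = "scanpathr")
#' fix <- read_fixations(csv)
#' head(fix)
#' @export
read_fixations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_fixations(df)
}

#' Validate a fixation event table
#'
#' Checks the column contract used throughout the package and sorts the
#' records. Called by [read_fixations()]; exported so tables built in
#' memory (e.g. by [simulate_fixations()]) can be checked the same way.
#'
#' @param df A data frame with columns `participant`, `condition`,
#'   `onset_ms`, `duration_ms`, `aoi`.
#' @return A validated tibble sorted by participant, condition and onset.
#' @export
validate_fixations <- function(df) {
  required <- c("participant", "condition", "onset_ms", "duration_ms", "aoi")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("fixation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[required]
  if (nrow(df) == 0) {
    df$participant <- character(0); df$condition <- character(0)
    return(tibble::as_tibble(df))
  }
  df$participant <- as.character(df$participant)
  df$condition <- as.character(df$condition)

  bad_aoi <- which(is.na(df$aoi) | !(df$aoi %in% aoi_codes()) |
                     df$aoi != round(df$aoi))
  if (length(bad_aoi))
    stop("invalid AOI code (must be an integer 0-6) in row(s): ",
         paste(utils::head(bad_aoi, 5), collapse = ", "), call. = FALSE)
  df$aoi <- as.integer(df$aoi)

  bad_dur <- which(is.na(df$duration_ms) | df$duration_ms <= 0)
  if (length(bad_dur))
    stop("non-positive fixation duration in row(s): ",
         paste(utils::head(bad_dur, 5), collapse = ", "), call. = FALSE)
  bad_on <- which(is.na(df$onset_ms) | df$onset_ms < 0)
  if (length(bad_on))
    stop("negative or missing onset in row(s): ",
         paste(utils::head(bad_on, 5), collapse = ", "), call. = FALSE)
  df$onset_ms <- as.numeric(df$onset_ms)
  df$duration_ms <- as.numeric(df$duration_ms)

  ord <- order(df$participant, df$condition, df$onset_ms)
  out <- df[ord, , drop = FALSE]
  grp <- paste(out$participant, out$condition, sep = "\r")
  prev_end <- c(-Inf, (out$onset_ms + out$duration_ms)[-nrow(out)])
  same <- c(FALSE, grp[-1] == grp[-length(grp)])
  overlap <- which(same & out$onset_ms < prev_end - 1e-9)
  if (length(overlap))
    stop("overlapping fixations within a participant-condition stream ",
         "(sorted row(s) ", paste(utils::head(overlap, 5), collapse = ", "),
         ")", call. = FALSE)
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Remove fixations shorter than a minimum duration
#'
#' Applies the minimum fixation duration used when the events were
#' detected; the default of 80 ms keeps any fixation of 80 ms or longer
#' (inclusive boundary). Filtering precedes run-length collapsing into
#' AOI visits.
#'
#' @param fixations A validated fixation tibble.
#' @param min_ms Minimum duration in milliseconds (default 80).
#' @return The filtered tibble, order preserved.
#' @examples
#' fix <- make_worked_example()$fixations
#' nrow(fix); nrow(filter_min_duration(fix))
#' @export
filter_min_duration <- function(fixations, min_ms = 80) {
  if (!is.numeric(min_ms) || length(min_ms) != 1 || is.na(min_ms) || min_ms <= 0)
    stop("`min_ms` must be a single positive number", call. = FALSE)
  fixations[fixations$duration_ms >= min_ms, , drop = FALSE]
}

#' Collapse fixations of one stream into an AOI visit sequence
#'
#' Consecutive fixations inside the same AOI merge into a single visit,
#' regardless of their number and durations, so the result never has two
#' adjacent equal codes. The input must come from a single
#' participant-condition stream; use [visit_sequences()] for a whole table.
#'
#' @param fixations Fixation tibble for one participant and condition,
#'   sorted by onset.
#' @return An `aoi_visits` object: a list with `participant`, `condition`
#'   and `visits` (integer vector of AOI codes, no adjacent duplicates).
#' @examples
#' fix <- filter_min_duration(make_worked_example()$fixations)
#' collapse_to_visits(fix)
#' @export
collapse_to_visits <- function(fixations) {
  if (length(unique(fixations$participant)) > 1 ||
      length(unique(fixations$condition)) > 1)
    stop("`fixations` mixes participants or conditions; ",
         "use visit_sequences() instead", call. = FALSE)
  visits <- rle(fixations$aoi)$values
  structure(
    list(participant = if (nrow(fixations)) fixations$participant[1] else NA_character_,
         condition = if (nrow(fixations)) fixations$condition[1] else NA_character_,
         visits = as.integer(visits)),
    class = "aoi_visits")
}

#' @export
print.aoi_visits <- function(x, ...) {
  cat("<aoi_visits> participant", x$participant, "|", x$condition,
      "|", length(x$visits), "visits\n")
  cat(" ", sp_string(x$visits), "\n")
  invisible(x)
}

#' Collapse a full fixation table into AOI visit sequences
#'
#' Splits a fixation table by participant and condition and collapses each
#' stream with [collapse_to_visits()].
#'
#' @param fixations A validated fixation tibble (any number of streams).
#' @param min_ms Minimum fixation duration applied first; `NULL` to skip.
#' @return A list of `aoi_visits` objects, ordered by participant then
#'   condition.
#' @export
visit_sequences <- function(fixations, min_ms = 80) {
  if (!is.null(min_ms)) fixations <- filter_min_duration(fixations, min_ms)
  key <- paste(fixations$participant, fixations$condition, sep = "\r")
  idx <- split(seq_len(nrow(fixations)), key)
  out <- lapply(idx, function(i) collapse_to_visits(fixations[i, , drop = FALSE]))
  names(out) <- NULL
  out
}

#' Relative frequency of AOI visits
#'
#' For each participant and condition, the share of visits falling in each
#' of the seven AOIs (summing to 1; absent AOIs get 0), then the
#' across-participant mean and standard error per condition, plus pooled
#' visit counts for chi-squared use.
#'
#' @param seqs A list of `aoi_visits` objects (at least one per condition).
#' @return An `aoi_frequency_table`: list with `per_participant` (tibble:
#'   participant, condition, aoi, freq), `summary` (tibble: condition, aoi,
#'   mean_freq, se, n_participants) and `pooled` (matrix of visit counts,
#'   conditions in rows, AOIs 0-6 in columns).
#' @examples
#' sim <- simulate_fixations(generator_config(n_participants = 2, seed = 1))
#' freqs <- aoi_visit_frequencies(visit_sequences(sim$fixations))
#' freqs$summary
#' @export
aoi_visit_frequencies <- function(seqs) {
  if (!length(seqs)) stop("no visit sequences supplied", call. = FALSE)
  lv <- as.character(aoi_codes())
  rows <- lapply(seqs, function(s) {
    counts <- table(factor(s$visits, levels = lv))
    total <- sum(counts)
    if (total == 0)
      stop("empty visit sequence for participant ", s$participant, call. = FALSE)
    tibble::tibble(participant = s$participant, condition = s$condition,
                   aoi = as.integer(lv), count = as.integer(counts),
                   freq = as.numeric(counts) / total)
  })
  per <- do.call(rbind, rows)

  conds <- sort(unique(per$condition))
  summ <- do.call(rbind, lapply(conds, function(cc) {
    sub <- per[per$condition == cc, , drop = FALSE]
    n <- length(unique(sub$participant))
    m <- tapply(sub$freq, sub$aoi, mean)
    s <- tapply(sub$freq, sub$aoi, stats::sd)
    tibble::tibble(condition = cc, aoi = as.integer(names(m)),
                   mean_freq = as.numeric(m),
                   se = if (n > 1) as.numeric(s) / sqrt(n) else NA_real_,
                   n_participants = n)
  }))
  pooled <- do.call(rbind, lapply(conds, function(cc) {
    sub <- per[per$condition == cc, , drop = FALSE]
    tapply(sub$count, sub$aoi, sum)
  }))
  rownames(pooled) <- conds
  structure(list(per_participant = per[, c("participant", "condition", "aoi", "freq")],
                 summary = summ, pooled = pooled),
            class = "aoi_frequency_table")
}

#' @export
print.aoi_frequency_table <- function(x, ...) {
  cat("<aoi_frequency_table>\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
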