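# Orchestration: run the full pipeline and write the analysis artifacts
# (CSV tables, a JSON summary, an optional set of plain plots) to a
# directory. scanpath_cli() exposes the same steps as shell subcommands;
# a thin Rscript wrapper ships in inst/scripts/scanpath-cli.R.

#' Run the full scan-path analysis pipeline
#'
#' Reads (or simulates) a fixation table, filters sub-threshold fixations,
#' collapses AOI visits, and writes: AOI visit frequencies, the
#' length-selection curve, per-condition scan-path tables, classified
#' scan-path tables and class frequencies (length 4 and triplets), the
#' between-condition statistics report, and a JSON run summary. Every run
#' writes a log with the configuration echo and seed.
#'
#' @param input Path to a fixation CSV, or `NULL` to simulate with
#'   `generator_config(seed = seed)`.
#' @param outdir Output directory (created if needed).
#' @param length Scan-path length for the main analysis (default 4).
#' @param cutoff Relative-frequency cutoff for the frequent subset
#'   (default 0.004).
#' @param lengths Lengths for the selection curve (default 2:8).
#' @param alpha BH rejection level (default 0.05).
#' @param min_ms Minimum fixation duration (default 80).
#' @param seed Seed used when simulating.
#' @param precedence Rule precedence for [classify_quad()].
#' @param plots If `TRUE` and ggplot2 is available, also write plain
#'   re-renderings of the frequency/curve/class figures as PDFs.
#' @return (Invisibly) a list with the computed objects: `seqs`,
#'   `aoi_freq`, `curve`, `pools`, `class_tables`, `triplet_tables`,
#'   `comparison`, `files`.
#' @export
run_report <- function(input = NULL, outdir, length = 4, cutoff = 0.004,
                       lengths = 2:8, alpha = 0.05, min_ms = 80, seed = 1L,
                       precedence = default_precedence(), plots = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("scanpathr", as.character(utils::packageVersion("scanpathr")),
       "| R", paste(R.version$major, R.version$minor, sep = "."))
  logf("config: length =", length, "cutoff =", cutoff, "alpha =", alpha,
       "min_ms =", min_ms, "seed =", seed,
       "precedence =", paste(precedence, collapse = " > "))

  if (is.null(input)) {
    logf("no input given: simulating with generator_config(seed =", seed, ")")
    sim <- simulate_fixations(generator_config(seed = seed))
    fixations <- sim$fixations
    utils::write.csv(sim$ledger, file.path(outdir, "simulation_ledger.csv"),
                     row.names = FALSE)
  } else {
    logf("reading fixations from", input)
    fixations <- read_fixations(input)
  }

  seqs <- visit_sequences(fixations, min_ms = min_ms)
  conds <- sort(unique(vapply(seqs, `[[`, character(1), "condition")))
  logf(base::length(seqs), "visit sequences across", base::length(conds),
       "condition(s):", paste(conds, collapse = ", "))

  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  aoi_freq <- aoi_visit_frequencies(seqs)
  wr(aoi_freq$summary, "aoi_frequencies.csv")
  curve <- length_selection_curve(seqs, lengths = lengths)
  wr(curve, "length_curve.csv")

  pools <- list(); class_tables <- list(); triplet_tables <- list()
  for (cc in conds) {
    dists <- scanpath_distributions(seqs, length, condition = cc)
    pool <- pooled_distribution(dists)
    pools[[cc]] <- pool
    wr(pool, paste0("scanpaths_", cc, ".csv"))
    cond_arg <- if (identical(cc, "HAD")) "HAD" else "MD"
    wr(classified_table(pool, cutoff, cond_arg, precedence),
       paste0("classified_", cc, ".csv"))
    ct <- withCallingHandlers(
      class_frequencies(dists, scope = "frequent_subset", cutoff = cutoff,
                        precedence = precedence),
      warning = function(w) { logf("warning:", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    class_tables[[cc]] <- ct
    tri <- scanpath_distributions(seqs, 3, condition = cc)
    tt <- withCallingHandlers(
      class_frequencies(tri, scope = "full_dataset"),
      warning = function(w) { logf("warning:", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    triplet_tables[[cc]] <- tt
  }
  cf <- do.call(rbind, lapply(conds, function(cc) {
    s <- class_tables[[cc]]$summary; s$condition <- cc; s$length <- length; s
  }))
  tf <- do.call(rbind, lapply(conds, function(cc) {
    s <- triplet_tables[[cc]]$summary; s$condition <- cc; s$length <- 3L; s
  }))
  wr(rbind(cf, tf), "class_frequencies.csv")

  comparison <- NULL
  if (all(c("MD", "HAD") %in% conds)) {
    comparison <- list(
      quad = compare_conditions(class_tables$MD, class_tables$HAD,
                                alpha = alpha),
      triplet = compare_conditions(triplet_tables$MD, triplet_tables$HAD,
                                   alpha = alpha))
    stats_rows <- rbind(
      cbind(analysis = "quad_overall", comparison$quad$overall[, 1:4]),
      cbind(analysis = "triplet_overall", comparison$triplet$overall[, 1:4]))
    wr(stats_rows, "stats_overall.csv")
    wr(cbind(analysis = "quad", comparison$quad$per_class),
       "stats_per_class_quad.csv")
    wr(cbind(analysis = "triplet", comparison$triplet$per_class),
       "stats_per_class_triplet.csv")
  } else {
    logf("single condition: between-condition statistics skipped")
  }

  if (plots) .write_plots(outdir, aoi_freq, curve, cf, logf)

  summary <- list(
    seed = seed, length = length, cutoff = cutoff, alpha = alpha,
    conditions = conds,
    n_sequences = base::length(seqs),
    total_windows = lapply(pools, function(p) attr(p, "total_windows")),
    distinct_types = lapply(pools, nrow),
    files = basename(files))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("wrote", base::length(files) + 1, "artifact(s)")
  invisible(list(seqs = seqs, aoi_freq = aoi_freq, curve = curve,
                 pools = pools, class_tables = class_tables,
                 triplet_tables = triplet_tables, comparison = comparison,
                 files = files))
}

.write_plots <- function(outdir, aoi_freq, curve, class_freq, logf) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    logf("ggplot2 not available: plots skipped")
    return(invisible(NULL))
  }
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  p1 <- gg(aoi_freq$summary,
           aes(x = factor(.data[["aoi"]]), y = .data[["mean_freq"]],
               fill = .data[["condition"]])) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "AOI", y = "mean visit frequency")
  ggplot2::ggsave(file.path(outdir, "fig_aoi_frequencies.pdf"), p1,
                  width = 6, height = 4)
  p2 <- gg(curve, aes(x = .data[["length"]], y = .data[["percent_observed"]],
                      colour = .data[["condition"]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "scan path length", y = "% of possible permutations")
  ggplot2::ggsave(file.path(outdir, "fig_length_curve.pdf"), p2,
                  width = 6, height = 4)
  p3 <- gg(class_freq, aes(x = .data[["class"]], y = .data[["mean_freq"]],
                           fill = .data[["condition"]])) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean class frequency")
  ggplot2::ggsave(file.path(outdir, "fig_class_frequencies.pdf"), p3,
                  width = 6, height = 4)
  logf("wrote 3 figure(s)")
  invisible(NULL)
}

#' Command-line interface to the pipeline
#'
#' Subcommands: `simulate` (synthetic CSV + ground-truth ledger), `extract`
#' (scan-path and length-curve tables), `classify` (classified tables and
#' class frequencies, lengths 4 and 3), `compare` (between-condition
#' statistics report) and `report` (everything). Flags: `--input`,
#' `--outdir`, `--length`, `--cutoff`, `--alpha`, `--min-ms`, `--seed`,
#' `--plots`. Designed to be called from
#' `inst/scripts/scanpath-cli.R`.
#'
#' @param args Character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, 0 on success (invisibly); validation problems
#'   signal errors with actionable messages.
#' @examples
#' \donttest{
#' out <- tempfile()
#' scanpath_cli(c("simulate", "--outdir", out, "--seed", "7"))
#' }
#' @export
scanpath_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: scanpath-cli <simulate|extract|classify|compare|report> [flags]",
    "flags: --input PATH --outdir DIR --length N --cutoff X --alpha X",
    "       --min-ms N --seed N --plots", sep = "\n")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  if (!cmd %in% c("simulate", "extract", "classify", "compare", "report"))
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
  opts <- list(input = NULL, outdir = "scanpath-output", length = 4,
               cutoff = 0.004, alpha = 0.05, `min-ms` = 80, seed = 1,
               plots = FALSE)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    flag <- sub("^--", "", rest[i])
    if (!flag %in% names(opts))
      stop("unknown flag '", rest[i], "'\n", usage, call. = FALSE)
    if (flag == "plots") { opts$plots <- TRUE; i <- i + 1; next }
    if (i == length(rest))
      stop("flag --", flag, " needs a value", call. = FALSE)
    val <- rest[i + 1]
    opts[[flag]] <- if (flag %in% c("input", "outdir")) val else as.numeric(val)
    i <- i + 2
  }
  if (cmd == "simulate") {
    dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_fixations(generator_config(seed = as.integer(opts$seed)))
    utils::write.csv(sim$fixations, file.path(opts$outdir, "fixations.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$ledger, file.path(opts$outdir, "simulation_ledger.csv"),
                     row.names = FALSE)
    message("wrote ", file.path(opts$outdir, "fixations.csv"))
    return(invisible(0L))
  }
  # extract/classify/compare are views over the full report
  res <- run_report(input = opts$input, outdir = opts$outdir,
                    length = opts$length, cutoff = opts$cutoff,
                    alpha = opts$alpha, min_ms = opts$`min-ms`,
                    seed = as.integer(opts$seed), plots = isTRUE(opts$plots))
  if (cmd == "compare" && is.null(res$comparison))
    stop("compare needs both MD and HAD in the input", call. = FALSE)
  message("wrote ", length(res$files), " table(s) to ", opts$outdir)
  invisible(0L)
}
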