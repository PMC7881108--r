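# Independent oracles, kept free of the implementation paths they check.

# all length-L sequences over k symbols with no two adjacent equal,
# as a character matrix of digit strings
enumerate_norepeat <- function(k, L) {
  symbols <- seq_len(k) - 1L
  seqs <- as.list(symbols)
  for (i in seq_len(L - 1)) {
    seqs <- unlist(lapply(seqs, function(s) {
      lapply(setdiff(symbols, s[length(s)]), function(x) c(s, x))
    }), recursive = FALSE)
  }
  vapply(seqs, paste, character(1), collapse = "")
}

# two-sided Fisher p by exhaustive enumeration over tables with the
# observed margins, summing probabilities <= that of the observed table
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  prob_of <- function(x) {
    # table with cell (1,1) = x and the observed margins
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, prob_of, numeric(1))
  p_obs <- prob_of(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand step-up Benjamini-Hochberg
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, ranked[i] * m / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# closed-form Pearson statistic
chi2_oracle <- function(obs, expected) sum((obs - expected)^2 / expected)

# build an aoi_visits object directly
visits_obj <- function(v, participant = "p", condition = "MD") {
  structure(list(participant = participant, condition = condition,
                 visits = as.integer(v)), class = "aoi_visits")
}

# random valid visit sequence (no adjacent repeats)
random_visits <- function(n, k = 7) {
  v <- integer(n)
  v[1] <- sample.int(k, 1) - 1L
  for (i in seq_len(n - 1))
    v[i + 1] <- sample(setdiff(seq_len(k) - 1L, v[i]), 1)
  v
}

# fixation tibble from an AOI stream with given durations
fixation_table <- function(aoi, dur = rep(200, length(aoi)),
                           participant = "p", condition = "MD", gap = 40) {
  onset <- cumsum(c(0, (dur + gap)[-length(dur)]))
  tibble::tibble(participant = participant, condition = condition,
                 onset_ms = onset, duration_ms = dur, aoi = as.integer(aoi))
}
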