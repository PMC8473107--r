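# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# exceedance count over one window, via an explicit loop
oracle_pnn50 <- function(window, threshold = 50) {
  k <- 0L
  for (i in seq_len(length(window) - 1)) {
    if (abs(window[i + 1] - window[i]) > threshold) k <- k + 1L
  }
  k / (length(window) - 1)
}

# latest-value-at-or-before-t by linear scan
oracle_latest <- function(times, values, t) {
  best <- NA_real_
  for (i in seq_along(times)) {
    if (times[i] <= t) best <- values[i]
  }
  best
}

# 1 Hz merge by per-second linear scans
oracle_align <- function(eeg, pnn50, start, stop) {
  rows <- list()
  for (t in seq(ceiling(start), ceiling(stop) - 1)) {
    if (t >= stop) next
    a <- oracle_latest(eeg$t_sec, eeg$attention - eeg$meditation, t)
    v <- oracle_latest(pnn50$t_sec, pnn50$pnn50, t)
    if (!is.na(a) && !is.na(v)) {
      rows[[length(rows) + 1]] <- data.frame(t_sec = t, arousal_raw = a,
                                             valence_raw = v)
    }
  }
  do.call(rbind, rows)
}

# quadrant by sign table
oracle_quadrant <- function(valence, arousal) {
  if (arousal >= 0 && valence >= 0) return("happy")
  if (arousal >= 0 && valence < 0) return("angry")
  if (arousal < 0 && valence < 0) return("sad")
  "relaxed"
}

# Pearson chi-square by explicit expected-count loop
oracle_chisq <- function(m) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  stat
}

# small deterministic session for pipeline tests
make_test_session <- function(seed = 42, condition = "synchronized",
                              target_pnn50 = 0.4, beta = c(0, 1, 4),
                              click_rate = 24) {
  generate_session(
    participant_spec(true_beta = beta, click_rate = click_rate, seed = seed),
    signal_spec(75, target_pnn50 = target_pnn50, target_arousal = 20),
    condition = condition
  )
}
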