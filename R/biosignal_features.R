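#' Construct an R-R interval series
#'
#' Bundles beat arrival times with the corresponding R-R interval durations.
#' Timestamps are seconds from session start and must be strictly increasing;
#' intervals are in milliseconds. Values outside the physiologically plausible
#' band \[300, 2000\] ms are flagged with a warning but kept: no artifact
#' rejection is applied.
#'
#' @param t_sec numeric vector of arrival times (s from session start),
#'   strictly increasing.
#' @param rri_ms numeric vector of R-R intervals (ms), same length as `t_sec`,
#'   all strictly positive.
#' @return A data frame of class `rri_series` with columns `t_sec`, `rri_ms`
#'   and a logical `implausible` flag.
#' @examples
#' rri <- rri_series(t_sec = cumsum(rep(0.8, 5)), rri_ms = rep(800, 5))
#' @export
rri_series <- function(t_sec, rri_ms) {
  t_sec <- as.numeric(t_sec)
  rri_ms <- as.numeric(rri_ms)
  if (length(t_sec) != length(rri_ms)) {
    ra_stop("t_sec and rri_ms must have equal length", "roboaffect_invalid_series")
  }
  if (anyNA(t_sec) || anyNA(rri_ms)) {
    ra_stop("RRI series may not contain missing values", "roboaffect_invalid_series")
  }
  if (length(t_sec) > 1 && any(diff(t_sec) <= 0)) {
    ra_stop("RRI timestamps must be strictly increasing", "roboaffect_invalid_series")
  }
  if (any(rri_ms <= 0)) {
    ra_stop("R-R intervals must be strictly positive", "roboaffect_invalid_series")
  }
  implausible <- rri_ms < 300 | rri_ms > 2000
  if (any(implausible)) {
    warning(sprintf("%d R-R interval(s) outside [300, 2000] ms flagged as implausible",
                    sum(implausible)), call. = FALSE)
  }
  structure(
    data.frame(t_sec = t_sec, rri_ms = rri_ms, implausible = implausible),
    class = c("rri_series", "data.frame")
  )
}

#' pNN50 over one window of consecutive R-R intervals
#'
#' The proportion of successive R-R interval differences whose absolute value
#' exceeds 50 ms (strict inequality). The window holds `n_diff + 1` intervals,
#' yielding `n_diff` successive differences; the default of 30 differences
#' (31 intervals) matches the convention of counting exceedances among 30
#' adjacent interval pairs.
#'
#' @param window numeric vector of exactly `n_diff + 1` consecutive R-R
#'   intervals in milliseconds.
#' @param n_diff number of successive differences (window length minus one).
#' @param threshold_ms exceedance threshold in ms (default 50).
#' @return Proportion in \[0, 1\], always `k / n_diff` for an integer `k`.
#' @examples
#' compute_pnn50(rep(800, 31))              # 0
#' compute_pnn50(rep(c(700, 800), 16)[1:31]) # 1
#' @export
compute_pnn50 <- function(window, n_diff = 30L, threshold_ms = 50) {
  window <- as.numeric(window)
  needed <- n_diff + 1L
  if (length(window) != needed) {
    ra_stop(
      sprintf("pNN50 window needs exactly %d intervals, got %d", needed, length(window)),
      "roboaffect_window_too_short",
      required = needed, actual = length(window)
    )
  }
  sum(abs(diff(window)) > threshold_ms) / n_diff
}

#' Sliding pNN50 over an R-R interval series
#'
#' Evaluates [compute_pnn50()] over the trailing window ending at each beat
#' from the `(n_diff + 1)`-th onward. Each value is stamped with the arrival
#' time of the newest interval in its window.
#'
#' @param series an [rri_series()].
#' @inheritParams compute_pnn50
#' @return Data frame with columns `t_sec`, `pnn50`; one row per beat from
#'   the `(n_diff + 1)`-th, i.e. `nrow(series) - n_diff` rows.
#' @export
pnn50_stream <- function(series, n_diff = 30L, threshold_ms = 50) {
  n <- nrow(series)
  win <- n_diff + 1L
  if (n < win) {
    ra_stop(
      sprintf("pNN50 stream needs at least %d intervals, got %d", win, n),
      "roboaffect_window_too_short",
      required = win, actual = n
    )
  }
  exceed <- abs(diff(series$rri_ms)) > threshold_ms
  # trailing sum of n_diff exceedance flags ending at each beat
  cs <- c(0, cumsum(exceed))
  k <- cs[(win):(n)] - cs[seq_len(n - n_diff)]
  data.frame(t_sec = series$t_sec[win:n], pnn50 = k / n_diff)
}

#' Arousal index from EEG Attention and Meditation
#'
#' Attention minus Meditation, both on the sensor's 0-100 relative scale.
#' Attention emphasizes beta-band activity and Meditation alpha-band
#' activity, so their difference serves as the arousal proxy.
#'
#' @param attention,meditation numeric vectors in \[0, 100\].
#' @return `attention - meditation`, in \[-100, 100\].
#' @examples
#' arousal_index(70, 30)  # 40
#' @export
arousal_index <- function(attention, meditation) {
  if (anyNA(attention) || any(attention < 0 | attention > 100)) {
    ra_stop("attention must lie in [0, 100]", "roboaffect_domain_error", field = "attention")
  }
  if (anyNA(meditation) || any(meditation < 0 | meditation > 100)) {
    ra_stop("meditation must lie in [0, 100]", "roboaffect_domain_error", field = "meditation")
  }
  attention - meditation
}

# latest value of `values` observed at or before each query time; NA if none
latest_at <- function(times, values, at) {
  idx <- findInterval(at, times)
  out <- rep(NA_real_, length(at))
  out[idx > 0] <- values[idx[idx > 0]]
  out
}

#' Merge unsynchronized EEG and pNN50 streams on a 1 Hz clock
#'
#' The EEG and pulse sensors are unsynchronized, so for each integer second
#' `t` in `[start, stop)` the most recent sample of each stream with
#' timestamp `<= t` is carried forward. Seconds before the first sample of
#' either stream are dropped (no back-filling, no interpolation).
#'
#' @param eeg data frame with columns `t_sec`, `attention`, `meditation`,
#'   time-sorted.
#' @param pnn50 data frame with columns `t_sec`, `pnn50`, time-sorted
#'   (as produced by [pnn50_stream()]).
#' @param start,stop session window bounds in seconds; half-open
#'   `[start, stop)`.
#' @return Data frame with columns `t_sec` (integer clock second),
#'   `arousal_raw` (Attention - Meditation, \[-100, 100\]) and `valence_raw`
#'   (pNN50, \[0, 1\]).
#' @export
align_streams <- function(eeg, pnn50, start, stop) {
  if (is.null(eeg) || nrow(eeg) == 0) {
    ra_stop("EEG stream is empty", "roboaffect_empty_stream", stream = "eeg")
  }
  if (is.null(pnn50) || nrow(pnn50) == 0) {
    ra_stop("pNN50 stream is empty", "roboaffect_empty_stream", stream = "pnn50")
  }
  if (start >= stop) {
    ra_stop("start must be < stop", "roboaffect_domain_error", field = "start")
  }
  secs <- seq(from = ceiling(start), to = ceiling(stop) - 1L)
  secs <- secs[secs < stop]
  ar <- latest_at(eeg$t_sec, arousal_index(eeg$attention, eeg$meditation), secs)
  va <- latest_at(pnn50$t_sec, pnn50$pnn50, secs)
  keep <- !is.na(ar) & !is.na(va)
  data.frame(t_sec = secs[keep], arousal_raw = ar[keep], valence_raw = va[keep])
}
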