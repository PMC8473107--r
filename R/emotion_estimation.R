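#' Baseline physiological profile from a rest period
#'
#' Mean pNN50 and mean Attention-Meditation over the pre-stimulus rest
#' period, later used to center the affect axes so that the resting state
#' maps to the circumplex origin. The protocol records 60 s of rest; at
#' least 30 aligned seconds are required.
#'
#' @param aligned data frame from [align_streams()] covering the rest period.
#' @param min_samples minimum number of aligned seconds required.
#' @return List of class `baseline_profile` with `baseline_pnn50` and
#'   `baseline_arousal`.
#' @export
baseline_profile <- function(aligned, min_samples = 30L) {
  if (is.null(aligned) || nrow(aligned) < min_samples) {
    ra_stop(
      sprintf("baseline needs >= %d aligned seconds, got %d",
              min_samples, if (is.null(aligned)) 0L else nrow(aligned)),
      "roboaffect_baseline_required"
    )
  }
  structure(
    list(baseline_pnn50 = mean(aligned$valence_raw),
         baseline_arousal = mean(aligned$arousal_raw)),
    class = "baseline_profile"
  )
}

#' @export
print.baseline_profile <- function(x, ...) {
  cat(sprintf("<baseline_profile> pNN50 = %.3f, arousal = %.1f\n",
              x$baseline_pnn50, x$baseline_arousal))
  invisible(x)
}

#' Normalize raw indices onto the circumplex plane
#'
#' Maps raw arousal (Attention - Meditation, \[-100, 100\]) and raw valence
#' (pNN50, \[0, 1\]) onto a common \[-1, 1\] x \[-1, 1\] plane so that the
#' Euclidean distance from the origin is comparable across axes:
#' arousal is baseline-centered and divided by 100; valence is pNN50 minus
#' the baseline pNN50 (or minus a fixed 0.5 midpoint with
#' `valence_normalization = "midpoint"`). Both coordinates are clamped to
#' \[-1, 1\]. The resting state maps to the origin under the baseline method.
#'
#' @param arousal_raw numeric in \[-100, 100\].
#' @param valence_raw numeric in \[0, 1\].
#' @param baseline a [baseline_profile()]; required for the baseline method.
#' @param valence_normalization `"baseline"` (default) or `"midpoint"`.
#' @return Data frame with columns `valence`, `arousal`, each in \[-1, 1\].
#' @export
normalize_affect <- function(arousal_raw, valence_raw, baseline = NULL,
                             valence_normalization = c("baseline", "midpoint")) {
  valence_normalization <- match.arg(valence_normalization)
  if (is.null(baseline)) {
    ra_stop("a baseline_profile is required to normalize affect",
            "roboaffect_baseline_required")
  }
  arousal <- clamp((arousal_raw - baseline$baseline_arousal) / 100, -1, 1)
  ref <- if (valence_normalization == "baseline") baseline$baseline_pnn50 else 0.5
  valence <- clamp(valence_raw - ref, -1, 1)
  data.frame(valence = valence, arousal = arousal)
}

#' Classify a circumplex quadrant
#'
#' Russell's circumplex model: valence on the horizontal axis, arousal on
#' the vertical axis. Points on an axis are assigned to the non-negative
#' side, so the origin classifies as `happy`.
#'
#' @param valence,arousal numeric vectors in \[-1, 1\].
#' @return Character vector: `happy` (arousal >= 0, valence >= 0), `angry`
#'   (arousal >= 0, valence < 0), `sad` (both negative) or `relaxed`
#'   (arousal < 0, valence >= 0).
#' @examples
#' classify_quadrant(valence = 0.3, arousal = 0.5)   # "happy"
#' classify_quadrant(valence = -0.4, arousal = -0.1) # "sad"
#' @export
classify_quadrant <- function(valence, arousal) {
  ifelse(arousal >= 0,
         ifelse(valence >= 0, "happy", "angry"),
         ifelse(valence >= 0, "relaxed", "sad"))
}

#' Five-level emotional intensity from distance to the origin
#'
#' Intensity is the Euclidean length of the (valence, arousal) point,
#' quantized into five equal-width bins over \[0, sqrt(2)\]: higher emotion
#' values give higher intensity. Level 1 includes the origin; level 5 is
#' reached at `4 * sqrt(2) / 5` and above.
#'
#' @param valence,arousal numeric vectors in \[-1, 1\].
#' @param bins number of intensity levels (default 5).
#' @return Data frame with `intensity_raw` in \[0, sqrt(2)\] and integer
#'   `intensity_level` in `1..bins`.
#' @examples
#' intensity_level(0.6, 0)  # raw 0.6, level 3
#' @export
intensity_level <- function(valence, arousal, bins = 5L) {
  raw <- sqrt(valence^2 + arousal^2)
  width <- sqrt(2) / bins
  lev <- pmin(bins, floor(raw / width) + 1L)
  data.frame(intensity_raw = raw, intensity_level = as.integer(lev))
}

#' Cumulative emotion estimates on a 2.5 s tick
#'
#' At each tick `k * tick_interval` from stimulus onset the running
#' (expanding) mean of valence and arousal over all samples observed so far
#' is classified and graded. Ticks before the first sample produce no
#' estimate (deferred, not an error).
#'
#' @param points data frame with columns `t_sec` (seconds from stimulus
#'   onset, sorted), `valence`, `arousal` (normalized).
#' @param duration_s stimulus duration in seconds; ticks run up to
#'   `floor(duration_s / tick_interval) * tick_interval`.
#' @param tick_interval tick spacing in seconds (default 2.5).
#' @param bins intensity levels passed to [intensity_level()].
#' @return Data frame with one row per tick holding the tick time `t_sec`,
#'   mean `valence` and `arousal`, the quadrant `label`, `intensity_raw`
#'   and `intensity_level`.
#' @export
cumulative_estimate <- function(points, duration_s, tick_interval = 2.5,
                                bins = 5L) {
  if (tick_interval <= 0) {
    ra_stop("tick_interval must be > 0", "roboaffect_domain_error",
            field = "tick_interval")
  }
  ticks <- seq_len(floor(duration_s / tick_interval)) * tick_interval
  rows <- lapply(ticks, function(tk) {
    seen <- points[points$t_sec <= tk, , drop = FALSE]
    if (nrow(seen) == 0) return(NULL)
    v <- mean(seen$valence)
    a <- mean(seen$arousal)
    cbind(data.frame(t_sec = tk, valence = v, arousal = a,
                     label = classify_quadrant(v, a)),
          intensity_level(v, a, bins = bins))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(t_sec = numeric(0), valence = numeric(0),
                      arousal = numeric(0), label = character(0),
                      intensity_raw = numeric(0),
                      intensity_level = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
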