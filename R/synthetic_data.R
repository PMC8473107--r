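#' Specification of a synthetic biosignal segment
#'
#' Controls the statistical structure of generated R-R interval and EEG
#' streams: the target pNN50 (proportion of successive R-R differences
#' exceeding 50 ms), the mean R-R interval, and the target mean
#' Attention - Meditation difference. Optional linear drifts (per second)
#' move either target over the segment.
#'
#' @param duration_s segment length in seconds (> 0).
#' @param target_pnn50 desired exceedance rate in \[0, 1\].
#' @param mean_rri_ms mean R-R interval in ms (default 800, i.e. 75 bpm).
#' @param target_arousal desired mean Attention - Meditation in
#'   \[-100, 100\].
#' @param eeg_rate_hz EEG index sampling rate (default 1 Hz).
#' @param eeg_noise_sd standard deviation of the Gaussian noise added to
#'   each EEG index (default 5; 0 switches noise off).
#' @param arousal_drift,pnn50_drift linear trends per second applied to the
#'   respective target (default 0).
#' @return List of class `signal_spec`.
#' @export
signal_spec <- function(duration_s, target_pnn50 = 0.25, mean_rri_ms = 800,
                        target_arousal = 0, eeg_rate_hz = 1,
                        eeg_noise_sd = 5, arousal_drift = 0,
                        pnn50_drift = 0) {
  if (duration_s <= 0) {
    ra_stop("duration_s must be > 0", "roboaffect_domain_error",
            field = "duration_s")
  }
  if (target_pnn50 < 0 || target_pnn50 > 1) {
    ra_stop("target_pnn50 must lie in [0, 1]", "roboaffect_domain_error",
            field = "target_pnn50")
  }
  if (mean_rri_ms < 300 || mean_rri_ms > 2000) {
    ra_stop("mean_rri_ms must lie in [300, 2000]", "roboaffect_domain_error",
            field = "mean_rri_ms")
  }
  if (abs(target_arousal) > 100) {
    ra_stop("target_arousal must lie in [-100, 100]",
            "roboaffect_domain_error", field = "target_arousal")
  }
  structure(
    list(duration_s = duration_s, target_pnn50 = target_pnn50,
         mean_rri_ms = mean_rri_ms, target_arousal = target_arousal,
         eeg_rate_hz = eeg_rate_hz, eeg_noise_sd = eeg_noise_sd,
         arousal_drift = arousal_drift, pnn50_drift = pnn50_drift),
    class = "signal_spec"
  )
}

#' Specification of a simulated participant
#'
#' Ground truth for the preference model: the generating logistic
#' coefficients over normalized (arousal, valence), and the free-clicking
#' rate. A fixed seed makes every generated stream reproducible.
#'
#' @param true_beta numeric length-3: (beta0, beta_arousal, beta_valence)
#'   of the generating like-probability model.
#' @param click_rate expected clicks per minute (> 0). The default of 24
#'   corresponds to roughly one judgement per 2.5 s display frame.
#' @param seed RNG seed.
#' @return List of class `participant_spec`.
#' @export
participant_spec <- function(true_beta = c(0, 2, 3), click_rate = 24,
                             seed = 1L) {
  if (length(true_beta) != 3 || anyNA(true_beta)) {
    ra_stop("true_beta must be numeric length 3", "roboaffect_domain_error",
            field = "true_beta")
  }
  if (click_rate <= 0) {
    ra_stop("click_rate must be > 0", "roboaffect_domain_error",
            field = "click_rate")
  }
  structure(
    list(true_beta = as.numeric(true_beta), click_rate = click_rate,
         seed = as.integer(seed)),
    class = "participant_spec"
  )
}

# exceedance flags for n_diff successive differences: an (almost) exact
# count round(sum(q)) of exceedances is allocated at random positions,
# weighted by the per-step rate, so the realized rate tracks the target
# tightly rather than with full Bernoulli noise
draw_exceedances <- function(q) {
  n <- length(q)
  k <- round(sum(q))
  flags <- rep(FALSE, n)
  if (k >= n) return(rep(TRUE, n))
  if (k > 0) {
    if (length(unique(q)) == 1) {
      idx <- sample.int(n, k)
    } else {
      idx <- sample.int(n, k, prob = pmax(q, 1e-12))
    }
    flags[idx] <- TRUE
  }
  flags
}

# one random-walk step magnitude per successive difference: exceedances are
# U(55, 120) ms, the rest U(0, 45) ms, so a difference crosses the 50 ms
# pNN50 threshold exactly when its step was drawn as an exceedance
rri_walk <- function(n_diff, q, mean_rri_ms, max_dev = 150) {
  exceed <- draw_exceedances(q)
  mag <- ifelse(exceed, stats::runif(n_diff, 55, 120),
                stats::runif(n_diff, 0, 45))
  signs <- sample(c(-1, 1), n_diff, replace = TRUE)
  e <- numeric(n_diff + 1)
  for (i in seq_len(n_diff)) {
    step <- signs[i] * mag[i]
    if (abs(e[i] + step) > max_dev) step <- -step
    if (abs(e[i] + step) > max_dev) step <- sign(-e[i]) * mag[i]
    e[i + 1] <- e[i] + step
  }
  mean_rri_ms + e
}

#' Generate a synthetic R-R interval stream
#'
#' Intervals follow a bounded random walk around `mean_rri_ms` (deviation
#' capped at 150 ms) whose successive-difference magnitudes are drawn from
#' an exceedance mixture: with the target pNN50 rate the magnitude is
#' uniform on (55, 120) ms, otherwise uniform on (0, 45) ms, so the realized
#' pNN50 is controlled directly by the target. Physiological realism beyond
#' the exceedance statistic is not attempted.
#'
#' @param spec a [signal_spec()].
#' @param seed optional seed; omit to consume the current RNG stream.
#' @return An [rri_series()] covering `spec$duration_s` seconds; timestamps
#'   accumulate the interval durations.
#' @export
generate_rri <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, ceiling(spec$duration_s * 1000 / spec$mean_rri_ms) + 8L)
  beat_t <- (seq_len(n - 1)) * spec$mean_rri_ms / 1000
  q <- clamp(spec$target_pnn50 + spec$pnn50_drift * beat_t, 0, 1)
  rri <- rri_walk(n - 1L, q, spec$mean_rri_ms)
  t <- cumsum(rri) / 1000
  while (t[length(t)] < spec$duration_s) {
    ex <- stats::runif(1) < clamp(spec$target_pnn50 +
                                    spec$pnn50_drift * t[length(t)], 0, 1)
    mag <- if (ex) stats::runif(1, 55, 120) else stats::runif(1, 0, 45)
    prev <- rri[length(rri)] - spec$mean_rri_ms
    step <- sample(c(-1, 1), 1) * mag
    if (abs(prev + step) > 150) step <- -step
    rri <- c(rri, spec$mean_rri_ms + prev + step)
    t <- c(t, t[length(t)] + rri[length(rri)] / 1000)
  }
  keep <- c(TRUE, t[-length(t)] < spec$duration_s)
  rri_series(t_sec = t[keep], rri_ms = rri[keep])
}

#' Generate a synthetic EEG index stream
#'
#' Attention and Meditation are placed symmetrically around 50 so their
#' expected difference equals the target arousal:
#' `attention = 50 + target/2 + noise`, `meditation = 50 - target/2 + noise`
#' with independent Gaussian noise, both clamped to \[0, 100\].
#'
#' @param spec a [signal_spec()].
#' @param seed optional seed; omit to consume the current RNG stream.
#' @return Data frame with columns `t_sec`, `attention`, `meditation`.
#' @export
generate_eeg <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, spec$duration_s - 1 / spec$eeg_rate_hz,
           by = 1 / spec$eeg_rate_hz)
  target <- clamp(spec$target_arousal + spec$arousal_drift * t, -100, 100)
  n <- length(t)
  att <- clamp(50 + target / 2 + stats::rnorm(n, 0, spec$eeg_noise_sd), 0, 100)
  med <- clamp(50 - target / 2 + stats::rnorm(n, 0, spec$eeg_noise_sd), 0, 100)
  data.frame(t_sec = t, attention = att, meditation = med)
}

#' Generate like/dislike clicks from a ground-truth preference model
#'
#' Candidate click times are a homogeneous Poisson process at the
#' participant's click rate over the aligned window; each candidate's
#' polarity is drawn as "like" with the probability given by the logistic
#' law evaluated at the normalized features carried at that time.
#'
#' @param aligned data frame of normalized aligned samples with columns
#'   `t_sec`, `x_arousal`, `x_valence`.
#' @param part a [participant_spec()].
#' @param seed optional seed; omit to consume the current RNG stream.
#' @return Data frame with columns `t_sec`, `polarity`, sorted by time.
#' @export
generate_clicks <- function(aligned, part, seed = NULL) {
  if (is.null(aligned) || nrow(aligned) == 0) {
    ra_stop("aligned samples are required to generate clicks",
            "roboaffect_empty_input")
  }
  if (!is.null(seed)) set.seed(seed)
  t0 <- min(aligned$t_sec)
  t1 <- max(aligned$t_sec) + 1
  n <- stats::rpois(1, part$click_rate / 60 * (t1 - t0))
  if (n == 0) {
    return(data.frame(t_sec = numeric(0), polarity = character(0)))
  }
  times <- sort(stats::runif(n, t0, t1))
  a <- latest_at(aligned$t_sec, aligned$x_arousal, times)
  v <- latest_at(aligned$t_sec, aligned$x_valence, times)
  b <- part$true_beta
  p <- 1 / (1 + exp(-(b[1] + b[2] * a + b[3] * v)))
  data.frame(
    t_sec = times,
    polarity = ifelse(stats::runif(n) < p, "like", "dislike")
  )
}

#' Simulate labeled preference samples directly
#'
#' Draws normalized (arousal, valence) features uniformly on
#' \[-1, 1\] x \[-1, 1\] and labels them from the generating logistic law.
#' Used for parameter-recovery and accuracy studies of [fit_logistic()]
#' without running the full session pipeline.
#'
#' @param n number of samples.
#' @param beta generating (beta0, beta_arousal, beta_valence).
#' @param seed optional seed.
#' @return Data frame `x_arousal`, `x_valence`, `y`, plus `p_true`, the
#'   generating like probability of each row.
#' @export
simulate_preference_samples <- function(n, beta = c(0, 2, 3), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x_arousal <- stats::runif(n, -1, 1)
  x_valence <- stats::runif(n, -1, 1)
  p <- 1 / (1 + exp(-(beta[1] + beta[2] * x_arousal + beta[3] * x_valence)))
  data.frame(x_arousal = x_arousal, x_valence = x_valence,
             y = stats::rbinom(n, 1, p), p_true = p)
}

#' Simulate a full experimental session
#'
#' Reproduces the session protocol: a rest segment for the baseline
#' measurement followed by a music-stimulus segment during which the robot
#' expression is updated at 2.5 s ticks and the participant clicks freely.
#' The segments may carry different signal targets (`baseline_signal`
#' defaults to a neutral resting profile sharing the stimulus spec's mean
#' R-R interval). One RNG stream seeded from the participant spec is
#' consumed in a fixed order (RRI, EEG, clicks) so runs are reproducible.
#'
#' @param part a [participant_spec()]; its seed initializes the RNG unless
#'   `seed = NA` is passed to keep the current stream.
#' @param signal a [signal_spec()] for the stimulus segment (its
#'   `duration_s` is overridden by `stimulus_s`).
#' @param condition `"synchronized"`, `"inversely_synchronized"`, `"funny"`
#'   or `"personalized"` (the latter requires `policy`).
#' @param baseline_signal optional [signal_spec()] for the rest segment.
#' @param policy a [build_personalized_policy()] result, for
#'   `condition = "personalized"`.
#' @param baseline_s,stimulus_s protocol durations (defaults 60 and 75 s).
#' @param tick_interval expression update interval (default 2.5 s).
#' @param seed overrides the participant seed; `NA` keeps the current RNG
#'   stream.
#' @return List of class `affect_session`: raw streams (`rri`, `eeg`,
#'   session-clock times), `aligned` (raw 1 Hz merge over the whole
#'   session), `baseline` profile, `aligned_norm` (stimulus window,
#'   stimulus-relative seconds, normalized features), `estimates`,
#'   `expressions`, `clicks` (stimulus-relative), and the specs used.
#' @export
generate_session <- function(part, signal, condition = "synchronized",
                             baseline_signal = NULL, policy = NULL,
                             baseline_s = 60, stimulus_s = 75,
                             tick_interval = 2.5, seed = NULL) {
  if (condition == "personalized" && is.null(policy)) {
    ra_stop("condition 'personalized' requires a policy",
            "roboaffect_config_error", field = "policy")
  }
  if (condition != "personalized" && !condition %in% EXPRESSION_CONDITIONS) {
    ra_stop(sprintf("unknown expression condition: %s", condition),
            "roboaffect_config_error", field = "condition")
  }
  seed <- seed %||% part$seed
  if (!is.na(seed)) set.seed(seed)

  if (is.null(baseline_signal)) {
    baseline_signal <- signal_spec(
      duration_s = baseline_s, target_pnn50 = 0.25,
      mean_rri_ms = signal$mean_rri_ms, target_arousal = 0,
      eeg_rate_hz = signal$eeg_rate_hz, eeg_noise_sd = signal$eeg_noise_sd
    )
  }
  baseline_signal$duration_s <- baseline_s
  stim_signal <- signal
  stim_signal$duration_s <- stimulus_s

  # fixed consumption order: RRI (baseline, stimulus), EEG (baseline,
  # stimulus), clicks
  rri_b <- generate_rri(baseline_signal)
  rri_s <- generate_rri(stim_signal)
  t_shift <- rri_b$t_sec[nrow(rri_b)]
  rri <- rri_series(c(rri_b$t_sec, t_shift + rri_s$t_sec),
                    c(rri_b$rri_ms, rri_s$rri_ms))
  eeg_b <- generate_eeg(baseline_signal)
  eeg_s <- generate_eeg(stim_signal)
  eeg_s$t_sec <- eeg_s$t_sec + baseline_s
  eeg <- rbind(eeg_b, eeg_s)

  total_s <- baseline_s + stimulus_s
  ps <- pnn50_stream(rri)
  aligned <- align_streams(eeg, ps, 0, total_s)

  baseline <- baseline_profile(aligned[aligned$t_sec < baseline_s, ,
                                       drop = FALSE])
  stim <- aligned[aligned$t_sec >= baseline_s, , drop = FALSE]
  norm <- normalize_affect(stim$arousal_raw, stim$valence_raw, baseline)
  aligned_norm <- data.frame(
    t_sec = stim$t_sec - baseline_s,
    x_arousal = norm$arousal, x_valence = norm$valence,
    valence_raw = stim$valence_raw, arousal_raw = stim$arousal_raw
  )

  estimates <- cumulative_estimate(
    data.frame(t_sec = aligned_norm$t_sec, valence = aligned_norm$x_valence,
               arousal = aligned_norm$x_arousal),
    duration_s = stimulus_s, tick_interval = tick_interval
  )
  expressions <- if (condition == "personalized") {
    personalized_expression(policy, estimates)
  } else {
    select_expression(estimates, condition)
  }
  clicks <- generate_clicks(aligned_norm, part)

  structure(
    list(condition = condition, rri = rri, eeg = eeg, aligned = aligned,
         baseline = baseline, aligned_norm = aligned_norm,
         estimates = estimates, expressions = expressions, clicks = clicks,
         participant = part, signal = stim_signal,
         baseline_signal = baseline_signal,
         baseline_s = baseline_s, stimulus_s = stimulus_s,
         tick_interval = tick_interval, seed = seed),
    class = "affect_session"
  )
}

#' @export
print.affect_session <- function(x, ...) {
  cat(sprintf(paste0(
    "<affect_session> condition: %s\n",
    "  %g s baseline + %g s stimulus, %d beats, %d aligned stimulus seconds\n",
    "  %d expression commands, %d clicks (%d like / %d dislike)\n"),
    x$condition, x$baseline_s, x$stimulus_s, nrow(x$rri),
    nrow(x$aligned_norm), nrow(x$expressions), nrow(x$clicks),
    sum(x$clicks$polarity == "like"), sum(x$clicks$polarity == "dislike")))
  invisible(x)
}
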