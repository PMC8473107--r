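#' Session configuration
#'
#' Bundles the protocol durations, processing parameters and file paths for
#' [run_pipeline()]. All durations are seconds and must be positive; the
#' number of expression ticks is `floor(stimulus_s / tick_interval_s)` (a
#' non-integral final tick is truncated).
#'
#' @param rri_csv,eeg_csv,clicks_csv input file paths (see
#'   [read_rri_csv()] for formats).
#' @param out_dir output directory for the logs; `NULL` disables writing.
#' @param condition expression condition for the session.
#' @param baseline_s,stimulus_s,tick_interval_s,lookback_s protocol
#'   parameters (defaults 60, 75, 2.5, 30).
#' @param valence_normalization `"baseline"` or `"midpoint"` (see
#'   [normalize_affect()]).
#' @param first_click_only label only the first click's window (see
#'   [build_dataset()]).
#' @return List of class `session_config`.
#' @export
session_config <- function(rri_csv = NULL, eeg_csv = NULL, clicks_csv = NULL,
                           out_dir = NULL, condition = "synchronized",
                           baseline_s = 60, stimulus_s = 75,
                           tick_interval_s = 2.5, lookback_s = 30,
                           valence_normalization = "baseline",
                           first_click_only = FALSE) {
  for (f in c(baseline_s = baseline_s, stimulus_s = stimulus_s,
              tick_interval_s = tick_interval_s, lookback_s = lookback_s)) {
    if (!is.numeric(f) || f <= 0) {
      ra_stop("all durations must be positive", "roboaffect_config_error",
              field = "durations")
    }
  }
  structure(
    list(rri_csv = rri_csv, eeg_csv = eeg_csv, clicks_csv = clicks_csv,
         out_dir = out_dir, condition = condition, baseline_s = baseline_s,
         stimulus_s = stimulus_s, tick_interval_s = tick_interval_s,
         lookback_s = lookback_s,
         valence_normalization = valence_normalization,
         first_click_only = first_click_only),
    class = "session_config"
  )
}

#' Run the full session pipeline on recorded streams
#'
#' Composes the whole method on one session's files: sliding pNN50 over the
#' R-R intervals, 1 Hz carry-forward alignment with the EEG indices,
#' baseline normalization onto the circumplex plane, cumulative emotion
#' estimation at the configured tick, expression selection under the
#' configured condition, click-window dataset construction, logistic
#' preference fitting, and confusion-matrix metrics with preference-group
#' assignment. When `config$out_dir` is set, the logs are written there
#' (`aligned.csv`, `estimates.csv`, `expressions.csv`, `dataset.csv`,
#' `model.json`, `metrics.json`).
#'
#' @param config a [session_config()] with input paths set.
#' @return List with `aligned`, `baseline`, `aligned_norm`, `estimates`,
#'   `expressions`, `dataset`, and — when the dataset supports fitting —
#'   `model`, `counts`, `metrics` (list with TP/FP/FN/TN/ACC/group).
#' @export
run_pipeline <- function(config) {
  rri <- read_rri_csv(config$rri_csv)
  eeg <- read_eeg_csv(config$eeg_csv)
  clicks <- if (!is.null(config$clicks_csv)) {
    read_clicks_csv(config$clicks_csv)
  } else {
    data.frame(t_sec = numeric(0), polarity = character(0))
  }
  total_s <- config$baseline_s + config$stimulus_s
  ps <- pnn50_stream(rri)
  aligned <- align_streams(eeg, ps, 0, total_s)
  baseline <- baseline_profile(
    aligned[aligned$t_sec < config$baseline_s, , drop = FALSE])
  stim <- aligned[aligned$t_sec >= config$baseline_s, , drop = FALSE]
  norm <- normalize_affect(stim$arousal_raw, stim$valence_raw, baseline,
                           config$valence_normalization)
  aligned_norm <- data.frame(t_sec = stim$t_sec - config$baseline_s,
                             x_arousal = norm$arousal,
                             x_valence = norm$valence)
  estimates <- cumulative_estimate(
    data.frame(t_sec = aligned_norm$t_sec, valence = aligned_norm$x_valence,
               arousal = aligned_norm$x_arousal),
    duration_s = config$stimulus_s, tick_interval = config$tick_interval_s)
  expressions <- select_expression(estimates, config$condition)
  dataset <- suppressWarnings(
    build_dataset(aligned_norm, clicks, lookback = config$lookback_s,
                  first_click_only = config$first_click_only))

  out <- list(aligned = aligned, baseline = baseline,
              aligned_norm = aligned_norm, estimates = estimates,
              expressions = expressions, dataset = dataset)
  if (nrow(dataset) >= 2 && length(unique(dataset$y)) == 2) {
    model <- fit_logistic(dataset)
    counts <- confusion_counts(model, dataset)
    out$model <- model
    out$counts <- counts
    out$metrics <- list(TP = counts$TP, FP = counts$FP, FN = counts$FN,
                        TN = counts$TN, ACC = accuracy(counts),
                        group = assign_group(dataset))
  }
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(aligned, file.path(d, "aligned.csv"), row.names = FALSE)
    utils::write.csv(estimates, file.path(d, "estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(expressions, file.path(d, "expressions.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset, file.path(d, "dataset.csv"), row.names = FALSE)
    if (!is.null(out$model)) {
      write_model_json(out$model, file.path(d, "model.json"))
      jsonlite::write_json(out$metrics, file.path(d, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  out
}

# map an affect_session to the log bundle build_personalized_policy() wants
session_bundle <- function(session) {
  list(pnn50 = session$aligned_norm$valence_raw,
       clicks = session$clicks,
       expressions = session$expressions)
}

like_ratio <- function(clicks) {
  if (nrow(clicks) == 0) return(NA_real_)
  mean(clicks$polarity == "like")
}

#' Run the personalization follow-up on three condition sessions
#'
#' Builds the personalized policy from the three fixed-condition sessions
#' (highest-average-pNN50 condition, expressions active at Like clicks),
#' replays a fresh session under that policy, and reports per-condition
#' like/dislike frequencies together with the chi-square test of
#' click-condition association.
#'
#' The replayed session's physiological signal follows the chosen
#' condition's stimulus spec plus `personalized_boost` on the target pNN50:
#' the personalized robot shows the liked expression in every frame rather
#' than intermittently, so the valence response is modeled as at least as
#' strong as in the originating condition.
#'
#' @param main_sessions named list of `affect_session` objects for
#'   `synchronized`, `inversely_synchronized` and `funny`.
#' @param part a [participant_spec()] for the replayed session.
#' @param personalized_boost additive increment on the chosen condition's
#'   target pNN50 for the replay (default 0.1, clamped to \[0, 1\]).
#' @param seed seed for the replayed session (default derived from the
#'   participant seed).
#' @return List of class `followup_report`: `policy`, `personalized_session`,
#'   `click_table` (4 x 2 like/dislike counts), `like_ratios`, and
#'   `association` (chi-square result, or `NULL` with `association_note`
#'   when the table is degenerate).
#' @export
run_followup <- function(main_sessions, part, personalized_boost = 0.1,
                         seed = NULL) {
  absent <- setdiff(EXPRESSION_CONDITIONS, names(main_sessions))
  if (length(absent) > 0) {
    ra_stop(sprintf("missing condition session(s): %s",
                    paste(absent, collapse = ", ")),
            "roboaffect_empty_input", missing = absent)
  }
  policy <- build_personalized_policy(
    lapply(main_sessions[EXPRESSION_CONDITIONS], session_bundle),
    frame_s = main_sessions[[1]]$tick_interval)

  chosen <- main_sessions[[policy$chosen_condition]]
  replay_signal <- chosen$signal
  replay_signal$target_pnn50 <- clamp(
    replay_signal$target_pnn50 + personalized_boost, 0, 1)
  seed <- seed %||% (part$seed + 7919L)
  personalized <- generate_session(
    part, replay_signal, condition = "personalized", policy = policy,
    baseline_signal = chosen$baseline_signal,
    baseline_s = chosen$baseline_s, stimulus_s = chosen$stimulus_s,
    tick_interval = chosen$tick_interval, seed = seed)

  all_sessions <- c(main_sessions[EXPRESSION_CONDITIONS],
                    list(personalized = personalized))
  tab <- t(vapply(all_sessions, function(s) {
    c(like = sum(s$clicks$polarity == "like"),
      dislike = sum(s$clicks$polarity == "dislike"))
  }, c(like = 0, dislike = 0)))
  ratios <- vapply(all_sessions, function(s) like_ratio(s$clicks), numeric(1))

  association <- NULL
  note <- NULL
  assoc_try <- tryCatch(click_association_test(tab),
                        roboaffect_degenerate_table = function(e) e)
  if (inherits(assoc_try, "condition")) {
    note <- conditionMessage(assoc_try)
  } else {
    association <- assoc_try
  }
  structure(
    list(policy = policy, personalized_session = personalized,
         click_table = tab, like_ratios = ratios,
         association = association, association_note = note),
    class = "followup_report"
  )
}

#' @export
print.followup_report <- function(x, ...) {
  cat(sprintf("<followup_report> chosen condition: %s\n",
              x$policy$chosen_condition))
  cat("  like ratios:",
      paste(sprintf("%s %.2f", names(x$like_ratios), x$like_ratios),
            collapse = ", "), "\n")
  if (!is.null(x$association)) {
    cat(sprintf("  association: X2(%d) = %.2f, p = %.3g\n",
                x$association$df, x$association$statistic,
                x$association$p_value))
  } else {
    cat("  association test not computable:", x$association_note, "\n")
  }
  invisible(x)
}

#' Simulate the whole study for one participant
#'
#' Generates the three fixed-condition sessions with per-condition stimulus
#' signal specs (the paper-style main experiment) and then runs the
#' personalization follow-up via [run_followup()].
#'
#' @param part a [participant_spec()].
#' @param condition_signals named list of [signal_spec()]s for
#'   `synchronized`, `inversely_synchronized`, `funny`; a default set with
#'   pNN50 targets 0.40 / 0.22 / 0.30 is used when omitted.
#' @param personalized_boost passed to [run_followup()].
#' @param seed base seed; per-session seeds are derived from it.
#' @return List with `sessions` (the three main sessions) and `followup`
#'   (the [run_followup()] report).
#' @export
simulate_followup_study <- function(part, condition_signals = NULL,
                                    personalized_boost = 0.1,
                                    seed = part$seed) {
  if (is.null(condition_signals)) {
    condition_signals <- list(
      synchronized = signal_spec(75, target_pnn50 = 0.40,
                                 target_arousal = 15),
      inversely_synchronized = signal_spec(75, target_pnn50 = 0.22,
                                           target_arousal = -10),
      funny = signal_spec(75, target_pnn50 = 0.30, target_arousal = 25)
    )
  }
  sessions <- list()
  for (i in seq_along(EXPRESSION_CONDITIONS)) {
    cond <- EXPRESSION_CONDITIONS[i]
    sessions[[cond]] <- generate_session(
      part, condition_signals[[cond]], condition = cond,
      seed = (seed + i * 1009L) %% .Machine$integer.max)
  }
  followup <- run_followup(sessions, part,
                           personalized_boost = personalized_boost,
                           seed = (seed + 4L * 1009L) %% .Machine$integer.max)
  list(sessions = sessions, followup = followup)
}
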