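#' Diagonal opposite of an emotion on the circumplex
#'
#' happy and sad swap, angry and relaxed swap. An involution on the four
#' quadrant labels; the funny expression has no inverse.
#'
#' @param label character vector of emotion labels
#'   (`happy`, `angry`, `sad`, `relaxed`).
#' @return The opposite label(s).
#' @examples
#' invert_emotion("sad")   # "happy"
#' invert_emotion("angry") # "relaxed"
#' @export
invert_emotion <- function(label) {
  map <- c(happy = "sad", sad = "happy", angry = "relaxed", relaxed = "angry")
  bad <- !(label %in% names(map))
  if (any(bad)) {
    ra_stop(
      sprintf("no circumplex inverse for label(s): %s",
              paste(unique(label[bad]), collapse = ", ")),
      "roboaffect_domain_error", field = "label"
    )
  }
  unname(map[label])
}

#' Select a robot expression command under a fixed condition
#'
#' Converts emotion estimates into symbolic expression commands. Under
#' `synchronized` the robot mirrors the estimated emotion; under
#' `inversely_synchronized` it shows the diagonal opposite; under `funny`
#' it always shows the funny expression. In every condition the intensity
#' level is taken live from the estimate.
#'
#' @param estimate data frame of estimates from [cumulative_estimate()]
#'   (columns `t_sec`, `label`, `intensity_level`).
#' @param condition one of `"synchronized"`, `"inversely_synchronized"`,
#'   `"funny"`.
#' @return Data frame with columns `t_sec`, `condition`, `expression`,
#'   `intensity_level`.
#' @examples
#' est <- data.frame(t_sec = 2.5, label = "sad", intensity_level = 3L)
#' select_expression(est, "inversely_synchronized")  # happy, level 3
#' @export
select_expression <- function(estimate, condition) {
  if (length(condition) != 1 || !condition %in% EXPRESSION_CONDITIONS) {
    ra_stop(
      sprintf("unknown expression condition: %s",
              paste(condition, collapse = ", ")),
      "roboaffect_config_error", field = "condition"
    )
  }
  expression <- switch(condition,
    synchronized = estimate$label,
    inversely_synchronized = invert_emotion(estimate$label),
    funny = rep("funny", nrow(estimate))
  )
  data.frame(t_sec = estimate$t_sec, condition = condition,
             expression = expression,
             intensity_level = as.integer(estimate$intensity_level))
}

# expression command active in the display frame containing time t;
# frames are half-open [t_cmd, t_cmd + frame_s)
expression_at <- function(expressions, t, frame_s = 2.5) {
  idx <- findInterval(t, expressions$t_sec)
  ok <- idx > 0 & t < expressions$t_sec[pmax(idx, 1)] + frame_s
  idx[!ok] <- NA_integer_
  idx
}

#' Build a personalized expression policy from prior condition sessions
#'
#' The personalization rule: (1) pick the condition whose session had the
#' highest average stimulus-window pNN50 (ties resolved by the fixed
#' priority synchronized > inversely_synchronized > funny); (2) collect the
#' expression commands that were on display during the 2.5 s frame
#' containing each "Like" click of that session.
#'
#' @param sessions named list (names are conditions) of session logs; each
#'   must contain `pnn50` (numeric vector or data frame with a `pnn50` or
#'   `valence_raw` column of stimulus-window pNN50 values), `clicks` (data
#'   frame `t_sec`, `polarity`) and `expressions` (data frame `t_sec`,
#'   `expression`, `intensity_level`).
#' @param frame_s display-frame length in seconds (default 2.5).
#' @return List of class `personalized_policy` with `chosen_condition`,
#'   `mean_pnn50` (per condition), `liked_expressions` (data frame `t_sec`,
#'   `expression`, `intensity_level`, ordered by click time) and `fallback`
#'   (condition delegated to when no likes were recorded).
#' @export
build_personalized_policy <- function(sessions, frame_s = 2.5) {
  if (length(sessions) == 0) {
    ra_stop("at least one condition session is required",
            "roboaffect_empty_input")
  }
  conds <- names(sessions)
  if (is.null(conds) || !all(conds %in% EXPRESSION_CONDITIONS)) {
    ra_stop("sessions must be named by expression condition",
            "roboaffect_config_error", field = "sessions")
  }
  pnn50_of <- function(x) {
    if (is.data.frame(x)) {
      if ("pnn50" %in% names(x)) x$pnn50 else x$valence_raw
    } else as.numeric(x)
  }
  means <- vapply(sessions, function(s) mean(pnn50_of(s$pnn50)), numeric(1))
  # argmax with fixed priority order on ties
  ordered <- intersect(EXPRESSION_CONDITIONS, conds)
  chosen <- ordered[which.max(means[ordered])]

  ses <- sessions[[chosen]]
  likes <- ses$clicks[ses$clicks$polarity == "like", , drop = FALSE]
  liked <- data.frame(t_sec = numeric(0), expression = character(0),
                      intensity_level = integer(0))
  if (nrow(likes) > 0 && nrow(ses$expressions) > 0) {
    idx <- expression_at(ses$expressions, likes$t_sec, frame_s = frame_s)
    hit <- !is.na(idx)
    liked <- data.frame(
      t_sec = likes$t_sec[hit],
      expression = ses$expressions$expression[idx[hit]],
      intensity_level = as.integer(ses$expressions$intensity_level[idx[hit]])
    )
    liked <- liked[order(liked$t_sec), , drop = FALSE]
    rownames(liked) <- NULL
  }
  structure(
    list(chosen_condition = chosen, mean_pnn50 = means,
         liked_expressions = liked, fallback = chosen),
    class = "personalized_policy"
  )
}

#' @export
print.personalized_policy <- function(x, ...) {
  cat(sprintf("<personalized_policy> chosen: %s (%d liked expression(s))\n",
              x$chosen_condition, nrow(x$liked_expressions)))
  invisible(x)
}

#' Select expressions under a personalized policy
#'
#' Replays the modal liked expression label (ties broken by the most recent
#' like) with the intensity level of the current estimate. With no recorded
#' likes the policy delegates to its fallback condition.
#'
#' @param policy a [build_personalized_policy()] result.
#' @param estimate estimates data frame as for [select_expression()].
#' @return Data frame `t_sec`, `condition` (`"personalized"`), `expression`,
#'   `intensity_level`.
#' @export
personalized_expression <- function(policy, estimate) {
  liked <- policy$liked_expressions
  if (nrow(liked) == 0) {
    out <- select_expression(estimate, policy$fallback)
    out$condition <- "personalized"
    return(out)
  }
  counts <- table(liked$expression)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) {
    # most recent like among the tied labels wins
    recency <- vapply(top, function(lab) max(liked$t_sec[liked$expression == lab]),
                      numeric(1))
    top <- top[which.max(recency)]
  }
  data.frame(t_sec = estimate$t_sec, condition = "personalized",
             expression = top,
             intensity_level = as.integer(estimate$intensity_level))
}
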