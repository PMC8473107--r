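# internal helpers shared across modules

ra_stop <- function(message, class, ...) {
  cond <- errorCondition(message, ..., class = c(class, "roboaffect_error"))
  stop(cond)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical condition labels, in tie-break priority order
EXPRESSION_CONDITIONS <- c("synchronized", "inversely_synchronized", "funny")
EMOTION_LABELS <- c("happy", "angry", "sad", "relaxed")
EXPRESSION_LABELS <- c(EMOTION_LABELS, "funny")
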