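#' Label aligned seconds from like/dislike clicks
#'
#' Each click claims the 30 s of biosignal data preceding it: second `t`
#' receives the polarity of the earliest click `c` with
#' `c$t_sec - lookback <= t < c$t_sec`. Each second belongs to at most one
#' window (the earlier click wins on overlap); seconds inside no window are
#' dropped. `first_click_only = TRUE` restricts labeling to the window of
#' the first click.
#'
#' @param aligned data frame of normalized aligned samples with columns
#'   `t_sec`, `x_arousal`, `x_valence` (columns `arousal` / `valence` are
#'   accepted and renamed).
#' @param clicks data frame with columns `t_sec`, `polarity`
#'   (`"like"` / `"dislike"`).
#' @param lookback window length in seconds before each click (default 30).
#' @param first_click_only use only the first click's window.
#' @return Data frame with columns `t_sec`, `x_arousal`, `x_valence`,
#'   `y` (1 = like, 0 = dislike) and `click_id` (index of the claiming
#'   click). Empty (with a warning) when there are no clicks.
#' @export
build_dataset <- function(aligned, clicks, lookback = 30, first_click_only = FALSE) {
  if (!"x_arousal" %in% names(aligned) && "arousal" %in% names(aligned)) {
    aligned$x_arousal <- aligned$arousal
  }
  if (!"x_valence" %in% names(aligned) && "valence" %in% names(aligned)) {
    aligned$x_valence <- aligned$valence
  }
  empty <- data.frame(t_sec = numeric(0), x_arousal = numeric(0),
                      x_valence = numeric(0), y = integer(0),
                      click_id = integer(0))
  if (is.null(clicks) || nrow(clicks) == 0) {
    warning("no clicks: empty preference dataset", call. = FALSE)
    return(empty)
  }
  clicks <- clicks[order(clicks$t_sec), , drop = FALSE]
  if (first_click_only) clicks <- clicks[1, , drop = FALSE]

  claimed_by <- rep(NA_integer_, nrow(aligned))
  for (i in seq_len(nrow(clicks))) {
    ct <- clicks$t_sec[i]
    in_win <- aligned$t_sec >= ct - lookback & aligned$t_sec < ct
    claimed_by[in_win & is.na(claimed_by)] <- i
  }
  keep <- !is.na(claimed_by)
  if (!any(keep)) {
    warning("no aligned seconds fall in any click window", call. = FALSE)
    return(empty)
  }
  data.frame(
    t_sec = aligned$t_sec[keep],
    x_arousal = aligned$x_arousal[keep],
    x_valence = aligned$x_valence[keep],
    y = as.integer(clicks$polarity[claimed_by[keep]] == "like"),
    click_id = claimed_by[keep]
  )
}

#' Fit the logistic-regression preference model
#'
#' Maximum-likelihood logistic regression of the like/dislike label on
#' normalized arousal and valence, fitted by iteratively reweighted least
#' squares (Newton-Raphson). A small ridge penalty (`lambda = 1e-6`)
#' guarantees a finite optimum under complete separation. Convergence is
#' declared when the max-norm of the penalized score drops below `tol`.
#'
#' @param data data frame with columns `x_arousal`, `x_valence` and binary
#'   `y` (1 = like, 0 = dislike).
#' @param lambda ridge penalty on the coefficients (intercept included).
#' @param tol gradient max-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return Object of class `preference_model`: list with `beta0`,
#'   `beta_arousal`, `beta_valence`, `converged`, `n_samples`,
#'   `n_iter`.
#' @export
fit_logistic <- function(data, lambda = 1e-6, tol = 1e-8, max_iter = 100L) {
  if (is.null(data) || nrow(data) < 2) {
    ra_stop("at least 2 samples are required to fit the preference model",
            "roboaffect_insufficient_data")
  }
  y <- as.numeric(data$y)
  if (!all(y %in% c(0, 1))) {
    ra_stop("labels must be binary 0/1", "roboaffect_degenerate_labels")
  }
  if (length(unique(y)) < 2) {
    ra_stop("both like and dislike labels are required",
            "roboaffect_degenerate_labels")
  }
  X <- cbind(1, data$x_arousal, data$x_valence)
  beta <- c(0, 0, 0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - p)) - lambda * beta
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X, X * w) + diag(lambda, 3)
    beta <- beta + solve(H, grad)
  }
  if (!converged) {
    # re-check score at the final iterate
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    converged <- max(abs(drop(crossprod(X, y - p)) - lambda * beta)) < tol
  }
  structure(
    list(beta0 = beta[1], beta_arousal = beta[2], beta_valence = beta[3],
         converged = converged, n_samples = nrow(data), n_iter = iter),
    class = "preference_model"
  )
}

#' @export
print.preference_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<preference_model> logit(p_like) = %.3f %+.3f*arousal %+.3f*valence\n",
    "  n = %d, converged: %s\n"),
    x$beta0, x$beta_arousal, x$beta_valence, x$n_samples, x$converged))
  invisible(x)
}

#' Predicted like probability
#'
#' `p = 1 / (1 + exp(-(beta0 + beta_arousal * x_arousal +
#' beta_valence * x_valence)))`.
#'
#' @param object a fitted `preference_model`.
#' @param newdata data frame with columns `x_arousal`, `x_valence`; or pass
#'   `x_arousal` / `x_valence` vectors directly.
#' @param x_arousal,x_valence numeric feature vectors (used when `newdata`
#'   is missing).
#' @param ... unused.
#' @return Probabilities in (0, 1).
#' @export
predict.preference_model <- function(object, newdata = NULL,
                                     x_arousal = NULL, x_valence = NULL, ...) {
  if (!is.null(newdata)) {
    x_arousal <- newdata$x_arousal
    x_valence <- newdata$x_valence
  }
  eta <- object$beta0 + object$beta_arousal * x_arousal +
    object$beta_valence * x_valence
  1 / (1 + exp(-eta))
}

#' Confusion-matrix counts for a preference model
#'
#' Classifies at threshold 0.5 ("like" when the predicted probability
#' exceeds it) and tabulates against the observed labels. In
#' `"per_sample"` mode every labeled second is one case; in `"per_click"`
#' mode the features are first averaged within each click's window, giving
#' one case per click.
#'
#' @param model a fitted `preference_model`.
#' @param data labeled dataset from [build_dataset()].
#' @param threshold classification threshold (default 0.5).
#' @param mode `"per_sample"` or `"per_click"`.
#' @return List of class `confusion_counts`: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(model, data, threshold = 0.5,
                             mode = c("per_sample", "per_click")) {
  mode <- match.arg(mode)
  if (mode == "per_click") {
    if (!"click_id" %in% names(data)) {
      ra_stop("per_click mode needs a click_id column",
              "roboaffect_config_error", field = "click_id")
    }
    agg <- aggregate(cbind(x_arousal, x_valence, y) ~ click_id,
                     data = data, FUN = mean)
    data <- agg
  }
  p <- predict(model, newdata = data)
  pred <- as.integer(p > threshold)
  obs <- as.integer(data$y > 0.5)
  structure(
    list(TP = sum(pred == 1 & obs == 1), FP = sum(pred == 1 & obs == 0),
         FN = sum(pred == 0 & obs == 1), TN = sum(pred == 0 & obs == 0)),
    class = "confusion_counts"
  )
}

#' Classification accuracy from confusion counts
#'
#' `ACC = (TP + TN) / (TP + FP + FN + TN)`.
#'
#' @param counts a `confusion_counts` object, or TP when giving the four
#'   counts positionally.
#' @param FP,FN,TN remaining counts when `counts` is given as TP.
#' @return Accuracy in \[0, 1\].
#' @examples
#' accuracy(8, 2, 2, 8)  # 0.8
#' @export
accuracy <- function(counts, FP = NULL, FN = NULL, TN = NULL) {
  if (inherits(counts, "confusion_counts")) {
    TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  } else {
    TP <- counts
  }
  total <- TP + FP + FN + TN
  if (is.na(total) || total < 1) {
    ra_stop("confusion counts are empty", "roboaffect_empty_counts")
  }
  if (any(c(TP, FP, FN, TN) < 0)) {
    ra_stop("confusion counts must be non-negative", "roboaffect_domain_error",
            field = "counts")
  }
  (TP + TN) / total
}

#' Assign a participant to one of five preference groups
#'
#' Summarizes where on the circumplex plane the participant's "like" clicks
#' concentrate, via the centroid of like-labeled samples, and applies the
#' rule table (threshold `theta`, rules in order):
#' \enumerate{
#'   \item high arousal, mid valence (`a > theta`, `|v| <= theta`) - group 1;
#'   \item relaxed (low arousal), mid valence - group 2;
#'   \item high pleasure and non-positive arousal (`v > theta`, `a <= 0`) -
#'     group 3;
#'   \item low pleasure and concentration (`v < -theta`, `a > 0`) - group 4;
#'   \item others (middle range of pleasure) - group 5.
#' }
#'
#' @param data labeled dataset with `x_arousal`, `x_valence`, `y`.
#' @param theta centroid threshold (default 0.25).
#' @return Integer group in `1..5`.
#' @export
assign_group <- function(data, theta = 0.25) {
  likes <- data[data$y == 1, , drop = FALSE]
  if (nrow(likes) == 0) {
    ra_stop("no like-labeled samples: participant cannot be grouped",
            "roboaffect_ungroupable")
  }
  a <- mean(likes$x_arousal)
  v <- mean(likes$x_valence)
  if (a > theta && abs(v) <= theta) return(1L)
  if (a < -theta && abs(v) <= theta) return(2L)
  if (v > theta && a <= 0) return(3L)
  if (v < -theta && a > 0) return(4L)
  5L
}

#' Chi-square test of click-condition association
#'
#' Pearson chi-square test of independence between expression condition and
#' click polarity on a k x 2 frequency table (conditions in rows, like /
#' dislike in columns), without continuity correction.
#'
#' @param counts k x 2 matrix (or data frame) of non-negative click counts;
#'   all row and column sums must be positive.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
click_association_test <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2 || nrow(m) < 2) {
    ra_stop("a k x 2 table with k >= 2 is required",
            "roboaffect_degenerate_table")
  }
  if (any(m < 0) || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    ra_stop("table has a zero (or negative) marginal",
            "roboaffect_degenerate_table")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
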