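aligned75 <- function() {
  data.frame(t_sec = 0:74, x_arousal = seq(-0.5, 0.5, length.out = 75),
             x_valence = seq(0.3, -0.3, length.out = 75))
}

test_that("a single click claims the 30 s before it", {
  clicks <- data.frame(t_sec = 40, polarity = "like")
  ds <- build_dataset(aligned75(), clicks)
  expect_equal(nrow(ds), 30)
  expect_equal(ds$t_sec, 10:39)
  expect_true(all(ds$y == 1))
})

test_that("overlapping windows give priority to the earlier click", {
  clicks <- data.frame(t_sec = c(20, 35), polarity = c("like", "dislike"))
  ds <- build_dataset(aligned75(), clicks)
  # like window clipped at session start: [0, 20); dislike gets the rest of
  # [5, 35) not already claimed, i.e. [20, 35)
  expect_equal(ds$t_sec[ds$y == 1], 0:19)
  expect_equal(ds$t_sec[ds$y == 0], 20:34)
  expect_equal(ds$click_id[ds$y == 0], rep(2L, 15))
})

test_that("clicks outside the window and empty click logs yield no samples", {
  expect_warning(
    ds <- build_dataset(aligned75(), data.frame(t_sec = 200, polarity = "like")),
    "no aligned seconds")
  expect_equal(nrow(ds), 0)
  expect_warning(
    ds <- build_dataset(aligned75(),
                        data.frame(t_sec = numeric(0),
                                   polarity = character(0))),
    "no clicks")
  expect_equal(nrow(ds), 0)
})

test_that("samples never leave their click window; first-click-only mode works", {
  set.seed(77)
  for (rep in 1:10) {
    clicks <- data.frame(t_sec = sort(runif(4, 5, 74)),
                         polarity = sample(c("like", "dislike"), 4,
                                           replace = TRUE))
    ds <- build_dataset(aligned75(), clicks)
    expect_lte(nrow(ds), 30 * nrow(clicks))
    for (i in seq_len(nrow(ds))) {
      ct <- clicks$t_sec[ds$click_id[i]]
      expect_true(ds$t_sec[i] >= ct - 30 && ds$t_sec[i] < ct)
    }
  }
  clicks <- data.frame(t_sec = c(40, 70), polarity = c("dislike", "like"))
  ds1 <- build_dataset(aligned75(), clicks, first_click_only = TRUE)
  expect_equal(ds1$t_sec, 10:39)
  expect_true(all(ds1$y == 0))
})

test_that("fit_logistic recovers a null model and agrees with glm", {
  set.seed(13)
  d <- data.frame(x_arousal = runif(2000, -1, 1),
                  x_valence = runif(2000, -1, 1),
                  y = rbinom(2000, 1, 0.5))
  m <- fit_logistic(d)
  expect_true(m$converged)
  expect_lt(max(abs(c(m$beta0, m$beta_arousal, m$beta_valence))), 0.1)

  # independent cross-check of the IRLS fitter against stats::glm
  d2 <- simulate_preference_samples(500, c(-0.5, 1.5, -2), seed = 4)
  m2 <- fit_logistic(d2)
  ref <- stats::glm(y ~ x_arousal + x_valence, family = binomial, data = d2)
  expect_equal(c(m2$beta0, m2$beta_arousal, m2$beta_valence),
               unname(coef(ref)), tolerance = 1e-5)
})

test_that("fit_logistic survives complete separation via the ridge guard", {
  d <- data.frame(x_arousal = c(-1, -0.5, 0.5, 1),
                  x_valence = c(-1, -1, 1, 1), y = c(0, 0, 1, 1))
  m <- fit_logistic(d)
  expect_true(is.finite(m$beta0) && is.finite(m$beta_arousal) &&
                is.finite(m$beta_valence))
  p <- predict(m, d)
  expect_true(all((p > 0.5) == (d$y == 1)))
})

test_that("fit_logistic rejects degenerate inputs", {
  expect_error(fit_logistic(data.frame(x_arousal = 1, x_valence = 1, y = 1)),
               class = "roboaffect_insufficient_data")
  d <- data.frame(x_arousal = 1:4 / 4, x_valence = 1:4 / 4, y = rep(1, 4))
  expect_error(fit_logistic(d), class = "roboaffect_degenerate_labels")
})

test_that("predict implements the logistic law and is monotone", {
  m <- structure(list(beta0 = 0, beta_arousal = 0, beta_valence = 0),
                 class = "preference_model")
  expect_equal(predict(m, x_arousal = 3, x_valence = -2), 0.5)
  m$beta_arousal <- 1
  expect_equal(predict(m, x_arousal = 0, x_valence = 9), 0.5)
  xs <- seq(-5, 5, by = 0.5)
  ps <- predict(m, x_arousal = xs, x_valence = 0)
  expect_true(all(diff(ps) > 0))
  expect_gt(predict(m, x_arousal = 50, x_valence = 0), 1 - 1e-9)
})

test_that("accuracy follows the confusion-count formula", {
  expect_identical(accuracy(8, 2, 2, 8), 0.8)
  expect_identical(accuracy(5, 0, 0, 5), 1)
  expect_identical(accuracy(0, 3, 3, 0), 0)
  expect_error(accuracy(0, 0, 0, 0), class = "roboaffect_empty_counts")
})

test_that("accuracy is invariant under label flips", {
  set.seed(3)
  for (i in 1:20) {
    cnt <- sample(0:20, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    expect_identical(accuracy(cnt[1], cnt[2], cnt[3], cnt[4]),
                     accuracy(cnt[4], cnt[3], cnt[2], cnt[1]))
  }
})

test_that("confusion_counts supports per-sample and per-click evaluation", {
  d <- simulate_preference_samples(400, c(0, 2, 3), seed = 9)
  d$click_id <- rep(1:40, each = 10)
  d$y <- ave(d$y, d$click_id)  # make labels constant within a click
  d$y <- as.integer(d$y > 0.5)
  m <- fit_logistic(d)
  cs <- confusion_counts(m, d)
  expect_equal(cs$TP + cs$FP + cs$FN + cs$TN, 400)
  ck <- confusion_counts(m, d, mode = "per_click")
  expect_equal(ck$TP + ck$FP + ck$FN + ck$TN, 40)
})

test_that("assign_group applies the centroid rule table in order", {
  mk <- function(a, v) data.frame(x_arousal = a, x_valence = v,
                                  y = rep(1, length(a)))
  expect_equal(assign_group(mk(0.6, 0)), 1L)
  expect_equal(assign_group(mk(-0.5, 0.1)), 2L)
  expect_equal(assign_group(mk(-0.5, 0.5)), 3L)
  expect_equal(assign_group(mk(0.4, -0.5)), 4L)
  expect_equal(assign_group(mk(0.05, 0.02)), 5L)
  # deterministic and total on noisy like sets
  set.seed(19)
  for (i in 1:20) {
    d <- data.frame(x_arousal = runif(30, -1, 1),
                    x_valence = runif(30, -1, 1),
                    y = rbinom(30, 1, 0.5))
    if (!any(d$y == 1)) d$y[1] <- 1
    g <- assign_group(d)
    expect_true(g %in% 1:5)
    expect_identical(assign_group(d), g)
  }
  expect_error(assign_group(mk(numeric(0), numeric(0))),
               class = "roboaffect_ungroupable")
})

test_that("click_association_test matches closed-form and brute-force Pearson", {
  even <- matrix(c(10, 20, 5, 20, 40, 10), ncol = 2)
  res <- click_association_test(even)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  m22 <- matrix(c(10, 0, 0, 10), nrow = 2)
  res <- click_association_test(m22)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)

  set.seed(23)
  for (i in 1:10) {
    m <- matrix(rpois(8, 15) + 1, nrow = 4)
    res <- click_association_test(m)
    expect_equal(res$statistic, oracle_chisq(m), tolerance = 1e-10)
    expect_equal(res$df, 3)
  }
  expect_error(click_association_test(matrix(c(0, 0, 3, 4), nrow = 2)),
               class = "roboaffect_degenerate_table")
})
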