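test_that("generate_rri hits degenerate pNN50 targets exactly", {
  lo <- generate_rri(signal_spec(75, target_pnn50 = 0), seed = 1)
  expect_true(all(abs(diff(lo$rri_ms)) <= 45))
  expect_equal(pnn50_stream(lo)$pnn50, rep(0, nrow(lo) - 30))

  hi <- generate_rri(signal_spec(75, target_pnn50 = 1), seed = 2)
  expect_true(all(abs(diff(hi$rri_ms)) > 50))
  expect_equal(pnn50_stream(hi)$pnn50, rep(1, nrow(hi) - 30))
})

test_that("realized pNN50 tracks the target within 0.08", {
  s <- generate_rri(signal_spec(75, target_pnn50 = 0.4), seed = 7)
  expect_lt(abs(mean(pnn50_stream(s)$pnn50) - 0.4), 0.08)
  for (seed in 1:5) {
    s <- generate_rri(signal_spec(75, target_pnn50 = 0.6), seed = seed)
    expect_lt(abs(mean(pnn50_stream(s)$pnn50) - 0.6), 0.08)
  }
})

test_that("realized pNN50 is monotone in the target in expectation", {
  targets <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  means <- sapply(targets, function(q) {
    mean(sapply(1:20, function(seed) {
      mean(pnn50_stream(generate_rri(signal_spec(75, target_pnn50 = q),
                                     seed = seed))$pnn50)
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("generated streams respect type invariants", {
  for (seed in 1:5) {
    s <- generate_rri(signal_spec(75, target_pnn50 = 0.5), seed = seed)
    expect_true(all(s$rri_ms > 0))
    expect_true(all(diff(s$t_sec) > 0))
    expect_gte(s$t_sec[nrow(s)], 75)
    e <- generate_eeg(signal_spec(75, target_arousal = 80), seed = seed)
    expect_true(all(e$attention >= 0 & e$attention <= 100))
    expect_true(all(e$meditation >= 0 & e$meditation <= 100))
  }
})

test_that("generate_eeg hits the target arousal", {
  quiet <- generate_eeg(signal_spec(10, target_arousal = 0, eeg_noise_sd = 0),
                        seed = 1)
  expect_true(all(quiet$attention == 50 & quiet$meditation == 50))
  ext <- generate_eeg(signal_spec(10, target_arousal = 100, eeg_noise_sd = 0),
                      seed = 1)
  expect_true(all(ext$attention == 100 & ext$meditation == 0))
  e <- generate_eeg(signal_spec(75, target_arousal = 30), seed = 11)
  expect_lt(abs(mean(e$attention - e$meditation) - 30), 3)
})

test_that("spec validation rejects out-of-range targets", {
  expect_error(signal_spec(75, target_pnn50 = 1.2),
               class = "roboaffect_domain_error")
  expect_error(signal_spec(-5), class = "roboaffect_domain_error")
  expect_error(participant_spec(click_rate = 0),
               class = "roboaffect_domain_error")
})

test_that("generate_clicks follows the ground-truth logistic law", {
  aligned <- data.frame(t_sec = 0:74, x_arousal = 0, x_valence = 0)
  alllike <- generate_clicks(aligned,
                             participant_spec(c(10, 0, 0), click_rate = 24),
                             seed = 1)
  expect_true(all(alllike$polarity == "like"))

  set.seed(2)
  coin <- generate_clicks(aligned,
                          participant_spec(c(0, 0, 0), click_rate = 400))
  frac <- mean(coin$polarity == "like")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(coin)) + 0.02)

  # likes concentrate where valence is high under a valence-only preference
  ramp <- data.frame(t_sec = 0:74, x_arousal = 0,
                     x_valence = seq(-0.5, 0.5, length.out = 75))
  hits <- 0
  for (seed in 1:10) {
    cl <- generate_clicks(ramp, participant_spec(c(0, 0, 5), click_rate = 48),
                          seed = seed)
    early <- cl[cl$t_sec < 37.5, ]
    late <- cl[cl$t_sec >= 37.5, ]
    if (mean(late$polarity == "like") > mean(early$polarity == "like")) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("sessions follow the rest-then-stimulus protocol", {
  s <- make_test_session(seed = 5)
  # no clicks or commands during the baseline (times are stimulus-relative)
  expect_true(all(s$clicks$t_sec >= 0 & s$clicks$t_sec < 75))
  expect_equal(nrow(s$expressions), 30)
  expect_equal(s$expressions$t_sec, (1:30) * 2.5)
  expect_true(all(s$aligned_norm$t_sec == 0:74))
  # synchronized labels mirror the estimates
  expect_identical(s$expressions$expression, s$estimates$label)
})

test_that("sessions are byte-identical under a fixed seed", {
  s1 <- make_test_session(seed = 9)
  s2 <- make_test_session(seed = 9)
  expect_identical(s1$rri, s2$rri)
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$clicks, s2$clicks)
  d1 <- tempfile(); d2 <- tempfile()
  write_session_csv(s1, d1)
  write_session_csv(s2, d2)
  for (f in c("rri.csv", "eeg.csv", "clicks.csv", "expressions.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("end-to-end parameter recovery gets every nonzero sign right", {
  # seven stimuli spanning the affect plane, pooled per participant
  session_spec <- function(k) {
    signal_spec(75,
                target_pnn50 = c(0.2, 0.35, 0.5, 0.25, 0.45, 0.3, 0.4)[k],
                target_arousal = c(-25, 20, 0, 30, -15, 10, -30)[k])
  }
  hits <- 0
  for (seed in 1:10) {
    part <- participant_spec(true_beta = c(0, 2, 3), click_rate = 24,
                             seed = seed)
    pooled <- do.call(rbind, lapply(1:7, function(k) {
      s <- generate_session(part, session_spec(k), seed = seed * 100 + k)
      suppressWarnings(build_dataset(s$aligned_norm, s$clicks))
    }))
    expect_gte(nrow(pooled), 500)
    m <- fit_logistic(pooled)
    if (m$beta_arousal > 0 && m$beta_valence > 0) hits <- hits + 1
  }
  expect_equal(hits, 10)
})
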