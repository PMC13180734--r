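# Breath detection, IBIs, apnoea classification and rates.

test_that("respiratory band-pass has the required frequency response", {
  t <- (0:19999) / 62.5
  gain_at <- function(f) {
    y <- filter_ip(ip_signal(sin(2 * pi * f * t)))$samples
    max(abs(y[5000:15000]))
  }
  expect_gt(gain_at(1.0), 0.95)   # respiratory band preserved
  expect_lt(gain_at(2.3), 0.20)   # cardiac attenuated >= 80%
  dc <- filter_ip(ip_signal(rep(10, 20000)))$samples
  expect_lt(abs(mean(dc[5000:15000])), 1e-6)
  expect_error(filter_ip(ip_signal(rnorm(100))), "too short")
})

test_that("clean train detection is near-exact with sub-sample IBI error", {
  sim <- clean_ip(120, 60)
  br <- detect_breaths(filter_ip(sim$signal))
  expect_true(abs(nrow(br) - 120) <= 1)
  ibis <- extract_ibis(br)
  expect_true(all(abs(ibis$intervals - 1.0) <= 1 / 62.5))
  # recall/precision against truth peaks
  d <- outer(br$onset_time, sim$truth$breath_times,
             function(a, b) abs(a - b))
  recall <- mean(apply(d, 2, min) < 0.25)
  precision <- mean(apply(d, 1, min) < 0.25)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})

test_that("no breaths are detected inside an apnoeic gap", {
  sim <- clean_ip(180, 60, apnoeas = apnoea_spec(
    data.frame(onset_s = 80, duration_s = 20)))
  br <- detect_breaths(filter_ip(sim$signal))
  expect_false(any(br$onset_time > 81 & br$onset_time < 99))
  ibis <- extract_ibis(br)
  expect_equal(sum(ibis$intervals > 15), 1)
})

test_that("shallow breathing below the 0.4-SD rule is not detected", {
  sim <- clean_ip(240, 60, shallow = data.frame(onset_s = 100,
                                                duration_s = 30,
                                                factor = 0.2))
  br <- detect_breaths(filter_ip(sim$signal))
  expect_false(any(br$onset_time > 102 & br$onset_time < 128))
})

test_that("detection is invariant to amplitude rescaling", {
  sim <- simulate_ip(300, 55, apnoeas = apnoea_spec(
    data.frame(onset_s = 150, duration_s = 20)), seed = 11)
  f1 <- filter_ip(sim$signal)
  f2 <- ip_signal(sim$signal$samples * 50, fs = sim$signal$fs)
  b1 <- detect_breaths(f1)
  b2 <- detect_breaths(filter_ip(f2))
  expect_equal(b1$onset_time, b2$onset_time)
})

test_that("all-zero signal yields no breaths", {
  expect_equal(nrow(detect_breaths(ip_signal(rep(0, 10000)))), 0)
})

test_that("IBI extraction is the onset difference with validation", {
  ib <- extract_ibis(data.frame(onset_time = c(0, 1, 2, 3),
                                peak_amplitude = 1))
  expect_equal(ib$intervals, c(1, 1, 1))
  ib2 <- extract_ibis(data.frame(onset_time = c(0, 1, 21),
                                 peak_amplitude = 1))
  expect_equal(ib2$intervals, c(1, 20))
  expect_error(extract_ibis(data.frame(onset_time = c(0, 2, 1),
                                       peak_amplitude = 1)), "increasing")
  expect_error(extract_ibis(data.frame(onset_time = 0,
                                       peak_amplitude = 1)), "at least 2")
})

test_that("a 15.0-s IBI is not an apnoea candidate (strict threshold)", {
  ibis <- structure(list(intervals = c(1, 15.0, 15.2, 1),
                         interval_start_times = c(0, 1, 16, 31.2),
                         total_duration_h = 32.2 / 3600, n_ibis = 4L),
                    class = "ibi_series")
  ev <- classify_long_ibis(ibis, ip_signal(rep(0.1, 3000)), clf = NULL)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 15.2)
})

test_that("the classifier separates true apnoeas from shallow breathing", {
  clf <- get_test_classifier()
  expect_gte(clf$holdout_balanced_accuracy, 0.9)
  sim <- simulate_ip(300, 60,
                     apnoeas = apnoea_spec(data.frame(onset_s = 100,
                                                      duration_s = 20)),
                     noise = ip_noise_spec(white_sd = 0.06), seed = 21)
  f <- filter_ip(sim$signal)
  ev <- classify_long_ibis(extract_ibis(detect_breaths(f)), f, clf)
  expect_equal(ev$label, "apnoea")

  sim2 <- simulate_ip(300, 60, noise = ip_noise_spec(white_sd = 0.06),
                      shallow = data.frame(onset_s = 100, duration_s = 22,
                                           factor = 0.2), seed = 22)
  f2 <- filter_ip(sim2$signal)
  ev2 <- classify_long_ibis(extract_ibis(detect_breaths(f2)), f2, clf)
  expect_equal(ev2$label, "rejected_noise_or_shallow")
})

test_that("conflicting identical features give chance-level accuracy", {
  feats <- matrix(rep(c(1, 2, 3), each = 40), ncol = 3)
  labs <- rep(c("apnoea", "rejected_noise_or_shallow"), 20)
  clf <- train_apnoea_classifier(feats, labs, seed = 1)
  expect_lt(abs(clf$holdout_balanced_accuracy - 0.5), 0.15)
})

test_that("classifier training requires both classes and is deterministic", {
  feats <- matrix(rnorm(60), ncol = 3)
  expect_error(train_apnoea_classifier(feats, rep("apnoea", 20)),
               "both classes")
  ts <- make_apnoea_training_set(6, seed = 5)
  c1 <- train_apnoea_classifier(ts$features, ts$labels, seed = 9)
  c2 <- train_apnoea_classifier(ts$features, ts$labels, seed = 9)
  expect_identical(c1$holdout_balanced_accuracy, c2$holdout_balanced_accuracy)
})

test_that("respiratory rate is 60 over the median IBI", {
  mk <- function(iv) structure(list(intervals = iv,
                                    interval_start_times = cumsum(c(0, iv[-length(iv)])),
                                    total_duration_h = sum(iv) / 3600,
                                    n_ibis = length(iv)),
                               class = "ibi_series")
  expect_equal(respiratory_rate(mk(rep(1.5, 10))), 40)
  expect_equal(respiratory_rate(mk(c(1, 1, 1, 20))), 60)
  # brute-force median oracle on random series
  set.seed(31)
  for (r in 1:200) {
    iv <- stats::rlnorm(sample(3:50, 1), 0, 0.4)
    srt <- sort(iv)
    n <- length(srt)
    med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
    expect_equal(respiratory_rate(mk(iv)), 60 / med)
  }
})

test_that("apnoea rate and QC follow their definitions", {
  ev <- data.frame(start_time = c(1, 2, 3, 4), duration = 16,
                   label = "apnoea")
  expect_equal(apnoea_rate(ev, 2), 2.0)
  expect_equal(apnoea_rate(ev[0, ], 2), 0.0)
  expect_error(apnoea_rate(ev, 0), "positive")
  mk <- function(n) structure(list(intervals = rep(1, n),
                                   interval_start_times = seq_len(n) - 1,
                                   total_duration_h = n / 3600, n_ibis = n),
                              class = "ibi_series")
  expect_false(qc_recording(mk(99)))
  expect_true(qc_recording(mk(100)))
  expect_false(qc_recording(mk(0)))
})

test_that("inserted apnoeas are recovered end-to-end within one event", {
  clf <- get_test_classifier()
  sim <- simulate_ip(1800, 55,
                     apnoeas = apnoea_spec(data.frame(
                       onset_s = c(300, 900, 1500),
                       duration_s = c(18, 25, 30))),
                     noise = ip_noise_spec(), seed = 41)
  res <- analyse_respiration(sim$signal, clf)
  n_true <- 3
  n_det <- sum(res$events$label == "apnoea")
  expect_lte(abs(n_det - n_true), 1)
  expect_true(res$summary$qc_pass)
})

test_that("discarding rejected long IBIs never increases the apnoea count", {
  clf <- get_test_classifier()
  sim <- simulate_ip(900, 60,
                     apnoeas = apnoea_spec(data.frame(onset_s = 300,
                                                      duration_s = 20)),
                     noise = ip_noise_spec(white_sd = 0.06),
                     shallow = data.frame(onset_s = 600, duration_s = 22,
                                          factor = 0.2),
                     seed = 43)
  f <- filter_ip(sim$signal)
  ibis <- extract_ibis(detect_breaths(f))
  all_cand <- classify_long_ibis(ibis, f, clf = NULL)
  kept <- classify_long_ibis(ibis, f, clf)
  expect_lte(sum(kept$label == "apnoea"), nrow(all_cand))
})
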