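# Cohort and signal generators: determinism, stated moments, ground-truth
# consistency.

test_that("cohort has the study's structure and is seed-deterministic", {
  co <- simulate_cohort(cohort_params(seed = 1))
  occ <- co$occasions
  expect_equal(length(unique(occ$infant_id)), 74)
  expect_gt(nrow(occ), 115)
  expect_lt(nrow(occ), 165)
  expect_true(all(occ$pma_weeks >= 31 & occ$pma_weeks <= 36))
  expect_true(all(levels(occ$infection) == c("no", "suspected", "treated")))
  co2 <- simulate_cohort(cohort_params(seed = 1))
  expect_identical(co, co2)
  co3 <- simulate_cohort(cohort_params(seed = 2))
  expect_false(identical(co$occasions$gap, co3$occasions$gap))
})

test_that("degenerate gap distribution collapses to the mean", {
  co <- simulate_cohort(cohort_params(n_infants = 20, gap_sd = 0,
                                      gap_mean = 0, seed = 3))
  expect_true(all(co$truth$true_gap == 0))
})

test_that("gap moments match the generator law over a large cohort", {
  co <- simulate_cohort(cohort_params(n_infants = 6000, seed = 4))
  g <- co$truth$true_gap
  se_mean <- 0.91 / sqrt(length(g))
  expect_lt(abs(mean(g) - 0), 3 * se_mean)
  expect_lt(abs(stats::sd(g) - 0.91), 3 * 0.91 / sqrt(2 * length(g)))
})

test_that("OLS on generated truth recovers the apnoea-gap slope", {
  co <- simulate_cohort(cohort_params(n_infants = 4000, seed = 5))
  fit <- stats::lm(true_apnoea_rate ~ true_gap, data = co$truth)
  expect_lt(abs(stats::coef(fit)["true_gap"] - (-0.22)), 0.02)
})

test_that("non-finite cohort parameters are rejected", {
  expect_error(cohort_params(gap_sd = NaN), "finite")
  expect_error(cohort_params(infection_probs = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(cohort_params(n_infants = 0), ">= 1")
})

test_that("noise-free IP train has exact construction", {
  sim <- clean_ip(60, 60)
  expect_length(sim$truth$breath_times, 60)
  expect_true(all(abs(sim$truth$ibis - 1.0) < 1e-12))
  expect_equal(length(sim$signal$samples), 60 * 62.5)
})

test_that("inserted apnoeas and shallow windows appear in the truth", {
  sim <- clean_ip(120, 60, apnoeas = apnoea_spec(
    data.frame(onset_s = 50, duration_s = 20)))
  expect_equal(nrow(sim$truth$apnoeas), 1)
  expect_equal(sim$truth$apnoeas$duration_s, 20)
  # no breath peak inside the apnoeic window
  expect_false(any(sim$truth$breath_times > 50 &
                     sim$truth$breath_times < 70))
  expect_error(
    simulate_ip(30, 60, apnoeas = apnoea_spec(
      data.frame(onset_s = 10, duration_s = 40))),
    "inside the recording")
})

test_that("IP generation is deterministic given the seed", {
  a <- simulate_ip(120, 55, apnoeas = apnoea_spec(rate_per_h = 20), seed = 7)
  b <- simulate_ip(120, 55, apnoeas = apnoea_spec(rate_per_h = 20), seed = 7)
  expect_identical(a, b)
})

test_that("random apnoea generation yields only >15-s in-bounds events", {
  for (s in 1:5) {
    sim <- simulate_ip(3600, 55, apnoeas = apnoea_spec(rate_per_h = 6),
                       seed = s)
    ev <- sim$truth$apnoeas
    if (nrow(ev) > 0) {
      expect_true(all(ev$duration_s > 15))
      expect_true(all(ev$onset_s >= 0 & ev$onset_s + ev$duration_s <= 3600))
    }
    # IBI truth equals diff of breath-time truth
    expect_equal(sim$truth$ibis, diff(sim$truth$breath_times))
  }
})

test_that("SpO2 generator matches its spec", {
  s <- simulate_spo2(600, seed = 1)
  expect_gte(min(s$signal$samples), 85)
  s2 <- simulate_spo2(600, desats = data.frame(onset_s = 100, duration_s = 12,
                                               depth_pct = 75), seed = 1)
  expect_equal(nrow(s2$truth$desats), 1)
  expect_equal(s2$truth$desats$duration_s, 12)
  expect_error(simulate_spo2(60, desats = data.frame(
    onset_s = 10, duration_s = 5, depth_pct = -2)), "\\[0, 100\\]")
  expect_error(simulate_spo2(60, baseline = 80), "85")
})

test_that("NRF basis is orthonormal, deterministic, correctly sized", {
  b <- get_test_basis()
  G <- crossprod(b$waveforms)
  expect_lt(max(abs(G - diag(6))), 1e-10)
  b500 <- make_nrf_basis(fs = 500, window = c(-0.5, 1.0))
  expect_equal(nrow(b500$waveforms), 750)
  expect_identical(make_nrf_basis(fs = 250), make_nrf_basis(fs = 250))
})

test_that("noise-free single-component evoked epochs equal the template", {
  b <- get_test_basis()
  ev <- simulate_evoked(33, b, slope_age_map = function(a) c(2, 0, 0, 0, 0, 0),
                        subject_sd = 0, jitter_ms = 0, noise_sd = 0,
                        n_epochs = 4, seed = 1)
  tpl <- 2 * b$waveforms[, 1]
  for (i in 1:4) expect_equal(ev$visual$data[i, ], tpl, tolerance = 1e-12)
  expect_true(all(ev$tactile$data == 0))
})

test_that("artifact epochs exceed the 150-uV pre-stimulus bound at ~the requested rate", {
  b <- get_test_basis()
  pre <- b$time < 0
  counts <- vapply(1:20, function(s) {
    ev <- simulate_evoked(33, b, artifact_frac = 0.1, n_epochs = 20,
                          seed = 200 + s)
    sum(apply(abs(ev$visual$data[, pre]), 1, max) > 150)
  }, numeric(1))
  expect_gt(mean(counts), 0.8)
  expect_lt(mean(counts), 3.5)
})

test_that("epoch-average projections vary linearly with age", {
  b <- get_test_basis()
  ages <- seq(31, 36, by = 0.5)
  proj1 <- vapply(seq_along(ages), function(i) {
    ev <- simulate_evoked(ages[i], b, subject_sd = 0, jitter_ms = 0,
                          noise_sd = 1, n_epochs = 10, seed = 300 + i)
    mean(ev$visual$data %*% b$waveforms[, 1])
  }, numeric(1))
  fit <- stats::lm(proj1 ~ ages)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(abs(stats::coef(fit)["ages"] - 30), 2)  # generator gradient
})

test_that("resting EEG matures per the generator law and is reproducible", {
  r31 <- simulate_resting_eeg(31, duration_s = 300, fs = 64, seed = 9)
  r36 <- simulate_resting_eeg(36, duration_s = 300, fs = 64, seed = 9)
  expect_gt(mean(r31$truth$interburst_durations),
            mean(r36$truth$interburst_durations))
  # shared exponential draws: strictly longer interval-by-interval
  k <- min(length(r31$truth$interburst_durations),
           length(r36$truth$interburst_durations))
  expect_true(all(r31$truth$interburst_durations[1:k] >=
                    r36$truth$interburst_durations[1:k]))
  r <- simulate_resting_eeg(33, duration_s = 10, fs = 2000, seed = 2)
  expect_equal(nrow(r$rec$channels), 20000)
  expect_identical(simulate_resting_eeg(33, 60, fs = 64, seed = 5),
                   simulate_resting_eeg(33, 60, fs = 64, seed = 5))
})
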