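# Evoked-potential pipeline: filtering, epoching, rejection, Woody
# alignment, NRF slope regression and the sensory age model.

make_rec <- function(x, fs = 500, ann = data.frame(time_s = numeric(),
                                                   modality = character())) {
  eeg_recording(cbind(Oz = x, Cz = x), fs = fs, annotations = ann)
}

test_that("EEG preprocessing keeps the passband and removes offset", {
  fs <- 500
  t <- (0:(60 * fs - 1)) / fs
  mid <- (20 * fs):(40 * fs)
  g10 <- preprocess_eeg(make_rec(sin(2 * pi * 10 * t), fs))$channels[mid, "Oz"]
  expect_gt(max(abs(g10)), 0.95)
  g50 <- preprocess_eeg(make_rec(sin(2 * pi * 50 * t), fs))$channels[mid, "Oz"]
  expect_lt(max(abs(g50)), 0.10)
  gdc <- preprocess_eeg(make_rec(rep(7, length(t)), fs))$channels[mid, "Oz"]
  expect_lt(max(abs(gdc)), 0.05)
  expect_error(preprocess_eeg(make_rec(rnorm(100), fs)), "too short")
})

test_that("epoching baseline-corrects and skips edge annotations", {
  fs <- 250
  n <- 60 * fs
  x <- rep(5, n)
  ann <- data.frame(time_s = c(0.1, 10, 20), modality = "visual")
  expect_message(eps <- epoch_and_baseline(make_rec(x, fs, ann), "visual"),
                 "skipped")
  expect_equal(nrow(eps$data), 2)
  expect_true(all(abs(eps$data) < 1e-12))  # constant removed by baseline
  set.seed(1)
  xr <- rnorm(n)
  eps2 <- epoch_and_baseline(make_rec(xr, fs,
                                      data.frame(time_s = c(10, 30),
                                                 modality = "visual")),
                             "visual")
  pre_means <- rowMeans(eps2$data[, eps2$time < 0])
  expect_true(all(abs(pre_means) < 1e-9))
})

test_that("adding a constant to the recording changes nothing after baseline", {
  fs <- 250
  set.seed(2)
  x <- rnorm(30 * fs)
  ann <- data.frame(time_s = c(5, 15, 25), modality = "visual")
  e1 <- epoch_and_baseline(make_rec(x, fs, ann), "visual")
  e2 <- epoch_and_baseline(make_rec(x + 42, fs, ann), "visual")
  expect_equal(e1$data, e2$data)
})

test_that("artifact rejection uses a strict 150-uV pre-stimulus bound", {
  b <- get_test_basis()
  n <- length(b$time)
  pre_idx <- which(b$time < 0)[10]
  mk_ep <- function(val) {
    m <- matrix(0, 6, n)
    m[1, pre_idx] <- val
    epoch_set(m, b$time, b$fs, "visual")
  }
  expect_true(reject_artifacts(mk_ep(200))$kept[1] == FALSE)
  expect_true(all(reject_artifacts(mk_ep(150))$kept))  # exactly 150 kept
  expect_true(all(reject_artifacts(mk_ep(-200))$kept[-1]))
  # fewer than five surviving epochs flags unavailability
  m <- matrix(0, 6, n)
  m[1:2, pre_idx] <- 300
  eps <- reject_artifacts(epoch_set(m, b$time, b$fs, "visual"))
  expect_equal(sum(eps$kept), 4)
  expect_false(attr(eps, "available"))
})

test_that("Woody alignment recovers shifts, matching a brute-force oracle", {
  b <- get_test_basis()
  tpl <- as.numeric(b$waveforms[, 1:4] %*% c(60, 30, 15, 5))
  L <- round(50 / 1000 * b$fs)
  set.seed(3)
  for (shift_ms in c(0, 20, -36)) {
    k <- round(shift_ms / 1000 * b$fs)
    ep <- shift_vector(tpl, k) + rnorm(length(tpl), 0, 1)
    eps <- epoch_set(rbind(ep), b$time, b$fs, "visual")
    al <- woody_align(eps, template = tpl)
    # brute-force oracle over all admissible integer lags
    cc <- vapply(seq(-L, L), function(l) {
      sum(shift_vector(ep, l) * tpl)
    }, numeric(1))
    best <- seq(-L, L)[which.max(cc)]
    expect_equal(al$data[1, ], shift_vector(ep, best))
    expect_lte(abs(best + k), 1)  # recovered lag within one sample
  }
  # shifts beyond the 50-ms bound are clipped to the maximum admissible lag
  ep_far <- shift_vector(tpl, round(0.08 * b$fs))
  al <- woody_align(epoch_set(rbind(ep_far), b$time, b$fs, "visual"),
                    template = tpl)
  expect_equal(al$data[1, ], shift_vector(ep_far, -L))
  # alignment never changes the epoch count
  expect_equal(nrow(al$data), 1)
})

test_that("NRF slope regression matches the least-squares oracle", {
  b <- get_test_basis()
  n <- length(b$time)
  mk <- function(avg, modality) {
    epoch_set(matrix(rep(avg, 6), 6, n, byrow = TRUE), b$time, b$fs, modality)
  }
  # pure component on an orthonormal basis
  sl <- fit_nrf_slopes(mk(2 * b$waveforms[, 1], "visual"),
                       mk(0 * b$waveforms[, 5], "tactile"), b)
  expect_equal(sl, c(2, 0, 0, 0, 0, 0), tolerance = 1e-10)
  # noisy mixture vs explicit normal-equations oracle
  set.seed(4)
  avg_v <- b$waveforms[, 1] + 3 * b$waveforms[, 2] + rnorm(n, 0, 0.01)
  avg_t <- 2 * b$waveforms[, 5] + rnorm(n, 0, 0.01)
  sl2 <- fit_nrf_slopes(mk(avg_v, "visual"), mk(avg_t, "tactile"), b)
  phi_v <- b$waveforms[, 1:4]
  oracle_v <- solve(t(phi_v) %*% phi_v, t(phi_v) %*% avg_v)
  expect_equal(sl2[1:4], as.numeric(oracle_v), tolerance = 1e-9)
  expect_lt(max(abs(sl2[1:2] - c(1, 3))), 0.05)
  # zero response -> zero slopes
  sl0 <- fit_nrf_slopes(mk(rep(0, n), "visual"), mk(rep(0, n), "tactile"), b)
  expect_equal(sl0, rep(0, 6))
})

test_that("alignment does not worsen the fit on jittered epochs", {
  b <- get_test_basis()
  ev <- simulate_evoked(33, b, jitter_ms = 40, noise_sd = 2, n_epochs = 15,
                        subject_sd = 0, seed = 6)
  resid_of <- function(eps) {
    avg <- colMeans(eps$data)
    phi <- b$waveforms[, 1:4]
    sum((avg - phi %*% solve(crossprod(phi), crossprod(phi, avg)))^2)
  }
  aligned <- woody_align(ev$visual, basis = b)
  expect_lte(resid_of(aligned), resid_of(ev$visual))
})

test_that("sensory model recovers age; permuted ages are uninformative", {
  b <- get_test_basis()
  set.seed(7)
  ages <- runif(40, 31, 36)
  slopes <- t(vapply(seq_along(ages), function(i) {
    measure_slopes(ages[i], b, seed = 700 + i, n_epochs = 15,
                   artifact_frac = 0.1)
  }, numeric(6)))
  m <- train_sensory_model(slopes, ages, seed = 8)
  expect_lt(m$cv_mae, 1.0)
  expect_equal(predict_sensory_age(m, slopes[1, ]),
               predict_sensory_age(m, slopes[1, ]))
  # noise -> 0 limit: slopes become exact linear functions of age
  exact <- t(vapply(ages, default_slope_age_map, numeric(6)))
  m0 <- train_sensory_model(exact, ages, seed = 9)
  expect_lt(m0$cv_mae, 0.15)
  # permuted ages: CV error comparable to the null model (predict the mean)
  perm <- sample(ages)
  mp <- train_sensory_model(slopes, perm, seed = 10)
  null_mae <- mean(abs(perm - mean(perm)))
  expect_gt(mp$cv_mae, 0.6 * null_mae)
  expect_error(train_sensory_model(slopes, rep(33, 40)), "constant")
  expect_error(train_sensory_model(slopes[1:10, ], ages[1:10]), ">= 20")
})
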