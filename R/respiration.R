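# Breath and apnoea detection from impedance pneumography.
#
# Pipeline: zero-phase band-pass to the respiratory band, adaptive-threshold
# breath detection (0.4 x SD of the signal over the preceding 15 breaths),
# inter-breath intervals (IBIs), candidate apnoeas = IBIs strictly longer
# than 15 s, and a trained margin classifier that discards long IBIs caused
# by noise or shallow breathing.

APNOEA_THRESHOLD_S <- 15
MIN_IBIS_QC <- 100

#' Band-pass filter an impedance pneumography signal
#'
#' Zero-phase FIR band-pass (Hamming windowed-sinc, forward-backward)
#' retaining the respiratory band 0.1-2 Hz, attenuating baseline wander and
#' cardiac contamination (~2.3 Hz).
#'
#' @param sig an [ip_signal()].
#' @param band passband edges, Hz.
#' @param n_taps FIR length (odd); the default gives a ~0.26 Hz transition at
#'   62.5 Hz.
#' @return A filtered [ip_signal()] of the same length.
#' @export
filter_ip <- function(sig, band = c(0.1, 2), n_taps = 801) {
  abort_if(!inherits(sig, "ip_signal"), "`sig` must be an ip_signal")
  n <- length(sig$samples)
  abort_if(n <= 3 * n_taps,
           sprintf("signal too short for filter warm-up (need > %d samples)",
                   3 * n_taps))
  b <- signal::fir1(n_taps - 1, band / (sig$fs / 2), type = "pass")
  # demean first: DC sits inside the FIR transition band otherwise
  y <- signal::filtfilt(b, sig$samples - mean(sig$samples))
  ip_signal(as.numeric(y), fs = sig$fs, start_time = sig$start_time)
}

#' Detect individual breaths with an adaptive amplitude threshold
#'
#' Local maxima of the band-passed signal are accepted as breaths when their
#' height exceeds 0.4 times the standard deviation of the signal over the
#' span of the preceding 15 detected breaths. Before 15 breaths exist the
#' threshold is bootstrapped from the first 15 s of signal. Detection is
#' invariant to amplitude rescaling (the threshold is relative).
#'
#' @param sig a filtered [ip_signal()] (see [filter_ip()]).
#' @param k_sd threshold multiplier on the windowed SD.
#' @param n_breaths_window number of preceding breaths spanning the SD window.
#' @param refractory_s minimum separation between accepted breaths, seconds.
#' @return Data frame of breath events: `onset_time` (s, strictly
#'   increasing), `peak_amplitude`.
#' @export
detect_breaths <- function(sig, k_sd = 0.4, n_breaths_window = 15,
                           refractory_s = 0.25) {
  abort_if(!inherits(sig, "ip_signal"), "`sig` must be an ip_signal")
  x <- sig$samples
  n <- length(x)
  empty <- data.frame(onset_time = numeric(), peak_amplitude = numeric())
  if (n < 3 || all(x == 0)) return(empty)

  # candidate peaks: strict rise then non-rise, positive deflections only
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > 0]
  if (length(cand) == 0) return(empty)

  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  boot_i2 <- min(n, round(15 * sig$fs))
  sd_boot <- window_sd(cs, cs2, 1L, boot_i2)

  det_idx <- integer(0)
  refract <- round(refractory_s * sig$fs)
  for (i in cand) {
    nd <- length(det_idx)
    thr <- if (nd >= n_breaths_window) {
      k_sd * window_sd(cs, cs2, det_idx[nd - n_breaths_window + 1L], i)
    } else {
      k_sd * sd_boot
    }
    if (x[i] > thr) {
      if (nd > 0 && i - det_idx[nd] < refract) {
        if (x[i] > x[det_idx[nd]]) det_idx[nd] <- i
      } else {
        det_idx <- c(det_idx, i)
      }
    }
  }
  if (length(det_idx) == 0) return(empty)
  data.frame(onset_time = sig$start_time + (det_idx - 1) / sig$fs,
             peak_amplitude = x[det_idx])
}

#' Extract the inter-breath-interval series
#'
#' @param breaths data frame from [detect_breaths()] with strictly increasing
#'   `onset_time`.
#' @return A list of class `ibi_series`: `intervals` (s),
#'   `interval_start_times` (s), `total_duration_h`, `n_ibis`.
#' @export
extract_ibis <- function(breaths) {
  abort_if(nrow(breaths) < 2, "need at least 2 breaths to form intervals")
  on <- breaths$onset_time
  abort_if(any(diff(on) <= 0), "breath onsets must be strictly increasing")
  structure(list(intervals = diff(on),
                 interval_start_times = on[-length(on)],
                 total_duration_h = (on[length(on)] - on[1]) / 3600,
                 n_ibis = length(on) - 1L),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d IBIs over %.2f h (median %.2f s)\n",
              x$n_ibis, x$total_duration_h, stats::median(x$intervals)))
  invisible(x)
}

# Scale-invariant features of a candidate apnoea window, computed on the
# filtered signal: amplitude and variability inside the gap relative to the
# surrounding breathing, and the fraction of in-gap power in the respiratory
# band. Shared by training and classification.
apnoea_window_features <- function(sig, start_time, duration,
                                   margin_s = 1, context_s = 15) {
  fs <- sig$fs
  x <- sig$samples
  n <- length(x)
  clampi <- function(i) min(max(i, 1L), n)
  g1 <- clampi(round((start_time - sig$start_time + margin_s) * fs) + 1)
  g2 <- clampi(round((start_time - sig$start_time + duration - margin_s) * fs))
  if (g2 <= g1 + 4) {
    g1 <- clampi(round((start_time - sig$start_time) * fs) + 1)
    g2 <- clampi(round((start_time - sig$start_time + duration) * fs))
  }
  gap <- x[g1:g2]
  c1 <- clampi(g1 - round(context_s * fs))
  c2 <- clampi(g2 + round(context_s * fs))
  ctx <- c(x[c1:max(c1, g1 - 1)], x[min(n, g2 + 1):c2])
  rms <- function(v) sqrt(mean(v^2))
  ctx_rms <- max(rms(ctx), .Machine$double.eps)
  ctx_sd <- max(stats::sd(ctx), .Machine$double.eps)
  # fraction of in-gap spectral power in the respiratory band (0.3-1.5 Hz)
  sp <- Mod(stats::fft(gap - mean(gap)))^2
  m <- length(gap)
  freqs <- (seq_len(m) - 1) * fs / m
  half <- freqs <= fs / 2
  tot <- sum(sp[half])
  resp_frac <- if (tot > 0) {
    sum(sp[half & freqs >= 0.3 & freqs <= 1.5]) / tot
  } else {
    0
  }
  c(log_rms_ratio = log(rms(gap) / ctx_rms),
    log_sd_ratio = log(max(stats::sd(gap), .Machine$double.eps) / ctx_sd),
    resp_band_frac = resp_frac)
}

#' Train the apnoea-vs-artifact classifier
#'
#' Linear-kernel support vector machine on scale-invariant features of
#' candidate apnoea windows (relative RMS, relative SD, respiratory-band
#' power fraction). The published classifier's weights are not available, so
#' the classifier is trained on labelled synthetic segments (see
#' [make_apnoea_training_set()]).
#'
#' @param features numeric matrix (windows x 3), as returned by the feature
#'   extractor.
#' @param labels factor or character vector with levels `"apnoea"` and
#'   `"rejected_noise_or_shallow"`.
#' @param holdout_frac fraction held out to report balanced accuracy.
#' @param seed integer seed (holdout split).
#' @return A list of class `apnoea_classifier` with the fitted SVM and
#'   `holdout_balanced_accuracy`.
#' @export
train_apnoea_classifier <- function(features, labels, holdout_frac = 0.25,
                                    seed = 1L) {
  labels <- factor(labels,
                   levels = c("apnoea", "rejected_noise_or_shallow"))
  abort_if(nlevels(droplevels(labels)) < 2,
           "training set must contain both classes")
  features <- as.matrix(features)
  with_seed(seed, {
    idx_test <- unlist(lapply(levels(labels), function(l) {
      ii <- which(labels == l)
      sample(ii, max(1, round(length(ii) * holdout_frac)))
    }))
    scale_cols <- apply(features, 2, stats::sd) > 1e-12
    fit <- e1071::svm(x = features[-idx_test, , drop = FALSE],
                      y = droplevels(labels[-idx_test]),
                      kernel = "linear", scale = scale_cols)
    pred <- stats::predict(fit, features[idx_test, , drop = FALSE])
    obs <- labels[idx_test]
    recall <- vapply(levels(labels), function(l) {
      den <- sum(obs == l)
      if (den == 0) NA_real_ else sum(pred == l & obs == l) / den
    }, numeric(1))
    bal_acc <- mean(recall, na.rm = TRUE)
    # refit on everything for deployment
    fit_all <- e1071::svm(x = features, y = labels, kernel = "linear",
                          scale = scale_cols)
    structure(list(svm = fit_all, holdout_balanced_accuracy = bal_acc),
              class = "apnoea_classifier")
  })
}

#' Generate a labelled training set for the apnoea classifier
#'
#' Synthesises IP recordings containing true (breath-free) apnoeas and
#' shallow-breathing impostor segments, and extracts the classifier features
#' for each candidate window.
#'
#' @param n_per_class windows per class.
#' @param seed integer seed.
#' @return A list with `features` (matrix) and `labels`.
#' @export
make_apnoea_training_set <- function(n_per_class = 100, seed = 1L) {
  feats <- matrix(NA_real_, 2 * n_per_class, 3)
  labs <- character(2 * n_per_class)
  for (i in seq_len(n_per_class)) {
    s1 <- substream_seed(seed, 2 * i - 1)
    dur <- with_seed(s1, stats::runif(1, 16, 35))
    sim <- simulate_ip(180, resp_rate = 55,
                       apnoeas = apnoea_spec(
                         data.frame(onset_s = 80, duration_s = dur)),
                       noise = ip_noise_spec(white_sd = 0.06),
                       seed = s1)
    f <- filter_ip(sim$signal)
    feats[2 * i - 1, ] <- apnoea_window_features(f, 80, dur)
    labs[2 * i - 1] <- "apnoea"

    s2 <- substream_seed(seed, 2 * i)
    dur2 <- with_seed(s2, stats::runif(1, 16, 35))
    fac <- with_seed(substream_seed(seed, 2 * i + 100000),
                     stats::runif(1, 0.1, 0.35))
    sim2 <- simulate_ip(180, resp_rate = 55,
                        noise = ip_noise_spec(white_sd = 0.06),
                        shallow = data.frame(onset_s = 80, duration_s = dur2,
                                             factor = fac),
                        seed = s2)
    f2 <- filter_ip(sim2$signal)
    feats[2 * i, ] <- apnoea_window_features(f2, 80, dur2)
    labs[2 * i] <- "rejected_noise_or_shallow"
  }
  colnames(feats) <- c("log_rms_ratio", "log_sd_ratio", "resp_band_frac")
  list(features = feats, labels = labs)
}

#' Classify long inter-breath intervals as apnoea or artifact
#'
#' Every IBI strictly longer than 15 s is a candidate apnoea; the classifier
#' labels it `apnoea` or `rejected_noise_or_shallow` from the filtered
#' signal. Rejected candidates are excluded from all downstream rate
#' computations. A 15.0-s IBI is not a candidate (the definition is strictly
#' "longer than 15 s").
#'
#' @param ibis an [extract_ibis()] result.
#' @param sig the filtered [ip_signal()] the IBIs came from.
#' @param clf a trained [train_apnoea_classifier()] object, or NULL to accept
#'   every candidate.
#' @return Data frame of events: `start_time` (s), `duration` (s), `label`.
#' @export
classify_long_ibis <- function(ibis, sig, clf = NULL) {
  abort_if(!inherits(ibis, "ibi_series"), "`ibis` must be an ibi_series")
  abort_if(!is.null(clf) && !inherits(clf, "apnoea_classifier"),
           "`clf` must be a trained apnoea_classifier (or NULL)")
  cand <- which(ibis$intervals > APNOEA_THRESHOLD_S)
  if (length(cand) == 0) {
    return(data.frame(start_time = numeric(), duration = numeric(),
                      label = character()))
  }
  st <- ibis$interval_start_times[cand]
  du <- ibis$intervals[cand]
  if (is.null(clf)) {
    lab <- rep("apnoea", length(cand))
  } else {
    feats <- t(vapply(seq_along(cand), function(k) {
      apnoea_window_features(sig, st[k], du[k])
    }, numeric(3)))
    lab <- as.character(stats::predict(clf$svm, feats))
  }
  data.frame(start_time = st, duration = du, label = lab,
             stringsAsFactors = FALSE)
}

#' Median respiratory rate
#'
#' 60 divided by the median inter-breath interval of the recording.
#'
#' @param ibis an [extract_ibis()] result.
#' @return Breaths per minute.
#' @export
respiratory_rate <- function(ibis) {
  abort_if(!inherits(ibis, "ibi_series") || ibis$n_ibis == 0,
           "`ibis` must be a non-empty ibi_series")
  60 / stats::median(ibis$intervals)
}

#' Apnoea rate
#'
#' Number of validated apnoeas per hour of available IBI data.
#'
#' @param apnoeas data frame from [classify_long_ibis()].
#' @param total_duration_h available IBI duration, hours.
#' @return Apnoeas per hour.
#' @export
apnoea_rate <- function(apnoeas, total_duration_h) {
  abort_if(total_duration_h <= 0, "`total_duration_h` must be positive")
  sum(apnoeas$label == "apnoea") / total_duration_h
}

#' Recording-level quality control
#'
#' A recording passes when it provides at least 100 inter-breath intervals.
#'
#' @param ibis an [extract_ibis()] result.
#' @return Logical flag.
#' @export
qc_recording <- function(ibis) {
  inherits(ibis, "ibi_series") && ibis$n_ibis >= MIN_IBIS_QC
}

#' Full respiration analysis of one IP recording
#'
#' Filter, detect breaths, extract IBIs, classify long IBIs and summarise.
#'
#' @param sig raw [ip_signal()].
#' @param clf apnoea classifier or NULL.
#' @return A list with `ibis`, `events`, and `summary` (a one-row data frame:
#'   `resp_rate`, `apnoea_rate`, `n_ibis`, `qc_pass`).
#' @export
analyse_respiration <- function(sig, clf = NULL) {
  filt <- filter_ip(sig)
  breaths <- detect_breaths(filt)
  if (nrow(breaths) < 2) {
    return(list(ibis = NULL, events = NULL,
                summary = data.frame(resp_rate = NA_real_,
                                     apnoea_rate = NA_real_,
                                     n_ibis = 0L, qc_pass = FALSE)))
  }
  ibis <- extract_ibis(breaths)
  events <- classify_long_ibis(ibis, filt, clf)
  # rejected long IBIs are discarded from the IBI pool entirely
  if (any(events$label == "rejected_noise_or_shallow")) {
    rej <- events[events$label == "rejected_noise_or_shallow", ]
    drop <- ibis$interval_start_times %in% rej$start_time
    kept <- ibis$intervals[!drop]
    ibis_kept <- structure(list(
      intervals = kept,
      interval_start_times = ibis$interval_start_times[!drop],
      total_duration_h = ibis$total_duration_h - sum(ibis$intervals[drop]) / 3600,
      n_ibis = length(kept)), class = "ibi_series")
  } else {
    ibis_kept <- ibis
  }
  qc <- qc_recording(ibis_kept)
  data_frame <- data.frame(
    resp_rate = if (ibis_kept$n_ibis > 0) respiratory_rate(ibis_kept) else NA_real_,
    apnoea_rate = if (ibis_kept$total_duration_h > 0) {
      apnoea_rate(events, ibis_kept$total_duration_h)
    } else {
      NA_real_
    },
    n_ibis = ibis_kept$n_ibis,
    qc_pass = qc)
  list(ibis = ibis_kept, events = events, summary = data_frame)
}
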