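# Sensory-evoked brain age: EEG preprocessing, epoching with baseline
# correction, artifact rejection, Woody alignment, NRF slope regression, and
# a linear-kernel support vector regression from the six slopes to age.

EPOCH_WINDOW_S <- c(-0.5, 1.0)
ARTIFACT_UV <- 150
MIN_EPOCHS_SENSORY <- 5
MODALITY_CHANNEL <- c(visual = "Oz", tactile = "Cz")

#' Preprocess an EEG recording
#'
#' Consecutive zero-phase high-pass (cut-off 0.05 Hz) and low-pass (cut-off
#' 33.75 Hz) Butterworth filtering of every channel, retaining the 0.1-30 Hz
#' band.
#'
#' @param rec an [eeg_recording()] sampled at >= 100 Hz.
#' @param hp_hz,lp_hz filter cut-offs, Hz.
#' @return The filtered [eeg_recording()].
#' @export
preprocess_eeg <- function(rec, hp_hz = 0.05, lp_hz = 33.75) {
  abort_if(!inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  abort_if(rec$fs < 100, "`rec` must be sampled at >= 100 Hz")
  abort_if(nrow(rec$channels) < rec$fs * 10,
           "recording too short to filter (need >= 10 s)")
  hp <- signal::butter(2, hp_hz / (rec$fs / 2), type = "high")
  lp <- signal::butter(4, lp_hz / (rec$fs / 2), type = "low")
  ch <- apply(rec$channels, 2, function(x) {
    y <- signal::filtfilt(hp, x)
    as.numeric(signal::filtfilt(lp, y))
  })
  colnames(ch) <- colnames(rec$channels)
  eeg_recording(ch, rec$fs, rec$annotations)
}

#' Epoch a recording around stimulus onsets and baseline-correct
#'
#' Epochs span -0.5 to 1.0 s around each annotation of the requested
#' modality, on the modality's channel (visual: Oz; tactile: Cz), and are
#' baseline-normalised by subtracting the mean amplitude over [-0.5, 0) s.
#' Annotations too close to a recording edge are skipped with a message.
#'
#' @param rec an [eeg_recording()] with annotations.
#' @param modality `"visual"` or `"tactile"`.
#' @param channel channel name; defaults to the modality's standard channel.
#' @return An [epoch_set()].
#' @export
epoch_and_baseline <- function(rec, modality = c("visual", "tactile"),
                               channel = NULL) {
  modality <- match.arg(modality)
  if (is.null(channel)) channel <- MODALITY_CHANNEL[[modality]]
  abort_if(!channel %in% colnames(rec$channels),
           sprintf("channel %s not present in the recording", channel))
  ann <- rec$annotations[rec$annotations$modality == modality, , drop = FALSE]
  abort_if(nrow(ann) == 0, sprintf("no %s annotations", modality))
  fs <- rec$fs
  x <- rec$channels[, channel]
  n <- length(x)
  n_pre <- round(-EPOCH_WINDOW_S[1] * fs)
  n_post <- round(EPOCH_WINDOW_S[2] * fs)
  time <- (seq_len(n_pre + n_post) - n_pre - 1) / fs
  rows <- list()
  skipped <- 0L
  for (t0 in ann$time_s) {
    i0 <- round(t0 * fs) + 1
    i1 <- i0 - n_pre
    i2 <- i0 + n_post - 1
    if (i1 < 1 || i2 > n) {
      skipped <- skipped + 1L
      next
    }
    ep <- x[i1:i2]
    ep <- ep - mean(ep[time < 0])
    rows[[length(rows) + 1]] <- ep
  }
  if (skipped > 0) {
    message(sprintf("%d %s annotation(s) too close to a recording edge; skipped",
                    skipped, modality))
  }
  abort_if(length(rows) == 0, "no epoch fits inside the recording")
  epoch_set(do.call(rbind, rows), time, fs, modality)
}

#' Reject high-amplitude epochs
#'
#' Marks epochs whose pre-stimulus amplitude strictly exceeds +/-150 uV as
#' rejected (an amplitude of exactly 150 uV is kept). When fewer than five
#' epochs survive, the set is flagged as unavailable for sensory brain-age
#' estimation. The rejection window is the available pre-stimulus span
#' (-0.5 to 0 s).
#'
#' @param eps an [epoch_set()].
#' @param threshold_uv rejection threshold, uV.
#' @return The [epoch_set()] with an updated `kept` mask and an `available`
#'   attribute.
#' @export
reject_artifacts <- function(eps, threshold_uv = ARTIFACT_UV) {
  pre <- eps$time < 0
  amp <- apply(abs(eps$data[, pre, drop = FALSE]), 1, max)
  eps$kept <- eps$kept & (amp <= threshold_uv)
  attr(eps, "available") <- sum(eps$kept) >= MIN_EPOCHS_SENSORY
  eps
}

#' Woody-align epochs to a template
#'
#' Each kept epoch is shifted by the integer-sample lag (|lag| <= 50 ms)
#' that maximises its cross-correlation with the template, in a single pass
#' (or `n_iter` passes with the template re-derived from the aligned
#' average's NRF projection when a basis is supplied).
#'
#' @param eps an [epoch_set()].
#' @param template numeric vector on the epoch grid; if NULL, the projection
#'   of the epoch average onto `basis` (required then).
#' @param basis an [make_nrf_basis()] object (used when `template` is NULL
#'   and to re-project between iterations).
#' @param max_jitter_ms maximum admissible shift, ms.
#' @param n_iter number of alignment passes.
#' @return The [epoch_set()] with aligned epochs; epoch count is unchanged.
#' @export
woody_align <- function(eps, template = NULL, basis = NULL,
                        max_jitter_ms = 50, n_iter = 1) {
  abort_if(is.null(template) && is.null(basis),
           "supply `template` or `basis`")
  L <- round(max_jitter_ms / 1000 * eps$fs)
  nrf_template <- function(mat) {
    avg <- colMeans(mat[eps$kept, , drop = FALSE])
    cols <- which(basis$modality == eps$modality)
    phi <- basis$waveforms[, cols, drop = FALSE]
    as.numeric(phi %*% crossprod(phi, avg))
  }
  for (it in seq_len(max(n_iter, 1))) {
    tpl <- if (!is.null(template)) template else nrf_template(eps$data)
    for (i in which(eps$kept)) {
      ep <- eps$data[i, ]
      cc <- vapply(seq(-L, L), function(k) sum(shift_vector(ep, k) * tpl),
                   numeric(1))
      best <- seq(-L, L)[which.max(cc)]
      eps$data[i, ] <- shift_vector(ep, best)
    }
  }
  eps
}

#' Fit neurodynamic response function slopes
#'
#' Ordinary least squares of the average evoked response (kept epochs) onto
#' the modality's NRFs jointly: the visual average (Oz) onto the four visual
#' waveforms and the tactile average (Cz) onto the two tactile waveforms.
#' The six regression slopes are the response magnitudes forwarded to the
#' sensory brain-age model.
#'
#' @param eps_visual,eps_tactile [epoch_set()]s after rejection/alignment.
#' @param basis an [make_nrf_basis()] object.
#' @param per_epoch if TRUE, fit each epoch and average the slopes instead of
#'   fitting the epoch average (documented alternative; identical for an
#'   orthonormal basis without jitter).
#' @return Numeric vector of 6 slopes (visual 1-4, tactile 1-2).
#' @export
fit_nrf_slopes <- function(eps_visual, eps_tactile, basis, per_epoch = FALSE) {
  one <- function(eps) {
    abort_if(sum(eps$kept) < MIN_EPOCHS_SENSORY,
             "need >= 5 kept epochs per modality")
    cols <- which(basis$modality == eps$modality)
    phi <- basis$waveforms[, cols, drop = FALSE]
    abort_if(qr(phi)$rank < ncol(phi), "rank-deficient NRF design")
    fit_one <- function(y) as.numeric(qr.coef(qr(phi), y))
    if (per_epoch) {
      rowMeans(apply(eps$data[eps$kept, , drop = FALSE], 1, fit_one))
    } else {
      fit_one(colMeans(eps$data[eps$kept, , drop = FALSE]))
    }
  }
  c(one(eps_visual), one(eps_tactile))
}

#' Train the sensory brain-age model
#'
#' Support vector regression with a linear kernel from the six NRF slopes to
#' age, with k-fold cross-validated mean absolute error.
#'
#' @param slopes numeric matrix (occasions x 6).
#' @param ages postmenstrual ages, weeks.
#' @param n_folds cross-validation folds.
#' @param seed integer seed (fold assignment).
#' @return A list of class `sensory_age_model` with the fitted SVR and
#'   `cv_mae` (weeks).
#' @export
train_sensory_model <- function(slopes, ages, n_folds = 5, seed = 1L) {
  slopes <- as.matrix(slopes)
  abort_if(nrow(slopes) < 20, "need >= 20 training occasions")
  abort_if(diff(range(ages)) < 1e-8, "ages must not be constant")
  abort_if(diff(range(ages)) < 3,
           "training ages must span >= 3 weeks")
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(n_folds), nrow(slopes)))
    pred <- numeric(nrow(slopes))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- e1071::svm(x = slopes[tr, , drop = FALSE], y = ages[tr],
                        kernel = "linear", type = "eps-regression")
      pred[!tr] <- stats::predict(fit, slopes[!tr, , drop = FALSE])
    }
    cv_mae <- mean(abs(pred - ages))
    fit_all <- e1071::svm(x = slopes, y = ages, kernel = "linear",
                          type = "eps-regression")
    structure(list(svm = fit_all, cv_mae = cv_mae, cv_pred = pred),
              class = "sensory_age_model")
  })
}

#' Predict sensory brain age
#'
#' @param model a [train_sensory_model()] object.
#' @param slopes numeric vector of 6 slopes or a matrix (occasions x 6).
#' @return Predicted brain age(s), weeks.
#' @export
predict_sensory_age <- function(model, slopes) {
  abort_if(!inherits(model, "sensory_age_model"),
           "`model` must be a trained sensory_age_model")
  if (is.null(dim(slopes))) slopes <- matrix(slopes, nrow = 1)
  as.numeric(stats::predict(model$svm, slopes))
}

#' @export
print.sensory_age_model <- function(x, ...) {
  cat(sprintf("<sensory_age_model> linear-kernel SVR, CV MAE %.2f weeks\n",
              x$cv_mae))
  invisible(x)
}
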