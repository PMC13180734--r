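# Resting-state brain age surrogate. Preserves the published model's I/O
# contract -- first 20 min of stimulus-free EEG, bipolar C3-C4 downsampled
# to 64 Hz, 30-s epochs, a 10-member ensemble, median over members then
# median over epochs -- with transparent spectral/amplitude features and
# ridge members in place of the unavailable deep network.

RESTING_FS <- 64
RESTING_DURATION_S <- 1200
RESTING_EPOCH_S <- 30
N_ENSEMBLE <- 10

#' Prepare the resting-state segment
#'
#' Bipolar C3 minus C4, anti-alias filtered and resampled to 64 Hz, first
#' 1200 s. Recordings shorter than 20 min are flagged unavailable (the
#' occasion then relies on the sensory model alone).
#'
#' @param rec an [eeg_recording()] with channels C3 and C4.
#' @return A list of class `resting_segment` with `samples` (76,800 values),
#'   `fs` (64), and attribute `available`; or an unavailable stub when the
#'   recording is too short.
#' @export
prepare_resting_segment <- function(rec) {
  abort_if(!inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  abort_if(!all(c("C3", "C4") %in% colnames(rec$channels)),
           "recording must contain channels C3 and C4")
  dur <- nrow(rec$channels) / rec$fs
  if (dur < RESTING_DURATION_S) {
    out <- structure(list(samples = numeric(), fs = RESTING_FS),
                     class = "resting_segment")
    attr(out, "available") <- FALSE
    return(out)
  }
  d <- rec$channels[, "C3"] - rec$channels[, "C4"]
  d <- d[seq_len(round(RESTING_DURATION_S * rec$fs))]
  if (rec$fs != RESTING_FS) {
    lp <- signal::butter(8, min(28 / (rec$fs / 2), 0.95), type = "low")
    d <- as.numeric(signal::filtfilt(lp, d))
    t_in <- (seq_along(d) - 1) / rec$fs
    t_out <- (seq_len(RESTING_DURATION_S * RESTING_FS) - 1) / RESTING_FS
    d <- stats::approx(t_in, d, xout = t_out)$y
  } else {
    d <- d[seq_len(RESTING_DURATION_S * RESTING_FS)]
  }
  out <- structure(list(samples = d, fs = RESTING_FS),
                   class = "resting_segment")
  attr(out, "available") <- TRUE
  out
}

# Features of one 30-s epoch: relative band powers, 95% spectral edge
# frequency, amplitude percentiles, burst fraction.
resting_epoch_features <- function(x, fs) {
  m <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / m
  freqs <- (seq_len(m) - 1) * fs / m
  half <- freqs > 0 & freqs <= fs / 2
  p <- sp[half]
  f <- freqs[half]
  bands <- rbind(c(0.5, 3), c(3, 8), c(8, 15), c(15, 30))
  tot <- sum(p[f >= 0.5 & f <= 30])
  rel <- apply(bands, 1, function(b) {
    if (tot > 0) sum(p[f >= b[1] & f < b[2]]) / tot else 0
  })
  csum <- cumsum(p) / sum(p)
  sef95 <- f[which(csum >= 0.95)[1]]
  qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  # burst fraction: 1-s RMS envelope above 1.5x its median
  w <- fs
  nw <- floor(m / w)
  env <- sqrt(colMeans(matrix(x[seq_len(nw * w)]^2, nrow = w)))
  burst_frac <- mean(env > 1.5 * stats::median(env))
  c(rel_delta = rel[1], rel_theta = rel[2], rel_alpha = rel[3],
    rel_beta = rel[4], sef95 = sef95, amp_p05 = qs[1], amp_p95 = qs[2],
    burst_frac = burst_frac)
}

#' Segment a resting trace into 30-s epochs and extract features
#'
#' @param seg a [prepare_resting_segment()] result.
#' @return Numeric matrix (40 epochs x 8 features): relative power in
#'   0.5-3, 3-8, 8-15, 15-30 Hz, 95% spectral edge frequency, 5th/95th
#'   amplitude percentiles, burst fraction.
#' @export
epoch_30s <- function(seg) {
  abort_if(!inherits(seg, "resting_segment"), "`seg` must be a resting_segment")
  abort_if(!isTRUE(attr(seg, "available")), "segment is unavailable")
  w <- RESTING_EPOCH_S * seg$fs
  n_ep <- floor(length(seg$samples) / w)
  t(vapply(seq_len(n_ep), function(i) {
    resting_epoch_features(seg$samples[((i - 1) * w + 1):(i * w)], seg$fs)
  }, numeric(8)))
}

# Closed-form ridge regression on standardised features.
ridge_fit <- function(X, y, lambda) {
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-12)
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  beta <- solve(crossprod(Z) + lambda * diag(ncol(Z)), crossprod(Z, y - mean(y)))
  list(mu = mu, sd = sdv, beta = as.numeric(beta), intercept = mean(y))
}

ridge_predict <- function(fit, X) {
  Z <- sweep(sweep(X, 2, fit$mu), 2, fit$sd, `/`)
  as.numeric(Z %*% fit$beta) + fit$intercept
}

#' Train the resting-state brain-age surrogate
#'
#' Ten ridge-regression members, each fitted on a bootstrap resample of the
#' training recordings (all 30-s epochs of a resampled recording carry its
#' age as target). Deterministic given the seed.
#'
#' @param feature_list list of feature matrices, one per recording (from
#'   [epoch_30s()]).
#' @param ages recording ages, weeks.
#' @param lambda ridge penalty.
#' @param seed integer seed.
#' @return A list of class `resting_age_model` with 10 members.
#' @export
train_resting_model <- function(feature_list, ages, lambda = 1, seed = 1L) {
  abort_if(length(feature_list) < 20, "need >= 20 training recordings")
  abort_if(diff(range(ages)) < 1e-8, "ages must not be constant")
  with_seed(seed, {
    members <- lapply(seq_len(N_ENSEMBLE), function(m) {
      idx <- sample(seq_along(feature_list), replace = TRUE)
      X <- do.call(rbind, feature_list[idx])
      y <- rep(ages[idx], vapply(feature_list[idx], nrow, integer(1)))
      ridge_fit(X, y, lambda)
    })
    structure(list(members = members, lambda = lambda),
              class = "resting_age_model")
  })
}

#' Predict resting-state brain age
#'
#' Each member predicts an age for every 30-s epoch; the median over the ten
#' members is taken per epoch, then the median over epochs gives the single
#' recording-level age. The double median makes the estimate robust to
#' artifactual epochs.
#'
#' @param model a [train_resting_model()] object.
#' @param features feature matrix for one recording (epochs x 8).
#' @return Predicted brain age, weeks.
#' @export
predict_resting_age <- function(model, features) {
  abort_if(!inherits(model, "resting_age_model"),
           "`model` must be a trained resting_age_model")
  features <- as.matrix(features)
  per_member <- vapply(model$members, function(m) ridge_predict(m, features),
                       numeric(nrow(features)))
  if (is.null(dim(per_member))) per_member <- matrix(per_member, nrow = 1)
  per_epoch <- apply(per_member, 1, stats::median)
  stats::median(per_epoch)
}

#' @export
print.resting_age_model <- function(x, ...) {
  cat(sprintf("<resting_age_model> %d ridge members (lambda=%g)\n",
              length(x$members), x$lambda))
  invisible(x)
}
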