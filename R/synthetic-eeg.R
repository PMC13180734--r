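# EEG generators: an orthonormal neurodynamic-response-function (NRF) basis,
# stimulus-evoked epochs with age-dependent component magnitudes, and a
# resting-state trace whose discontinuity and spectral tilt mature with age.
# The maturation laws are synthetic conventions, not physiology.

#' Build an orthonormal neurodynamic response function basis
#'
#' Six smooth waveforms (four visual, two tactile) on the stimulus epoch grid
#' (-0.5 to 1.0 s): Gaussian-windowed Hermite-type bumps at staggered
#' post-stimulus latencies, orthonormalised by QR with a fixed sign
#' convention (peak positive). Deterministic given its arguments. The
#' published basis was derived from real evoked potentials by principal
#' component analysis; any basis on the same grid can be supplied to the
#' fitting routines in its place.
#'
#' @param n_visual,n_tactile number of visual and tactile waveforms.
#' @param fs sampling rate, Hz.
#' @param window epoch window in seconds (start, end); must span -0.5 to 1 s.
#' @return A list of class `nrf_basis` with `waveforms` (samples x 6 matrix,
#'   unit-norm orthogonal columns), `time`, `fs`, `modality`.
#' @export
make_nrf_basis <- function(n_visual = 4, n_tactile = 2, fs = 2000,
                           window = c(-0.5, 1.0)) {
  abort_if(n_visual < 1 || n_tactile < 1, "need at least one waveform per modality")
  n <- round((window[2] - window[1]) * fs)
  time <- window[1] + (seq_len(n) - 1) / fs
  bump <- function(mu, sd, order) {
    z <- (time - mu) / sd
    h <- switch(order + 1L, rep(1, n), z, z^2 - 1, z^3 - 3 * z, z^4 - 6 * z^2 + 3)
    h * exp(-z^2 / 2)
  }
  mus_v <- seq(0.15, 0.55, length.out = n_visual)
  sds_v <- seq(0.05, 0.12, length.out = n_visual)
  mus_t <- seq(0.10, 0.35, length.out = n_tactile)
  sds_t <- seq(0.04, 0.10, length.out = n_tactile)
  raw <- cbind(
    vapply(seq_len(n_visual),
           function(k) bump(mus_v[k], sds_v[k], (k - 1) %% 4), numeric(n)),
    vapply(seq_len(n_tactile),
           function(k) bump(mus_t[k], sds_t[k], (k - 1) %% 4), numeric(n))
  )
  q <- qr.Q(qr(raw))
  flip <- apply(q, 2, function(col) sign(col[which.max(abs(col))]))
  q <- sweep(q, 2, flip, `*`)
  structure(list(waveforms = q, time = time, fs = fs,
                 modality = c(rep("visual", n_visual), rep("tactile", n_tactile))),
            class = "nrf_basis")
}

#' Default linear slope-age map for the evoked generator
#'
#' Returns the six NRF magnitudes (a.u.) as a linear function of brain age
#' centred at 33.5 weeks; gradients differ per component so the slope vector
#' identifies age.
#'
#' @param age brain age in weeks.
#' @return Numeric vector of 6 slopes.
#' @export
default_slope_age_map <- function(age) {
  # scaled so the reconstructed response peaks at ~10-15 uV against the
  # unit-norm basis vectors
  a <- 30 * c(3.0, 2.0, 1.5, 1.0, 2.5, 1.8)
  b <- 30 * c(1.0, -0.6, 0.5, -0.3, 0.8, -0.4)
  a + b * (age - 33.5)
}

#' Simulate stimulus-evoked EEG epochs
#'
#' Each epoch is the NRF reconstruction for the infant's brain age, shifted
#' by a per-epoch latency jitter, plus white noise; a configurable fraction
#' of epochs carries a high-amplitude pre-stimulus artifact (> 150 uV).
#'
#' @param true_brain_age brain age in weeks.
#' @param basis an [make_nrf_basis()] object.
#' @param slope_age_map function age -> 6 slopes; see
#'   [default_slope_age_map()].
#' @param subject_sd SD of the per-occasion deviation added to each slope
#'   (a.u.); models between-infant variability at fixed age.
#' @param jitter_ms maximum per-epoch latency jitter (uniform, +/-), ms;
#'   must be <= 50.
#' @param noise_sd white-noise SD per sample, uV.
#' @param n_epochs epochs per modality.
#' @param artifact_frac probability an epoch carries a pre-stimulus artifact.
#' @param seed integer seed.
#' @return A list with `visual` and `tactile` [epoch_set()]s and `truth`
#'   (true slopes, per-epoch jitters, artifact indices per modality).
#' @export
simulate_evoked <- function(true_brain_age, basis,
                            slope_age_map = default_slope_age_map,
                            subject_sd = 24,
                            jitter_ms = 10, noise_sd = 5, n_epochs = 20,
                            artifact_frac = 0, seed = 1L) {
  abort_if(n_epochs < 1, "`n_epochs` must be >= 1")
  abort_if(jitter_ms > 50, "`jitter_ms` must be <= 50 ms")
  with_seed(seed, {
    slopes <- slope_age_map(true_brain_age)
    if (subject_sd > 0) slopes <- slopes + stats::rnorm(6, 0, subject_sd)
    n <- length(basis$time)
    pre <- basis$time < 0
    max_shift <- round(jitter_ms / 1000 * basis$fs)

    one_modality <- function(mod) {
      cols <- which(basis$modality == mod)
      template <- as.numeric(basis$waveforms[, cols, drop = FALSE] %*%
                               slopes[cols])
      shifts <- if (max_shift > 0) {
        sample(seq(-max_shift, max_shift), n_epochs, replace = TRUE)
      } else {
        rep(0L, n_epochs)
      }
      art <- which(stats::runif(n_epochs) < artifact_frac)
      mat <- matrix(0, n_epochs, n)
      for (i in seq_len(n_epochs)) {
        ep <- shift_vector(template, shifts[i])
        if (noise_sd > 0) ep <- ep + stats::rnorm(n, 0, noise_sd)
        if (i %in% art) {
          bumpz <- (basis$time + 0.25) / 0.05
          ep <- ep + sample(c(-1, 1), 1) * 300 * exp(-bumpz^2 / 2) * pre
        }
        mat[i, ] <- ep
      }
      list(eps = epoch_set(mat, basis$time, basis$fs, mod),
           shifts = shifts, artifacts = art)
    }
    v <- one_modality("visual")
    t <- one_modality("tactile")
    list(visual = v$eps, tactile = t$eps,
         truth = list(slopes = slopes,
                      shifts = list(visual = v$shifts, tactile = t$shifts),
                      artifacts = list(visual = v$artifacts,
                                       tactile = t$artifacts)))
  })
}

# Shift a vector by k samples (positive = delay), zero-filled.
shift_vector <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  if (k >= 0) {
    if (k < n) out[(k + 1):n] <- x[1:(n - k)]
  } else {
    if (-k < n) out[1:(n + k)] <- x[(1 - k):n]
  }
  out
}

#' Simulate a resting-state EEG recording (C3, C4)
#'
#' Alternating bursts and inter-burst intervals. The generator law (a
#' synthetic convention): mean inter-burst duration shrinks linearly with
#' brain age, burst slow-wave amplitude falls and fast amplitude rises with
#' age, so both discontinuity and the low/high-frequency power ratio mature
#' monotonically. Inter-burst and burst durations are drawn as scaled unit
#' exponentials, so at a fixed seed every inter-burst interval is strictly
#' longer for a younger brain age.
#'
#' @param true_brain_age brain age in weeks (31-36 intended).
#' @param duration_s recording duration, seconds (>= 1200 for full use
#'   downstream).
#' @param fs sampling rate, Hz (2000 emulates the acquisition hardware; the
#'   pipeline may generate directly at a lower rate).
#' @param seed integer seed.
#' @return A list with `rec` (an [eeg_recording()] with channels C3, C4) and
#'   `truth` (segment table, inter-burst durations, amplitude law values).
#' @export
simulate_resting_eeg <- function(true_brain_age, duration_s = 1200,
                                 fs = 2000, seed = 1L) {
  abort_if(duration_s < 1, "`duration_s` must be >= 1 s")
  with_seed(seed, {
    ib_mean <- max(0.8, 6 - 1.0 * (true_brain_age - 31))
    burst_mean <- 3
    slow_amp <- 40 * (1 - 0.08 * (true_brain_age - 31))
    fast_amp <- 5 * (1 + 0.20 * (true_brain_age - 31))

    # alternating burst / inter-burst segments until the trace is covered;
    # the draw count is age-independent (worst case) so a fixed seed yields
    # the same unit exponentials at every age
    n_seg <- ceiling(duration_s / (0.5 * (0.8 + 1))) + 8
    u_burst <- stats::rexp(n_seg)
    u_ib <- stats::rexp(n_seg)
    durs <- as.numeric(rbind(pmax(1, burst_mean * u_burst),
                             pmax(0.5, ib_mean * u_ib)))
    is_burst <- rep(c(TRUE, FALSE), n_seg)
    cum <- cumsum(durs)
    keep <- which(cum - durs < duration_s)
    durs <- durs[keep]
    is_burst <- is_burst[keep]

    n <- round(duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    d <- stats::rnorm(n, 0, 2)  # continuous background, uV
    seg_start <- cumsum(c(0, durs[-length(durs)]))
    ib_durs <- durs[!is_burst]
    for (s in seq_along(durs)) {
      i1 <- floor(seg_start[s] * fs) + 1
      i2 <- min(floor((seg_start[s] + durs[s]) * fs), n)
      if (i1 > i2) next
      ts <- tt[i1:i2]
      if (is_burst[s]) {
        f_slow <- stats::runif(3, 0.5, 3)
        f_fast <- stats::runif(2, 8, 15)
        ph <- stats::runif(5, 0, 2 * pi)
        seg <- slow_amp / sqrt(3) *
          (sin(2 * pi * f_slow[1] * ts + ph[1]) +
             sin(2 * pi * f_slow[2] * ts + ph[2]) +
             sin(2 * pi * f_slow[3] * ts + ph[3])) +
          fast_amp / sqrt(2) *
          (sin(2 * pi * f_fast[1] * ts + ph[4]) +
             sin(2 * pi * f_fast[2] * ts + ph[5]))
        # taper the burst edges so transitions are smooth
        m <- length(ts)
        ramp <- pmin(1, seq_len(m) / (0.1 * fs + 1),
                     rev(seq_len(m)) / (0.1 * fs + 1))
        d[i1:i2] <- d[i1:i2] + seg * ramp
      } else {
        d[i1:i2] <- d[i1:i2] + stats::rnorm(i2 - i1 + 1, 0, 3)
      }
    }
    common <- 10 * sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi)) +
      stats::rnorm(n, 0, 2)
    channels <- cbind(C3 = common + 0.5 * d, C4 = common - 0.5 * d)
    list(rec = eeg_recording(channels, fs = fs),
         truth = list(segments = data.frame(start_s = seg_start,
                                            duration_s = durs,
                                            burst = is_burst),
                      interburst_durations = ib_durs,
                      slow_amp = slow_amp, fast_amp = fast_amp,
                      ib_mean = ib_mean))
  })
}
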