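# Signal-level generators: impedance pneumography with inserted apnoeas and
# shallow-breathing segments, and pulse-oximetry traces with desaturation
# dips. All are pure functions of (arguments, seed).

#' Specify inserted apnoeas
#'
#' Either an explicit table of events or a random Poisson process whose
#' durations are 15 s plus an exponential tail, so every generated event
#' satisfies the >15 s apnoea definition.
#'
#' @param events data frame with columns `onset_s`, `duration_s`, or NULL.
#' @param rate_per_h Poisson rate of random apnoeas (used when `events` is
#'   NULL).
#' @param duration_excess_mean mean of the exponential tail added to the 15-s
#'   floor, seconds.
#' @return A list of class `apnoea_spec`.
#' @export
apnoea_spec <- function(events = NULL, rate_per_h = 0,
                        duration_excess_mean = 5) {
  if (!is.null(events)) {
    abort_if(!all(c("onset_s", "duration_s") %in% names(events)),
             "`events` needs columns onset_s, duration_s")
    abort_if(any(events$duration_s <= 0), "apnoea durations must be > 0")
  }
  structure(list(events = events, rate_per_h = rate_per_h,
                 duration_excess_mean = duration_excess_mean),
            class = "apnoea_spec")
}

#' Noise model for the synthetic impedance pneumography trace
#'
#' @param white_sd white-noise SD relative to unit breath amplitude.
#' @param ibi_cv coefficient of variation of cycle-to-cycle breath duration.
#' @param amp_drift_sd SD of the per-breath log-amplitude random walk.
#' @param cardiac_amp amplitude of the cardiac contamination relative to the
#'   breath amplitude (default 10%).
#' @param cardiac_hz cardiac frequency, Hz (~140 bpm).
#' @return A list of class `ip_noise_spec`.
#' @export
ip_noise_spec <- function(white_sd = 0.05, ibi_cv = 0.04,
                          amp_drift_sd = 0.05, cardiac_amp = 0.1,
                          cardiac_hz = 2.3) {
  structure(as.list(environment()), class = "ip_noise_spec")
}

#' Simulate an impedance pneumography recording
#'
#' Raised-cosine breath cycles with a multiplicative amplitude random walk,
#' cardiac contamination and white noise. Apnoeas are breath-free segments at
#' recorded onsets/durations; shallow-breathing segments scale the local
#' breath amplitude and are flagged in the ground truth.
#'
#' @param duration_s recording duration, seconds.
#' @param resp_rate breathing rate, breaths/min (must lie in (10, 120)).
#' @param apnoeas an [apnoea_spec()].
#' @param noise an [ip_noise_spec()]; use
#'   `ip_noise_spec(0, 0, 0, 0)` for a noise-free train.
#' @param shallow data frame of shallow-breathing windows with columns
#'   `onset_s`, `duration_s`, `factor` (amplitude scale), or NULL.
#' @param seed integer seed.
#' @return A list with elements `signal` (an [ip_signal()]) and `truth`
#'   (breath peak times, true inter-breath intervals, inserted apnoea and
#'   shallow windows).
#' @export
simulate_ip <- function(duration_s, resp_rate = 60,
                        apnoeas = apnoea_spec(),
                        noise = ip_noise_spec(),
                        shallow = NULL,
                        seed = 1L) {
  check_finite_scalar(duration_s, "duration_s")
  abort_if(duration_s <= 0, "`duration_s` must be positive")
  abort_if(resp_rate <= 10 || resp_rate >= 120,
           "`resp_rate` must lie in (10, 120) breaths/min")
  fs <- 62.5
  with_seed(seed, {
    ev <- apnoeas$events
    if (is.null(ev) && apnoeas$rate_per_h > 0) {
      n_exp <- stats::rpois(1, apnoeas$rate_per_h * duration_s / 3600)
      if (n_exp > 0) {
        ons <- sort(stats::runif(n_exp, 0, duration_s))
        dur <- 15 + stats::rexp(n_exp, 1 / apnoeas$duration_excess_mean)
        ev <- data.frame(onset_s = ons, duration_s = dur)
        # thin events that spill out of the recording or overlap a predecessor
        keep <- ev$onset_s + ev$duration_s <= duration_s
        ev <- ev[keep, , drop = FALSE]
        if (nrow(ev) > 1) {
          keep <- c(TRUE, ev$onset_s[-1] >
                      (ev$onset_s + ev$duration_s)[-nrow(ev)] + 5)
          ev <- ev[keep, , drop = FALSE]
        }
      }
    }
    if (is.null(ev)) ev <- data.frame(onset_s = numeric(), duration_s = numeric())
    abort_if(any(ev$onset_s < 0 | ev$onset_s + ev$duration_s > duration_s),
             "inserted apnoeas must lie inside the recording")

    # breath cycle start times, skipping apnoeic windows
    L0 <- 60 / resp_rate
    starts <- numeric(0)
    lens <- numeric(0)
    amp <- 1
    amps <- numeric(0)
    t <- 0
    ev_end <- ev$onset_s + ev$duration_s
    while (t + L0 * 0.5 < duration_s) {
      L <- if (noise$ibi_cv > 0) L0 * exp(stats::rnorm(1, 0, noise$ibi_cv)) else L0
      # a cycle intersecting an apnoea window is suppressed; resume at its end
      hit <- which(ev$onset_s < t + L & ev_end > t)
      if (length(hit) > 0) {
        t <- max(ev_end[hit])
        next
      }
      if (t + L > duration_s) break
      starts <- c(starts, t)
      lens <- c(lens, L)
      amps <- c(amps, amp)
      if (noise$amp_drift_sd > 0) {
        amp <- min(max(amp * exp(stats::rnorm(1, 0, noise$amp_drift_sd)), 0.3), 3)
      }
      t <- t + L
    }
    abort_if(length(starts) == 0, "no breath cycle fits the recording")

    n <- round(duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    idx <- findInterval(tt, starts)
    x <- numeric(n)
    inb <- idx >= 1
    j <- idx[inb]
    phase <- (tt[inb] - starts[j]) / lens[j]
    inside <- phase < 1
    val <- numeric(sum(inb))
    val[inside] <- amps[j][inside] * 0.5 * (1 - cos(2 * pi * phase[inside]))
    x[inb] <- val

    sh <- shallow
    if (!is.null(sh)) {
      if (is.null(sh$factor)) sh$factor <- 0.2
      for (r in seq_len(nrow(sh))) {
        w <- tt >= sh$onset_s[r] & tt < sh$onset_s[r] + sh$duration_s[r]
        x[w] <- x[w] * sh$factor[r]
      }
    } else {
      sh <- data.frame(onset_s = numeric(), duration_s = numeric(),
                       factor = numeric())
    }

    if (noise$cardiac_amp > 0) {
      x <- x + noise$cardiac_amp * sin(2 * pi * noise$cardiac_hz * tt)
    }
    if (noise$white_sd > 0) x <- x + stats::rnorm(n, 0, noise$white_sd)

    peaks <- starts + lens / 2
    # peaks inside shallow windows are still true breaths (attenuated)
    list(
      signal = ip_signal(x, fs = fs),
      truth = list(breath_times = peaks,
                   ibis = diff(peaks),
                   apnoeas = ev,
                   shallow = sh)
    )
  })
}

#' Simulate an oxygen-saturation (SpO2) trace
#'
#' A 0.97-Hz trace near `baseline` with inserted desaturation dips of given
#' depth and duration.
#'
#' @param duration_s recording duration, seconds.
#' @param desats data frame of dips with columns `onset_s`, `duration_s`,
#'   `depth_pct` (saturation during the dip), or NULL.
#' @param baseline baseline saturation, percent, in (85, 100].
#' @param noise_sd SD of the measurement noise, percent.
#' @param seed integer seed.
#' @return A list with elements `signal` (an [spo2_signal()]) and `truth`
#'   (the inserted desaturation windows).
#' @export
simulate_spo2 <- function(duration_s, desats = NULL, baseline = 96,
                          noise_sd = 0.4, seed = 1L) {
  abort_if(duration_s <= 0, "`duration_s` must be positive")
  abort_if(baseline <= 85 || baseline > 100,
           "`baseline` must lie in (85, 100]")
  if (is.null(desats)) {
    desats <- data.frame(onset_s = numeric(), duration_s = numeric(),
                         depth_pct = numeric())
  }
  abort_if(nrow(desats) > 0 &&
             (any(desats$depth_pct < 0) || any(desats$depth_pct > 100)),
           "dip saturations must lie in [0, 100]")
  abort_if(nrow(desats) > 0 &&
             any(desats$onset_s < 0 |
                   desats$onset_s + desats$duration_s > duration_s),
           "desaturation windows must lie inside the recording")
  fs <- 0.97
  with_seed(seed, {
    n <- round(duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    x <- rep(baseline, n)
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    for (r in seq_len(nrow(desats))) {
      w <- tt >= desats$onset_s[r] & tt < desats$onset_s[r] + desats$duration_s[r]
      x[w] <- desats$depth_pct[r]
    }
    x <- pmin(pmax(x, 0), 100)
    list(signal = spo2_signal(x, fs = fs), truth = list(desats = desats))
  })
}
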