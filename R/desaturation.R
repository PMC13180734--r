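# Oxygen desaturation events: sustained (>= 10 s) periods of SpO2 strictly
# below 80%.

DESAT_THRESHOLD_PCT <- 80
DESAT_MIN_DURATION_S <- 10

#' Detect oxygen desaturation events
#'
#' Maximal contiguous runs of samples with saturation strictly below 80%
#' lasting at least 10 s; one event per run. Missing samples break runs.
#'
#' @param sig an [spo2_signal()].
#' @param threshold_pct saturation threshold, percent.
#' @param min_duration_s minimum run duration, seconds.
#' @return Data frame of events: `start_time` (s), `duration` (s).
#' @export
detect_desaturations <- function(sig, threshold_pct = DESAT_THRESHOLD_PCT,
                                 min_duration_s = DESAT_MIN_DURATION_S) {
  abort_if(!inherits(sig, "spo2_signal"), "`sig` must be an spo2_signal")
  x <- sig$samples
  abort_if(all(is.na(x)), "SpO2 trace is entirely missing")
  below <- !is.na(x) & x < threshold_pct
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  dur <- r$lengths[runs] / sig$fs
  keep <- dur >= min_duration_s
  data.frame(start_time = (starts[runs][keep] - 1) / sig$fs,
             duration = dur[keep])
}

#' Desaturation rate
#'
#' @param events data frame from [detect_desaturations()].
#' @param duration_h monitored duration, hours.
#' @return Events per hour.
#' @export
desat_rate <- function(events, duration_h) {
  abort_if(duration_h <= 0, "`duration_h` must be positive")
  nrow(events) / duration_h
}
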