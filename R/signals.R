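# Lightweight S3 containers for the physiological time series the pipeline
# consumes. All are uniformly sampled; times are seconds from recording start.

#' Impedance pneumography signal
#'
#' @param samples numeric vector of impedance values (arbitrary units).
#' @param fs sampling rate in Hz (62.5 for the bedside monitors emulated here).
#' @param start_time recording start offset in seconds.
#' @return An object of class `ip_signal` with fields `samples`, `fs`,
#'   `start_time`.
#' @export
ip_signal <- function(samples, fs = 62.5, start_time = 0) {
  check_finite_scalar(fs, "fs")
  abort_if(fs <= 0, "`fs` must be positive")
  samples <- as.numeric(samples)
  abort_if(any(!is.finite(samples)), "IP samples must be finite")
  structure(list(samples = samples, fs = fs, start_time = start_time),
            class = "ip_signal")
}

#' @export
print.ip_signal <- function(x, ...) {
  cat(sprintf("<ip_signal> %d samples @ %.3g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Oxygen saturation (SpO2) signal
#'
#' @param samples numeric vector of saturation values in percent; `NA` marks
#'   missing samples.
#' @param fs sampling rate in Hz (0.97 for the monitors emulated here).
#' @return An object of class `spo2_signal`.
#' @export
spo2_signal <- function(samples, fs = 0.97) {
  check_finite_scalar(fs, "fs")
  abort_if(fs <= 0, "`fs` must be positive")
  samples <- as.numeric(samples)
  ok <- is.na(samples) | (samples >= 0 & samples <= 100)
  abort_if(!all(ok), "SpO2 samples must lie in [0, 100] or be NA")
  structure(list(samples = samples, fs = fs), class = "spo2_signal")
}

#' Multi-channel EEG recording with stimulus annotations
#'
#' @param channels numeric matrix (samples x channels) with named columns, in
#'   microvolts.
#' @param fs sampling rate in Hz.
#' @param annotations data frame with columns `time_s` and `modality`
#'   (`"visual"` or `"tactile"`); may have zero rows.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(channels, fs,
                          annotations = data.frame(time_s = numeric(),
                                                   modality = character())) {
  abort_if(!is.matrix(channels) || is.null(colnames(channels)),
           "`channels` must be a matrix with named columns")
  check_finite_scalar(fs, "fs")
  dur <- nrow(channels) / fs
  abort_if(nrow(annotations) > 0 &&
             (any(annotations$time_s < 0) || any(annotations$time_s > dur)),
           "annotation times must lie within the recording")
  structure(list(channels = channels, fs = fs, annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz, %d annotations\n",
              nrow(x$channels), ncol(x$channels), x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Set of stimulus-locked EEG epochs on a fixed time grid
#'
#' Epochs span -0.5 to 1.0 s around stimulus onset; row `i` of `data` is epoch
#' `i`. `kept` tracks artifact rejection.
#'
#' @param data numeric matrix (epochs x time points), microvolts.
#' @param time numeric vector of epoch times in seconds (length `ncol(data)`).
#' @param fs sampling rate in Hz.
#' @param modality `"visual"` or `"tactile"`.
#' @param kept logical vector, one entry per epoch.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time, fs, modality = c("visual", "tactile"),
                      kept = rep(TRUE, nrow(data))) {
  modality <- match.arg(modality)
  abort_if(ncol(data) != length(time), "`time` must match epoch length")
  structure(list(data = data, time = time, fs = fs, modality = modality,
                 kept = kept),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d epochs (%d kept) x %d samples @ %g Hz\n",
              x$modality, nrow(x$data), sum(x$kept), ncol(x$data), x$fs))
  invisible(x)
}
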