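# Combine the two brain-age estimates, remove the systematic age bias, and
# classify maturity.

#' Combine sensory and resting brain-age estimates
#'
#' The combined brain age is the mean of the available estimates; when one
#' model is unavailable (NA) the other is used alone.
#'
#' @param sensory,resting ages in weeks, NA when unavailable. Vectorised.
#' @return Combined brain age(s), weeks.
#' @export
combine_ages <- function(sensory, resting) {
  abort_if(length(sensory) != length(resting),
           "`sensory` and `resting` must have equal length")
  abort_if(any(is.na(sensory) & is.na(resting)),
           "at least one estimate must be available per occasion")
  rowMeans(cbind(sensory, resting), na.rm = TRUE)
}

#' Age-bias correction of the brain age gap
#'
#' Brain-age models predict with a systematic linear bias relative to
#' chronological age. The corrected gap is the residual of the ordinary
#' least squares fit of combined brain age on PMA, which guarantees that the
#' corrected gap has exactly zero mean and zero sample correlation with PMA,
#' and is invariant to affine perturbations a*PMA + b of the brain ages.
#'
#' @param combined combined brain ages, weeks.
#' @param pma postmenstrual ages, weeks.
#' @param correct if FALSE, skip the correction and return the raw gap
#'   (brain age minus PMA).
#' @return Data frame with `raw_gap` and `corrected_gap` (weeks).
#' @export
bias_correct <- function(combined, pma, correct = TRUE) {
  abort_if(length(combined) != length(pma), "length mismatch")
  abort_if(length(pma) < 3, "need >= 3 occasions")
  abort_if(stats::sd(pma) < 1e-12, "PMA must not be constant")
  raw <- combined - pma
  corrected <- if (correct) {
    as.numeric(stats::residuals(stats::lm(combined ~ pma)))
  } else {
    raw
  }
  data.frame(raw_gap = raw, corrected_gap = corrected)
}

#' Classify brain maturity from the gap
#'
#' Mature when the corrected gap is strictly positive, immature otherwise
#' (a gap of exactly 0 is assigned to immature; fixed convention).
#'
#' @param gap corrected brain age gap(s), weeks.
#' @return Character vector, `"mature"` or `"immature"`.
#' @export
classify_maturity <- function(gap) {
  abort_if(any(!is.finite(gap)), "`gap` must be finite")
  ifelse(gap > 0, "mature", "immature")
}
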