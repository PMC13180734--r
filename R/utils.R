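# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators can be
#' nested without perturbing each other.
#'
#' @param seed integer seed, or NULL to leave the RNG stream untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

# Derive an independent substream seed from a global seed and an index, so
# adding one recording to a cohort never perturbs the others. Kept below
# .Machine$integer.max (R seeds are 32-bit).
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 30269
  as.integer(s %% 2147483629 + 1)
}

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

check_finite_scalar <- function(x, name) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           sprintf("`%s` must be a finite numeric scalar", name))
  invisible(x)
}

# Rolling-window standard deviation over [i1, i2] using prefix sums.
window_sd <- function(cs, cs2, i1, i2) {
  n <- i2 - i1 + 1
  if (n < 2) return(0)
  s <- cs[i2 + 1] - cs[i1]
  s2 <- cs2[i2 + 1] - cs2[i1]
  v <- (s2 - s^2 / n) / (n - 1)
  sqrt(max(v, 0))
}
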