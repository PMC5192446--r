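# Internal helpers shared across the pipeline.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that cohort generation,
#' cross-validation and permutation testing are reproducible without
#' clobbering the session RNG.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Truncated standard-normal draws, vectorized
#'
#' Samples Z | |Z| <= bound by inverse-CDF so that mass errors stay within a
#' hard accuracy window, as on a calibrated instrument.
#' @noRd
rnorm_trunc <- function(n, sd, bound = 4) {
  if (sd <= 0) return(rep(0, n))
  lo <- stats::pnorm(-bound)
  stats::qnorm(stats::runif(n, lo, 1 - lo)) * sd
}

#' Trapezoidal integral of y over a uniform grid with spacing dx
#' @noRd
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2) * dx
}

#' Sum of squares over non-missing cells
#' @noRd
ss_nonmissing <- function(x) sum(x^2, na.rm = TRUE)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
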