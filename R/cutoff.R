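#' Normalized cumulative spectrum
#'
#' The cumulative statistic `rc(i) = sum(s[1:i]) / sum(s)`: for a laminar
#' (step-shaped) spectrum it increases linearly up to the maximum frequency
#' shift and then stays flat. The normalization makes `rc(N) = 1`; since the
#' two-line intersection abscissa is invariant to any positive rescaling of
#' the spectrum, this choice carries no consequence for the estimated cutoff.
#'
#' @param spectrum A [PowerSpectrum-class].
#' @return Numeric vector of the same length as the spectrum; non-decreasing,
#'   ending at 1.
#' @examples
#' sp <- PowerSpectrum(1:8 * 100, c(1, 1, 1, 1, 0, 0, 0, 0))
#' cumulativeRc(sp)
#' @export
cumulativeRc <- function(spectrum) {
  stopifnot(is(spectrum, "PowerSpectrum"))
  total <- sum(spectrum@power)
  if (total <= 0) stop("no cutoff: spectrum has zero total power")
  cumsum(spectrum@power) / total
}

.olsLine <- function(x, y) {
  # plain least squares without lm() overhead; returns c(intercept, slope)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- if (sxx > 0) sum((x - mx) * (y - my)) / sxx else 0
  c(my - b * mx, b)
}

.noCutoff <- function(kx = NA_integer_) {
  new("CutoffResult", cutoffHz = NA_real_, kx = as.integer(kx),
      riseSlope = NA_real_, riseIntercept = NA_real_,
      plateauSlope = NA_real_, plateauIntercept = NA_real_,
      qualityFlag = "no_cutoff")
}

#' Detect the maximum Doppler frequency shift of a step spectrum
#'
#' Implements the cumulative-spectrum two-line intersection procedure:
#' \enumerate{
#'   \item compute `rc` with [cumulativeRc()];
#'   \item fit the plateau line by ordinary least squares over the last third
#'     of the bins (`ceiling(2N/3) .. N`), where only noise is expected;
#'   \item find `kx`, the largest bin whose `rc` lies at least 10\% below the
#'     local plateau-line value;
#'   \item fit the rise line over bins `1 .. kx`;
#'   \item the abscissa of the two lines' intersection, converted to Hz via
#'     the bin width, is the estimated cutoff.
#' }
#' The result is flagged `no_cutoff` when no rising region exists (`kx < 2`),
#' when the rise slope does not exceed the plateau slope by at least
#' `slopeFactor` (flat or noise-only spectra), or when the lines are
#' near-parallel; `out_of_band` when the intersection falls outside
#' `(0, Nyquist]`.
#'
#' @param spectrum A [PowerSpectrum-class].
#' @param dropFraction Relative deviation from the plateau line that defines
#'   `kx` (default 0.10).
#' @param slopeFactor Minimum ratio of rise slope to (positive) plateau slope
#'   for a credible cutoff (default 5).
#' @return A [CutoffResult-class].
#' @examples
#' s <- c(rep(1, 100), rep(0, 200))
#' sp <- PowerSpectrum(seq_along(s) * 100 / 3, s)
#' detectCutoff(sp)  # cutoff at bin 100 -> 3333 Hz
#' @export
detectCutoff <- function(spectrum, dropFraction = 0.10, slopeFactor = 5) {
  stopifnot(is(spectrum, "PowerSpectrum"))
  validObject(spectrum)
  n <- length(spectrum@power)
  if (sum(spectrum@power) <= 0) return(.noCutoff())
  rc <- cumsum(spectrum@power) / sum(spectrum@power)
  bins <- seq_len(n)

  i0 <- ceiling(2 * n / 3)
  pl <- .olsLine(bins[i0:n], rc[i0:n])
  plateauAt <- pl[1L] + pl[2L] * bins

  # small tolerance so exact-boundary bins (e.g. rc = 0.90 on a clean step)
  # qualify despite floating-point rounding
  qualifies <- which(plateauAt - rc >= dropFraction * plateauAt - 1e-12)
  if (length(qualifies) == 0L) return(.noCutoff())
  kx <- max(qualifies)
  if (kx < 2L) return(.noCutoff(kx))

  ri <- .olsLine(bins[1:kx], rc[1:kx])

  sep <- ri[2L] - pl[2L]
  if (ri[2L] <= 0 || sep <= .Machine$double.eps * max(1, abs(ri[2L])))
    return(.noCutoff(kx))
  if (pl[2L] > 0 && ri[2L] < slopeFactor * pl[2L])
    return(.noCutoff(kx))

  xStar <- (pl[1L] - ri[1L]) / sep
  df <- spectrum@frequencies[2L] - spectrum@frequencies[1L]
  f0 <- spectrum@frequencies[1L]
  cutoff <- f0 + (xStar - 1) * df
  nyquist <- spectrum@frequencies[n]
  flag <- if (!is.finite(cutoff) || cutoff <= 0 || cutoff > nyquist * (1 + 1e-9))
    "out_of_band" else "ok"
  new("CutoffResult",
      cutoffHz = if (flag == "ok") cutoff else NA_real_,
      kx = as.integer(kx),
      riseSlope = ri[2L], riseIntercept = ri[1L],
      plateauSlope = pl[2L], plateauIntercept = pl[1L],
      qualityFlag = flag)
}

#' @rdname CutoffResult-accessors
#' @export
setMethod("cutoffHz", "CutoffResult", function(object) object@cutoffHz)

#' @rdname CutoffResult-accessors
#' @export
setMethod("qualityFlag", "CutoffResult", function(object) object@qualityFlag)

setMethod("show", "CutoffResult", function(object) {
  if (object@qualityFlag == "ok") {
    cat(sprintf("CutoffResult: %.1f Hz (kx = %d, quality ok)\n",
                object@cutoffHz, object@kx))
  } else {
    cat(sprintf("CutoffResult: <%s>\n", object@qualityFlag))
  }
})

#' Absolute difference of two channel cutoffs
#'
#' @param resultA,resultB [CutoffResult-class] objects for channels A and B.
#' @return `|fA - fB|` in Hz, or `NA` (with a warning) when either input is
#'   not flagged `ok`.
#' @export
deltaCutoff <- function(resultA, resultB) {
  stopifnot(is(resultA, "CutoffResult"), is(resultB, "CutoffResult"))
  if (resultA@qualityFlag != "ok" || resultB@qualityFlag != "ok") {
    warning("no measurement: one or both cutoffs were not detected")
    return(NA_real_)
  }
  abs(resultA@cutoffHz - resultB@cutoffHz)
}
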