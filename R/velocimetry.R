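#' Absolute maximum velocity from the bidirectional Doppler geometry
#'
#' The maximum red-blood-cell velocity follows from the cutoff-frequency
#' difference of the two detection channels:
#' `vmax = lambda * |fA - fB| / (n * alpha * cos(beta))`,
#' with `alpha = atan(x / L)` the angle between the two detection directions.
#' The assumed axial length from the configuration is always used for
#' `alpha` (it is set identical for all subjects); a subject's measured
#' axial length enters only the pixel-to-micrometer conversion of the image
#' pipeline.
#'
#' @param deltaF Cutoff-frequency difference `|fA - fB|` in Hz, >= 0.
#' @param config An [OpticalConfig-class].
#' @param beta Angle between the velocity vector and the scattering plane,
#'   radians (default 0: the instrument nulls beta optically; nonzero values
#'   are for sensitivity studies).
#' @param frameIndex Frame counter.
#' @return A [VelocityEstimate-class]; `vmax(x)` gives m/s.
#' @examples
#' cfg <- OpticalConfig()
#' v <- computeVmax(3000, cfg)
#' 1000 * vmax(v)  # mm/s
#' @export
computeVmax <- function(deltaF, config, beta = 0, frameIndex = 0L) {
  stopifnot(is(config, "OpticalConfig"))
  if (!is.numeric(deltaF) || length(deltaF) != 1L || !is.finite(deltaF) ||
      deltaF < 0)
    stop("invalid input: deltaF must be a single non-negative frequency (Hz)")
  if (abs(beta) >= pi / 2) stop("invalid geometry: |beta| must be < 90 degrees")
  alpha <- scatteringAngle(config)
  if (alpha <= 0) stop("invalid geometry: scattering angle is zero")
  v <- config@wavelength * deltaF / (config@refractiveIndex * alpha * cos(beta))
  new("VelocityEstimate", vmax = v, deltaF = deltaF, alpha = alpha,
      beta = beta, frameIndex = as.integer(frameIndex))
}

#' Cutoff-frequency difference that yields a prescribed velocity
#'
#' Inverse of [computeVmax()]; the simulator uses it to place channel
#' cutoffs for a prescribed ground-truth velocity. The round trip
#' `computeVmax(invertVmaxToDeltaF(v, ...), ...)` reproduces `v` to
#' machine precision.
#'
#' @param vmaxMs Maximum velocity in m/s, >= 0.
#' @param config An [OpticalConfig-class].
#' @param beta Beta angle in radians.
#' @return Frequency difference in Hz.
#' @export
invertVmaxToDeltaF <- function(vmaxMs, config, beta = 0) {
  stopifnot(is(config, "OpticalConfig"))
  if (!is.numeric(vmaxMs) || length(vmaxMs) != 1L || !is.finite(vmaxMs) ||
      vmaxMs < 0)
    stop("invalid input: vmax must be a single non-negative velocity (m/s)")
  if (abs(beta) >= pi / 2) stop("invalid geometry: |beta| must be < 90 degrees")
  alpha <- scatteringAngle(config)
  if (alpha <= 0) stop("invalid geometry: scattering angle is zero")
  vmaxMs * config@refractiveIndex * alpha * cos(beta) / config@wavelength
}

#' @rdname velocity-accessors
#' @export
setMethod("vmax", "VelocityEstimate", function(object) object@vmax)

setMethod("show", "VelocityEstimate", function(object) {
  cat(sprintf(
    "VelocityEstimate: vmax = %.3f mm/s (deltaF = %.1f Hz, alpha = %.4f rad, beta = %.1f deg)\n",
    1e3 * object@vmax, object@deltaF, object@alpha, object@beta * 180 / pi))
})
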