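#' Construct a two-channel detector record
#'
#' @param channelA,channelB Equal-length numeric sample vectors.
#' @param samplingRate Sampling rate in Hz.
#' @param frameIndex Frame counter.
#' @return A [DetectorRecord-class].
#' @export
DetectorRecord <- function(channelA, channelB, samplingRate = 120000,
                           frameIndex = 0L) {
  new("DetectorRecord", channelA = as.numeric(channelA),
      channelB = as.numeric(channelB), samplingRate = samplingRate,
      frameIndex = as.integer(frameIndex))
}

#' Construct a power spectrum
#'
#' @param frequencies Ascending uniformly spaced frequencies in Hz.
#' @param power Non-negative power per bin.
#' @param channelLabel `"A"` or `"B"`.
#' @param frameIndex Frame counter.
#' @return A [PowerSpectrum-class].
#' @export
PowerSpectrum <- function(frequencies, power, channelLabel = "A",
                          frameIndex = 0L) {
  new("PowerSpectrum", frequencies = as.numeric(frequencies),
      power = as.numeric(power), channelLabel = channelLabel,
      frameIndex = as.integer(frameIndex))
}

#' @rdname PowerSpectrum-accessors
#' @export
setMethod("frequencies", "PowerSpectrum", function(object) object@frequencies)

#' @rdname PowerSpectrum-accessors
#' @export
setMethod("spectralPower", "PowerSpectrum", function(object) object@power)

#' @rdname PowerSpectrum-accessors
#' @export
setMethod("channelLabel", "PowerSpectrum", function(object) object@channelLabel)

setMethod("show", "PowerSpectrum", function(object) {
  n <- length(object@power)
  cat(sprintf("PowerSpectrum (channel %s, frame %d)\n",
              object@channelLabel, object@frameIndex))
  cat(sprintf("  %d bins, %.2f - %.2f Hz (df = %.3f Hz)\n",
              n, object@frequencies[1L], object@frequencies[n],
              object@frequencies[2L] - object@frequencies[1L]))
  cat(sprintf("  total power %.4g\n", sum(object@power)))
})

setMethod("show", "DetectorRecord", function(object) {
  cat(sprintf("DetectorRecord (frame %d): %d samples at %.0f Hz (%.1f ms)\n",
              object@frameIndex, length(object@channelA), object@samplingRate,
              1e3 * length(object@channelA) / object@samplingRate))
})

## One-sided periodogram of a de-meaned signal. Bin k (1-based, DC excluded)
## sits at k * fs / n. Scaling is chosen so that the summed one-sided power
## equals the population variance of the de-meaned input (Parseval).
.periodogram <- function(x, fs, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  n <- length(x)
  x <- x - mean(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w / sqrt(mean(w^2))  # preserve average power
  }
  X <- stats::fft(x)
  half <- n %/% 2L
  p <- (2 / n^2) * Mod(X[2L:(half + 1L)])^2
  if (n %% 2L == 0L) p[half] <- p[half] / 2  # Nyquist bin is not doubled
  list(frequencies = (1:half) * fs / n, power = p)
}

#' Compute per-channel Doppler power spectra
#'
#' Subtracts each channel's mean (digital stand-in for the instrument's
#' analog DC-removal), computes a single periodogram over the record, and
#' returns the one-sided spectrum per channel with the DC bin excluded so
#' that bin `k` corresponds to frequency `k * fs / n`. The summed one-sided
#' power equals the (population) variance of the de-meaned signal.
#'
#' @param record A [DetectorRecord-class].
#' @param window `"rectangular"` (default: one plain periodogram per 30 ms
#'   frame, as acquired) or `"hann"` for noise-robustness experiments.
#' @return A list with elements `A` and `B`, each a [PowerSpectrum-class].
#' @examples
#' t <- seq(0, 0.03, length.out = 3601)[-3601]
#' rec <- DetectorRecord(sin(2 * pi * 3000 * t), cos(2 * pi * 5000 * t))
#' sp <- computePowerSpectrum(rec)
#' frequencies(sp$A)[which.max(spectralPower(sp$A))]  # 3000 Hz
#' @export
computePowerSpectrum <- function(record, window = c("rectangular", "hann")) {
  stopifnot(is(record, "DetectorRecord"))
  validObject(record)
  window <- match.arg(window)
  if (length(record@channelA) < 16L)
    stop("invalid input: record shorter than one analysis window")
  pa <- .periodogram(record@channelA, record@samplingRate, window)
  pb <- .periodogram(record@channelB, record@samplingRate, window)
  list(
    A = PowerSpectrum(pa$frequencies, pa$power, "A", record@frameIndex),
    B = PowerSpectrum(pb$frequencies, pb$power, "B", record@frameIndex)
  )
}

#' Write / read detector records as CSV
#'
#' Two columns `channel_a,channel_b` preceded by a comment line
#' `# sampling_rate_hz=<fs>`.
#'
#' @param record A [DetectorRecord-class].
#' @param path Output file.
#' @return `readDetectorCsv` returns a [DetectorRecord-class];
#'   `writeDetectorCsv` returns `path` invisibly.
#' @export
writeDetectorCsv <- function(record, path) {
  stopifnot(is(record, "DetectorRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g", record@samplingRate), con)
  utils::write.csv(
    data.frame(channel_a = record@channelA, channel_b = record@channelB),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDetectorCsv
#' @param frameIndex Frame counter to attach on read.
#' @export
readDetectorCsv <- function(path, frameIndex = 0L) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("sampling_rate_hz=([0-9.eE+-]+)", first))[[1L]]
  if (length(m) < 2L)
    stop("invalid input: missing '# sampling_rate_hz=' header comment")
  df <- utils::read.csv(path, comment.char = "#")
  DetectorRecord(df$channel_a, df$channel_b, as.numeric(m[2L]), frameIndex)
}

#' Write / read spectrum pairs as CSV
#'
#' Columns `frequency_hz,power_a,power_b,frame_index`; several frames may be
#' stacked in one file.
#'
#' @param spectra A list with elements `A` and `B` ([PowerSpectrum-class]),
#'   or a list of such pairs.
#' @param path File path.
#' @return `readSpectraCsv` returns a list of `A`/`B` pairs (one per frame);
#'   `writeSpectraCsv` returns `path` invisibly.
#' @export
writeSpectraCsv <- function(spectra, path) {
  if (is(spectra$A, "PowerSpectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(pair) {
    stopifnot(is(pair$A, "PowerSpectrum"), is(pair$B, "PowerSpectrum"))
    data.frame(frequency_hz = pair$A@frequencies, power_a = pair$A@power,
               power_b = pair$B@power, frame_index = pair$A@frameIndex)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCsv
#' @export
readSpectraCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frequency_hz", "power_a", "power_b", "frame_index")
  if (!all(need %in% names(df)))
    stop("invalid input: spectra CSV must have columns ",
         paste(need, collapse = ", "))
  lapply(split(df, df$frame_index), function(d) {
    list(A = PowerSpectrum(d$frequency_hz, d$power_a, "A", d$frame_index[1L]),
         B = PowerSpectrum(d$frequency_hz, d$power_b, "B", d$frame_index[1L]))
  })
}
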