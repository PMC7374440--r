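#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters every channel of a record with a Butterworth filter of
#' the given overall order. With \code{zeroPhase = TRUE} the filter is
#' applied forward and backward (filtfilt), which doubles the magnitude
#' attenuation in dB and cancels the phase shift; this is the convention
#' used for both the 15-450 Hz EMG and the 5-100 Hz EEG conditioning.
#'
#' @param record a \linkS4class{SignalRecord}.
#' @param low,high corner frequencies in Hz, 0 < low < high < Nyquist.
#' @param order overall filter order (must be even for a band-pass; the
#'   underlying low-pass prototype has order \code{order/2}).
#' @param zeroPhase apply forward-backward for zero net phase shift.
#' @return a \linkS4class{SignalRecord} with filtered samples.
#' @export
bandpassFilter <- function(record, low, high, order = 4L, zeroPhase = TRUE) {
  fs <- samplingRate(record)
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("corner frequencies must satisfy 0 < low < high < Nyquist (",
         nyq, " Hz)")
  if (order %% 2 != 0)
    stop("'order' must be even for a band-pass design")
  ba <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  x <- signalMatrix(record)
  y <- apply(x, 2L, function(col) {
    if (zeroPhase) signal::filtfilt(ba, col) else
      as.numeric(signal::filter(ba, col))
  })
  SignalRecord(y, fs, channelRoles(record), annotations(record),
               record@metadata)
}

#' Analytic magnitude of the band-pass Butterworth response
#'
#' Closed-form magnitude |H(f)| of an analog Butterworth band-pass filter,
#' used as an independent check on the digital design away from the corners.
#' For a forward-backward application the magnitude is |H|^2.
#'
#' @param f frequency in Hz at which to evaluate.
#' @param low,high corner frequencies in Hz.
#' @param order overall filter order (even).
#' @return magnitude response in (0, 1].
#' @export
butterBandpassGain <- function(f, low, high, order) {
  w <- 2 * pi * f; w1 <- 2 * pi * low; w2 <- 2 * pi * high
  n <- order / 2
  s <- (w^2 - w1 * w2) / (w * (w2 - w1))
  1 / sqrt(1 + s^(2 * n))
}

.trailingMean <- function(a, win) {
  # mean of a over the trailing window of `win` samples ending at each
  # sample; partial windows at the start use the available samples only
  cs <- cumsum(a)
  n <- length(a)
  idx <- seq_len(n)
  lo <- idx - win
  full <- lo >= 1L
  out <- numeric(n)
  out[full] <- (cs[idx[full]] - cs[lo[full]]) / win
  out[!full] <- cs[idx[!full]] / idx[!full]
  out
}

#' Rectified moving-window amplitude envelope
#'
#' Computes, at each output tick, the mean of the rectified signal |x| over
#' the trailing window ending at that tick (causal, as required for
#' real-time feedback). Ticks earlier than one full window average the
#' samples available so far. Output ticks are placed at multiples of
#' \code{1/outputRate} (e.g. the 250 Hz rate of the training feedback, or
#' the source rate for the 1 s static-hold cursor).
#'
#' @param record a \linkS4class{SignalRecord}.
#' @param role channel role to process.
#' @param window window length in seconds (> 0).
#' @param outputRate output rate in Hz (defaults to the record's rate; must
#'   not exceed it).
#' @param which index among channels sharing the role.
#' @return an \linkS4class{EnvelopeSeries} at \code{outputRate}.
#' @export
movingEnvelope <- function(record, role, window, outputRate = NULL,
                           which = 1L) {
  fs <- samplingRate(record)
  if (is.null(outputRate)) outputRate <- fs
  if (outputRate > fs)
    stop("'outputRate' must not exceed the record sampling rate")
  if (window <= 0) stop("'window' must be positive")
  x <- channelSamples(record, role, which)
  win <- round(window * fs)
  if (win < 1L) win <- 1L
  if (win > length(x))
    stop("'window' is longer than the record")
  env <- .trailingMean(abs(x), win)
  # sample the trailing mean at the output ticks
  nOut <- floor(length(x) / fs * outputRate + 1e-9)
  ticks <- pmin(length(x), round(seq_len(nOut) * fs / outputRate))
  new("EnvelopeSeries", values = env[ticks], outputRate = outputRate,
      windowLength = win / fs, sourceChannel = role)
}

.analyticSignal <- function(x) {
  # FFT construction of the analytic signal: double positive frequencies,
  # zero negative ones, keep DC (and Nyquist for even n)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert amplitude envelope
#'
#' Magnitude of the analytic signal, computed via the FFT construction.
#' The input should be band-pass filtered beforehand (15-450 Hz for EMG) so
#' the analytic magnitude is a meaningful amplitude envelope.
#'
#' @param record a \linkS4class{SignalRecord}.
#' @param role channel role to process.
#' @param which index among channels sharing the role.
#' @return an \linkS4class{EnvelopeSeries} at the record's sampling rate,
#'   with \code{windowLength = 0}.
#' @export
hilbertEnvelope <- function(record, role, which = 1L) {
  x <- channelSamples(record, role, which)
  new("EnvelopeSeries", values = Mod(.analyticSignal(x)),
      outputRate = samplingRate(record), windowLength = 0,
      sourceChannel = role)
}

#' Hilbert envelope of a plain numeric vector
#'
#' Convenience wrapper used for epoch-wise processing where the epochs are
#' already extracted from a record.
#'
#' @param x numeric vector (band-pass filtered signal).
#' @return numeric vector, the analytic magnitude of \code{x}.
#' @export
hilbertEnvelopeVector <- function(x) Mod(.analyticSignal(x))

#' Standardize a series to zero mean and unit variance
#'
#' @param x an \linkS4class{EnvelopeSeries} or numeric vector.
#' @return object of the same type with mean 0 and SD 1.
#' @export
standardizeSeries <- function(x) {
  v <- if (is(x, "EnvelopeSeries")) x@values else x
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant series (zero variance)")
  z <- (v - mean(v)) / s
  if (is(x, "EnvelopeSeries")) {
    initialize(x, values = z)
  } else z
}

#' Normalization references for EMG amplitudes
#'
#' Builds the per-channel scale/offset pair used to express envelopes either
#' as a fraction of the maximal power-grip amplitude (\code{power_grip_max}:
#' offset 0, scale = grip maximum) or as a Z-score relative to a reference
#' session (\code{session_zscore}: offset = reference mean, scale =
#' reference SD).
#'
#' @param kind \code{"power_grip_max"} or \code{"session_zscore"}.
#' @param scale named numeric vector of per-channel scales (> 0), names are
#'   channel roles.
#' @param offset named numeric vector of per-channel offsets (defaults to 0).
#' @return a \code{NormalizationReference} (list with class attribute).
#' @export
normalizationReference <- function(kind = c("power_grip_max",
                                            "session_zscore"),
                                   scale, offset = NULL) {
  kind <- match.arg(kind)
  if (any(scale <= 0)) stop("normalization scales must be positive")
  if (is.null(offset)) offset <- setNames(numeric(length(scale)),
                                          names(scale))
  if (kind == "power_grip_max" && any(offset != 0))
    stop("power_grip_max normalization has zero offset by definition")
  structure(list(kind = kind, scale = scale, offset = offset),
            class = "NormalizationReference")
}

#' Build a session Z-score reference from observed amplitudes
#'
#' @param values named list of numeric vectors of per-trial amplitudes from
#'   the reference session, one entry per channel/metric.
#' @return a \code{session_zscore} \code{NormalizationReference}.
#' @export
sessionZScoreReference <- function(values) {
  mu <- vapply(values, mean, numeric(1))
  sdv <- vapply(values, stats::sd, numeric(1))
  if (any(!is.finite(sdv)) || any(sdv == 0))
    stop("reference session has zero-variance amplitudes")
  normalizationReference("session_zscore", scale = sdv, offset = mu)
}

#' Apply a normalization reference to an envelope
#'
#' @param env an \linkS4class{EnvelopeSeries} (or numeric vector with
#'   \code{channel} given).
#' @param ref a \code{NormalizationReference}.
#' @param channel channel role to look up in the reference; defaults to the
#'   envelope's source channel.
#' @return envelope in normalized units: fraction-of-maximum for
#'   \code{power_grip_max}, Z units for \code{session_zscore}.
#' @export
normalizeToReference <- function(env, ref, channel = NULL) {
  stopifnot(inherits(ref, "NormalizationReference"))
  if (is(env, "EnvelopeSeries")) {
    if (is.null(channel)) channel <- env@sourceChannel
    if (!channel %in% names(ref$scale))
      stop("reference has no entry for channel '", channel, "'")
    initialize(env, values = (env@values - ref$offset[[channel]]) /
                 ref$scale[[channel]])
  } else {
    if (is.null(channel))
      stop("'channel' is required for plain numeric input")
    if (!channel %in% names(ref$scale))
      stop("reference has no entry for channel '", channel, "'")
    (env - ref$offset[[channel]]) / ref$scale[[channel]]
  }
}

#' @rdname EnvelopeSeries-class
#' @export
setMethod("envelopeValues", "EnvelopeSeries", function(x) x@values)

#' @rdname EnvelopeSeries-class
#' @export
setMethod("outputRate", "EnvelopeSeries", function(x) x@outputRate)

setMethod("show", "EnvelopeSeries", function(object) {
  cat("EnvelopeSeries:", length(object@values), "samples @",
      object@outputRate, "Hz, window", object@windowLength, "s, source",
      object@sourceChannel, "\n")
})
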