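#' @import methods
NULL

.VALID_ROLES <- c("ECR", "ECU", "FCR", "FCU", "EEG_ipsi", "EEG_contra", "other")
.VALID_ANNOT_KINDS <- c("rest", "attempt", "hold_plateau", "grip")

#' SignalRecord: a uniformly sampled multichannel biosignal
#'
#' Container for a block of uniformly sampled time series (time along rows,
#' channels along columns) together with its sampling rate, the physiological
#' role of each channel (wrist extensors ECR/ECU, flexors FCR/FCU, EEG, or
#' other) and interval annotations marking task events (rest, movement
#' attempt, static-hold plateau, maximal grip).
#'
#' @slot samples numeric matrix, time x channel.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelRoles character vector, one role per column of
#'   \code{samples}; one of \code{ECR, ECU, FCR, FCU, EEG_ipsi, EEG_contra,
#'   other}.
#' @slot annotations data.frame with columns \code{kind} (one of
#'   \code{rest, attempt, hold_plateau, grip}), \code{start}, \code{end}
#'   (seconds, relative to the first sample) and \code{trial_index}.
#' @slot metadata free-form list; generators store ground-truth parameters
#'   (e.g. the simulated power-grip maximum) here.
#'
#' @seealso [SignalRecord()] for the user constructor,
#'   [generateCoherentPair()], [generateTrainingSession()],
#'   [generateStaticHold()] for synthetic records.
#' @export
setClass("SignalRecord",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    channelRoles = "character",
    annotations = "data.frame",
    metadata = "list"
  )
)

setValidity("SignalRecord", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "'samples' must be a numeric matrix")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  if (length(object@channelRoles) != ncol(object@samples))
    msg <- c(msg, "one channel role per column of 'samples' is required")
  if (!all(object@channelRoles %in% .VALID_ROLES))
    msg <- c(msg, paste0("channel roles must be in {",
                         paste(.VALID_ROLES, collapse = ", "), "}"))
  ann <- object@annotations
  if (nrow(ann)) {
    need <- c("kind", "start", "end", "trial_index")
    if (!all(need %in% names(ann))) {
      msg <- c(msg, "annotations need columns kind/start/end/trial_index")
    } else {
      dur <- nrow(object@samples) / object@samplingRate
      if (!all(ann$kind %in% .VALID_ANNOT_KINDS))
        msg <- c(msg, "unknown annotation kind")
      if (any(ann$start >= ann$end))
        msg <- c(msg, "annotation intervals must have start < end")
      if (any(ann$start < 0) || any(ann$end > dur + 1e-9))
        msg <- c(msg, "annotation intervals must lie within the record")
    }
  }
  if (length(msg)) msg else TRUE
})

#' EnvelopeSeries: an EMG amplitude envelope
#'
#' A single-channel amplitude envelope, possibly resampled to a lower output
#' rate than its source record (e.g. the 250 Hz feedback rate of the
#' training task). Values of rectified moving-window or Hilbert envelopes
#' are nonnegative; standardized or Z-scored envelopes may be negative.
#'
#' @slot values numeric envelope samples.
#' @slot outputRate output sampling rate in Hz.
#' @slot windowLength smoothing window length in seconds (0 for the
#'   sample-wise Hilbert envelope).
#' @slot sourceChannel role of the channel the envelope came from.
#' @export
setClass("EnvelopeSeries",
  representation(
    values = "numeric",
    outputRate = "numeric",
    windowLength = "numeric",
    sourceChannel = "character"
  )
)

setValidity("EnvelopeSeries", function(object) {
  msg <- character()
  if (length(object@outputRate) != 1L || object@outputRate <= 0)
    msg <- c(msg, "'outputRate' must be a single positive number")
  if (length(object@windowLength) != 1L || object@windowLength < 0)
    msg <- c(msg, "'windowLength' must be a single nonnegative number")
  if (length(object@sourceChannel) != 1L)
    msg <- c(msg, "'sourceChannel' must be a single string")
  if (length(msg)) msg else TRUE
})

#' CoherenceSpectrum: magnitude-squared coherence with its confidence limit
#'
#' The result of Welch-style pooled coherence estimation: a frequency grid,
#' coherence in [0,1] per frequency, the effective number of independent
#' segments L (corrected for window tapering and overlap, hence possibly
#' non-integer), and the analytic 95% confidence level
#' CL = 1 - 0.05^(1/(L-1)). Estimated coherence below CL is consistent with
#' zero underlying coherence at the 5% level.
#'
#' @slot frequencies frequency grid in Hz.
#' @slot coherence magnitude-squared coherence per frequency, in [0, 1].
#' @slot L effective number of independent segments (>= 1, non-integer when
#'   overlap-corrected).
#' @slot confidenceLevel the 95% confidence level for zero coherence.
#' @export
setClass("CoherenceSpectrum",
  representation(
    frequencies = "numeric",
    coherence = "numeric",
    L = "numeric",
    confidenceLevel = "numeric"
  )
)

setValidity("CoherenceSpectrum", function(object) {
  msg <- character()
  if (length(object@frequencies) != length(object@coherence))
    msg <- c(msg, "'frequencies' and 'coherence' must have equal length")
  if (any(object@coherence < -1e-12 | object@coherence > 1 + 1e-12))
    msg <- c(msg, "'coherence' must lie in [0, 1]")
  if (length(object@L) != 1L || object@L < 1)
    msg <- c(msg, "'L' must be a single number >= 1")
  if (length(object@confidenceLevel) != 1L ||
      object@confidenceLevel <= 0 || object@confidenceLevel >= 1)
    msg <- c(msg, "'confidenceLevel' must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' ZDiffSpectrum: standardized pre/post difference of coherence
#'
#' Per-frequency Z scores for the difference between two coherence spectra,
#' computed on the Fisher scale FZ = atanh(sqrt(coh)). Under the null of
#' equal underlying coherence each Z is approximately standard normal.
#'
#' @slot frequencies frequency grid in Hz (shared by both spectra).
#' @slot z standardized difference per frequency.
#' @slot LPre,LPost effective segment counts of the two input spectra.
#' @slot method denominator convention, \code{"pooled"} or \code{"literal"}.
#' @export
setClass("ZDiffSpectrum",
  representation(
    frequencies = "numeric",
    z = "numeric",
    LPre = "numeric",
    LPost = "numeric",
    method = "character"
  )
)

setValidity("ZDiffSpectrum", function(object) {
  msg <- character()
  if (length(object@frequencies) != length(object@z))
    msg <- c(msg, "'frequencies' and 'z' must have equal length")
  if (length(msg)) msg else TRUE
})
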