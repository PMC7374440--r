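#' Construct a SignalRecord
#'
#' @param samples numeric matrix (time x channel) or a numeric vector for a
#'   single channel.
#' @param samplingRate sampling rate in Hz.
#' @param channelRoles character vector of channel roles (see
#'   \linkS4class{SignalRecord}).
#' @param annotations data.frame with columns \code{kind}, \code{start},
#'   \code{end}, \code{trial_index}; may be empty.
#' @param metadata free-form list of provenance/ground-truth entries.
#' @return a validated \linkS4class{SignalRecord}.
#' @examples
#' rec <- SignalRecord(matrix(rnorm(2000), ncol = 2), 1000,
#'                     c("ECR", "EEG_contra"))
#' recordDuration(rec)
#' @export
SignalRecord <- function(samples, samplingRate, channelRoles,
                         annotations = emptyAnnotations(),
                         metadata = list()) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  storage.mode(samples) <- "double"
  if (length(channelRoles) == ncol(samples))
    colnames(samples) <- make.unique(channelRoles, sep = "_")
  new("SignalRecord", samples = samples, samplingRate = samplingRate,
      channelRoles = channelRoles, annotations = annotations,
      metadata = metadata)
}

#' Empty annotation table
#'
#' @return a zero-row data.frame with the annotation columns.
#' @export
emptyAnnotations <- function() {
  data.frame(kind = character(), start = numeric(), end = numeric(),
             trial_index = integer(), stringsAsFactors = FALSE)
}

#' @rdname SignalRecord-class
#' @export
setMethod("samplingRate", "SignalRecord", function(x) x@samplingRate)

#' @rdname SignalRecord-class
#' @export
setMethod("channelRoles", "SignalRecord", function(x) x@channelRoles)

#' @rdname SignalRecord-class
#' @export
setMethod("annotations", "SignalRecord", function(x) x@annotations)

#' @rdname SignalRecord-class
#' @export
setMethod("signalMatrix", "SignalRecord", function(x) x@samples)

#' @rdname SignalRecord-class
#' @export
setMethod("recordDuration", "SignalRecord",
          function(x) nrow(x@samples) / x@samplingRate)

setMethod("show", "SignalRecord", function(object) {
  cat("SignalRecord:", nrow(object@samples), "samples x",
      ncol(object@samples), "channels @", object@samplingRate, "Hz (",
      sprintf("%.1f", recordDuration(object)), "s )\n")
  cat("  roles:", paste(object@channelRoles, collapse = ", "), "\n")
  ann <- object@annotations
  if (nrow(ann))
    cat("  annotations:", nrow(ann), "intervals (",
        paste(sprintf("%s: %d", names(table(ann$kind)), table(ann$kind)),
              collapse = ", "), ")\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Extract one channel of a record by role
#'
#' @param record a \linkS4class{SignalRecord}.
#' @param role a channel role present in the record; if several channels
#'   share the role, \code{which} selects among them.
#' @param which index among channels with that role.
#' @return numeric vector of samples.
#' @export
channelSamples <- function(record, role, which = 1L) {
  idx <- which(channelRoles(record) == role)
  if (!length(idx))
    stop("no channel with role '", role, "' in record")
  record@samples[, idx[which]]
}

#' Restrict a record to a set of channels
#'
#' @param record a \linkS4class{SignalRecord}.
#' @param index integer or logical index over channels.
#' @return a \linkS4class{SignalRecord} with the selected channels.
#' @export
selectChannels <- function(record, index) {
  SignalRecord(record@samples[, index, drop = FALSE], record@samplingRate,
               record@channelRoles[index], record@annotations,
               record@metadata)
}

#' Cut annotated intervals out of a channel
#'
#' Returns the per-interval sample epochs of one channel, e.g. all
#' \code{hold_plateau} or \code{attempt} windows, for epoch-wise analyses
#' such as pooled coherence.
#'
#' @param record a \linkS4class{SignalRecord}.
#' @param role channel role to extract.
#' @param kind annotation kind selecting the intervals.
#' @param which index among channels with that role.
#' @return list of numeric vectors, one per annotation of that kind, in
#'   annotation order.
#' @export
annotationEpochs <- function(record, role, kind, which = 1L) {
  ann <- annotations(record)
  ann <- ann[ann$kind == kind, , drop = FALSE]
  if (!nrow(ann))
    stop("record has no '", kind, "' annotations")
  x <- channelSamples(record, role, which)
  fs <- samplingRate(record)
  lapply(seq_len(nrow(ann)), function(i) {
    i0 <- floor(ann$start[i] * fs) + 1L
    i1 <- min(length(x), floor(ann$end[i] * fs))
    x[i0:i1]
  })
}
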