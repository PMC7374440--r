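#' Write a SignalRecord as CSV plus a JSON sidecar
#'
#' The samples go to \code{<path>.csv} (a time column in seconds, then one
#' column per channel, header row naming the channel roles); sampling rate,
#' roles, annotations and metadata go to \code{<path>.json}. The round trip
#' through [readSignalRecord()] is lossless to full double precision.
#'
#' @param record a \linkS4class{SignalRecord}.
#' @param path file path without extension.
#' @return invisibly, the two file paths written.
#' @export
writeSignalRecord <- function(record, path) {
  csv <- paste0(path, ".csv"); json <- paste0(path, ".json")
  x <- signalMatrix(record)
  df <- data.frame(time = (seq_len(nrow(x)) - 1L) / samplingRate(record),
                   x, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   csv, row.names = FALSE, quote = FALSE)
  side <- list(sampling_rate = samplingRate(record),
               channel_roles = channelRoles(record),
               annotations = annotations(record),
               metadata = record@metadata)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = csv, json = json))
}

#' Read a SignalRecord written by [writeSignalRecord()]
#'
#' @param path file path without extension.
#' @return a \linkS4class{SignalRecord}.
#' @export
readSignalRecord <- function(path) {
  csv <- paste0(path, ".csv"); json <- paste0(path, ".json")
  if (!file.exists(json))
    stop("missing JSON sidecar: ", json)
  if (!file.exists(csv))
    stop("missing sample CSV: ", csv)
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  df <- utils::read.csv(csv, check.names = FALSE)
  samples <- as.matrix(df[, -1, drop = FALSE])
  ann <- side$annotations
  if (is.null(ann) || !length(ann)) ann <- emptyAnnotations()
  ann <- as.data.frame(ann)
  md <- side$metadata
  if (is.null(md)) md <- list()
  SignalRecord(samples, side$sampling_rate, side$channel_roles, ann, md)
}
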