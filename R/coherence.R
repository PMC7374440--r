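#' EEG preprocessing: band-pass and common-average reference
#'
#' Drops the listed bad channels, band-pass filters the remaining channels
#' (5-100 Hz, 6th-order zero-phase Butterworth by default) and re-references
#' each sample by subtracting the across-channel mean of the retained
#' channels.
#'
#' @param record a \linkS4class{SignalRecord} of EEG channels.
#' @param badChannels integer indices or column names of channels to
#'   exclude before referencing.
#' @param low,high,order band-pass parameters.
#' @return a \linkS4class{SignalRecord} of the retained, filtered,
#'   re-referenced channels.
#' @export
preprocessEEG <- function(record, badChannels = integer(), low = 5,
                          high = 100, order = 6L) {
  x <- signalMatrix(record)
  keep <- seq_len(ncol(x))
  if (length(badChannels)) {
    if (is.character(badChannels))
      badChannels <- match(badChannels, colnames(x))
    keep <- setdiff(keep, badChannels)
  }
  if (length(keep) < 2L)
    stop("at least two channels must remain after exclusion")
  rec <- selectChannels(record, keep)
  rec <- bandpassFilter(rec, low, high, order = order, zeroPhase = TRUE)
  y <- signalMatrix(rec)
  y <- y - rowMeans(y)
  SignalRecord(y, samplingRate(rec), channelRoles(rec), annotations(rec),
               rec@metadata)
}

.hannWindow <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

.segWindow <- function(n, window = c("hann", "rect")) {
  switch(match.arg(window), hann = .hannWindow(n), rect = rep(1, n))
}

.segmentStarts <- function(len, nSeg, shift)
  if (len < nSeg) integer(0) else seq(1L, len - nSeg + 1L, by = shift)

.effectiveL <- function(epochLengths, nSeg, shift, w) {
  # variance-equivalent number of independent segments for tapered,
  # overlapping segments tiled within epochs: the per-epoch variance
  # inflation is 1 + 2*sum_m (1 - m/K) c_m^2 with c_m the normalized
  # window overlap correlation at lag m*shift; segments of different
  # epochs are independent
  counts <- vapply(epochLengths, function(l)
    length(.segmentStarts(l, nSeg, shift)), integer(1))
  K <- sum(counts)
  if (K < 1) stop("no full segment fits in any epoch")
  maxM <- max(0L, floor((nSeg - 1) / shift))
  c2 <- vapply(seq_len(maxM), function(m) {
    i <- seq_len(nSeg - m * shift)
    (sum(w[i] * w[i + m * shift]) / sum(w^2))^2
  }, numeric(1))
  denom <- sum(vapply(counts[counts > 0], function(Ke) {
    m <- seq_len(min(maxM, Ke - 1L))
    infl <- 1 + if (length(m)) 2 * sum((1 - m / Ke) * c2[m]) else 0
    Ke * infl
  }, numeric(1)))
  K^2 / denom
}

.asEpochList <- function(x) if (is.list(x)) x else list(x)

#' Pooled magnitude-squared coherence
#'
#' Welch-style coherence on Hann-windowed overlapping segments (512 ms and
#' 75% overlap by default), pooled over a list of epochs: auto- and
#' cross-periodograms are averaged over all segments of all epochs, and
#' segments are tiled strictly within epochs so no segment straddles a
#' concatenation boundary. Pooling over several signal pairs (channels,
#' participants) is done by extending the epoch lists pairwise.
#'
#' The effective number of independent segments L is the variance-
#' equivalent count corrected for window tapering and overlap, and sets the
#' 95% confidence level for zero coherence, CL = 1 - 0.05^(1/(L-1)).
#'
#' @param x,y numeric vectors or lists of epoch vectors; pairwise entries
#'   must have equal lengths.
#' @param samplingRate sampling rate in Hz.
#' @param segmentSec segment length in seconds (default 0.512).
#' @param overlap fractional segment overlap in [0, 1) (default 0.75).
#' @param window segment taper: \code{"hann"} (default) or \code{"rect"}.
#'   With a Hann taper adjacent frequency bins are correlated by spectral
#'   leakage; rectangular non-overlapping segments give independent bins,
#'   which matters when bins are combined across a band.
#' @return a \linkS4class{CoherenceSpectrum}.
#' @examples
#' set.seed(1)
#' s <- rnorm(10000)
#' sp <- pooledCoherence(s, s + 0.5 * rnorm(10000), 1000)
#' @export
pooledCoherence <- function(x, y, samplingRate, segmentSec = 0.512,
                            overlap = 0.75, window = "hann") {
  x <- .asEpochList(x); y <- .asEpochList(y)
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same number of epochs")
  lx <- lengths(x)
  if (!all(lx == lengths(y)))
    stop("paired epochs must have equal lengths")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  nSeg <- round(segmentSec * samplingRate)
  shift <- max(1L, round(nSeg * (1 - overlap)))
  if (all(lx < nSeg)) stop("every epoch is shorter than one segment")
  w <- .segWindow(nSeg, window)
  nF <- nSeg %/% 2 + 1L
  Pxx <- Pyy <- numeric(nF)
  Pxy <- complex(nF)
  for (e in seq_along(x)) {
    for (s0 in .segmentStarts(lx[e], nSeg, shift)) {
      i <- s0:(s0 + nSeg - 1L)
      X <- stats::fft(w * x[[e]][i])[seq_len(nF)]
      Y <- stats::fft(w * y[[e]][i])[seq_len(nF)]
      Pxx <- Pxx + Mod(X)^2
      Pyy <- Pyy + Mod(Y)^2
      Pxy <- Pxy + X * Conj(Y)
    }
  }
  coh <- Mod(Pxy)^2 / (Pxx * Pyy)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  L <- .effectiveL(lx, nSeg, shift, w)
  new("CoherenceSpectrum",
      frequencies = (seq_len(nF) - 1L) * samplingRate / nSeg,
      coherence = coh, L = L, confidenceLevel = confidenceLevel(L))
}

#' Analytic confidence level for zero coherence
#'
#' The level below which an estimated coherence is consistent with zero
#' underlying coherence: CL = 1 - alpha^(1/(L-1)) for L independent
#' averaged segments, alpha = 0.05 for the conventional 95% level.
#'
#' @param L effective number of independent segments (> 1).
#' @param alpha significance level (default 0.05).
#' @return the confidence level in (0, 1).
#' @examples
#' confidenceLevel(2)    # 0.95
#' confidenceLevel(21)   # ~0.139
#' @export
confidenceLevel <- function(L, alpha = 0.05) {
  if (any(L <= 1)) stop("'L' must exceed 1")
  1 - alpha^(1 / (L - 1))
}

#' Fisher transform of coherence
#'
#' The variance-stabilizing transform FZ = atanh(sqrt(coh)); its sampling
#' variance is approximately 1/(2L) for L independent segments.
#'
#' @param coh magnitude-squared coherence in [0, 1].
#' @return Fisher-transformed values.
#' @export
fisherZ <- function(coh) atanh(sqrt(pmin(pmax(coh, 0), 1 - 1e-12)))

#' Standardized pre/post difference of coherence spectra
#'
#' Per frequency, z = (FZpost - FZpre) / SD where FZ = atanh(sqrt(coh)).
#' The default \code{"pooled"} denominator sqrt(1/(2*Lpre) + 1/(2*Lpost))
#' uses the Fisher variance 1/(2L) of each spectrum and reduces to
#' sqrt(1/L) when both spectra share the same L; the \code{"literal"} mode
#' uses sqrt(1/L) with L = min(Lpre, Lpost).
#'
#' @param pre,post \linkS4class{CoherenceSpectrum} objects on identical
#'   frequency grids.
#' @param method \code{"pooled"} (default) or \code{"literal"}.
#' @return a \linkS4class{ZDiffSpectrum}.
#' @export
zDifference <- function(pre, post, method = c("pooled", "literal")) {
  method <- match.arg(method)
  stopifnot(is(pre, "CoherenceSpectrum"), is(post, "CoherenceSpectrum"))
  if (length(frequencies(pre)) != length(frequencies(post)) ||
      any(abs(frequencies(pre) - frequencies(post)) > 1e-9))
    stop("pre and post spectra must share one frequency grid")
  dz <- fisherZ(coherenceValues(post)) - fisherZ(coherenceValues(pre))
  sdv <- switch(method,
    pooled = sqrt(1 / (2 * pre@L) + 1 / (2 * post@L)),
    literal = sqrt(1 / min(pre@L, post@L)))
  new("ZDiffSpectrum", frequencies = frequencies(pre), z = dz / sdv,
      LPre = pre@L, LPost = post@L, method = method)
}

#' Stouffer composite Z over a frequency band
#'
#' Combines the per-frequency Z scores of a \linkS4class{ZDiffSpectrum}
#' within a band into one composite, sum(z)/sqrt(n_bins); composites with
#' |Z| > 1.96 are flagged significant at the two-sided 5% level.
#'
#' @param zdiff a \linkS4class{ZDiffSpectrum}.
#' @param band numeric length-2 band limits in Hz (inclusive).
#' @param name optional band label.
#' @param critical significance cutoff (default 1.96).
#' @return one-row data.frame: \code{band}, \code{low}, \code{high},
#'   \code{n_bins}, \code{composite_z}, \code{significant}.
#' @export
bandComposite <- function(zdiff, band = c(12, 30), name = NULL,
                          critical = 1.96) {
  stopifnot(is(zdiff, "ZDiffSpectrum"))
  sel <- frequencies(zdiff) >= band[1] & frequencies(zdiff) <= band[2]
  if (!any(sel)) stop("band contains no frequency bin")
  z <- sum(zValues(zdiff)[sel]) / sqrt(sum(sel))
  data.frame(band = if (is.null(name)) sprintf("%g-%g Hz", band[1], band[2])
                    else name,
             low = band[1], high = band[2], n_bins = sum(sel),
             composite_z = z, significant = abs(z) > critical)
}

#' Composite Z table for the alpha, beta and gamma bands
#'
#' @param zdiff a \linkS4class{ZDiffSpectrum}.
#' @return data.frame with one [bandComposite()] row per band: alpha
#'   (8-12 Hz), beta (12-30 Hz), gamma (30-50 Hz).
#' @export
bandCompositeTable <- function(zdiff) {
  rbind(bandComposite(zdiff, c(8, 12), "alpha"),
        bandComposite(zdiff, c(12, 30), "beta"),
        bandComposite(zdiff, c(30, 50), "gamma"))
}

#' Corticomuscular coherence of an annotated record
#'
#' Convenience pipeline for one record: EMG channels are band-pass filtered
#' (15-450 Hz), cut into the annotated epochs, Hilbert-enveloped and
#' standardized per epoch; EEG channels are cut into the same epochs; the
#' coherence is pooled over every EEG x EMG channel pair.
#'
#' @param record a \linkS4class{SignalRecord} holding EEG and EMG channels.
#' @param eegRoles,emgRoles channel roles to pair.
#' @param kind annotation kind delimiting the epochs (default
#'   \code{"hold_plateau"}); \code{NULL} uses the whole record as one epoch.
#' @param segmentSec,overlap,window passed to [pooledCoherence()].
#' @param emgBand EMG band-pass corners in Hz.
#' @return a \linkS4class{CoherenceSpectrum}.
#' @export
corticomuscularCoherence <- function(record, eegRoles, emgRoles,
                                     kind = "hold_plateau",
                                     segmentSec = 0.512, overlap = 0.75,
                                     window = "hann",
                                     emgBand = c(15, 450)) {
  fs <- samplingRate(record)
  emgIdx <- which(channelRoles(record) %in% emgRoles)
  filtered <- record
  if (length(emgIdx)) {
    emgRec <- bandpassFilter(selectChannels(record, emgIdx),
                             emgBand[1], emgBand[2], order = 4L)
    m <- signalMatrix(record)
    m[, emgIdx] <- signalMatrix(emgRec)
    filtered <- SignalRecord(m, fs, channelRoles(record),
                             annotations(record), record@metadata)
  }
  epochsOf <- function(role, envelope) {
    eps <- if (is.null(kind)) {
      list(channelSamples(filtered, role))
    } else annotationEpochs(filtered, role, kind)
    lapply(eps, function(e) {
      if (envelope) e <- hilbertEnvelopeVector(e)
      standardizeSeries(e)
    })
  }
  xs <- list(); ys <- list()
  for (er in eegRoles) {
    ee <- epochsOf(er, envelope = FALSE)
    for (mr in emgRoles) {
      xs <- c(xs, ee)
      ys <- c(ys, epochsOf(mr, envelope = TRUE))
    }
  }
  pooledCoherence(xs, ys, fs, segmentSec, overlap, window)
}

#' @rdname CoherenceSpectrum-class
#' @export
setMethod("frequencies", "CoherenceSpectrum", function(x) x@frequencies)

#' @rdname ZDiffSpectrum-class
#' @export
setMethod("frequencies", "ZDiffSpectrum", function(x) x@frequencies)

#' @rdname CoherenceSpectrum-class
#' @export
setMethod("coherenceValues", "CoherenceSpectrum", function(x) x@coherence)

#' @rdname CoherenceSpectrum-class
#' @export
setMethod("effectiveSegments", "CoherenceSpectrum", function(x) x@L)

#' @rdname CoherenceSpectrum-class
#' @export
setMethod("confidenceLimit", "CoherenceSpectrum",
          function(x) x@confidenceLevel)

#' @rdname ZDiffSpectrum-class
#' @export
setMethod("zValues", "ZDiffSpectrum", function(x) x@z)

setMethod("show", "CoherenceSpectrum", function(object) {
  cat("CoherenceSpectrum:", length(object@frequencies), "bins, df",
      sprintf("%.1f", object@frequencies[2] - object@frequencies[1]),
      "Hz, L =", sprintf("%.1f", object@L),
      ", 95% CL =", sprintf("%.4f", object@confidenceLevel), "\n")
})

setMethod("show", "ZDiffSpectrum", function(object) {
  cat("ZDiffSpectrum:", length(object@frequencies), "bins, method",
      object@method, ", L pre/post =", sprintf("%.1f", object@LPre), "/",
      sprintf("%.1f", object@LPost), "\n")
})
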