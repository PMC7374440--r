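#' Extensor ratio
#'
#' The feedback quantity of the training task: summed extensor activity
#' divided by the summed extensor-plus-flexor activity, both in
#' fraction-of-grip-maximum units. The ratio is undefined (NA) whenever the
#' total activity does not exceed the activity floor, which avoids 0/0 at
#' rest.
#'
#' @param extensorSum,flexorSum nonnegative summed envelopes
#'   (fraction-of-maximum units); vectors are processed elementwise.
#' @param floor activity floor on the denominator (default 0.01, i.e. 1% of
#'   a single channel's grip maximum).
#' @return extensor ratio in [0, 1], NA where undefined.
#' @examples
#' computeER(0.3, 0.3)   # equal activity -> 0.5
#' computeER(0.3, 0.1)   # 0.75
#' @export
computeER <- function(extensorSum, flexorSum, floor = 0.01) {
  if (any(extensorSum < 0, na.rm = TRUE) || any(flexorSum < 0, na.rm = TRUE))
    stop("summed activities must be nonnegative")
  total <- extensorSum + flexorSum
  er <- ifelse(total > floor, extensorSum / total, NA_real_)
  er
}

#' Evaluate one training trial
#'
#' A feedback sample meets the success criteria when the summed extensor
#' activity exceeds \code{activationThreshold} of its grip maximum AND the
#' extensor ratio exceeds the current staircase threshold (undefined ER
#' never meets the criteria). The trial succeeds when some contiguous run of
#' meeting samples spans at least \code{requiredDuration} seconds; with
#' \code{contiguous = FALSE} the cumulative meeting time is used instead.
#'
#' @param erSeries extensor-ratio samples over the attempt window (NA where
#'   undefined).
#' @param extensorSeries summed extensor envelope over the same window,
#'   fraction-of-maximum units.
#' @param flexorSeries summed flexor envelope (used for the trial means
#'   only).
#' @param feedbackRate sample rate of the series in Hz (default 250).
#' @param erThreshold the staircase extensor-ratio threshold for this trial.
#' @param activationThreshold minimum extensor activation as a fraction of
#'   the summed grip maximum (default 0.30).
#' @param requiredDuration seconds the criteria must be sustained (default
#'   2).
#' @param gripSum grip maximum of the summed extensor envelope in
#'   normalized units (2 when two per-channel-normalized extensors are
#'   summed).
#' @param contiguous require one contiguous run (default) or cumulate.
#' @param trialIndex index recorded in the result.
#' @return one-row data.frame: \code{trial_index}, \code{success},
#'   \code{max_sustained} (s), \code{er_threshold_used}, \code{mean_er},
#'   \code{mean_extensor}, \code{mean_flexor}.
#' @export
evaluateTrial <- function(erSeries, extensorSeries, flexorSeries = NULL,
                          feedbackRate = 250, erThreshold,
                          activationThreshold = 0.30, requiredDuration = 2,
                          gripSum = 2, contiguous = TRUE, trialIndex = 1L) {
  nReq <- ceiling(requiredDuration * feedbackRate)
  if (length(erSeries) < nReq)
    stop("attempt series shorter than the required duration")
  if (length(extensorSeries) != length(erSeries))
    stop("'erSeries' and 'extensorSeries' must have equal length")
  meets <- !is.na(erSeries) & erSeries > erThreshold &
    extensorSeries > activationThreshold * gripSum
  maxRun <- longestRun(meets)
  sustained <- if (contiguous) maxRun else sum(meets)
  maxSustained <- maxRun / feedbackRate
  success <- sustained >= nReq
  data.frame(trial_index = trialIndex, success = success,
             max_sustained = maxSustained,
             er_threshold_used = erThreshold,
             mean_er = mean(erSeries, na.rm = TRUE),
             mean_extensor = mean(extensorSeries),
             mean_flexor = if (is.null(flexorSeries)) NA_real_
                           else mean(flexorSeries))
}

#' Longest contiguous run of TRUE
#'
#' @param x logical vector.
#' @return length of the longest contiguous run of \code{TRUE} (0 if none).
#' @export
longestRun <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(as.logical(x))
  max(r$lengths[r$values])
}

#' Adaptive extensor-ratio staircase
#'
#' State of the difficulty staircase: the threshold starts at 0.5 (equal
#' flexor and extensor activity) at the beginning of each session and moves
#' in steps of 0.3, clipped to [0.3, 0.97], whenever the three trials since
#' the last adjustment were all successes (up) or all failures (down).
#'
#' @param threshold starting threshold (default 0.5).
#' @param step adjustment increment (default 0.3).
#' @param lower,upper clipping bounds (defaults 0.3 and 0.97).
#' @return a \code{StaircaseState} list with an empty outcome history.
#' @export
staircaseState <- function(threshold = 0.5, step = 0.3, lower = 0.3,
                           upper = 0.97) {
  if (threshold < lower || threshold > upper)
    stop("starting threshold outside [lower, upper]")
  structure(list(threshold = threshold, step = step, lower = lower,
                 upper = upper, history = logical(0)),
            class = "StaircaseState")
}

#' Record a trial outcome and update the staircase
#'
#' Appends the outcome to the history accumulated since the last
#' adjustment. When the last three recorded outcomes are all successes the
#' threshold increases by one step; all failures, it decreases; the result
#' is clipped to the bounds and the history cleared after any adjustment.
#' Mixed outcomes leave the threshold unchanged.
#'
#' @param state a \code{StaircaseState}.
#' @param outcome logical success flag of the trial just finished.
#' @return the updated \code{StaircaseState}.
#' @examples
#' s <- staircaseState()
#' for (i in 1:3) s <- staircaseUpdate(s, TRUE)
#' s$threshold  # 0.8
#' @export
staircaseUpdate <- function(state, outcome) {
  stopifnot(inherits(state, "StaircaseState"))
  h <- c(state$history, as.logical(outcome))
  if (length(h) >= 3L) {
    last3 <- h[(length(h) - 2L):length(h)]
    if (all(last3)) {
      state$threshold <- min(state$upper, state$threshold + state$step)
      h <- logical(0)
    } else if (!any(last3)) {
      state$threshold <- max(state$lower, state$threshold - state$step)
      h <- logical(0)
    }
  }
  state$history <- h
  state
}

#' Run the biofeedback engine over an annotated session record
#'
#' Processes the record's \code{attempt} annotations in order: extensor
#' (ECR + ECU) and flexor (FCR + FCU) moving-window envelopes are computed
#' at the feedback rate, each channel normalized to its power-grip maximum,
#' the extensor ratio formed, and each trial evaluated against the current
#' staircase threshold; the staircase is updated after every trial, so the
#' threshold used for trial k reflects all outcomes through trial k-1.
#'
#' @param record a \linkS4class{SignalRecord} with rest/attempt annotations
#'   and the four wrist channels.
#' @param gripRef a \code{power_grip_max} \code{NormalizationReference};
#'   defaults to the record's own ground truth via [gripReference()].
#' @param feedbackRate feedback sample rate in Hz (default 250).
#' @param window envelope window in seconds (default 0.48).
#' @param erStart,erStep,erLower,erUpper staircase parameters.
#' @param activationThreshold,requiredDuration,floor,contiguous trial
#'   criteria, see [evaluateTrial()] and [computeER()].
#' @return list with \code{trials} (data.frame of per-trial results) and
#'   \code{summary} (percent success, mean threshold, mean ER, mean
#'   extensor/flexor amplitudes over trials).
#' @export
runSession <- function(record, gripRef = NULL, feedbackRate = 250,
                       window = 0.48, erStart = 0.5, erStep = 0.3,
                       erLower = 0.3, erUpper = 0.97,
                       activationThreshold = 0.30, requiredDuration = 2,
                       floor = 0.01, contiguous = TRUE) {
  ann <- annotations(record)
  attempts <- ann[ann$kind == "attempt", , drop = FALSE]
  if (!nrow(attempts))
    stop("record has no 'attempt' annotations")
  attempts <- attempts[order(attempts$start), , drop = FALSE]
  if (is.null(gripRef)) gripRef <- gripReference(record)

  envOf <- function(role) {
    e <- movingEnvelope(record, role, window, feedbackRate)
    envelopeValues(normalizeToReference(e, gripRef))
  }
  extSum <- envOf("ECR") + envOf("ECU")
  flexSum <- envOf("FCR") + envOf("FCU")
  erAll <- computeER(extSum, flexSum, floor = floor)

  st <- staircaseState(erStart, erStep, erLower, erUpper)
  rows <- vector("list", nrow(attempts))
  for (k in seq_len(nrow(attempts))) {
    i0 <- floor(attempts$start[k] * feedbackRate) + 1L
    i1 <- min(length(extSum), floor(attempts$end[k] * feedbackRate))
    idx <- i0:i1
    rows[[k]] <- evaluateTrial(erAll[idx], extSum[idx], flexSum[idx],
                               feedbackRate = feedbackRate,
                               erThreshold = st$threshold,
                               activationThreshold = activationThreshold,
                               requiredDuration = requiredDuration,
                               gripSum = 2, contiguous = contiguous,
                               trialIndex = attempts$trial_index[k])
    st <- staircaseUpdate(st, rows[[k]]$success)
  }
  trials <- do.call(rbind, rows)
  list(trials = trials,
       summary = list(
         percent_success = 100 * mean(trials$success),
         mean_threshold = mean(trials$er_threshold_used),
         mean_er = mean(trials$mean_er, na.rm = TRUE),
         mean_extensor = mean(trials$mean_extensor),
         mean_flexor = mean(trials$mean_flexor)))
}
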