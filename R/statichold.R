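#' Trapezoid hold target
#'
#' The tracking target of the static-hold task: a trapezoid spanning 6 s
#' (ramp up, 4 s plateau, ramp down) within a 10 s cursor sweep, with the
#' plateau at 15% of the tracked muscle's grip maximum by default. Ramp
#' durations are split symmetrically (1 s + 1 s) unless overridden.
#'
#' @param plateauLevel plateau height as a fraction of maximum (default
#'   0.15).
#' @param rampUp,plateau,rampDown trapezoid phase durations in seconds;
#'   they must total 6 s.
#' @param sweep cursor sweep duration in seconds (>= trapezoid span).
#' @return a \code{HoldTarget} list.
#' @export
holdTarget <- function(plateauLevel = 0.15, rampUp = 1, plateau = 4,
                       rampDown = 1, sweep = 10) {
  span <- rampUp + plateau + rampDown
  if (abs(span - 6) > 1e-9)
    stop("trapezoid phases must span 6 s (got ", span, ")")
  if (sweep < span) stop("'sweep' must be at least the trapezoid span")
  if (plateauLevel <= 0 || plateauLevel > 1)
    stop("'plateauLevel' must be in (0, 1]")
  structure(list(plateauLevel = plateauLevel, rampUp = rampUp,
                 plateau = plateau, rampDown = rampDown, sweep = sweep),
            class = "HoldTarget")
}

#' Feedback cursor of the static-hold task
#'
#' The cursor height is the rectified 1 s moving-window envelope of the
#' tracked channel, normalized to the power-grip maximum, at the record's
#' sampling rate.
#'
#' @param record a \linkS4class{SignalRecord}.
#' @param role tracked channel role.
#' @param window smoothing window in seconds (default 1).
#' @param gripRef a \code{power_grip_max} reference; defaults to the
#'   record's ground truth via [gripReference()].
#' @return an \linkS4class{EnvelopeSeries} in fraction-of-maximum units.
#' @export
cursorSeries <- function(record, role, window = 1, gripRef = NULL) {
  if (is.null(gripRef)) gripRef <- gripReference(record)
  normalizeToReference(movingEnvelope(record, role, window), gripRef)
}

#' Static-hold tracking error
#'
#' For every annotated plateau, the tracking error is the median absolute
#' deviation of the feedback cursor from the plateau level over the last
#' \code{analysisWindow} seconds of the hold: median(|cursor - target|).
#' The deviation is taken about the target, not about the sample median.
#'
#' @param cursor an \linkS4class{EnvelopeSeries} from [cursorSeries()].
#' @param target a \code{HoldTarget}.
#' @param plateaus annotation data.frame (rows of kind \code{hold_plateau});
#'   pass \code{annotations(record)} and the hold rows are selected.
#' @param analysisWindow seconds at the end of each plateau to analyse
#'   (default 3).
#' @return a \code{HoldError} list with \code{errors} (one nonnegative
#'   value per hold, in fraction-of-maximum units), \code{n_holds},
#'   \code{analysis_window}.
#' @export
holdError <- function(cursor, target, plateaus, analysisWindow = 3) {
  stopifnot(is(cursor, "EnvelopeSeries"), inherits(target, "HoldTarget"))
  if (is.data.frame(plateaus))
    plateaus <- plateaus[plateaus$kind == "hold_plateau", , drop = FALSE]
  if (!nrow(plateaus)) stop("no hold_plateau annotations supplied")
  if (any(plateaus$end - plateaus$start < analysisWindow - 1e-9))
    stop("every plateau must be at least as long as the analysis window")
  rate <- outputRate(cursor)
  v <- envelopeValues(cursor)
  errors <- vapply(seq_len(nrow(plateaus)), function(k) {
    i1 <- min(length(v), floor(plateaus$end[k] * rate))
    i0 <- floor((plateaus$end[k] - analysisWindow) * rate) + 1L
    stats::median(abs(v[i0:i1] - target$plateauLevel))
  }, numeric(1))
  structure(list(errors = errors, n_holds = length(errors),
                 analysis_window = analysisWindow,
                 plateau_level = target$plateauLevel),
            class = "HoldError")
}

#' Pre/post comparison of static-hold errors
#'
#' Individual-level paired t-test over the per-hold errors of one
#' participant, pairing hold k before training with hold k after training.
#' Negative t indicates reduced (improved) tracking error after training.
#'
#' @param pre,post \code{HoldError} objects with equal hold counts.
#' @return a \code{PairedComparison} (see [pairedT()]) of post versus pre,
#'   plus the pre/post means and SDs.
#' @export
compareSessions <- function(pre, post) {
  stopifnot(inherits(pre, "HoldError"), inherits(post, "HoldError"))
  if (pre$n_holds != post$n_holds)
    stop("pre and post must have equal hold counts")
  cmp <- pairedT(pre$errors, post$errors)
  cmp$pre_mean <- mean(pre$errors); cmp$pre_sd <- stats::sd(pre$errors)
  cmp$post_mean <- mean(post$errors); cmp$post_sd <- stats::sd(post$errors)
  cmp
}

#' Group-level comparison of static-hold performance
#'
#' Paired t-test across participants of their mean per-hold error before
#' versus after training.
#'
#' @param preList,postList lists of \code{HoldError} objects, one per
#'   participant, in matching order.
#' @return a \code{PairedComparison} over participant means.
#' @export
groupHoldComparison <- function(preList, postList) {
  if (length(preList) != length(postList))
    stop("pre and post participant lists must have equal length")
  pre <- vapply(preList, function(h) mean(h$errors), numeric(1))
  post <- vapply(postList, function(h) mean(h$errors), numeric(1))
  pairedT(pre, post)
}
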