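#' Paired t-test with explicit degenerate handling
#'
#' Classical two-sided paired t-test on the differences \code{post - pre}.
#' Zero-variance differences are flagged degenerate instead of yielding an
#' infinite statistic: identical vectors report t = 0, p = 1; a constant
#' nonzero shift reports an undefined statistic.
#'
#' @param pre,post numeric vectors of equal length (n >= 2).
#' @return a \code{PairedComparison} list: \code{n}, \code{df}, \code{t},
#'   \code{p}, \code{mean_diff}, \code{degenerate}.
#' @export
pairedT <- function(pre, post) {
  if (length(pre) != length(post))
    stop("'pre' and 'post' must have equal length")
  n <- length(pre)
  if (n < 2) stop("paired t-test needs at least two pairs")
  d <- post - pre
  out <- list(n = n, df = n - 1L, mean_diff = mean(d), degenerate = FALSE)
  # treat numerically constant differences as degenerate too
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.xmin)) {
    out$degenerate <- TRUE
    if (mean(d) == 0) { out$t <- 0; out$p <- 1 }
    else { out$t <- NA_real_; out$p <- NA_real_ }
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
  }
  structure(out, class = "PairedComparison")
}

#' Spearman rank trend across sessions
#'
#' Rank correlation (midrank ties) of a per-session metric against session
#' order, with a two-sided p-value (exact for n <= 9 without ties,
#' asymptotic otherwise). Constant metrics are reported with an explicit
#' tie flag rather than an error.
#'
#' @param values metric value per session.
#' @param sessions session order (defaults to 1..n).
#' @return a \code{TrendResult} list: \code{rho}, \code{p}, \code{n},
#'   \code{all_tied}.
#' @export
spearmanTrend <- function(values, sessions = seq_along(values)) {
  if (length(values) < 3) stop("trend needs at least three sessions")
  if (length(sessions) != length(values))
    stop("'sessions' and 'values' must have equal length")
  if (stats::sd(values) == 0)
    return(structure(list(rho = NA_real_, p = NA_real_,
                          n = length(values), all_tied = TRUE),
                     class = "TrendResult"))
  hasTies <- anyDuplicated(values) > 0 || anyDuplicated(sessions) > 0
  ct <- suppressWarnings(stats::cor.test(sessions, values,
                                         method = "spearman",
                                         exact = length(values) <= 9 &&
                                           !hasTies))
  structure(list(rho = unname(ct$estimate), p = ct$p.value,
                 n = length(values), all_tied = FALSE),
            class = "TrendResult")
}

.sessionRow <- function(s) {
  with(s$summary, data.frame(pct_success = percent_success,
                             mean_threshold = mean_threshold,
                             mean_er = mean_er,
                             mean_extensor = mean_extensor,
                             mean_flexor = mean_flexor))
}

.participantTable <- function(sessions) {
  # per-session metrics with extensor/flexor/ER amplitudes expressed as
  # Z-scores relative to the first session's per-trial distribution
  raw <- do.call(rbind, lapply(sessions, .sessionRow))
  raw$session <- seq_len(nrow(raw))
  first <- sessions[[1]]$trials
  zRef <- sessionZScoreReference(list(
    extensor = first$mean_extensor, flexor = first$mean_flexor,
    er = first$mean_er))
  raw$extensor_z <- normalizeToReference(raw$mean_extensor, zRef, "extensor")
  raw$flexor_z <- normalizeToReference(raw$mean_flexor, zRef, "flexor")
  raw$er_z <- normalizeToReference(raw$mean_er, zRef, "er")
  raw[, c("session", "extensor_z", "flexor_z", "er_z", "pct_success",
          "mean_threshold", "mean_er", "mean_extensor", "mean_flexor")]
}

#' Session metric table with trend statistics
#'
#' Summarises training performance across sessions. Amplitude metrics
#' (extensor, flexor, ER) are Z-scored against the per-trial mean and SD of
#' the first supplied session, mirroring normalization to the first
#' training day; percent success and the mean staircase threshold are kept
#' raw. A Spearman rank trend across sessions is attached per metric; with
#' two or more participants, a first-versus-last-session paired t-test
#' across participants is added.
#'
#' @param sessions for a single participant, a list of [runSession()]
#'   results in session order; for several participants, a list of such
#'   lists.
#' @return list with \code{table} (one row per participant x session),
#'   \code{trends} (per participant and metric: rho, p) and \code{group}
#'   (first-vs-last paired t per metric, or a note when only one
#'   participant is supplied).
#' @export
sessionMetricTable <- function(sessions) {
  single <- !is.null(sessions[[1]]$summary)
  participants <- if (single) list(sessions) else sessions
  if (length(participants[[1]]) < 2)
    stop("at least two sessions are required")
  tabs <- lapply(participants, .participantTable)
  metrics <- c("extensor_z", "flexor_z", "er_z", "pct_success",
               "mean_threshold")
  trends <- do.call(rbind, lapply(seq_along(tabs), function(p) {
    do.call(rbind, lapply(metrics, function(m) {
      tr <- if (nrow(tabs[[p]]) >= 3)
        spearmanTrend(tabs[[p]][[m]], tabs[[p]]$session)
      else list(rho = NA_real_, p = NA_real_)  # too few sessions
      data.frame(participant = p, metric = m, rho = tr$rho, p = tr$p)
    }))
  }))
  for (p in seq_along(tabs)) tabs[[p]]$participant <- p
  table <- do.call(rbind, tabs)
  group <- if (length(tabs) >= 2) {
    do.call(rbind, lapply(metrics, function(m) {
      firsts <- vapply(tabs, function(t) t[[m]][1], numeric(1))
      lasts <- vapply(tabs, function(t) t[[m]][nrow(t)], numeric(1))
      pt <- pairedT(firsts, lasts)
      data.frame(metric = m, t = pt$t, p = pt$p, df = pt$df,
                 degenerate = pt$degenerate)
    }))
  } else {
    "group-level paired t omitted: fewer than two participants"
  }
  list(table = table, trends = trends, group = group)
}
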