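#' Configuration of the synthetic EMG/EEG generator
#'
#' Bundles the parameters shared by all synthetic generators. The cortical
#' drive is a band-limited noise process shared between the EEG channel and
#' the EMG amplitude envelope; the two power ratios set, per frequency
#' inside the drive band, the ratio of shared-drive power to independent
#' noise power in each channel, which fixes the magnitude-squared coherence
#' in closed form (see [theoreticalCoherence()]).
#'
#' @param samplingRate sampling rate in Hz (default 1000, the common rate
#'   the recordings are brought to).
#' @param duration record duration in seconds.
#' @param driveBand numeric length-2, the shared-drive band in Hz (default
#'   beta, 12-30 Hz).
#' @param drivePowerRatioEEG,drivePowerRatioEMG nonnegative in-band ratios
#'   of shared-drive power to independent-noise power for the EEG channel
#'   and the EMG envelope respectively.
#' @param activationLevel simulated activation as a fraction of the
#'   simulated maximum, in [0, 1].
#' @param coactivationRatio flexor activation per unit extensor activation
#'   (>= 0).
#' @param seed integer seed; \code{NULL} leaves the RNG state untouched.
#' @return a validated \code{SynthConfig} list.
#' @export
synthConfig <- function(samplingRate = 1000, duration = 120,
                        driveBand = c(12, 30),
                        drivePowerRatioEEG = 1, drivePowerRatioEMG = 1,
                        activationLevel = 0.5, coactivationRatio = 0.3,
                        seed = NULL) {
  stopifnot(samplingRate > 0, duration > 0)
  if (length(driveBand) != 2L || driveBand[1] <= 0 ||
      driveBand[1] >= driveBand[2] || driveBand[2] >= samplingRate / 2)
    stop("'driveBand' must satisfy 0 < low < high < Nyquist")
  if (drivePowerRatioEEG < 0 || drivePowerRatioEMG < 0)
    stop("drive power ratios must be nonnegative")
  if (activationLevel < 0 || activationLevel > 1)
    stop("'activationLevel' must be in [0, 1]")
  if (coactivationRatio < 0)
    stop("'coactivationRatio' must be nonnegative")
  cohMax <- .mixtureCoherence(drivePowerRatioEEG, drivePowerRatioEMG)
  if (cohMax < 0 || cohMax > 1)
    stop("configured power ratios imply coherence outside [0, 1]")
  structure(list(samplingRate = samplingRate, duration = duration,
                 driveBand = driveBand,
                 drivePowerRatioEEG = drivePowerRatioEEG,
                 drivePowerRatioEMG = drivePowerRatioEMG,
                 activationLevel = activationLevel,
                 coactivationRatio = coactivationRatio, seed = seed),
            class = "SynthConfig")
}

.mixtureCoherence <- function(r1, r2) {
  # msc of two channels sharing a common component with per-channel
  # signal-to-noise power ratios r1, r2 (flat in band):
  # P_s^2 / ((P_s + P_n1)(P_s + P_n2)) with P_s = r_i * P_ni
  (r1 * r2) / ((1 + r1) * (1 + r2))
}

#' Closed-form coherence of the synthetic EEG/EMG pair
#'
#' The generator shares one band-limited drive between the EEG channel and
#' the EMG envelope, with independent noise whose in-band power spectral
#' density is flat. The magnitude-squared coherence is therefore constant
#' inside the drive band, \code{r1*r2/((1+r1)*(1+r2))}, and exactly zero
#' outside it.
#'
#' @param config a \code{SynthConfig}.
#' @param frequencies frequencies (Hz) at which to evaluate.
#' @return numeric vector of theoretical coherence values.
#' @export
theoreticalCoherence <- function(config, frequencies) {
  inband <- frequencies >= config$driveBand[1] &
    frequencies <= config$driveBand[2]
  out <- numeric(length(frequencies))
  out[inband] <- .mixtureCoherence(config$drivePowerRatioEEG,
                                   config$drivePowerRatioEMG)
  out
}

.bandlimitedNoise <- function(n, fs, low, high) {
  # white Gaussian noise restricted to [low, high] Hz by an FFT mask; the
  # in-band PSD equals that of the unmasked unit-variance white noise
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  X[f < low | f > high] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

.fmCarrier <- function(n, fs, centre = 200, deviation = 40) {
  # constant-modulus noise-like carrier: cosine with a randomly wandering
  # instantaneous frequency. Its Hilbert envelope is exactly 1 as long as
  # the modulator bandwidth stays below the lowest instantaneous frequency,
  # so amplitude modulation survives envelope extraction undistorted.
  v <- .bandlimitedNoise(n, fs, 0.2, 8)
  v <- v / stats::sd(v)
  v[v > 2.5] <- 2.5; v[v < -2.5] <- -2.5
  fInst <- centre + deviation * v
  phase <- 2 * pi * cumsum(fInst) / fs + stats::runif(1, 0, 2 * pi)
  cos(phase)
}

# modulation depth of the envelope processes (fraction of the mean level)
.ENV_DEPTH <- 0.2
# resting modulator level, as a fraction of the simulated grip maximum
.BASELINE_LEVEL <- 0.02

.gripMetadata <- function(roles, carrier) {
  # ground truth for normalization: the modulator equals 1 at a maximal
  # power grip; the rectified moving-average envelope of the constant-
  # modulus carrier at that level is mean|cos| = 2/pi
  emg <- roles %in% c("ECR", "ECU", "FCR", "FCU")
  scale <- ifelse(carrier, 2 / pi, 1)
  list(gripMax = setNames(rep(1, sum(emg)), roles[emg]),
       rectifiedGripEnvelope = setNames(rep(scale, sum(emg)), roles[emg]),
       carrier = carrier)
}

#' Power-grip normalization reference of a synthetic record
#'
#' Synthetic records carry the exact amplitude a maximal power grip would
#' produce in their metadata; this helper turns it into the
#' \code{power_grip_max} \code{NormalizationReference} used by the feedback
#' and static-hold analyses.
#'
#' @param record a synthetic \linkS4class{SignalRecord}.
#' @return a \code{NormalizationReference} with one entry per EMG channel.
#' @export
gripReference <- function(record) {
  md <- record@metadata
  if (is.null(md$rectifiedGripEnvelope))
    stop("record carries no power-grip ground truth in its metadata")
  normalizationReference("power_grip_max",
                         scale = unlist(md$rectifiedGripEnvelope))
}

#' Generate an EEG/EMG pair with known coherence
#'
#' Simulates one EEG-role channel and one EMG-role channel sharing a
#' band-limited cortical drive. The EEG channel is the drive plus
#' independent broadband noise; the EMG channel is a constant-modulus
#' broadband carrier amplitude-modulated by the drive plus independent
#' band-limited envelope noise. The magnitude-squared coherence between the
#' EEG and the EMG envelope is known in closed form
#' (see [theoreticalCoherence()]): constant inside the drive band and zero
#' outside it.
#'
#' @param config a \code{SynthConfig}.
#' @param carrier if \code{FALSE}, the EMG channel holds the envelope
#'   modulator itself rather than the modulated carrier (useful for exact
#'   envelope-domain checks).
#' @param eegRole,emgRole channel roles for the two channels.
#' @return a \linkS4class{SignalRecord} with two channels; metadata records
#'   the configuration and grip ground truth.
#' @examples
#' cfg <- synthConfig(duration = 30, drivePowerRatioEEG = 4,
#'                    drivePowerRatioEMG = 4, seed = 1)
#' rec <- generateCoherentPair(cfg)
#' theoreticalCoherence(cfg, c(5, 20, 80))  # 0, 0.64, 0
#' @export
generateCoherentPair <- function(config, carrier = TRUE,
                                 eegRole = "EEG_contra", emgRole = "ECR") {
  stopifnot(inherits(config, "SynthConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$samplingRate
  n <- round(config$duration * fs)
  band <- config$driveBand

  s <- .bandlimitedNoise(n, fs, band[1], band[2])          # shared drive
  eeg <- sqrt(config$drivePowerRatioEEG) * s + stats::rnorm(n)

  m <- .bandlimitedNoise(n, fs, band[1], band[2])          # envelope noise
  mix <- sqrt(config$drivePowerRatioEMG) * s + m
  mix <- mix / stats::sd(mix)
  level <- max(config$activationLevel, 0.05)
  A <- level * (1 + .ENV_DEPTH * mix)
  A[A < 0.02 * level] <- 0.02 * level                      # keep positive

  emg <- if (carrier) A * .fmCarrier(n, fs) else A

  SignalRecord(cbind(eeg, emg), fs, c(eegRole, emgRole),
               metadata = c(.gripMetadata(c(eegRole, emgRole), carrier),
                            list(config = unclass(config),
                                 theoreticalInBandCoherence =
                                   .mixtureCoherence(
                                     config$drivePowerRatioEEG,
                                     config$drivePowerRatioEMG))))
}

.raisedCosineGate <- function(n, rampSamples) {
  # 0 -> 1 -> 0 gate with raised-cosine edges, length n
  g <- rep(1, n)
  r <- min(rampSamples, floor(n / 2))
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    g[seq_len(r)] <- up
    g[n + 1 - seq_len(r)] <- up
  }
  g
}

#' Generate a synthetic biofeedback training session
#'
#' Builds the four-channel wrist EMG record of one training session: each
#' trial is 7 s of rest followed by a 5 s movement attempt. During attempts
#' the two extensor channels (ECR, ECU) activate around
#' \code{activationLevel} and the two flexor channels (FCR, FCU) around
#' \code{coactivationRatio} times the extensor level. Trial-to-trial
#' variability is log-normal and shrinks to zero as \code{agentSkill}
#' approaches 1.
#'
#' @param config a \code{SynthConfig} (its \code{duration} is ignored; the
#'   trial schedule fixes the length).
#' @param agentSkill in [0, 1]; 1 is a perfectly reproducible agent.
#' @param nBlocks,nTrialsPerBlock session structure (defaults 6 x 20).
#' @param restSec,attemptSec trial phase durations in seconds.
#' @param baselineLevel resting modulator level as a fraction of the grip
#'   maximum (default 0.02); sets the antagonist floor that bounds the
#'   achievable extensor ratio.
#' @return a \linkS4class{SignalRecord} with channels ECR, ECU, FCR, FCU and
#'   rest/attempt annotations; metadata carries the per-trial true levels.
#' @export
generateTrainingSession <- function(config, agentSkill = 0.7, nBlocks = 6,
                                    nTrialsPerBlock = 20, restSec = 7,
                                    attemptSec = 5,
                                    baselineLevel = .BASELINE_LEVEL) {
  stopifnot(inherits(config, "SynthConfig"))
  if (agentSkill < 0 || agentSkill > 1)
    stop("'agentSkill' must be in [0, 1]")
  if (nBlocks < 1 || nTrialsPerBlock < 1)
    stop("'nBlocks' and 'nTrialsPerBlock' must be >= 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$samplingRate
  nTrials <- nBlocks * nTrialsPerBlock
  trialSec <- restSec + attemptSec
  n <- round(nTrials * trialSec * fs)
  roles <- c("ECR", "ECU", "FCR", "FCU")
  sdLog <- 0.4 * (1 - agentSkill)

  # per-trial true activation levels (fraction of grip maximum)
  extLevel <- sapply(seq_len(nTrials), function(i)
    config$activationLevel * exp(stats::rnorm(2, 0, sdLog)))    # ECR, ECU
  flexLevel <- sapply(seq_len(nTrials), function(i)
    config$coactivationRatio * config$activationLevel *
      exp(stats::rnorm(2, 0, sdLog)))                           # FCR, FCU
  levels <- rbind(extLevel, flexLevel)  # 4 x nTrials, rows follow `roles`

  attemptStart <- (seq_len(nTrials) - 1) * trialSec + restSec
  i0 <- round(attemptStart * fs) + 1L
  nAtt <- round(attemptSec * fs)
  gate <- .raisedCosineGate(nAtt, round(0.2 * fs))

  samples <- matrix(0, n, 4L)
  for (ch in 1:4) {
    A <- rep(baselineLevel, n)
    jitter <- .bandlimitedNoise(n, fs, 0.5, 5)
    jitter <- 0.02 * jitter / stats::sd(jitter)
    for (k in seq_len(nTrials)) {
      idx <- i0[k]:(i0[k] + nAtt - 1L)
      A[idx] <- A[idx] + levels[ch, k] * gate
    }
    A <- A + jitter * (A > 2 * baselineLevel)
    A[A < 0] <- 0
    samples[, ch] <- A * .fmCarrier(n, fs)
  }

  ann <- rbind(
    data.frame(kind = "rest", start = attemptStart - restSec,
               end = attemptStart, trial_index = seq_len(nTrials)),
    data.frame(kind = "attempt", start = attemptStart,
               end = attemptStart + attemptSec,
               trial_index = seq_len(nTrials)))
  ann <- ann[order(ann$start), ]
  rownames(ann) <- NULL

  SignalRecord(samples, fs, roles, ann,
               metadata = c(.gripMetadata(roles, carrier = TRUE),
                            list(config = unclass(config),
                                 agentSkill = agentSkill,
                                 trueLevels = levels,
                                 nBlocks = nBlocks,
                                 nTrialsPerBlock = nTrialsPerBlock)))
}

#' Generate a synthetic static-hold assessment
#'
#' Simulates the quasi-isometric tracking task: for each hold the tracked
#' extensor's envelope follows a trapezoid (1 s ramp up, 4 s plateau at
#' \code{targetFraction} of the grip maximum, 1 s ramp down), preceded by
#' 4 s of rest. \code{trackingNoise} is the standard deviation of the
#' cursor-level tracking error, i.e. of the envelope error that survives
#' the 1 s feedback smoothing window, in fraction-of-maximum units. It is
#' realised as slow band-limited Gaussian noise (0.05-0.45 Hz) on the
#' modulator, rescaled per record so its smoothed version has SD exactly
#' \code{trackingNoise}; the cursor error is therefore Gaussian with the
#' requested SD but correlated over lags of a second or two, as a human
#' tracking error would be.
#'
#' @param config a \code{SynthConfig} (duration ignored).
#' @param targetFraction plateau level as a fraction of maximum (default
#'   0.15).
#' @param nHolds number of holds (default 16).
#' @param trackingNoise cursor-error SD in fraction-of-maximum units.
#' @param carrier as in [generateCoherentPair()].
#' @param cursorWindow the feedback smoothing window the noise level is
#'   calibrated to, in seconds.
#' @param role EMG channel role of the tracked muscle.
#' @return a \linkS4class{SignalRecord} with one EMG channel and
#'   \code{hold_plateau} annotations.
#' @export
generateStaticHold <- function(config, targetFraction = 0.15, nHolds = 16,
                               trackingNoise = 0.02, carrier = TRUE,
                               cursorWindow = 1, role = "ECR") {
  stopifnot(inherits(config, "SynthConfig"))
  if (targetFraction <= 0 || targetFraction > 1)
    stop("'targetFraction' must be in (0, 1]")
  if (nHolds < 1) stop("'nHolds' must be >= 1")
  if (trackingNoise < 0) stop("'trackingNoise' must be nonnegative")
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$samplingRate
  restSec <- 4; rampSec <- 1; plateauSec <- 4
  holdSec <- restSec + 2 * rampSec + plateauSec
  n <- round(nHolds * holdSec * fs)

  ramp <- seq_len(round(rampSec * fs)) / round(rampSec * fs)
  trapezoid <- c(ramp, rep(1, round(plateauSec * fs)), rev(ramp))
  profile <- numeric(n)
  starts <- (seq_len(nHolds) - 1) * holdSec + restSec
  for (k in seq_len(nHolds)) {
    idx <- round(starts[k] * fs) + seq_along(trapezoid)
    profile[idx] <- trapezoid
  }

  winSamples <- round(cursorWindow * fs)
  if (trackingNoise > 0) {
    raw <- .bandlimitedNoise(n, fs, 0.05, 0.45)
    smoothed <- .trailingMean(raw, winSamples)
    noise <- raw * trackingNoise / stats::sd(smoothed)
  } else noise <- numeric(n)
  A <- targetFraction * profile + noise * (profile > 0)
  A[A < 0] <- 0

  emg <- if (carrier) A * .fmCarrier(n, fs) else A

  ann <- data.frame(kind = "hold_plateau",
                    start = starts + rampSec,
                    end = starts + rampSec + plateauSec,
                    trial_index = seq_len(nHolds))

  SignalRecord(matrix(emg, ncol = 1), fs, role, ann,
               metadata = c(.gripMetadata(role, carrier),
                            list(config = unclass(config),
                                 targetFraction = targetFraction,
                                 trackingNoise = trackingNoise,
                                 cursorWindow = cursorWindow)))
}
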