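#' Apply the sparse-event merge rule
#'
#' Events closer than `minGap` seconds to the last *kept* event are flagged
#' as dropped (they remain in the table and are treated as part of the
#' implicit baseline); the comparison is against the last kept event, not
#' the last raw event, and the boundary is inclusive (a spacing of exactly
#' `minGap` keeps the event).
#'
#' @param events data.frame with an ascending `onset` (or `onset_s`)
#'   column, seconds.
#' @param minGap minimum separation, seconds (default 2, one TR).
#' @return the input with a logical `included` column.
#' @examples
#' mergeEvents(data.frame(onset = c(0, 1.5, 4)))$included # TRUE FALSE TRUE
#' @export
mergeEvents <- function(events, minGap = 2) {
  onset <- if (!is.null(events$onset)) events$onset else events$onset_s
  if (is.null(onset)) stop("events need an 'onset' or 'onset_s' column")
  if (is.unsorted(onset)) stop("event onsets must be sorted ascending")
  keep <- logical(length(onset))
  lastKept <- -Inf
  for (i in seq_along(onset)) {
    if (onset[i] >= lastKept + minGap - 1e-9) {
      keep[i] <- TRUE
      lastKept <- onset[i]
    }
  }
  events$included <- keep
  events
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peaking near 5 s, undershoot
#' near 15 s, 1:6 amplitude ratio), the standard parameterization of the
#' gamma-variate BOLD impulse response.
#'
#' @param t time grid, seconds (>= 0).
#' @param peakShape,peakRate shape/rate of the response gamma.
#' @param undershootShape,undershootRate shape/rate of the undershoot gamma.
#' @param ratio response:undershoot amplitude ratio.
#' @return unitless response sampled at `t`; `hrf(0) = 0`.
#' @examples
#' tt <- seq(0, 30, 0.1)
#' tt[which.max(hrf(tt))] # peak close to 5 s
#' @export
hrf <- function(t, peakShape = 6, peakRate = 1, undershootShape = 16,
                undershootRate = 1, ratio = 6) {
  if (any(t < 0)) stop("the HRF is defined on a non-negative time grid")
  dgamma(t, peakShape, peakRate) -
    dgamma(t, undershootShape, undershootRate) / ratio
}

# Add boxcar amplitude to a microtime accumulator.
addBoxcars <- function(acc, dt, onsets, durations, amplitudes) {
  nT <- length(acc)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- min(nT, ceiling((onsets[i] + durations[i]) / dt))
    if (a <= nT && b >= a) acc[a:b] <- acc[a:b] + amplitudes[i]
  }
  acc
}

# Convolve a microtime series with the HRF kernel and return both the
# response and its numerical first derivative, sampled at the volume times.
convolveAndSample <- function(x, dt, kernel, sampleIdx) {
  y <- stats::convolve(x, rev(kernel), type = "open")[seq_along(x)] * dt
  dy <- c(diff(y) / dt, 0)
  list(y = y[sampleIdx], dy = dy[sampleIdx])
}

#' Build the first-level design matrix
#'
#' Constructs the mixed event/epoch design: a main-effect column for action
#' onsets (amplitude 1), parametric-modulation columns for conditional
#' entropy and conditional surprisal (amplitudes equal to the respective
#' measure; mean-centered across included events by default, which
#' decorrelates them from the main effect), question-trial and video-epoch
#' columns (amplitude 1), and a step-duration regressor of no interest.
#' Action and question events are modeled as 1 s and 3 s boxcars, epochs
#' with their own duration; every column is convolved with the gamma HRF on
#' a 0.1 s microtime grid and sampled at the middle of each TR, and each
#' event column receives a first-derivative twin (numerical derivative of
#' the convolved column). An intercept column is appended.
#'
#' Only rows of `events` with `annotate_ok` and `included` both TRUE (when
#' present) contribute modulation amplitudes; all kept events contribute to
#' the main effect.
#'
#' @param events data.frame of action-step events: `onset` (seconds, session
#'   clock), `entropy`, `surprisal`, `step_duration`; optional `included`
#'   (from [mergeEvents()]) and `annotate_ok` flags.
#' @param epochs data.frame of video epochs: `onset`, `duration`.
#' @param questions data.frame of question trials: `onset` (may be empty or
#'   NULL).
#' @param nVolumes number of volumes acquired.
#' @param tr repetition time, seconds.
#' @param centerModulators mean-center modulator amplitudes (default TRUE).
#' @param eventDuration modeled duration of action-step events, seconds.
#' @param questionDuration modeled duration of question trials, seconds.
#' @param derivatives append first-derivative twins (default TRUE).
#' @param hrfParams named list passed to [hrf()].
#' @param dt microtime resolution, seconds.
#' @return a [DesignMatrix-class].
#' @export
buildDesign <- function(events, epochs = NULL, questions = NULL, nVolumes,
                        tr = 2, centerModulators = TRUE, eventDuration = 1,
                        questionDuration = 3, derivatives = TRUE,
                        hrfParams = list(), dt = 0.1) {
  scanEnd <- nVolumes * tr
  getOnset <- function(d) if (!is.null(d$onset)) d$onset else d$onset_s
  ons <- getOnset(events)
  if (is.null(ons)) stop("events need an 'onset' column")
  if (length(ons) && max(ons) > scanEnd)
    stop("event beyond scan end (", max(ons), " s > ", scanEnd, " s)")
  keep <- rep(TRUE, nrow(events))
  if (!is.null(events$included)) keep <- keep & events$included
  okmod <- keep
  if (!is.null(events$annotate_ok)) okmod <- okmod & events$annotate_ok

  nT <- ceiling(scanEnd / dt) + 1
  kernel <- do.call(hrf, c(list(t = seq(0, 32, by = dt)), hrfParams))
  frameTimes <- (seq_len(nVolumes) - 0.5) * tr
  sampleIdx <- pmin(nT, round(frameTimes / dt) + 1)

  center <- function(a) if (centerModulators && length(a)) a - mean(a) else a
  cols <- list()
  addColumn <- function(name, onsets, durations, amplitudes) {
    acc <- addBoxcars(numeric(nT), dt, onsets, durations, amplitudes)
    cs <- convolveAndSample(acc, dt, kernel, sampleIdx)
    cols[[name]] <<- cs$y
    if (derivatives) cols[[paste0(name, "_d")]] <<- cs$dy
  }

  evOn <- ons[keep]
  evDur <- rep(eventDuration, sum(keep))
  addColumn("main", evOn, evDur, rep(1, sum(keep)))
  H <- events$entropy[okmod]
  I <- events$surprisal[okmod]
  D <- events$step_duration[okmod]
  if (is.null(D)) D <- events$duration_s[okmod]
  modOn <- ons[okmod]
  modDur <- rep(eventDuration, sum(okmod))
  addColumn("entropy", modOn, modDur, center(H))
  addColumn("surprisal", modOn, modDur, center(I))
  if (!is.null(questions) && nrow(questions)) {
    qon <- getOnset(questions)
    if (max(qon) > scanEnd) stop("question trial beyond scan end")
    addColumn("question", qon, rep(questionDuration, length(qon)),
              rep(1, length(qon)))
  }
  if (!is.null(epochs) && nrow(epochs)) {
    eon <- getOnset(epochs)
    if (max(eon) > scanEnd) stop("epoch beyond scan end")
    addColumn("epoch", eon, epochs$duration, rep(1, nrow(epochs)))
  }
  if (!is.null(D)) addColumn("duration", modOn, modDur, center(D))
  cols[["intercept"]] <- rep(1, nVolumes)

  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  new("DesignMatrix", X = X, tr = tr, frameTimes = frameTimes,
      settings = list(hrfParams = hrfParams, dt = dt,
                      centerModulators = centerModulators,
                      eventDuration = eventDuration,
                      questionDuration = questionDuration,
                      derivatives = derivatives))
}

#' Temporal Gaussian smoothing matrix (precoloring operator)
#'
#' Row-normalized discrete Gaussian kernel with `sigma = FWHM / 2.3548`
#' seconds, expressed at the TR sampling; rows are renormalized at the
#' edges so a constant series is preserved. The same operator must be
#' applied to the data and to the design (the precoloring contract).
#'
#' @param n number of time points.
#' @param tr sampling interval, seconds.
#' @param fwhm kernel full width at half maximum, seconds.
#' @return n x n smoothing matrix.
#' @export
gaussianSmootherMatrix <- function(n, tr, fwhm) {
  if (fwhm <= 0) stop("FWHM must be positive")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  tdiff <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * tr)
  S <- exp(-tdiff^2 / (2 * sigma^2))
  S / rowSums(S)
}

#' Low-frequency drift basis for highpass filtering
#'
#' Sine/cosine harmonics of the acquisition window up to `cutoffHz`;
#' projecting a series onto the orthogonal complement of this basis removes
#' slow drift of either phase (the constant term is excluded, so the mean
#' survives and an intercept column is unaffected).
#'
#' @param n number of time points.
#' @param tr sampling interval, seconds.
#' @param cutoffHz highpass cutoff, Hz (e.g. `1/70`).
#' @return n x 2k basis matrix (k may be 0).
#' @export
highpassBasis <- function(n, tr, cutoffHz) {
  kmax <- floor(n * tr * cutoffHz)
  if (kmax < 1) return(matrix(0, n, 0))
  t0 <- (seq_len(n) - 1) / n
  B <- lapply(seq_len(kmax), function(k)
    cbind(cos(2 * pi * k * t0), sin(2 * pi * k * t0)))
  do.call(cbind, B)
}

#' Apply the temporal filters (highpass + Gaussian precoloring)
#'
#' Removes drift components below the highpass cutoff by projecting out the
#' DCT basis, then applies Gaussian temporal smoothing. Used identically on
#' BOLD data and design columns.
#'
#' @param x numeric vector or time x series matrix, sampled at `tr`.
#' @param tr sampling interval, seconds.
#' @param highpassHz highpass cutoff in Hz, or NULL to skip.
#' @param gaussianFwhmS Gaussian FWHM in seconds, or NULL to skip.
#' @return filtered series with the input shape.
#' @export
temporalFilter <- function(x, tr, highpassHz = 1 / 70, gaussianFwhmS = 4) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is.null(highpassHz)) {
    B <- highpassBasis(n, tr, highpassHz)
    if (ncol(B)) x <- x - B %*% qr.solve(B, x)
  }
  if (!is.null(gaussianFwhmS)) {
    if (gaussianFwhmS <= 0) stop("FWHM must be positive")
    x <- gaussianSmootherMatrix(n, tr, gaussianFwhmS) %*% x
  }
  if (vec) drop(x) else x
}
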