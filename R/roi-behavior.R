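#' Voxel set of an ROI on a grid
#'
#' Default mode `"faces"`: the voxel nearest the center plus its six
#' face-adjacent neighbors (7 voxels, the reading of "a sphere of six
#' adjacent voxels" that yields exactly six neighbors around a center).
#' Mode `"radius"`: all voxels within `radiusMm` of the center.
#'
#' @param roi an [ROISpec-class].
#' @param dim grid dimensions.
#' @param voxelSizeMm isotropic voxel size, mm.
#' @return integer vector of linear voxel indices; errors when any voxel
#'   falls outside the grid.
#' @export
roiVoxels <- function(roi, dim, voxelSizeMm = 3) {
  ctr <- mmToVoxel(roi@centerMm, dim, voxelSizeMm)
  if (roi@mode == "faces") {
    offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    vox <- sweep(offs, 2, ctr, `+`)
  } else {
    r <- ceiling(roi@radiusMm / voxelSizeMm)
    g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    g <- g[sqrt(rowSums(g^2)) * voxelSizeMm <= roi@radiusMm + 1e-9, ,
           drop = FALSE]
    vox <- sweep(g, 2, ctr, `+`)
  }
  if (any(vox < 1) || any(vox > rep(dim, each = nrow(vox))))
    stop("ROI '", roi@label, "' extends outside the grid")
  sort(vox[, 1] + dim[1] * (vox[, 2] - 1) + dim[1] * dim[2] * (vox[, 3] - 1))
}

#' Extract per-participant ROI means and test them against zero
#'
#' @param betaMaps list of per-participant 3-D beta/contrast arrays (or an
#'   n x voxels matrix with `dim` given).
#' @param roi an [ROISpec-class].
#' @param voxelSizeMm voxel size, mm.
#' @param dim grid dimensions when a matrix is given.
#' @return list with `betas` (per-participant ROI means), `t`, `df`, `p`
#'   (two-tailed), `mean`, `sd`, and the `voxels` used.
#' @export
extractRoiBetas <- function(betaMaps, roi, voxelSizeMm = 3, dim = NULL) {
  if (is.list(betaMaps)) {
    dim <- dim(betaMaps[[1]])
    M <- do.call(rbind, lapply(betaMaps, as.vector))
  } else M <- as.matrix(betaMaps)
  vox <- roiVoxels(roi, dim, voxelSizeMm)
  betas <- rowMeans(M[, vox, drop = FALSE])
  n <- length(betas)
  s <- sd(betas)
  tval <- if (s == 0 && mean(betas) == 0) 0 else mean(betas) / (s / sqrt(n))
  list(betas = betas, t = tval, df = n - 1,
       p = 2 * pt(abs(tval), n - 1, lower.tail = FALSE),
       mean = mean(betas), sd = s, voxels = vox)
}

#' Aggregate post-test probability judgments by true probability level
#'
#' Averages each participant's judged probabilities over all transitions
#' sharing the same implemented probability level (0, 0.25, 0.5, 0.75,
#' 1.0). Crosses from the paper-pencil test can be converted to the
#' percent scale with [crossesToPercent()] (one cross corresponds to
#' p = 0.125, i.e. 12.5 percentage points).
#'
#' @param data data.frame with columns `participant`, `judgment`,
#'   `true_level` (and anything else, ignored).
#' @return data.frame `participant` x `true_level` with mean judgments
#'   (long format, columns `participant`, `true_level`, `mean_judgment`).
#' @export
aggregatePostTest <- function(data) {
  stopifnot(all(c("participant", "judgment", "true_level") %in% names(data)))
  if (any(is.na(data$true_level)))
    stop("every transition must be labeled with a true probability level")
  agg <- aggregate(judgment ~ participant + true_level, data, mean)
  names(agg)[3] <- "mean_judgment"
  agg[order(agg$participant, agg$true_level), ]
}

#' @describeIn aggregatePostTest convert paper-pencil crosses to percent
#' @param crosses numeric vector of cross counts (0-8).
#' @export
crossesToPercent <- function(crosses) crosses * 12.5

#' Probability represented by a single cross in the paper-pencil test
#' @export
crossProbability <- function() 0.125

#' Familiarity with the statistical structure
#'
#' `p_max - mean(|judged - true|)` over all judged transitions: the maximal
#' judgment of the response scale (100 for the computer test, 8 for the
#' paper-pencil test) minus the average absolute deviation of the
#' judgments from the implemented probabilities. Maximal iff every
#' judgment is exact; strictly decreasing in any single deviation.
#'
#' @param judgments numeric vector of probability judgments, on the
#'   response scale.
#' @param truths implemented probabilities on the same scale.
#' @param pMax maximal judgment of the scale (100 or 8).
#' @return familiarity score (<= pMax).
#' @export
familiarity <- function(judgments, truths, pMax) {
  stopifnot(length(judgments) == length(truths), length(judgments) > 0)
  if (max(judgments) > pMax + 1e-9 || max(truths) > pMax + 1e-9)
    stop("judgments/truths exceed pMax: response scale mismatch")
  pMax - mean(abs(judgments - truths))
}

#' Per-participant familiarity scores from a post-test table
#'
#' @param data data.frame with `participant`, `judgment`, `true_value`
#'   columns (true_value on the response scale).
#' @param pMax maximal judgment of the scale.
#' @return data.frame with `participant` and `familiarity`.
#' @export
familiarityScores <- function(data, pMax) {
  stopifnot(all(c("participant", "judgment", "true_value") %in% names(data)))
  out <- do.call(rbind, lapply(split(data, data$participant), function(d)
    data.frame(participant = d$participant[1],
               familiarity = familiarity(d$judgment, d$true_value, pMax))))
  rownames(out) <- NULL
  out
}

#' Correlate ROI betas with familiarity across participants
#'
#' Pearson correlation with `t = r * sqrt(n - 2) / sqrt(1 - r^2)`,
#' df = n - 2 and a two-tailed p value.
#'
#' @param betas per-participant ROI beta values.
#' @param fam per-participant familiarity scores (same order).
#' @return list with `r`, `t`, `df`, `p`.
#' @export
correlateBetasFamiliarity <- function(betas, fam) {
  n <- length(betas)
  if (n < 3 || length(fam) != n)
    stop("at least 3 paired observations are required")
  if (sd(betas) == 0 || sd(fam) == 0)
    stop("correlation undefined: zero variance in betas or familiarity")
  r <- sum((betas - mean(betas)) * (fam - mean(fam))) /
    ((n - 1) * sd(betas) * sd(fam))
  r <- max(-1, min(1, r))
  tval <- if (abs(r) == 1) sign(r) * Inf
          else r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, t = tval, df = n - 2,
       p = 2 * pt(abs(tval), n - 2, lower.tail = FALSE))
}

# Largest-remainder allocation of `total` crosses proportional to w >= 0.
allocateCrosses <- function(w, total = 8) {
  w <- pmax(w, 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  raw <- total * w / sum(w)
  fl <- floor(raw)
  rem <- total - sum(fl)
  if (rem > 0) {
    extra <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  fl
}

#' Simulate post-test responders
#'
#' Synthetic judgment model: judged probability = implemented probability
#' plus truncated Gaussian noise. The computer test judges every ordered
#' step pair (30 pairs without immediate repeats by default, 36 with) on a
#' 0-100 percent scale; the paper-pencil test distributes 8 crosses per
#' predecessor over the six steps by largest-remainder rounding of the
#' noisy probabilities.
#'
#' @param chain an [ActionChain-class] giving the implemented
#'   probabilities.
#' @param nParticipants number of synthetic responders.
#' @param noiseSd SD of the judgment noise, on the probability (0-1)
#'   scale.
#' @param test `"computer"` or `"paper"`.
#' @param includeRepeats include immediate repetitions in the computer
#'   test's pair list (36 pairs instead of 30).
#' @param seed integer seed.
#' @return data.frame with columns `participant`, `prev`, `next`,
#'   `judgment` (percent or crosses), `true_level` (implemented
#'   probability, 0-1) and `true_value` (implemented probability on the
#'   response scale).
#' @export
simulatePostTest <- function(chain, nParticipants = 15, noiseSd = 0.15,
                             test = c("computer", "paper"),
                             includeRepeats = FALSE, seed = NULL) {
  test <- match.arg(test)
  lab <- chainLabels(chain)
  P <- transitionMatrix(chain)
  pairs <- expand.grid(prev = lab, nxt = lab, stringsAsFactors = FALSE)
  if (!includeRepeats) pairs <- pairs[pairs$prev != pairs$nxt, ]
  withSeed(seed, {
    out <- lapply(seq_len(nParticipants), function(pp) {
      truth <- P[cbind(pairs$prev, pairs$nxt)]
      if (test == "computer") {
        judged <- pmin(pmax(truth + rnorm(nrow(pairs), 0, noiseSd), 0), 1)
        data.frame(participant = pp, prev = pairs$prev, next. = pairs$nxt,
                   judgment = judged * 100, true_level = truth,
                   true_value = truth * 100)
      } else {
        # one trial per predecessor: distribute 8 crosses over all 6 steps
        do.call(rbind, lapply(lab, function(pr) {
          noisy <- pmax(P[pr, ] + rnorm(length(lab), 0, noiseSd), 0)
          cr <- allocateCrosses(noisy, 8)
          data.frame(participant = pp, prev = pr, next. = lab,
                     judgment = cr, true_level = P[pr, ],
                     true_value = P[pr, ] * 8)
        }))
      }
    })
    out <- do.call(rbind, out)
    names(out)[names(out) == "next."] <- "next_step"
    rownames(out) <- NULL
    out
  })
}
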