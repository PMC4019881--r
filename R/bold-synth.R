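# 1-D Gaussian kernel in voxel units, truncated at 4 sigma.
gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigmaVox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# Separable 3-D Gaussian smoothing of a 3-D array (replicate-edge padding
# via kernel renormalization is not needed for zero-mean noise; plain
# zero-padded convolution with edge renormalization keeps constants).
smooth3d <- function(vol, sigmaVox) {
  if (sigmaVox <= 0) return(vol)
  k <- gaussKernel1d(sigmaVox)
  d <- dim(vol)
  conv1 <- function(m, k) {
    # filter columns of matrix m with kernel k, edge-renormalized
    n <- nrow(m)
    r <- (length(k) - 1) / 2
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - r - 1
      src <- seq_len(n) + off
      okv <- src >= 1 & src <= n
      out[okv, ] <- out[okv, ] + k[j] * m[src[okv], ]
      norm[okv] <- norm[okv] + k[j]
    }
    out / norm
  }
  v <- conv1(matrix(vol, d[1]), k) # along x
  vol <- array(v, d)
  vol <- aperm(vol, c(2, 1, 3))
  vol <- array(conv1(matrix(vol, d[2]), k), d[c(2, 1, 3)]) # along y
  vol <- aperm(vol, c(2, 1, 3))
  vol <- aperm(vol, c(3, 2, 1))
  vol <- array(conv1(matrix(vol, d[3]), k), d[c(3, 2, 1)]) # along z
  aperm(vol, c(3, 2, 1))
}

# Variance attenuation factor of unit white noise after separable
# smoothing: product over dims of sum(k^2). Used to restandardize null
# fields analytically.
smoothVarFactor <- function(sigmaVox) sum(gaussKernel1d(sigmaVox)^2)^3

#' Construct a ground-truth effect specification for BOLD simulation
#'
#' Places three disjoint compact (spherical) voxel sets on the grid - one
#' carrying the entropy effect, one the surprisal effect, and an overlap
#' set carrying both - and records the noise model. Compact sets mimic
#' focal activations, so cluster-level inference on the recovered maps is
#' meaningful. Effect amplitudes can be given directly, or calibrated from
#' a design so that the designated voxels carry a group-level effect size
#' of about Cohen's d = 0.8 (see [calibrateNoiseSd()]).
#'
#' @param dim integer length-3 grid dimensions.
#' @param nEntropy,nSurprisal,nOverlap sizes of the designated voxel sets.
#' @param betaMain,betaH,betaI effect amplitudes (BOLD units) at the
#'   designated voxels.
#' @param noiseSd marginal SD of the AR(1) noise.
#' @param ar1 lag-1 AR coefficient.
#' @param whiteSd SD of the additional white noise.
#' @param driftAmplitude,driftPeriodS slow cosine drift parameters.
#' @param betweenSubjectSd SD of the per-participant random effect.
#' @param voxelSizeMm isotropic voxel size, mm.
#' @param spatialFwhmMm spatial smoothing FWHM, mm.
#' @param seed integer seed for the voxel-set draw.
#' @return a [GroundTruth-class].
#' @export
makeGroundTruth <- function(dim = c(20L, 20L, 20L), nEntropy = 30,
                            nSurprisal = 30, nOverlap = 10, betaMain = 1,
                            betaH = 1, betaI = 1, noiseSd = 1, ar1 = 0.3,
                            whiteSd = 0.5, driftAmplitude = 1,
                            driftPeriodS = 128, betweenSubjectSd = 0.15,
                            voxelSizeMm = 3, spatialFwhmMm = 5.65,
                            seed = NULL) {
  dim <- as.integer(dim)
  nv <- prod(dim)
  stopifnot(nEntropy + nSurprisal + nOverlap <= nv)
  # the `size` voxels nearest a center form a compact quasi-spherical blob
  growBlob <- function(center, size, taken) {
    ijk <- arrayInd(seq_len(nv), dim)
    d2 <- rowSums(sweep(ijk, 2, center)^2)
    d2[taken] <- Inf
    sort(order(d2)[seq_len(size)])
  }
  withSeed(seed, {
    margin <- max(1L, min(3L, floor(min(dim) / 4)))
    minDist <- min(7, max(3, min(dim) - 2 * margin - 1))
    centers <- list()
    tries <- 0
    while (length(centers) < 3) {
      tries <- tries + 1
      if (tries > 1e4) stop("grid too small to place disjoint effect sets")
      cand <- vapply(dim, function(d)
        sample(seq(margin + 1, d - margin), 1), numeric(1))
      farEnough <- all(vapply(centers, function(cc)
        sqrt(sum((cc - cand)^2)) >= minDist, logical(1)))
      if (farEnough) centers[[length(centers) + 1]] <- cand
    }
    taken <- integer(0)
    ent <- growBlob(centers[[1]], nEntropy, taken)
    taken <- c(taken, ent)
    sur <- growBlob(centers[[2]], nSurprisal, taken)
    taken <- c(taken, sur)
    ovl <- growBlob(centers[[3]], nOverlap, taken)
    bM <- numeric(nv); bH <- numeric(nv); bI <- numeric(nv)
    bM[c(ent, sur, ovl)] <- betaMain
    bH[c(ent, ovl)] <- betaH
    bI[c(sur, ovl)] <- betaI
    new("GroundTruth", dim = dim, betaMain = bM, betaH = bH, betaI = bI,
        entropyVoxels = as.integer(ent), surprisalVoxels = as.integer(sur),
        overlapVoxels = as.integer(ovl), noiseSd = noiseSd, ar1 = ar1,
        whiteSd = whiteSd, driftAmplitude = driftAmplitude,
        driftPeriodS = driftPeriodS, betweenSubjectSd = betweenSubjectSd,
        voxelSizeMm = voxelSizeMm, spatialFwhmMm = spatialFwhmMm)
  })
}

#' Calibrate the noise SD to a target group-level effect size
#'
#' Given a design and an effect amplitude on one modulator column, returns
#' the AR(1) marginal noise SD such that the across-participant SD of the
#' per-voxel first-level estimate (first-level sampling error plus the
#' between-subject effect SD) yields `beta / sd = targetD`. Pure design
#' algebra (uses the precolored OLS covariance); no data involved.
#'
#' @param design a [DesignMatrix-class].
#' @param column design column carrying the effect (e.g. `"entropy"`).
#' @param beta effect amplitude at the designated voxels.
#' @param targetD target group-level Cohen's d (default 0.8).
#' @param betweenSubjectSd between-subject effect SD.
#' @param ar1 lag-1 coefficient of the simulated AR(1) noise.
#' @param whiteFrac SD of the simulated white component as a fraction of
#'   the AR(1) marginal SD.
#' @param highpassHz,gaussianFwhmS filters used at fit time.
#' @return noise SD (>= 0).
#' @export
calibrateNoiseSd <- function(design, column = "entropy", beta = 1,
                             targetD = 0.8, betweenSubjectSd = 0.15,
                             ar1 = 0.3, whiteFrac = 0.5,
                             highpassHz = 1 / 70, gaussianFwhmS = 4) {
  X <- designMatrix(design)
  n <- nrow(X)
  Xf <- temporalFilter(X, design@tr, highpassHz, gaussianFwhmS)
  j <- match(column, colnames(X))
  if (is.na(j)) stop("unknown design column: ", column)
  # var(beta_j) = [A V0 A']_jj with A the filtered-OLS estimator applied to
  # the *unfiltered* data and V0 the noise covariance per unit noiseSd^2:
  # AR(1) Toeplitz plus the white component (drift is absorbed by the
  # highpass and ignored here).
  a <- solve(crossprod(Xf), t(Xf))[j, ]
  # the estimator acts on filtered data: fold the filter into a
  Fop <- diag(n)
  if (!is.null(highpassHz)) {
    B <- highpassBasis(n, design@tr, highpassHz)
    if (ncol(B)) Fop <- Fop - B %*% qr.solve(B, diag(n))
  }
  if (!is.null(gaussianFwhmS))
    Fop <- gaussianSmootherMatrix(n, design@tr, gaussianFwhmS) %*% Fop
  aF <- drop(a %*% Fop)
  R <- ar1^abs(outer(seq_len(n), seq_len(n), `-`))
  unitVar <- drop(aF %*% R %*% aF) + whiteFrac^2 * sum(aF^2)
  targetSdTotal <- beta / targetD
  need <- targetSdTotal^2 - betweenSubjectSd^2
  if (need <= 0) return(0)
  sqrt(need / unitVar)
}

# Seeded AR(1)+white noise matrix (time x voxels), marginal AR sd = noiseSd.
arNoise <- function(nT, nVox, noiseSd, ar1, whiteSd) {
  innov <- matrix(rnorm(nT * nVox), nT, nVox)
  if (ar1 != 0) {
    e <- innov * noiseSd * sqrt(1 - ar1^2)
    x <- e
    x[1, ] <- rnorm(nVox, sd = noiseSd)
    for (t in 2:nT) x[t, ] <- ar1 * x[t - 1, ] + e[t, ]
  } else x <- innov * noiseSd
  if (whiteSd > 0) x <- x + matrix(rnorm(nT * nVox, sd = whiteSd), nT, nVox)
  x
}

#' Simulate one participant's 4-D BOLD series
#'
#' Voxel time series are `design %*% betas` plus AR(1) noise, white noise
#' and a slow cosine drift with a random phase per voxel; the designated
#' voxels carry the ground-truth `betaH`/`betaI` on the entropy/surprisal
#' columns (plus `betaMain` on the main-effect column). Optionally applies
#' spatial Gaussian smoothing volume by volume.
#'
#' @param design a [DesignMatrix-class].
#' @param truth a [GroundTruth-class]; `betaShift` adds a per-participant
#'   deviation to the designated effect maps.
#' @param seed integer seed (bit-reproducible output).
#' @param betaShift named numeric: additive deviations for `main`, `H`,
#'   `I` applied over each map's nonzero support.
#' @param spatialSmooth apply the `spatialFwhmMm` Gaussian to each volume.
#' @return 4-D array (x, y, z, t).
#' @export
simulateParticipant <- function(design, truth, seed = NULL,
                                betaShift = c(main = 0, H = 0, I = 0),
                                spatialSmooth = FALSE) {
  X <- designMatrix(design)
  nT <- nrow(X)
  nv <- prod(truth@dim)
  bM <- truth@betaMain + betaShift[["main"]] * (truth@betaMain != 0)
  bH <- truth@betaH + betaShift[["H"]] * (truth@betaH != 0)
  bI <- truth@betaI + betaShift[["I"]] * (truth@betaI != 0)
  B <- matrix(0, ncol(X), nv)
  if ("main" %in% colnames(X)) B[match("main", colnames(X)), ] <- bM
  B[match("entropy", colnames(X)), ] <- bH
  B[match("surprisal", colnames(X)), ] <- bI
  Y <- X %*% B
  withSeed(seed, {
    if (truth@noiseSd > 0 || truth@whiteSd > 0)
      Y <- Y + arNoise(nT, nv, truth@noiseSd, truth@ar1, truth@whiteSd)
    if (truth@driftAmplitude > 0) {
      tsec <- design@frameTimes
      phase <- runif(nv, 0, 2 * pi)
      Y <- Y + truth@driftAmplitude *
        cos(outer(2 * pi * tsec / truth@driftPeriodS, phase, `+`))
    }
    NULL
  })
  vol4 <- array(t(Y), c(truth@dim, nT))
  if (spatialSmooth && truth@spatialFwhmMm > 0) {
    sigmaVox <- truth@spatialFwhmMm / (2 * sqrt(2 * log(2))) /
      truth@voxelSizeMm
    for (t in seq_len(nT)) vol4[, , , t] <- smooth3d(vol4[, , , t], sigmaVox)
  }
  vol4
}

#' Simulate a cohort of participants
#'
#' Per-participant effect deviations are drawn once (Gaussian with SD
#' `truth@betweenSubjectSd`, shared across that participant's designated
#' voxels), then each participant's 4-D series is generated with a child
#' seed. With `dir` set, volumes are written as NIfTI (3 mm voxels, grid
#' centered on the origin), events and ground truth as TSV/JSON sidecars,
#' and file paths are returned instead of arrays.
#'
#' @param design a [DesignMatrix-class] (shared across participants).
#' @param truth a [GroundTruth-class].
#' @param nParticipants cohort size (>= 2; a second-level t-test needs it).
#' @param seed master seed.
#' @param dir output directory, or NULL to keep arrays in memory.
#' @param spatialSmooth apply spatial smoothing per volume.
#' @return list with `bold` (list of arrays or NIfTI paths), `shifts`
#'   (participants x 3 matrix of effect deviations), `truth`, `seed`.
#' @export
simulateCohort <- function(design, truth, nParticipants = 15, seed = NULL,
                           dir = NULL, spatialSmooth = FALSE) {
  if (nParticipants < 2)
    stop("at least 2 participants are required for second-level inference")
  shifts <- withSeed(seed, matrix(
    rnorm(3 * nParticipants, sd = truth@betweenSubjectSd),
    nParticipants, 3, dimnames = list(NULL, c("main", "H", "I"))))
  bold <- vector("list", nParticipants)
  for (p in seq_len(nParticipants)) {
    vol <- simulateParticipant(design, truth,
      seed = if (is.null(seed)) NULL else childSeed(seed, paste0("sub", p)),
      betaShift = shifts[p, ], spatialSmooth = spatialSmooth)
    if (is.null(dir)) bold[[p]] <- vol
    else {
      path <- file.path(dir, sprintf("sub-%02d_bold.nii", p))
      writeBoldNifti(vol, path, voxelSizeMm = truth@voxelSizeMm,
                     tr = design@tr)
      bold[[p]] <- path
    }
  }
  if (!is.null(dir)) {
    jsonlite::write_json(list(
      dim = truth@dim, entropyVoxels = truth@entropyVoxels,
      surprisalVoxels = truth@surprisalVoxels,
      overlapVoxels = truth@overlapVoxels,
      betaMain = max(truth@betaMain), betaH = max(truth@betaH),
      betaI = max(truth@betaI), noiseSd = truth@noiseSd, ar1 = truth@ar1,
      whiteSd = truth@whiteSd, driftAmplitude = truth@driftAmplitude,
      driftPeriodS = truth@driftPeriodS,
      betweenSubjectSd = truth@betweenSubjectSd,
      shifts = apply(shifts, 1, identity, simplify = FALSE),
      seed = seed), file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(bold = bold, shifts = shifts, truth = truth, seed = seed)
}

#' Write / read a 4-D BOLD array as NIfTI
#'
#' The affine places the grid center at the origin with isotropic voxels,
#' so dataset mm coordinates are symmetric around 0.
#'
#' @param vol4 4-D array (x, y, z, t).
#' @param path file path (`.nii`).
#' @param voxelSizeMm isotropic voxel size.
#' @param tr repetition time, seconds.
#' @return `writeBoldNifti` returns `path` invisibly; `readBoldNifti`
#'   returns the 4-D array.
#' @export
writeBoldNifti <- function(vol4, path, voxelSizeMm = 3, tr = 2) {
  img <- RNifti::asNifti(vol4)
  d <- dim(vol4)[1:3]
  off <- -(d / 2 - 0.5) * voxelSizeMm
  xform <- rbind(cbind(diag(voxelSizeMm, 3), off), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xform, code = 2L)
  RNifti::pixdim(img) <- c(rep(voxelSizeMm, 3), tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeBoldNifti
#' @export
readBoldNifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  arr
}

#' Grid mm coordinates of voxel indices (center-origin convention)
#'
#' @param idx linear voxel indices.
#' @param dim grid dimensions.
#' @param voxelSizeMm isotropic voxel size.
#' @return matrix of mm coordinates, one row per index.
#' @export
voxelToMm <- function(idx, dim, voxelSizeMm = 3) {
  ijk <- arrayInd(idx, dim)
  sweep(ijk - 1, 2, (dim / 2 - 0.5), `-`) * voxelSizeMm
}

#' Nearest voxel index for mm coordinates (center-origin convention)
#'
#' @param mm numeric length-3 mm coordinates.
#' @param dim grid dimensions.
#' @param voxelSizeMm isotropic voxel size.
#' @return integer length-3 voxel subscript (1-based), or an error when the
#'   point lies outside the grid.
#' @export
mmToVoxel <- function(mm, dim, voxelSizeMm = 3) {
  ijk <- round(mm / voxelSizeMm + (dim / 2 - 0.5)) + 1
  if (any(ijk < 1) || any(ijk > dim))
    stop("coordinates (", paste(mm, collapse = ", "),
         ") mm fall outside the grid")
  as.integer(ijk)
}
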