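# Satterthwaite-type effective degrees of freedom for precolored OLS:
# trace(RV)^2 / trace(RVRV), with R the residual-forming matrix of the
# filtered design and V = F F' the covariance imposed by the filter.
effectiveDf <- function(Xf, F) {
  V <- tcrossprod(F)
  Q <- qr.Q(qr(Xf))
  RV <- V - Q %*% (crossprod(Q, V))
  tr1 <- sum(diag(RV))
  tr2 <- sum(RV * t(RV))
  tr1^2 / tr2
}

#' Fit the precolored first-level GLM
#'
#' Applies the identical temporal filter (DCT highpass + Gaussian
#' precoloring) to the data and to every design column, then estimates the
#' model by ordinary least squares per voxel. Effective degrees of freedom
#' use the Satterthwaite-type trace correction for the imposed
#' autocorrelation.
#'
#' @param bold 4-D array (x, y, z, t), time x voxel matrix, or path to a
#'   NIfTI file.
#' @param design a [DesignMatrix-class] with rows matching the volumes.
#' @param precolor apply the Gaussian precoloring filter (default TRUE).
#' @param highpassHz highpass cutoff, Hz (NULL to skip).
#' @param gaussianFwhmS precoloring FWHM, seconds.
#' @param dim spatial dimensions when `bold` is a matrix.
#' @return a [FirstLevelResult-class].
#' @export
fitFirstLevel <- function(bold, design, precolor = TRUE,
                          highpassHz = 1 / 70, gaussianFwhmS = 4,
                          dim = NULL) {
  if (is.character(bold)) bold <- readBoldNifti(bold)
  if (length(dim(bold)) == 4) {
    dim <- dim(bold)[1:3]
    Y <- t(matrix(bold, prod(dim), dim(bold)[4]))
  } else {
    Y <- as.matrix(bold)
    if (is.null(dim)) dim <- c(ncol(Y), 1L, 1L)
  }
  X <- designMatrix(design)
  if (nrow(X) != nrow(Y))
    stop("design rows (", nrow(X), ") do not match volumes (", nrow(Y), ")")
  n <- nrow(X)
  fwhm <- if (precolor) gaussianFwhmS else NULL
  Xf <- temporalFilter(X, design@tr, highpassHz, fwhm)
  Yf <- temporalFilter(Y, design@tr, highpassHz, fwhm)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("design is rank deficient after filtering; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, Yf)
  res <- Yf - Xf %*% beta
  # filter operator for the df correction
  F <- diag(n)
  if (!is.null(highpassHz)) {
    B <- highpassBasis(n, design@tr, highpassHz)
    if (ncol(B)) F <- F - B %*% qr.solve(B, diag(n))
  }
  if (precolor) F <- gaussianSmootherMatrix(n, design@tr, gaussianFwhmS) %*% F
  effDf <- effectiveDf(Xf, F)
  sigma2 <- colSums(res^2) / effDf
  new("FirstLevelResult", beta = beta, dim = as.integer(dim),
      sigma2 = sigma2, effDf = effDf, columns = colnames(X))
}

#' Second-level one-sample t-test with t-to-z transformation
#'
#' Per-voxel one-sample t against zero over the participants' contrast
#' maps (df = n - 1); z is the standard-normal quantile matching the
#' one-tailed t tail probability, so t and z are rank-identical.
#' Zero-variance voxels are flagged: their t is 0 when the mean is also 0,
#' otherwise the z value is guarded at the largest finite quantile.
#'
#' @param contrasts list of 3-D arrays, or an n x voxels matrix.
#' @param dim spatial dimensions when a matrix is given.
#' @return a [GroupStatMap-class].
#' @export
groupTTest <- function(contrasts, dim = NULL) {
  if (is.list(contrasts)) {
    dim <- dim(contrasts[[1]])
    M <- do.call(rbind, lapply(contrasts, as.vector))
  } else {
    M <- as.matrix(contrasts)
    if (is.null(dim)) dim <- c(ncol(M), 1L, 1L)
  }
  n <- nrow(M)
  if (n < 2) stop("at least 2 contrast images are required")
  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  flagged <- s == 0
  tvals <- ifelse(flagged, ifelse(mu == 0, 0, sign(mu) * Inf),
                  mu / (s / sqrt(n)))
  p <- pt(tvals, df = n - 1, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  z <- qnorm(p, lower.tail = FALSE)
  new("GroupStatMap", tMap = array(tvals, dim), zMap = array(z, dim),
      df = n - 1, n = as.integer(n), flagged = array(flagged, dim))
}

# 3-D connected-component labeling of a logical array. Returns an integer
# array (0 = background). BFS over the suprathreshold voxels only.
labelClusters <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  sub <- arrayInd(idx, d)
  cur <- 0L
  for (v in idx) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue)) {
      w <- queue[1]; queue <- queue[-1]
      s <- arrayInd(w, d)
      nb <- sweep(offs, 2, as.integer(s), `+`)
      okn <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[okn, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      new <- lin[mask[lin] & lab[lin] == 0L]
      if (length(new)) {
        lab[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  lab
}

# Max cluster size and mass of one thresholded z field.
maxClusterStats <- function(z, initialZ, connectivity) {
  mask <- z > initialZ
  if (!any(mask)) return(c(size = 0, mass = 0))
  lab <- labelClusters(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  masses <- vapply(seq_along(sizes), function(i) sum(z[lab == i]), numeric(1))
  c(size = max(sizes), mass = max(masses))
}

#' Monte Carlo cluster-size/cluster-mass thresholds
#'
#' Simulates smooth Gaussian null fields (white noise smoothed to the
#' stated spatial FWHM and analytically restandardized to unit variance),
#' thresholds them at `initialZ` (one-tailed, positive), and records the
#' maximal cluster extent and maximal cluster mass (sum of suprathreshold
#' z) per iteration. The returned thresholds are the smallest values whose
#' exceedance probability across the null simulations is at most `alpha`,
#' so applying them (jointly, "and" rule) to fresh null fields controls the
#' familywise error rate at `alpha`.
#'
#' @param dim grid dimensions.
#' @param smoothFwhmMm spatial smoothness of the null fields, mm.
#' @param voxelSizeMm voxel size, mm.
#' @param initialZ cluster-forming threshold (default 2.33, one-tailed
#'   p < 0.01).
#' @param alpha familywise level (default 0.05, one-tailed).
#' @param iterations number of null fields (>= 100).
#' @param connectivity 6, 18 or 26 (must match the application path; the
#'   same labeling code is used in both).
#' @param rule `"and"` (default) or `"or"` survival rule recorded for the
#'   application step.
#' @param seed integer seed.
#' @return a [ClusterThresholds-class].
#' @export
mcClusterThresholds <- function(dim, smoothFwhmMm = 5.65, voxelSizeMm = 3,
                                initialZ = 2.33, alpha = 0.05,
                                iterations = 1000, connectivity = 26,
                                rule = c("and", "or"), seed = NULL) {
  rule <- match.arg(rule)
  if (iterations < 100) stop("at least 100 Monte Carlo iterations required")
  sigmaVox <- smoothFwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm
  r <- if (sigmaVox > 0) max(1L, ceiling(4 * sigmaVox)) else 0L
  if (any(dim < 2 * r + 1))
    stop("grid is smaller than the smoothing kernel support")
  scale <- if (sigmaVox > 0) sqrt(smoothVarFactor(sigmaVox)) else 1
  stats <- withSeed(seed, vapply(seq_len(iterations), function(i) {
    z <- array(rnorm(prod(dim)), dim)
    if (sigmaVox > 0) z <- smooth3d(z, sigmaVox) / scale
    maxClusterStats(z, initialZ, connectivity)
  }, c(size = 0, mass = 0)))
  thrFor <- function(x) {
    # smallest threshold with P(max >= thr) <= alpha
    xs <- sort(x)
    cand <- xs[ceiling((1 - alpha) * iterations)]
    while (mean(x >= cand) > alpha) cand <- cand + if (max(x) > cand)
      min(x[x > cand]) - cand else 1
    cand
  }
  new("ClusterThresholds", initialZ = initialZ, alpha = alpha,
      sizeThreshold = max(1, thrFor(stats["size", ])),
      massThreshold = thrFor(stats["mass", ]),
      iterations = as.integer(iterations), smoothnessFwhmMm = smoothFwhmMm,
      voxelSizeMm = voxelSizeMm, connectivity = as.integer(connectivity),
      rule = rule)
}

#' Apply the cluster-level correction to a z map
#'
#' Labels connected components above the initial threshold (same labeling
#' code path as the Monte Carlo simulation) and keeps those satisfying the
#' size/mass rule. Peak coordinates are reported in the dataset's mm space
#' (grid centered on the origin).
#'
#' @param zmap a [GroupStatMap-class] or a 3-D z array.
#' @param thresholds a [ClusterThresholds-class].
#' @return data.frame with one row per surviving cluster: `cluster_id`,
#'   `size`, `mass`, `peak_z`, `peak_x`, `peak_y`, `peak_z_mm` (mm
#'   coordinates of the peak voxel). Empty when nothing survives.
#' @export
applyClusterCorrection <- function(zmap, thresholds) {
  z <- if (is(zmap, "GroupStatMap")) zmap@zMap else zmap
  if (any(!is.finite(z))) stop("z map must be finite")
  d <- dim(z)
  empty <- data.frame(cluster_id = integer(0), size = integer(0),
                      mass = numeric(0), peak_z = numeric(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z_mm = numeric(0))
  mask <- z > thresholds@initialZ
  if (!any(mask)) return(empty)
  lab <- labelClusters(mask, thresholds@connectivity)
  ncl <- max(lab)
  rows <- lapply(seq_len(ncl), function(i) {
    vox <- which(lab == i)
    size <- length(vox)
    mass <- sum(z[vox])
    keep <- if (thresholds@rule == "and")
      size >= thresholds@sizeThreshold && mass >= thresholds@massThreshold
    else size >= thresholds@sizeThreshold || mass >= thresholds@massThreshold
    if (!keep) return(NULL)
    pk <- vox[which.max(z[vox])]
    mm <- voxelToMm(pk, d, thresholds@voxelSizeMm)
    data.frame(cluster_id = i, size = size, mass = mass, peak_z = z[pk],
               peak_x = mm[1], peak_y = mm[2], peak_z_mm = mm[3])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_z), ]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
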