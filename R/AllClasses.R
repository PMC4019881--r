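#' ActionChain: a labeled first-order Markov action grammar
#'
#' Row-stochastic transition matrix over a small vocabulary of action steps.
#' Row i gives the distribution of the next step given that step i was just
#' performed. Structural soundness (square, labeled, non-negative, finite)
#' is enforced by the validity method; the experiment-level design
#' constraints (admissible probability set, degree limits, no immediate
#' repetitions) are checked by [validateChain()] so that deliberately
#' non-conforming matrices can still be constructed and examined.
#'
#' @slot labels character vector of K step identifiers.
#' @slot P K x K numeric matrix, `P[i, j] = p(x_t = j | x_{t-1} = i)`.
#' @export
setClass("ActionChain", representation(labels = "character", P = "matrix"))

setValidity("ActionChain", function(object) {
  P <- object@P
  if (!is.numeric(P)) return("transition matrix must be numeric")
  if (nrow(P) != ncol(P)) return("transition matrix must be square")
  if (length(object@labels) != nrow(P))
    return("label count must match matrix dimension")
  if (anyDuplicated(object@labels)) return("step labels must be unique")
  if (any(!is.finite(P))) return("transition probabilities must be finite")
  if (any(P < 0)) return("transition probabilities must be non-negative")
  TRUE
})

#' Construct an ActionChain
#'
#' @param P square numeric matrix of transition probabilities; dimnames are
#'   used as labels when `labels` is missing.
#' @param labels optional character vector of step identifiers.
#' @return an [ActionChain-class] object.
#' @examples
#' ch <- defaultChain()
#' chainLabels(ch)
#' @export
ActionChain <- function(P, labels = NULL) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stopStructural("transition matrix must be a square matrix")
  if (!is.numeric(P) || any(!is.finite(P)))
    stopStructural("transition matrix must be finite numeric")
  if (any(P < 0))
    stopStructural("transition matrix must have non-negative entries")
  if (is.null(labels)) labels <- rownames(P)
  if (is.null(labels)) labels <- paste0("step", seq_len(nrow(P)))
  dimnames(P) <- list(labels, labels)
  new("ActionChain", labels = labels, P = P)
}

#' @describeIn ActionChain step labels
#' @param chain an ActionChain.
#' @export
chainLabels <- function(chain) chain@labels

#' @describeIn ActionChain transition probability matrix
#' @export
transitionMatrix <- function(chain) chain@P

setMethod("show", "ActionChain", function(object) {
  cat(sprintf("ActionChain with %d action steps\n", length(object@labels)))
  print(round(object@P, 3))
})

#' ActionCorpus: a generated set of action sequences
#'
#' Long-format event table of a corpus of Markov-structured action-step
#' sequences, together with the chain that generated it. One row per action
#' step, ordered by sequence and position.
#'
#' @slot events data.frame with columns `sequence_id`, `scaffold_id`,
#'   `position`, `step`, `onset_s`, `duration_s` (onsets are
#'   sequence-relative; session-level timing is assigned by
#'   [buildSessionSchedule()]).
#' @slot chain the generating [ActionChain-class].
#' @export
setClass("ActionCorpus", representation(events = "data.frame",
                                        chain = "ActionChain"))

setValidity("ActionCorpus", function(object) {
  ev <- object@events
  need <- c("sequence_id", "scaffold_id", "position", "step",
            "onset_s", "duration_s")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev) && !all(ev$step %in% object@chain@labels))
    return("all steps must belong to the chain vocabulary")
  TRUE
})

#' @describeIn ActionCorpus the long-format event table
#' @param corpus an ActionCorpus.
#' @export
corpusEvents <- function(corpus) corpus@events

#' @describeIn ActionCorpus number of sequences
#' @export
nSequences <- function(corpus) length(unique(corpus@events$sequence_id))

#' @describeIn ActionCorpus per-sequence step counts
#' @export
sequenceLengths <- function(corpus) {
  as.integer(table(factor(corpus@events$sequence_id,
                          levels = unique(corpus@events$sequence_id))))
}

#' @describeIn ActionCorpus total occurrences of each step
#' @export
stepCounts <- function(corpus) {
  table(factor(corpus@events$step, levels = corpus@chain@labels))
}

#' @describeIn ActionCorpus counts of each step in sequence-initial position
#' @export
firstCounts <- function(corpus) {
  ev <- corpus@events
  table(factor(ev$step[ev$position == 1], levels = corpus@chain@labels))
}

#' @describeIn ActionCorpus counts of each step in sequence-final position
#' @export
lastCounts <- function(corpus) {
  ev <- corpus@events
  last <- !duplicated(ev$sequence_id, fromLast = TRUE)
  table(factor(ev$step[last], levels = corpus@chain@labels))
}

#' @describeIn ActionCorpus step lists, one character vector per sequence
#' @export
corpusSequences <- function(corpus) {
  split(corpus@events$step,
        factor(corpus@events$sequence_id,
               levels = unique(corpus@events$sequence_id)))
}

setMethod("show", "ActionCorpus", function(object) {
  n <- nSequences(object)
  cat(sprintf("ActionCorpus: %d sequences, %d action steps\n",
              n, nrow(object@events)))
  if (n) {
    cat("  step counts: ",
        paste(sprintf("%s=%d", names(stepCounts(object)),
                      as.integer(stepCounts(object))), collapse = " "), "\n")
    cat(sprintf("  mean length %.2f, mean duration %.2f s\n",
                nrow(object@events) / n,
                sum(object@events$duration_s) / n))
  }
})

#' ObserverState: running counts of the ideal Bayesian observer
#'
#' Tracks per-step occurrence counts and transition counts; conditional
#' probabilities are posterior-mean estimates under an add-one (Dirichlet)
#' prior. Three smoothing denominators are supported: `dirichlet_K`
#' (`(n+1)/(N+K)`, the proper Dirichlet(1) posterior mean, default),
#' `literal_plus1` (`(n+1)/(N+1)`), and `binomial_plus2` (`(n+1)/(N+2)`).
#'
#' @slot labels step vocabulary.
#' @slot itemCounts named numeric vector of occurrence counts `n(x)`.
#' @slot transCounts K x K matrix of transition counts `n(prev -> next)`.
#' @slot smoothing one of `"dirichlet_K"`, `"literal_plus1"`,
#'   `"binomial_plus2"`.
#' @slot logBase `"e"` (nats, default) or `"2"` (bits).
#' @export
setClass("ObserverState", representation(labels = "character",
                                         itemCounts = "numeric",
                                         transCounts = "matrix",
                                         smoothing = "character",
                                         logBase = "character"))

setValidity("ObserverState", function(object) {
  K <- length(object@labels)
  if (length(object@itemCounts) != K) return("itemCounts length must be K")
  if (!all(dim(object@transCounts) == c(K, K)))
    return("transCounts must be K x K")
  if (any(object@itemCounts < 0) || any(object@transCounts < 0))
    return("counts must be non-negative")
  if (any(object@itemCounts != round(object@itemCounts)))
    return("counts must be integers")
  if (any(rowSums(object@transCounts) > object@itemCounts + 1e-9))
    return("row sums of transCounts cannot exceed itemCounts")
  if (!object@smoothing %in% c("dirichlet_K", "literal_plus1",
                               "binomial_plus2"))
    return("unknown smoothing mode")
  if (!object@logBase %in% c("e", "2")) return("logBase must be 'e' or '2'")
  TRUE
})

#' Construct an empty ObserverState
#'
#' @param labels step vocabulary (character) or an [ActionChain-class].
#' @param smoothing smoothing mode; see [ObserverState-class].
#' @param logBase `"e"` or `"2"`.
#' @return an ObserverState with all counts zero.
#' @export
ObserverState <- function(labels,
                          smoothing = c("dirichlet_K", "literal_plus1",
                                        "binomial_plus2"),
                          logBase = c("e", "2")) {
  if (is(labels, "ActionChain")) labels <- chainLabels(labels)
  smoothing <- match.arg(smoothing)
  logBase <- match.arg(logBase)
  K <- length(labels)
  new("ObserverState", labels = labels,
      itemCounts = structure(numeric(K), names = labels),
      transCounts = matrix(0, K, K, dimnames = list(labels, labels)),
      smoothing = smoothing, logBase = logBase)
}

setMethod("show", "ObserverState", function(object) {
  cat(sprintf(
    "ObserverState over %d steps (%s smoothing, log base %s): %d items, %d transitions observed\n",
    length(object@labels), object@smoothing, object@logBase,
    sum(object@itemCounts), sum(object@transCounts)))
})

#' DesignMatrix: a first-level fMRI design
#'
#' Column-named design sampled at the repetition time, produced by
#' [buildDesign()]. Event columns are boxcars convolved with the
#' hemodynamic response function on a super-resolved time grid; each event
#' column carries a first-derivative twin.
#'
#' @slot X numeric matrix, volumes x regressors.
#' @slot tr repetition time, seconds.
#' @slot frameTimes acquisition times of the volume samples, seconds.
#' @slot settings list of construction settings (HRF parameters, microtime
#'   resolution, centering flags).
#' @export
setClass("DesignMatrix", representation(X = "matrix", tr = "numeric",
                                        frameTimes = "numeric",
                                        settings = "list"))

setValidity("DesignMatrix", function(object) {
  if (nrow(object@X) != length(object@frameTimes))
    return("frameTimes must match design rows")
  if (is.null(colnames(object@X))) return("design columns must be named")
  TRUE
})

#' @describeIn DesignMatrix the numeric design matrix
#' @param design a DesignMatrix.
#' @export
designMatrix <- function(design) design@X

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d volumes (TR %.3g s) x %d regressors\n",
              nrow(object@X), object@tr, ncol(object@X)))
  cat("  columns:", paste(colnames(object@X), collapse = ", "), "\n")
})

#' GroundTruth: known effect maps and noise model for BOLD simulation
#'
#' @slot dim integer grid dimensions (x, y, z).
#' @slot betaMain,betaH,betaI numeric effect maps (vectors of length
#'   prod(dim)) for the main action-onset effect, the conditional-entropy
#'   modulation and the conditional-surprisal modulation.
#' @slot entropyVoxels,surprisalVoxels,overlapVoxels linear voxel indices of
#'   the designated effect sets (overlap carries both effects).
#' @slot noiseSd marginal SD of the AR(1) noise component.
#' @slot ar1 lag-1 autoregressive coefficient.
#' @slot whiteSd SD of the additional white-noise component.
#' @slot driftAmplitude,driftPeriodS slow cosine drift amplitude and period
#'   (seconds).
#' @slot betweenSubjectSd SD of the per-participant random effect added to
#'   each designated effect map.
#' @slot voxelSizeMm isotropic voxel edge, mm.
#' @slot spatialFwhmMm spatial smoothing kernel FWHM, mm (applied when
#'   requested).
#' @export
setClass("GroundTruth", representation(dim = "integer", betaMain = "numeric",
  betaH = "numeric", betaI = "numeric", entropyVoxels = "integer",
  surprisalVoxels = "integer", overlapVoxels = "integer", noiseSd = "numeric",
  ar1 = "numeric", whiteSd = "numeric", driftAmplitude = "numeric",
  driftPeriodS = "numeric", betweenSubjectSd = "numeric",
  voxelSizeMm = "numeric", spatialFwhmMm = "numeric"))

setValidity("GroundTruth", function(object) {
  nv <- prod(object@dim)
  if (length(object@betaMain) != nv || length(object@betaH) != nv ||
      length(object@betaI) != nv)
    return("effect maps must have one value per voxel")
  if (length(intersect(object@entropyVoxels, object@surprisalVoxels)))
    return("entropy and surprisal voxel sets must be disjoint (overlap set is separate)")
  if (object@ar1 <= -1 || object@ar1 >= 1) return("ar1 must be in (-1, 1)")
  if (object@noiseSd < 0 || object@whiteSd < 0) return("noise SDs must be >= 0")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth on %s grid: %d entropy, %d surprisal, %d overlap voxels\n",
    paste(object@dim, collapse = "x"), length(object@entropyVoxels),
    length(object@surprisalVoxels), length(object@overlapVoxels)))
  cat(sprintf("  noise: AR(1) rho=%.2f sd=%.3g + white sd=%.3g; drift %.3g / %.4g s; between-subject sd %.3g\n",
              object@ar1, object@noiseSd, object@whiteSd,
              object@driftAmplitude, object@driftPeriodS,
              object@betweenSubjectSd))
})

#' FirstLevelResult: per-voxel GLM estimates
#'
#' @slot beta regressors x voxels matrix of estimates.
#' @slot dim spatial grid dimensions.
#' @slot sigma2 per-voxel residual variance (on the precolored scale).
#' @slot effDf effective degrees of freedom after precoloring
#'   (Satterthwaite-type correction).
#' @slot columns design column names.
#' @export
setClass("FirstLevelResult", representation(beta = "matrix", dim = "integer",
  sigma2 = "numeric", effDf = "numeric", columns = "character"))

#' @describeIn FirstLevelResult extract one beta/contrast map as a 3-D array
#' @param fit a FirstLevelResult.
#' @param column design column name (e.g. `"entropy"`, `"surprisal"`).
#' @export
betaMap <- function(fit, column) {
  if (!column %in% fit@columns) stop("unknown design column: ", column)
  array(fit@beta[column, ], dim = fit@dim)
}

setMethod("show", "FirstLevelResult", function(object) {
  cat(sprintf("FirstLevelResult: %d voxels, %d regressors, effective df %.1f\n",
              ncol(object@beta), nrow(object@beta), object@effDf))
})

#' GroupStatMap: second-level one-sample statistics
#'
#' @slot tMap,zMap 3-D arrays of t and z statistics (z from one-tailed
#'   probability matching).
#' @slot df degrees of freedom (n - 1).
#' @slot n number of contrast images.
#' @slot flagged logical array marking zero-variance voxels whose statistics
#'   were guarded.
#' @export
setClass("GroupStatMap", representation(tMap = "array", zMap = "array",
  df = "numeric", n = "integer", flagged = "array"))

setValidity("GroupStatMap", function(object) {
  if (any(!is.finite(object@zMap))) return("z map must be finite")
  TRUE
})

setMethod("show", "GroupStatMap", function(object) {
  cat(sprintf("GroupStatMap: n=%d (df=%g), z range [%.2f, %.2f]\n",
              object@n, object@df, min(object@zMap), max(object@zMap)))
})

#' ClusterThresholds: Monte Carlo cluster-level correction thresholds
#'
#' @slot initialZ voxel-level threshold forming clusters.
#' @slot alpha familywise significance level (one-tailed).
#' @slot sizeThreshold minimum cluster extent, voxels.
#' @slot massThreshold minimum cluster mass (sum of suprathreshold z).
#' @slot iterations number of null-field simulations used.
#' @slot smoothnessFwhmMm spatial smoothness of the simulated null fields.
#' @slot voxelSizeMm voxel edge used to express smoothness in voxels.
#' @slot connectivity 6, 18 or 26.
#' @slot rule `"and"` (cluster must exceed both thresholds, default) or
#'   `"or"`.
#' @export
setClass("ClusterThresholds", representation(initialZ = "numeric",
  alpha = "numeric", sizeThreshold = "numeric", massThreshold = "numeric",
  iterations = "integer", smoothnessFwhmMm = "numeric",
  voxelSizeMm = "numeric", connectivity = "integer", rule = "character"))

setValidity("ClusterThresholds", function(object) {
  if (object@sizeThreshold < 1) return("size threshold must be >= 1")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  if (!object@rule %in% c("and", "or")) return("rule must be 'and' or 'or'")
  TRUE
})

setMethod("show", "ClusterThresholds", function(object) {
  cat(sprintf(
    "ClusterThresholds: z > %.2f, size >= %g vox, mass >= %.1f (%s rule), alpha %.3g, %d iterations\n",
    object@initialZ, object@sizeThreshold, object@massThreshold,
    object@rule, object@alpha, object@iterations))
})

#' ROISpec: a small spherical region of interest
#'
#' The default reading of a "sphere of six adjacent voxels" is the center
#' voxel plus its six face-adjacent neighbors (7 voxels); a radius-based
#' sphere is available via `mode = "radius"`.
#'
#' @slot label ROI name.
#' @slot centerMm center coordinates in the dataset's mm space.
#' @slot mode `"faces"` (default) or `"radius"`.
#' @slot radiusMm sphere radius when `mode = "radius"`.
#' @export
setClass("ROISpec", representation(label = "character", centerMm = "numeric",
  mode = "character", radiusMm = "numeric"))

#' Construct an ROISpec
#' @param label ROI name.
#' @param centerMm numeric length-3 center, mm.
#' @param mode `"faces"` or `"radius"`.
#' @param radiusMm radius in mm for `mode = "radius"`.
#' @export
ROISpec <- function(label, centerMm, mode = c("faces", "radius"),
                    radiusMm = 3) {
  mode <- match.arg(mode)
  stopifnot(length(centerMm) == 3)
  new("ROISpec", label = label, centerMm = as.numeric(centerMm),
      mode = mode, radiusMm = radiusMm)
}

setMethod("show", "ROISpec", function(object) {
  cat(sprintf("ROISpec '%s' at (%g, %g, %g) mm [%s]\n", object@label,
              object@centerMm[1], object@centerMm[2], object@centerMm[3],
              object@mode))
})
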