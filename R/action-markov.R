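#' Default action grammar over the six construction-toy steps
#'
#' A reconstruction of the experiment's 6-state Markov chain. The published
#' description fixes only part of the matrix (board is always followed by
#' the cube; the cube is followed by a short screw with p = 0.5 and by a nut
#' or washer with p = 0.25 each; board-cube, short screw-long screw and
#' washer-nut are the highest-probability pairs; the cube is the only step
#' with a single possible predecessor). Among all matrices satisfying those
#' constraints with probabilities restricted to {0.25, 0.5, 0.75, 1.0},
#' out-/in-degrees of 1-3 and no immediate repetitions, this one was chosen
#' because its stationary distribution is exactly uniform, matching the
#' requirement that all action steps have a comparable base rate. Any
#' user-supplied matrix can be used in its place.
#'
#' @return an [ActionChain-class] over board, cube, long_screw, short_screw,
#'   nut, washer.
#' @examples
#' validateChain(defaultChain())
#' @export
defaultChain <- function() {
  lab <- c("board", "cube", "long_screw", "short_screw", "nut", "washer")
  P <- matrix(0, 6, 6, dimnames = list(lab, lab))
  P["board", "cube"] <- 1
  P["cube", c("short_screw", "nut", "washer")] <- c(0.50, 0.25, 0.25)
  P["long_screw", c("board", "short_screw", "washer")] <- c(0.25, 0.25, 0.50)
  P["short_screw", c("long_screw", "washer")] <- c(0.75, 0.25)
  P["nut", c("board", "long_screw")] <- c(0.75, 0.25)
  P["washer", c("short_screw", "nut")] <- c(0.25, 0.75)
  ActionChain(P, lab)
}

#' Validate an action chain against the stimulus-design invariants
#'
#' Structural defects (non-square, non-numeric, negative entries) raise an
#' error of class `seqBOLD_structural_error`; design-invariant violations
#' are reported, never raised. The checked invariants are: rows sum to 1
#' (1e-9 tolerance); in strict mode all nonzero probabilities belong to
#' {0.25, 0.5, 0.75, 1.0}; the diagonal is zero (no immediate repetitions);
#' every row has 1-3 nonzero entries; every column has 1-3 nonzero entries
#' with at most one column of in-degree 1 (the cube role).
#'
#' @param chain an [ActionChain-class] or a square numeric matrix.
#' @param strict check the admissible probability set (default TRUE).
#' @return a list of class `chainValidation` with elements `pass` (logical)
#'   and `violations` (character). The input is never modified.
#' @export
validateChain <- function(chain, strict = TRUE) {
  if (is(chain, "ActionChain")) P <- chain@P
  else {
    if (!is.matrix(P <- chain) || !is.numeric(P))
      stopStructural("chain must be an ActionChain or a numeric matrix")
    if (nrow(P) != ncol(P)) stopStructural("transition matrix must be square")
    if (any(!is.finite(P))) stopStructural("transition matrix must be finite")
    if (any(P < 0)) stopStructural("negative transition probabilities")
  }
  v <- character()
  if (any(abs(rowSums(P) - 1) > 1e-9))
    v <- c(v, "row-stochasticity: some row does not sum to 1")
  if (strict) {
    nz <- P[P > 0]
    if (any(vapply(nz, function(p) min(abs(p - c(0.25, 0.5, 0.75, 1))) > 1e-9,
                   logical(1))))
      v <- c(v, "admissible-set: nonzero probability outside {0.25, 0.5, 0.75, 1.0}")
  }
  if (any(diag(P) > 0))
    v <- c(v, "immediate repetition: nonzero diagonal entry")
  outdeg <- rowSums(P > 0)
  if (any(outdeg < 1 | outdeg > 3))
    v <- c(v, "out-degree: some row has fewer than 1 or more than 3 successors")
  indeg <- colSums(P > 0)
  if (any(indeg < 1 | indeg > 3))
    v <- c(v, "in-degree: some column has fewer than 1 or more than 3 predecessors")
  if (sum(indeg == 1) > 1)
    v <- c(v, "in-degree: more than one column with a single predecessor")
  structure(list(pass = length(v) == 0, violations = v),
            class = "chainValidation")
}

#' @export
print.chainValidation <- function(x, ...) {
  cat(if (x$pass) "chain PASSES all design invariants\n"
      else paste0("chain FAILS ", length(x$violations), " invariant(s):\n  ",
                  paste(x$violations, collapse = "\n  "), "\n"))
  invisible(x)
}

# Sample one trajectory of the chain; internal, assumes valid inputs.
sampleSteps <- function(P, labels, length, start) {
  steps <- integer(length)
  steps[1] <- match(start, labels)
  if (length > 1) for (t in 2:length) {
    row <- P[steps[t - 1], ]
    if (sum(row) <= 0)
      stop("absorbing state: '", labels[steps[t - 1]],
           "' has no successors but more steps were requested")
    steps[t] <- sample.int(length(labels), 1, prob = row)
  }
  labels[steps]
}

#' Sample a single action sequence from a chain
#'
#' @param chain an [ActionChain-class].
#' @param length number of steps (>= 1).
#' @param start starting step label.
#' @param seed optional integer seed; identical seeds give identical
#'   sequences.
#' @return character vector of step labels; every consecutive pair has
#'   nonzero probability under the chain.
#' @examples
#' sampleSequence(defaultChain(), 4, "board", seed = 1)
#' @export
sampleSequence <- function(chain, length, start, seed = NULL) {
  stopifnot(is(chain, "ActionChain"), length >= 1)
  if (!start %in% chain@labels) stop("unknown start step: ", start)
  withSeed(seed, sampleSteps(chain@P, chain@labels, length, start))
}

# Objective pieces for the balancing search: total shortfall/excess outside
# the admissible ranges.
rangePenalty <- function(counts, range) {
  if (is.null(range)) return(0)
  sum(pmax(0, range[1] - counts) + pmax(0, counts - range[2]))
}

# Transition-count matrix of one integer-coded sequence.
transCountsOf <- function(s, K) {
  m <- matrix(0L, K, K)
  if (length(s) > 1) for (t in 2:length(s)) m[s[t - 1], s[t]] <-
      m[s[t - 1], s[t]] + 1L
  m
}

# Chain sampling with a soft bias toward transitions that are currently
# under their designed share (deficit > 0) and away from over-used ones.
sampleBiasedSteps <- function(P, K, length, startWeights, deficitT) {
  s <- integer(length)
  s[1] <- sample.int(K, 1, prob = startWeights)
  if (length > 1) for (t in 2:length) {
    row <- P[s[t - 1], ]
    if (sum(row) <= 0)
      stop("absorbing state encountered during corpus sampling")
    w <- row * exp(pmin(pmax(0.8 * deficitT[s[t - 1], ], -3), 3))
    s[t] <- sample.int(K, 1, prob = w)
  }
  s
}

#' Generate a balanced corpus of action sequences
#'
#' Stochastic search with local repair: sequence lengths are fixed up front
#' to sum to `totalSteps`, sequences are sampled from the chain, and
#' individual sequences are then iteratively resampled (with start steps
#' biased toward under-represented sequence-initial steps and transitions
#' biased toward their designed share) until the per-step occurrence
#' counts, the first/last balancing constraints and - by default - the
#' realized transition proportions are all satisfied, or an iteration cap
#' is reached. The search restarts from a fresh sample when it stalls.
#' Deterministic given `seed`.
#'
#' Defaults reproduce the experiment's corpus: 74 sequences of 3-7 steps,
#' 362 steps in total (so each of the 6 steps occurs 58-63 times, mean
#' 60.33, and the mean length is 362/74 = 4.89), with each step opening and
#' closing 10-15 sequences. Transition balancing
#' (`balanceTransitions = TRUE`) additionally requires every realized
#' transition count to sit within `transTol` of its designed share
#' `P[i, j] * N_i` (N_i = non-final occurrences of step i), reflecting that
#' the stimulus set implements the pre-defined probabilities rather than
#' merely sampling them. Step durations are lognormal with mean
#' `durationMeanS` chosen so that the mean sequence duration is about 20 s.
#'
#' @param chain an [ActionChain-class].
#' @param nSequences number of sequences.
#' @param lengthRange integer pair, admissible sequence lengths.
#' @param countRange integer pair, admissible per-step total counts.
#' @param totalSteps total number of action steps in the corpus.
#' @param firstLastRange integer pair for sequence-initial/-final balancing,
#'   or NULL to disable.
#' @param seed integer seed.
#' @param nScaffolds number of starting scaffolds to assign (balanced).
#' @param balanceTransitions require realized transition counts to match
#'   the chain probabilities (default TRUE).
#' @param transTol total allowed absolute deviation of transition counts
#'   from their designed shares (default 0: exact implementation, which
#'   drives the non-final occurrence totals to multiples of the probability
#'   denominators; use 0.5 to permit integer rounding).
#' @param durationMeanS,durationSdS mean/SD of the lognormal step-duration
#'   model, seconds.
#' @param maxIter iteration cap of the repair search.
#' @return an [ActionCorpus-class] satisfying all constraints.
#' @examples
#' corp <- generateCorpus(defaultChain(), nSequences = 6,
#'                        lengthRange = c(3, 7), countRange = c(1, 10),
#'                        totalSteps = 30, firstLastRange = NULL,
#'                        balanceTransitions = FALSE, seed = 1)
#' stepCounts(corp)
#' @export
generateCorpus <- function(chain, nSequences = 74, lengthRange = c(3, 7),
                           countRange = c(58, 63), totalSteps = 362,
                           firstLastRange = c(10, 15), seed = NULL,
                           nScaffolds = 5, balanceTransitions = TRUE,
                           transTol = 0, durationMeanS = 4.115,
                           durationSdS = 1.34, maxIter = 1e5) {
  stopifnot(is(chain, "ActionChain"))
  K <- length(chain@labels)
  if (totalSteps < nSequences * lengthRange[1] ||
      totalSteps > nSequences * lengthRange[2])
    stopFeasibility("totalSteps incompatible with sequence lengths",
                    "n_sequences x length_range")
  if (totalSteps < K * countRange[1] || totalSteps > K * countRange[2])
    stopFeasibility("totalSteps incompatible with per-step count range",
                    "count_range")
  if (!is.null(firstLastRange) &&
      (nSequences < K * firstLastRange[1] ||
       nSequences > K * firstLastRange[2]))
    stopFeasibility("n_sequences incompatible with first/last balancing",
                    "firstlast_range")

  withSeed(seed, {
    labels <- chain@labels
    P <- chain@P
    # fix lengths summing to totalSteps
    len <- sample(seq(lengthRange[1], lengthRange[2]), nSequences,
                  replace = TRUE)
    while (sum(len) != totalSteps) {
      if (sum(len) > totalSteps) {
        i <- sample(which(len > lengthRange[1]), 1)
        len[i] <- len[i] - 1L
      } else {
        i <- sample(which(len < lengthRange[2]), 1)
        len[i] <- len[i] + 1L
      }
    }
    startWeights <- function(firsts) {
      if (is.null(firstLastRange)) return(rep(1, K))
      pmax(firstLastRange[2] - firsts, 0) + 0.25
    }
    freshCorpus <- function() {
      seqs <- vector("list", nSequences)
      firsts <- integer(K)
      zeroT <- matrix(0, K, K)
      for (i in seq_len(nSequences)) {
        seqs[[i]] <- sampleBiasedSteps(P, K, len[i], startWeights(firsts),
                                       zeroT)
        firsts[seqs[[i]][1]] <- firsts[seqs[[i]][1]] + 1L
      }
      seqs
    }
    state <- function(seqs) {
      counts <- tabulate(unlist(seqs), K)
      firsts <- tabulate(vapply(seqs, `[`, integer(1), 1), K)
      lasts <- tabulate(vapply(seqs, function(s) s[length(s)],
                               integer(1)), K)
      trans <- Reduce(`+`, lapply(seqs, transCountsOf, K = K))
      list(counts = counts, firsts = firsts, lasts = lasts, trans = trans)
    }
    penalties <- function(st) {
      hard <- rangePenalty(st$counts, countRange) +
        rangePenalty(st$firsts, firstLastRange) +
        rangePenalty(st$lasts, firstLastRange)
      tp <- if (balanceTransitions)
        sum(abs(st$trans - P * rowSums(st$trans))) else 0
      c(hard = hard, trans = tp)
    }
    solved <- function(p) p["hard"] == 0 &&
      (!balanceTransitions || p["trans"] <= transTol + 1e-9)
    seqs <- freshCorpus()
    st <- state(seqs)
    p <- penalties(st)
    obj <- p["hard"] + p["trans"]
    iter <- 0L
    stall <- 0L
    while (!solved(p) && iter < maxIter) {
      iter <- iter + 1L
      if (stall > 2000L) { # restart from a fresh sample on plateaus
        seqs <- freshCorpus()
        st <- state(seqs)
        p <- penalties(st)
        obj <- p["hard"] + p["trans"]
        stall <- 0L
        next
      }
      i <- sample.int(nSequences, 1)
      old <- seqs[[i]]
      firsts2 <- st$firsts
      firsts2[old[1]] <- firsts2[old[1]] - 1L
      trans2 <- st$trans - transCountsOf(old, K)
      deficitT <- if (balanceTransitions)
        P * (rowSums(trans2) + (len[i] - 1) / K) - trans2
      else matrix(0, K, K)
      cand <- seqs
      cand[[i]] <- sampleBiasedSteps(P, K, len[i], startWeights(firsts2),
                                     deficitT)
      stC <- state(cand)
      pC <- penalties(stC)
      objC <- pC["hard"] + pC["trans"]
      if (objC <= obj) {
        stall <- if (objC < obj) 0L else stall + 1L
        seqs <- cand
        st <- stC
        p <- pC
        obj <- objC
      } else stall <- stall + 1L
    }
    if (!solved(p)) {
      binding <- if (balanceTransitions && p["trans"] > transTol)
        "transition proportions"
      else c("per-step counts", "first counts", "last counts")[
        which.max(c(rangePenalty(st$counts, countRange),
                    rangePenalty(st$firsts, firstLastRange),
                    rangePenalty(st$lasts, firstLastRange)))]
      stopFeasibility("balancing search exceeded iteration cap", binding)
    }
    seqs <- lapply(seqs, function(s) labels[s])
    scaffold <- sample(rep_len(seq_len(nScaffolds), nSequences))
    sdlog <- sqrt(log(1 + durationSdS^2 / durationMeanS^2))
    meanlog <- log(durationMeanS) - sdlog^2 / 2
    ev <- do.call(rbind, lapply(seq_len(nSequences), function(i) {
      dur <- rlnorm(len[i], meanlog, sdlog)
      data.frame(sequence_id = i, scaffold_id = scaffold[i],
                 position = seq_len(len[i]), step = seqs[[i]],
                 onset_s = cumsum(c(0, dur[-len[i]])), duration_s = dur)
    }))
    new("ActionCorpus", events = ev, chain = chain)
  })
}

# TRUE when a's step list occurs as a contiguous window of b's.
isContiguousSubsequence <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na > nb) return(FALSE)
  for (s in 0:(nb - na))
    if (all(a == b[s + seq_len(na)])) return(TRUE)
  FALSE
}

# Independent descriptor table used for the run-length constraints.
orderAttributes <- function(corpus) {
  seqs <- corpusSequences(corpus)
  ev <- corpusEvents(corpus)
  sc <- ev$scaffold_id[!duplicated(ev$sequence_id)]
  data.frame(scaffold = sc,
             length = lengths(seqs),
             first = vapply(seqs, `[`, character(1), 1),
             last = vapply(seqs, function(s) s[length(s)], character(1)))
}

checkOrderConstraints <- function(order, attr, seqs) {
  n <- length(order)
  for (col in names(attr)) {
    r <- rle(attr[[col]][order])
    if (any(r$lengths > 2)) return(FALSE)
  }
  if (n > 1) for (i in seq_len(n - 1)) {
    a <- seqs[[order[i]]]; b <- seqs[[order[i + 1]]]
    if (isContiguousSubsequence(a, b) || isContiguousSubsequence(b, a))
      return(FALSE)
  }
  TRUE
}

#' Randomize the presentation order of a corpus
#'
#' Produces a permutation of sequence indices subject to the experiment's
#' randomization constraints: no run of more than two consecutive sequences
#' sharing the scaffold, the length, the first step, or the last step, and
#' no adjacent pair in which one sequence's step list is a contiguous
#' subsequence of the other's. Implemented as shuffle-and-repair with
#' restarts under an iteration cap; deterministic given `seed`.
#'
#' @param corpus an [ActionCorpus-class].
#' @param seed integer seed.
#' @param maxIter iteration cap.
#' @return integer permutation of `1:nSequences(corpus)`.
#' @export
randomizeOrder <- function(corpus, seed = NULL, maxIter = 1e5) {
  n <- nSequences(corpus)
  if (n == 0) stop("corpus is empty")
  attr <- orderAttributes(corpus)
  seqs <- corpusSequences(corpus)
  violationAt <- function(order) {
    # first position taking part in any violated constraint, or 0
    for (i in seq_len(n)) {
      if (i >= 3) {
        for (col in names(attr)) {
          v <- attr[[col]][order[(i - 2):i]]
          if (v[1] == v[2] && v[2] == v[3]) return(i)
        }
      }
      if (i >= 2) {
        a <- seqs[[order[i - 1]]]; b <- seqs[[order[i]]]
        if (isContiguousSubsequence(a, b) || isContiguousSubsequence(b, a))
          return(i)
      }
    }
    0L
  }
  withSeed(seed, {
    iter <- 0
    repeat {
      order <- sample.int(n)
      repeat {
        iter <- iter + 1
        if (iter > maxIter)
          stop("randomization failed after ", maxIter,
               " iterations; consider relaxing the order constraints")
        bad <- violationAt(order)
        if (bad == 0L) return(order)
        j <- sample.int(n, 1)
        order[c(bad, j)] <- order[c(j, bad)]
        if (iter %% 500 == 0) break # restart from a fresh shuffle
      }
    }
  })
}

#' Enumerate the video inventory of a corpus
#'
#' Each sequence is filmed once with each starting scaffold, so the
#' inventory holds one entry per (sequence, scaffold) pair.
#'
#' @param corpus an [ActionCorpus-class].
#' @param nScaffolds number of starting scaffolds (>= 1).
#' @return data.frame with columns `video_id`, `sequence_id`,
#'   `scaffold_id`; `nSequences x nScaffolds` rows, all pairs unique.
#' @export
buildVideoSet <- function(corpus, nScaffolds = 5) {
  stopifnot(nScaffolds >= 1)
  ids <- unique(corpusEvents(corpus)$sequence_id)
  inv <- expand.grid(sequence_id = ids, scaffold_id = seq_len(nScaffolds),
                     KEEP.OUT.ATTRS = FALSE)
  inv <- inv[order(inv$sequence_id, inv$scaffold_id), ]
  inv$video_id <- seq_len(nrow(inv))
  rownames(inv) <- NULL
  inv[, c("video_id", "sequence_id", "scaffold_id")]
}
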