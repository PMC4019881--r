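# Shared fixtures, built in code. The three-session study assembly is used
# by several tests; it is cached per session to keep the suite fast.

.fixtureCache <- new.env(parent = emptyenv())

# Full-scale study assembly: balanced 74-sequence corpus, two training
# passes with observer updating, frozen-at-scan annotation of the third
# session, merged events and the first-level design.
studyAssembly <- function(seed = 1) {
  key <- paste0("study", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  chain <- defaultChain()
  corpus <- generateCorpus(chain, seed = childSeed(seed, "corpus"))
  sched <- lapply(1:3, function(s)
    buildSessionSchedule(corpus,
      randomizeOrder(corpus, seed = childSeed(seed, paste0("order", s))),
      session = paste0("s", s),
      seed = childSeed(seed, paste0("questions", s))))
  obs <- ObserverState(chain)
  trained <- annotateEvents(rbind(sched[[1]]$events, sched[[2]]$events),
                            obs, update = TRUE)
  scan <- annotateEvents(sched[[3]]$events, trained$state, update = FALSE)
  fmri <- mergeEvents(scan$annotations)
  design <- buildDesign(fmri, epochs = sched[[3]]$epochs,
                        questions = sched[[3]]$questions,
                        nVolumes = sched[[3]]$nVolumes)
  out <- list(chain = chain, corpus = corpus, sched = sched,
              trainedState = trained$state, fmri = fmri, design = design)
  .fixtureCache[[key]] <- out
  out
}

# Small 3-state chain for hand-checkable observer tests.
toyChain <- function() {
  P <- matrix(c(0, 1, 0,
                0.5, 0, 0.5,
                1, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ActionChain(P)
}

# Independent brute-force checker for presentation-order constraints:
# plain loops, no shared code with randomizeOrder().
bruteForceOrderOk <- function(order, corpus) {
  seqs <- corpusSequences(corpus)
  ev <- corpusEvents(corpus)
  scaff <- ev$scaffold_id[!duplicated(ev$sequence_id)]
  feats <- list(
    scaffold = scaff[order],
    len = vapply(seqs[order], length, integer(1)),
    first = vapply(seqs[order], function(s) s[1], character(1)),
    last = vapply(seqs[order], function(s) s[length(s)], character(1)))
  for (f in feats) {
    run <- 1
    for (i in seq_along(f)[-1]) {
      run <- if (f[i] == f[i - 1]) run + 1 else 1
      if (run > 2) return(FALSE)
    }
  }
  contig <- function(a, b) {
    if (length(a) > length(b)) return(FALSE)
    for (s in 0:(length(b) - length(a)))
      if (identical(a, b[s + seq_along(a)])) return(TRUE)
    FALSE
  }
  for (i in seq_along(order)[-1]) {
    a <- seqs[[order[i - 1]]]
    b <- seqs[[order[i]]]
    if (contig(a, b) || contig(b, a)) return(FALSE)
  }
  TRUE
}

# Independent direct-summation convolution at microtime resolution.
directConvolution <- function(onsets, durations, amplitudes, kernelFun,
                              frameTimes, dt = 0.1, tmax) {
  tg <- seq(0, tmax, by = dt)
  x <- numeric(length(tg))
  for (i in seq_along(onsets)) {
    idx <- which(tg >= onsets[i] - 1e-9 &
                   tg <= onsets[i] + durations[i] + 1e-9)
    # boxcar bins as in the package: floor/ceiling convention
    a <- floor(onsets[i] / dt) + 1
    b <- min(length(tg), ceiling((onsets[i] + durations[i]) / dt))
    x[a:b] <- x[a:b] + amplitudes[i]
  }
  k <- kernelFun(seq(0, 32, by = dt))
  y <- numeric(length(tg))
  for (t in seq_along(tg)) {
    jmax <- min(t, length(k))
    y[t] <- sum(x[t - seq_len(jmax) + 1] * k[seq_len(jmax)]) * dt
  }
  y[pmin(length(tg), round(frameTimes / dt) + 1)]
}

# Smoothed unit-variance Gaussian null field, matching the Monte Carlo
# generator's construction (used to probe familywise error independently).
nullField <- function(dim, fwhmMm, voxelSizeMm = 3) {
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm
  z <- array(rnorm(prod(dim)), dim)
  if (sigmaVox > 0) {
    z <- seqBOLD:::smooth3d(z, sigmaVox)
    z <- z / sqrt(seqBOLD:::smoothVarFactor(sigmaVox))
  }
  z
}
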