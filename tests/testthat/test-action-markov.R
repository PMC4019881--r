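test_that("the default chain satisfies every design invariant", {
  chain <- defaultChain()
  rep <- validateChain(chain, strict = TRUE)
  expect_true(rep$pass)
  expect_length(rep$violations, 0)
  # the published cube row
  expect_equal(unname(transitionMatrix(chain)["cube", ]),
               c(0, 0, 0, 0.50, 0.25, 0.25))
  expect_equal(unname(transitionMatrix(chain)["board", "cube"]), 1.0)
  # uniform stationary distribution (comparable base rates)
  P <- transitionMatrix(chain)
  pi0 <- rep(1 / 6, 6)
  expect_equal(unname(drop(pi0 %*% P)), pi0, tolerance = 1e-12)
})

test_that("validateChain reports invariant violations without mutating", {
  chain <- defaultChain()
  P <- transitionMatrix(chain)
  Pbad <- P
  Pbad["board", "cube"] <- 0.9 # row sums to 0.9
  rep <- validateChain(ActionChain(Pbad), strict = FALSE)
  expect_false(rep$pass)
  expect_true(any(grepl("row-stochasticity", rep$violations)))
  Pdiag <- P
  Pdiag["cube", "cube"] <- 0.25
  Pdiag["cube", "short_screw"] <- 0.25
  rep2 <- validateChain(ActionChain(Pdiag))
  expect_false(rep2$pass)
  expect_true(any(grepl("immediate repetition", rep2$violations)))
  # off-admissible-set probability flagged only in strict mode
  Podd <- P
  Podd["cube", c("short_screw", "nut", "washer")] <- c(0.6, 0.2, 0.2)
  expect_false(validateChain(ActionChain(Podd), strict = TRUE)$pass)
  expect_true(validateChain(ActionChain(Podd), strict = FALSE)$pass)
  # original object untouched
  expect_identical(transitionMatrix(chain), P)
})

test_that("structural defects raise a distinct error class", {
  expect_error(validateChain(matrix(1, 2, 3)),
               class = "seqBOLD_structural_error")
  expect_error(ActionChain(matrix(-0.5, 2, 2)),
               class = "seqBOLD_structural_error")
})

test_that("sampleSequence follows the chain and is seed-deterministic", {
  chain <- defaultChain()
  # deterministic transition
  expect_equal(sampleSequence(chain, 2, "board", seed = 5),
               c("board", "cube"))
  expect_equal(sampleSequence(chain, 1, "washer"), "washer")
  s1 <- sampleSequence(chain, 7, "cube", seed = 11)
  s2 <- sampleSequence(chain, 7, "cube", seed = 11)
  expect_identical(s1, s2)
  # every consecutive pair has positive probability
  P <- transitionMatrix(chain)
  long <- sampleSequence(chain, 500, "nut", seed = 3)
  expect_true(all(P[cbind(long[-500], long[-1])] > 0))
  # empirical successor frequencies of the cube row within binomial error
  set.seed(21)
  draws <- replicate(1000, sample(chainLabels(chain), 1,
                                  prob = P["cube", ]))
  freq <- table(factor(draws, chainLabels(chain))) / 1000
  se3 <- 3 * sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(freq[["short_screw"]] - 0.50), se3)
  expect_lt(abs(freq[["nut"]] - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
  expect_lt(abs(freq[["washer"]] - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
})

test_that("an absorbing start state errors for multi-step requests", {
  P <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  ch <- ActionChain(P)
  expect_error(sampleSequence(ch, 3, "b", seed = 1), "absorbing")
  expect_equal(sampleSequence(ch, 1, "b"), "b")
})

test_that("generateCorpus satisfies all corpus invariants", {
  study <- studyAssembly(1)
  corp <- study$corpus
  expect_equal(nSequences(corp), 74)
  expect_equal(nrow(corpusEvents(corp)), 362)
  counts <- as.integer(stepCounts(corp))
  expect_true(all(counts >= 58 & counts <= 63))
  expect_equal(sum(counts), 362)
  expect_true(all(firstCounts(corp) >= 10 & firstCounts(corp) <= 15))
  expect_true(all(lastCounts(corp) >= 10 & lastCounts(corp) <= 15))
  expect_true(all(sequenceLengths(corp) >= 3 & sequenceLengths(corp) <= 7))
  expect_equal(mean(sequenceLengths(corp)), 362 / 74)
  # every realized transition has nonzero chain probability, no immediate
  # repetitions, and realized counts implement the probabilities exactly
  P <- transitionMatrix(study$chain)
  K <- length(chainLabels(study$chain))
  tm <- matrix(0, K, K, dimnames = dimnames(P))
  for (s in corpusSequences(corp)) {
    expect_false(any(s[-1] == s[-length(s)]))
    if (length(s) > 1) for (t in 2:length(s))
      tm[s[t - 1], s[t]] <- tm[s[t - 1], s[t]] + 1
  }
  expect_true(all(P[tm > 0] > 0))
  expect_equal(sum(abs(tm - P * rowSums(tm))), 0)
  # onsets are cumulative within sequence
  ev <- corpusEvents(corp)
  one <- ev[ev$sequence_id == ev$sequence_id[1], ]
  expect_equal(one$onset_s[-1],
               cumsum(one$duration_s)[-nrow(one)], tolerance = 1e-9)
  # determinism
  corp2 <- generateCorpus(study$chain, seed = childSeed(1, "corpus"))
  expect_identical(corpusEvents(corp2), corpusEvents(corp))
})

test_that("generateCorpus handles degenerate and infeasible constraint sets", {
  chain <- defaultChain()
  tiny <- generateCorpus(chain, nSequences = 1, lengthRange = c(3, 3),
                         countRange = c(0, 3), totalSteps = 3,
                         firstLastRange = NULL,
                         balanceTransitions = FALSE, seed = 2)
  expect_equal(nSequences(tiny), 1)
  expect_equal(nrow(corpusEvents(tiny)), 3)
  expect_error(
    generateCorpus(chain, nSequences = 2, lengthRange = c(3, 7),
                   countRange = c(0, 100), totalSteps = 100,
                   firstLastRange = NULL, seed = 1),
    class = "seqBOLD_feasibility_error")
})

test_that("randomizeOrder obeys the run-length and subsequence constraints", {
  study <- studyAssembly(1)
  ord <- randomizeOrder(study$corpus, seed = 9)
  expect_setequal(ord, seq_len(74))
  expect_true(bruteForceOrderOk(ord, study$corpus))
  ord2 <- randomizeOrder(study$corpus, seed = 9)
  expect_identical(ord, ord2)
})

test_that("subsequence-related sequences are never adjacent", {
  # toy corpus: A = (board, cube, short_screw) is a contiguous
  # subsequence of B = (board, cube, short_screw, long_screw); C unrelated
  lab <- chainLabels(defaultChain())
  ev <- rbind(
    data.frame(sequence_id = 1, scaffold_id = 1, position = 1:3,
               step = c("board", "cube", "short_screw"),
               onset_s = 0:2, duration_s = 1),
    data.frame(sequence_id = 2, scaffold_id = 2, position = 1:4,
               step = c("board", "cube", "short_screw", "long_screw"),
               onset_s = 0:3, duration_s = 1),
    data.frame(sequence_id = 3, scaffold_id = 3, position = 1:3,
               step = c("washer", "nut", "board"),
               onset_s = 0:2, duration_s = 1))
  corp <- new("ActionCorpus", events = ev, chain = defaultChain())
  # exhaustive truth: the only valid orders separate 1 and 2
  perms <- list(c(1L, 3L, 2L), c(2L, 3L, 1L))
  for (seed in 1:20) {
    ord <- randomizeOrder(corp, seed = seed)
    expect_true(bruteForceOrderOk(ord, corp))
    expect_true(any(vapply(perms, function(p) all(p == ord), logical(1))))
  }
})

test_that("buildVideoSet enumerates all unique sequence-scaffold pairs", {
  study <- studyAssembly(1)
  inv <- buildVideoSet(study$corpus, nScaffolds = 5)
  expect_equal(nrow(inv), 370)
  expect_equal(anyDuplicated(inv[, c("sequence_id", "scaffold_id")]), 0)
  small <- generateCorpus(defaultChain(), nSequences = 3,
                          lengthRange = c(3, 4), countRange = c(0, 12),
                          totalSteps = 10, firstLastRange = NULL,
                          balanceTransitions = FALSE, seed = 4)
  expect_equal(nrow(buildVideoSet(small, 2)), 6)
  expect_equal(nrow(buildVideoSet(small, 1)), 3)
})

test_that("unbalanced sampling converges to the chain probabilities", {
  chain <- defaultChain()
  steps <- sampleSequence(chain, 12000, "board", seed = 6)
  P <- transitionMatrix(chain)
  K <- 6
  tm <- matrix(0, K, K, dimnames = dimnames(P))
  for (t in 2:length(steps)) tm[steps[t - 1], steps[t]] <-
    tm[steps[t - 1], steps[t]] + 1
  freq <- tm / rowSums(tm)
  for (i in 1:K) for (j in 1:K) if (P[i, j] > 0) {
    se <- sqrt(P[i, j] * (1 - P[i, j]) / sum(tm[i, ]))
    expect_lt(abs(freq[i, j] - P[i, j]), 3 * se + 1e-12)
  }
})

test_that("chain and corpus round-trip through their file formats", {
  chain <- defaultChain()
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  writeChain(chain, csv)
  writeChain(chain, json)
  expect_equal(transitionMatrix(readChain(csv)), transitionMatrix(chain))
  expect_equal(transitionMatrix(readChain(json)), transitionMatrix(chain))
  small <- generateCorpus(chain, nSequences = 4, lengthRange = c(3, 5),
                          countRange = c(0, 10), totalSteps = 16,
                          firstLastRange = NULL,
                          balanceTransitions = FALSE, seed = 8)
  tsv <- tempfile(fileext = ".tsv")
  writeCorpusTsv(small, tsv)
  back <- readCorpusTsv(tsv, chain)
  expect_equal(corpusEvents(back)$step, corpusEvents(small)$step)
  expect_equal(corpusEvents(back)$onset_s, corpusEvents(small)$onset_s,
               tolerance = 1e-9)
})
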