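test_that("condProb matches hand-evaluated smoothed estimators", {
  st <- ObserverState(defaultChain())
  # uniform prior on the empty state
  expect_equal(unname(condProb(st, "board", "cube")), 1 / 6)
  expect_equal(sum(condProb(st, "cube")), 1)
  # n(board->cube) = 10 of n(board) = 10
  st@itemCounts["board"] <- 10
  st@transCounts["board", "cube"] <- 10
  expect_equal(unname(condProb(st, "board", "cube")), 11 / 16)
  stLit <- st; stLit@smoothing <- "literal_plus1"
  expect_equal(unname(condProb(stLit, "board", "cube")), 1) # 11/11
  stBin <- st; stBin@smoothing <- "binomial_plus2"
  expect_equal(unname(condProb(stBin, "board", "cube")), 11 / 12)
  expect_error(condProb(st, "board", "widget"), "unknown")
})

test_that("conditional probabilities are proper and monotone in evidence", {
  st <- ObserverState(defaultChain())
  ann <- annotateEvents(
    data.frame(step = sampleSequence(defaultChain(), 300, "board", seed = 2),
               sequence_id = 1), st)
  st <- ann$state
  for (prev in chainLabels(defaultChain()))
    expect_equal(sum(condProb(st, prev)), 1, tolerance = 1e-12)
  # one more observation of (prev -> next) never decreases its estimate
  for (prev in c("cube", "washer")) for (nxt in c("nut", "short_screw")) {
    before <- condProb(st, prev, nxt)
    st2 <- st
    st2@itemCounts[prev] <- st2@itemCounts[prev] + 1
    st2@itemCounts[nxt] <- st2@itemCounts[nxt] + 1
    st2@transCounts[prev, nxt] <- st2@transCounts[prev, nxt] + 1
    expect_gte(condProb(st2, prev, nxt), before)
  }
})

test_that("surprisal is the negative log with a guarded domain", {
  expect_equal(surprisal(1), 0)
  expect_equal(surprisal(0.25), 1.3863, tolerance = 1e-4)
  expect_equal(surprisal(0.5), 0.6931, tolerance = 1e-4)
  expect_equal(surprisal(0.25, logBase = "2"), 2)
  expect_error(surprisal(0), "\\(0, 1\\]")
  expect_error(surprisal(-0.1), "\\(0, 1\\]")
})

test_that("specific conditional entropy matches hand evaluation", {
  # successor distribution (0.5, 0.25, 0.25) weighted by p(prev) = 1/6
  expect_equal(condEntropy(c(0.5, 0.25, 0.25), pPrior = 1 / 6),
               (0.5 * log(2) + 0.5 * log(4)) / 6, tolerance = 1e-12)
  expect_equal(condEntropy(c(0.5, 0.25, 0.25), pPrior = 1 / 6), 0.1733,
               tolerance = 1e-4)
  # degenerate successor row has zero entropy for any context probability
  expect_equal(condEntropy(c(1, 0, 0), pPrior = 0.42), 0)
  expect_equal(condEntropy(c(0.5, 0.5), pPrior = 1), log(2))
  # state-based version: empty state over K=6 gives uniform successors
  st <- ObserverState(defaultChain())
  expect_equal(specificCondEntropy(st, "cube"), (1 / 6) * log(6),
               tolerance = 1e-12)
})

test_that("annotateEvents replays a toy corpus exactly as hand-tracked", {
  st <- ObserverState(toyChain())
  ev <- data.frame(
    step = c("A", "B", "A", "B", "A", "B"),
    sequence_id = c(1, 1, 1, 2, 2, 2))
  ann <- annotateEvents(ev, st)
  a <- ann$annotations
  expect_equal(a$annotate_ok, c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  # hand-tracked counts (K = 3, add-one smoothing):
  expect_equal(a$p_cond[2], 1 / 3)           # no transitions seen yet
  expect_equal(a$surprisal[2], log(3))
  expect_equal(a$p_prior[2], 2 / 4)          # n(A)=1 of 1 item
  expect_equal(a$entropy[2], 0.5 * log(3))
  expect_equal(a$p_cond[3], 1 / 3)           # B row still empty
  expect_equal(a$p_prior[3], 2 / 5)
  expect_equal(a$entropy[3], 0.4 * log(3))
  expect_equal(a$p_cond[5], 2 / 4)           # B->A seen once of N(B)=1
  expect_equal(a$surprisal[5], log(2))
  expect_equal(a$p_prior[5], 3 / 7)
  expect_equal(a$entropy[5],
               (3 / 7) * (0.5 * log(2) + 0.5 * log(4)), tolerance = 1e-12)
  expect_equal(a$p_cond[6], 2 / 4)           # A->B seen once of N(A)=1
  expect_equal(a$p_prior[6], 4 / 8)
  # final state counts
  expect_equal(unname(ann$state@itemCounts), c(3, 3, 0))
  expect_equal(ann$state@transCounts["A", "B"], 2)
  expect_equal(ann$state@transCounts["B", "A"], 2)
})

test_that("annotateEvents handles the degenerate and frozen cases", {
  st <- ObserverState(toyChain())
  empty <- annotateEvents(data.frame(step = character(0),
                                     sequence_id = character(0)), st)
  expect_equal(nrow(empty$annotations), 0)
  expect_error(
    annotateEvents(data.frame(step = "Z", sequence_id = 1), st),
    "unknown")
  # with update off the state is untouched and repeated events annotate
  # identically
  ev <- data.frame(step = c("A", "B", "A", "B"), sequence_id = c(1, 1, 2, 2))
  warm <- annotateEvents(ev, st, update = TRUE)$state
  frozen1 <- annotateEvents(ev, warm, update = FALSE)
  frozen2 <- annotateEvents(ev, warm, update = FALSE)
  expect_identical(frozen1$annotations, frozen2$annotations)
  expect_identical(frozen1$state@itemCounts, warm@itemCounts)
  expect_equal(frozen1$annotations$p_cond[2], frozen1$annotations$p_cond[4])
})

test_that("the estimated matrix converges to the generating chain", {
  chain <- defaultChain()
  ann <- annotateEvents(
    data.frame(step = sampleSequence(chain, 6000, "board", seed = 1),
               sequence_id = 1), ObserverState(chain))
  err <- max(abs(estimatedTransitionMatrix(ann$state) -
                   transitionMatrix(chain)))
  expect_lt(err, 0.05)
})

test_that("observer state round-trips through its JSON dump", {
  chain <- defaultChain()
  ann <- annotateEvents(
    data.frame(step = sampleSequence(chain, 200, "cube", seed = 4),
               sequence_id = 1), ObserverState(chain))
  path <- tempfile(fileext = ".json")
  writeObserverState(ann$state, path)
  back <- readObserverState(path)
  expect_equal(back@itemCounts, ann$state@itemCounts)
  expect_equal(back@transCounts, ann$state@transCounts)
  expect_identical(back@smoothing, ann$state@smoothing)
})
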