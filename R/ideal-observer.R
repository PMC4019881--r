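obsLog <- function(state) if (state@logBase == "2") log2 else log

checkLabel <- function(state, x, what) {
  if (!all(x %in% state@labels))
    stop("unknown ", what, " label: ", paste(setdiff(x, state@labels),
                                             collapse = ", "))
}

#' Estimated conditional transition probability
#'
#' Posterior-mean estimate of `p(next | prev)` from the observer's running
#' transition counts under an add-one prior. With `dirichlet_K` smoothing
#' (default) this is `(n(prev -> next) + 1) / (n(prev) + K)`, the proper
#' Dirichlet(1) posterior mean, so the probabilities over all successors sum
#' to 1 and are never 0. The `literal_plus1` (`(n+1)/(N+1)`) and
#' `binomial_plus2` (`(n+1)/(N+2)`) denominators are available as
#' alternative published smoothing conventions; they need not form a proper
#' distribution over successors.
#'
#' @param state an [ObserverState-class].
#' @param prev predecessor step label.
#' @param next_ successor step label(s); defaults to the full vocabulary.
#' @return named numeric vector of probabilities in (0, 1].
#' @examples
#' st <- ObserverState(defaultChain())
#' condProb(st, "board", "cube") # 1/6 under the uniform prior
#' @export
condProb <- function(state, prev, next_ = state@labels) {
  checkLabel(state, prev, "predecessor")
  checkLabel(state, next_, "successor")
  n <- state@transCounts[prev, next_]
  N <- sum(state@transCounts[prev, ])
  K <- length(state@labels)
  denom <- switch(state@smoothing,
                  dirichlet_K = N + K,
                  literal_plus1 = N + 1,
                  binomial_plus2 = N + 2)
  (n + 1) / denom
}

#' Estimated marginal (base-rate) probability of a step
#'
#' Add-one smoothed occurrence frequency, `(n(x) + 1) / (sum_i n(x_i) + K)`.
#'
#' @inheritParams condProb
#' @param x step label(s).
#' @export
priorProb <- function(state, x) {
  checkLabel(state, x, "step")
  (state@itemCounts[x] + 1) /
    (sum(state@itemCounts) + length(state@labels))
}

#' Surprisal of a probability
#'
#' `-log(p)`: zero iff the event was certain, increasing as the event was
#' less probable.
#'
#' @param p probability in (0, 1].
#' @param logBase `"e"` (nats, default) or `"2"` (bits).
#' @return non-negative surprisal.
#' @examples
#' surprisal(0.25) # -ln 0.25 = 1.3863 nats
#' @export
surprisal <- function(p, logBase = c("e", "2")) {
  logBase <- match.arg(logBase)
  if (any(p <= 0) || any(p > 1))
    stop("surprisal is defined for probabilities in (0, 1]")
  if (logBase == "2") -log2(p) else -log(p)
}

#' Shannon entropy of a successor distribution, weighted by the context
#' probability
#'
#' Computes `pPrior * (-sum_i p_i log p_i)`: the entropy of the successor
#' distribution of one predecessor, standardized on the probability of that
#' predecessor. Zero-probability successors contribute nothing.
#'
#' @param p numeric vector of successor probabilities.
#' @param pPrior probability of the predecessor context (default 1, giving
#'   the plain Shannon entropy).
#' @param logBase `"e"` or `"2"`.
#' @return non-negative entropy; zero when the distribution is degenerate.
#' @examples
#' condEntropy(c(0.5, 0.25, 0.25), pPrior = 1 / 6) # 0.1733 nats
#' @export
condEntropy <- function(p, pPrior = 1, logBase = c("e", "2")) {
  logBase <- match.arg(logBase)
  if (any(p < 0)) stop("probabilities must be non-negative")
  lg <- if (logBase == "2") log2 else log
  p <- p[p > 0]
  pPrior * (-sum(p * lg(p)))
}

#' Specific conditional entropy under the observer's current estimates
#'
#' Entropy of the estimated successor distribution of `prev`, weighted by
#' the estimated marginal probability of `prev`. Successor probabilities
#' are the smoothed estimates from [condProb()] (renormalized for the
#' non-Dirichlet smoothing modes, which do not natively sum to 1).
#'
#' @inheritParams condProb
#' @return non-negative entropy in the configured log base.
#' @export
specificCondEntropy <- function(state, prev) {
  checkLabel(state, prev, "predecessor")
  p <- condProb(state, prev)
  p <- p / sum(p)
  unname(condEntropy(p, pPrior = priorProb(state, prev),
                     logBase = state@logBase))
}

#' Annotate an ordered event stream with ideal-observer quantities
#'
#' Replays the events in presentation order. Each event is annotated with
#' the observer state *before* its own update: the estimated conditional
#' probability given its predecessor, the conditional surprisal, the
#' specific conditional entropy of the predecessor context, and the
#' predecessor's marginal probability. Sequence-initial events (predecessor
#' `NA`) have undefined conditional quantities; they are flagged
#' `annotate_ok = FALSE` and carry `NA` annotations. With `update = TRUE`
#' (default) the observer counts are incremented after each annotation, so
#' learning continues through the stream; with `update = FALSE` the state
#' is frozen.
#'
#' @param events data.frame in presentation order with columns `step` and
#'   either `predecessor` (step label or NA) or `sequence_id` (predecessors
#'   derived within sequences).
#' @param state an [ObserverState-class]; typically empty, or carried over
#'   from training sessions.
#' @param update logical; increment counts while annotating.
#' @return list with `annotations` (the input plus columns `predecessor`,
#'   `p_cond`, `surprisal`, `entropy`, `p_prior`, `annotate_ok`) and
#'   `state` (the final ObserverState).
#' @export
annotateEvents <- function(events, state, update = TRUE) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    ann <- cbind(events, data.frame(predecessor = character(0),
      p_cond = numeric(0), surprisal = numeric(0), entropy = numeric(0),
      p_prior = numeric(0), annotate_ok = logical(0)))
    return(list(annotations = ann, state = state))
  }
  checkLabel(state, events$step, "step")
  if (is.null(events$predecessor)) {
    if (is.null(events$sequence_id))
      stop("events need a 'predecessor' or 'sequence_id' column")
    pred <- c(NA, events$step[-nrow(events)])
    pred[!duplicated(events$sequence_id)] <- NA
  } else {
    pred <- as.character(events$predecessor)
    checkLabel(state, pred[!is.na(pred)], "predecessor")
  }
  n <- nrow(events)
  lg <- obsLog(state)
  labels <- state@labels
  K <- length(labels)
  item <- state@itemCounts
  trans <- state@transCounts
  p_cond <- p_prior <- surp <- entr <- rep(NA_real_, n)
  ok <- !is.na(pred)
  stepIdx <- match(events$step, labels)
  predIdx <- match(pred, labels)
  for (i in seq_len(n)) {
    if (ok[i]) {
      pi <- predIdx[i]
      Nrow <- sum(trans[pi, ])
      denom <- switch(state@smoothing, dirichlet_K = Nrow + K,
                      literal_plus1 = Nrow + 1, binomial_plus2 = Nrow + 2)
      p_cond[i] <- (trans[pi, stepIdx[i]] + 1) / denom
      p_prior[i] <- (item[pi] + 1) / (sum(item) + K)
      surp[i] <- -lg(p_cond[i])
      psucc <- (trans[pi, ] + 1) / denom
      psucc <- psucc / sum(psucc)
      entr[i] <- p_prior[i] * (-sum(psucc * lg(psucc)))
    }
    if (update) {
      item[stepIdx[i]] <- item[stepIdx[i]] + 1
      if (ok[i]) trans[predIdx[i], stepIdx[i]] <-
          trans[predIdx[i], stepIdx[i]] + 1
    }
  }
  out <- events
  out$predecessor <- pred
  out$p_cond <- p_cond
  out$surprisal <- surp
  out$entropy <- entr
  out$p_prior <- p_prior
  out$annotate_ok <- ok
  newState <- state
  newState@itemCounts <- item
  newState@transCounts <- trans
  list(annotations = out, state = newState)
}

#' Estimated transition matrix of an observer state
#'
#' @param state an [ObserverState-class].
#' @return K x K matrix of smoothed conditional probabilities (rows sum to
#'   1 under `dirichlet_K`).
#' @export
estimatedTransitionMatrix <- function(state) {
  t(vapply(state@labels, function(pr) condProb(state, pr),
           numeric(length(state@labels))))
}

#' Serialize / restore an observer state as JSON counts
#'
#' Replay-oriented dump of the running counts plus configuration.
#'
#' @param state an [ObserverState-class].
#' @param path file path.
#' @return `writeObserverState` returns `path` invisibly;
#'   `readObserverState` returns the restored ObserverState.
#' @export
writeObserverState <- function(state, path) {
  jsonlite::write_json(list(labels = state@labels,
    itemCounts = unname(state@itemCounts),
    transCounts = apply(state@transCounts, 1, identity, simplify = FALSE),
    smoothing = state@smoothing, logBase = state@logBase),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeObserverState
#' @export
readObserverState <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- ObserverState(j$labels, smoothing = j$smoothing, logBase = j$logBase)
  st@itemCounts[] <- j$itemCounts
  st@transCounts[] <- t(matrix(unlist(j$transCounts), length(j$labels)))
  validObject(st)
  st
}
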