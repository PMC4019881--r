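#' Lay out a presentation session on a common clock
#'
#' Arranges the corpus sequences in a given presentation order: each video
#' is announced by a fixation period, plays for its full duration (action
#' steps at their within-sequence onsets), and is followed by a question
#' trial for a fixed proportion of videos (with a minimum post-question
#' fixation). Returns session-clock event, epoch and question tables plus
#' the number of volumes covering the session.
#'
#' @param corpus an [ActionCorpus-class].
#' @param order presentation order from [randomizeOrder()].
#' @param session label prefixed to sequence instances (keeps instances
#'   unique when sessions are concatenated for observer replay).
#' @param tr repetition time, seconds.
#' @param fixationS fixation duration announcing each video, seconds.
#' @param questionRate proportion of videos followed by a question.
#' @param questionDurS modeled question duration, seconds.
#' @param postQuestionFixS minimum fixation after a question, seconds.
#' @param restS rest appended at the end of the session, seconds.
#' @param seed seed for selecting which videos get questions.
#' @return list with `events` (onset, duration, step, step_duration,
#'   sequence_id instance, source_sequence, position), `epochs` (onset,
#'   duration), `questions` (onset), `totalDuration`, `nVolumes`.
#' @export
buildSessionSchedule <- function(corpus, order, session = "s1", tr = 2,
                                 fixationS = 3, questionRate = 0.48,
                                 questionDurS = 3, postQuestionFixS = 2,
                                 restS = 10, seed = NULL) {
  ev <- corpusEvents(corpus)
  n <- length(order)
  nQ <- round(questionRate * n)
  hasQ <- withSeed(seed, {
    q <- logical(n)
    q[sample.int(n, nQ)] <- TRUE
    q
  })
  rows <- vector("list", n)
  epochs <- data.frame(onset = numeric(n), duration = numeric(n))
  questions <- numeric(0)
  t <- 0
  for (k in seq_len(n)) {
    sid <- unique(ev$sequence_id)[order[k]]
    se <- ev[ev$sequence_id == sid, ]
    t <- t + fixationS
    epochs$onset[k] <- t
    dur <- sum(se$duration_s)
    epochs$duration[k] <- dur
    rows[[k]] <- data.frame(onset = t + se$onset_s,
                            duration = se$duration_s,
                            step = se$step, step_duration = se$duration_s,
                            sequence_id = paste0(session, "_", k),
                            source_sequence = sid, position = se$position)
    t <- t + dur
    if (hasQ[k]) {
      questions <- c(questions, t)
      t <- t + questionDurS + postQuestionFixS
    }
  }
  t <- t + restS
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  list(events = events, epochs = epochs,
       questions = data.frame(onset = questions),
       totalDuration = t, nVolumes = as.integer(ceiling(t / tr)))
}
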