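#' Read / write an action chain as CSV or JSON
#'
#' CSV files carry the labeled transition matrix with a header row and a
#' leading label column; JSON files carry `labels` and the row-major
#' matrix.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @param chain an [ActionChain-class].
#' @return `readChain` returns an ActionChain; `writeChain` returns `path`
#'   invisibly.
#' @export
readChain <- function(path) {
  if (grepl("\\.json$", path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    P <- matrix(unlist(j$P), length(j$labels), byrow = TRUE)
    return(ActionChain(P, j$labels))
  }
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  ActionChain(as.matrix(d), rownames(d))
}

#' @rdname readChain
#' @export
writeChain <- function(chain, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(labels = chainLabels(chain),
      P = apply(transitionMatrix(chain), 1, identity, simplify = FALSE)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(transitionMatrix(chain)), path)
  }
  invisible(path)
}

#' Write / read corpus events as tab-separated text
#'
#' Long-format event table (one row per action step).
#'
#' @param corpus an [ActionCorpus-class] (write) or chain to re-attach
#'   (read).
#' @param path file path.
#' @param chain the generating [ActionChain-class], re-attached on read.
#' @return `writeCorpusTsv` returns `path` invisibly; `readCorpusTsv`
#'   returns an ActionCorpus.
#' @export
writeCorpusTsv <- function(corpus, path) {
  utils::write.table(corpusEvents(corpus), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCorpusTsv
#' @export
readCorpusTsv <- function(path, chain) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new("ActionCorpus", events = ev, chain = chain)
}

#' Write an annotated event table as tab-separated text
#'
#' @param events data.frame (e.g. the `annotations` element of
#'   [annotateEvents()]).
#' @param path file path.
#' @export
writeEventsTsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
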