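# Concept-annotated sentence corpora: JSON-lines I/O and a dictionary
# annotator standing in for an external concept recognizer.

#' Read and write JSON-lines corpora
#'
#' One JSON object per line:
#' `{"text": ..., "source": ..., "mentions": [{"concept": ..., "start": ...,
#' "end": ...}]}` with 0-based half-open character offsets. Writing then
#' reading reproduces the corpus exactly.
#'
#' @param path file path.
#' @param x a [Corpus-class].
#' @return `readCorpus()` returns a [Corpus-class]; `writeCorpus()` returns
#'   `path` invisibly.
#' @name corpusIO
NULL

#' @rdname corpusIO
#' @export
readCorpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sents <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("%s line %d: malformed JSON (%s)", path, i,
                                   conditionMessage(e)), call. = FALSE))
    ms <- obj$mentions %||% list()
    mdf <- if (length(ms))
      data.frame(concept = vapply(ms, function(m) as.character(m$concept), ""),
                 start = vapply(ms, function(m) as.integer(m$start), 0L),
                 end = vapply(ms, function(m) as.integer(m$end), 0L),
                 stringsAsFactors = FALSE)
    else .emptyMentions()
    sents[[i]] <- tryCatch(
      annotatedSentence(obj$text, mdf, obj$source %||% ""),
      error = function(e)
        stop(sprintf("%s line %d: %s", path, i, conditionMessage(e)),
             call. = FALSE))
  }
  corpus(sents)
}

#' @rdname corpusIO
#' @export
writeCorpus <- function(x, path) {
  stopifnot(is(x, "Corpus"))
  lines <- vapply(x@sentences, function(s) {
    ms <- s@mentions
    mlist <- lapply(seq_len(nrow(ms)), function(i)
      list(concept = ms$concept[i], start = ms$start[i], end = ms$end[i]))
    as.character(jsonlite::toJSON(
      list(text = s@text, source = s@source, mentions = mlist),
      auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.rxQuote <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Annotate a sentence with concept mentions from a dictionary
#'
#' Matches concept labels from the TBox against the text, case-insensitively
#' and at word boundaries only, with runs of whitespace in a label matching
#' runs of whitespace in the text. Overlapping candidates are resolved
#' longest-match-first; ties between equal-length matches are broken by
#' leftmost start, then by lexicographic concept id (so when two concepts
#' share a label the first id wins, and a note is emitted).
#'
#' @param text the raw sentence.
#' @param tbox a [TBox-class] supplying `id` and `label` for each concept.
#' @return an [AnnotatedSentence-class]; zero mentions if nothing matches.
#' @examples
#' s <- annotateWithDictionary(
#'   "Baritosis is pneumoconiosis caused by barium dust",
#'   baritosisFixture())
#' mentions(s)
#' @export
annotateWithDictionary <- function(text, tbox) {
  stopifnot(is(tbox, "TBox"), is.character(text), length(text) == 1L)
  cs <- tbox@concepts
  cand <- list()
  for (k in seq_len(nrow(cs))) {
    lab <- trimws(cs$label[k])
    if (!nzchar(lab)) next
    pieces <- strsplit(lab, "[[:space:]]+")[[1]]
    core <- paste(vapply(pieces, .rxQuote, ""), collapse = "[[:space:]]+")
    pat <- paste0("(?<![[:alnum:]])", core, "(?![[:alnum:]])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    cand[[length(cand) + 1L]] <- data.frame(
      concept = cs$id[k], start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + as.integer(len), stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(annotatedSentence(text, .emptyMentions(), source = "dictionary"))
  cand <- do.call(rbind, cand)
  span <- paste(cand$start, cand$end)
  if (anyDuplicated(span))
    message("ambiguous label: multiple concepts match one span; ",
            "keeping the lexicographically first id")
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$concept,
                     method = "radix"), , drop = FALSE]
  taken <- logical(nchar(text))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- (cand$start[i] + 1L):cand$end[i]
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      keep[i] <- TRUE
    }
  }
  annotatedSentence(text, cand[keep, , drop = FALSE], source = "dictionary")
}

#' Annotate every sentence of a corpus
#'
#' Applies [annotateWithDictionary()] to each sentence text; existing
#' mentions are replaced.
#'
#' @param x a [Corpus-class] (or character vector of raw sentences).
#' @param tbox a [TBox-class].
#' @return a [Corpus-class] of annotated sentences.
#' @export
annotateCorpus <- function(x, tbox) {
  texts <- if (is(x, "Corpus"))
    vapply(x@sentences, function(s) s@text, "")
  else as.character(x)
  corpus(lapply(texts, annotateWithDictionary, tbox = tbox))
}
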