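# Distant supervision: turn annotated sentences plus a relationship base
# into labeled relation instances. A sentence mentioning concepts A and B
# (A before B) is aligned with every role r such that A|r|B is in the base;
# the text fragment between the two mentions becomes the lexical evidence.

#' Extract the between-string of two mentions
#'
#' Returns the sentence fragment strictly between the first and the second
#' mention, trimmed of leading/trailing whitespace and lowercased. The first
#' mention must end at or before the start of the second (mentions may be
#' adjacent, giving an empty between-string, but must not overlap).
#'
#' @param sentence an [AnnotatedSentence-class].
#' @param first,second row indices into `mentions(sentence)`.
#' @return a single string (possibly `""`).
#' @examples
#' s <- annotateWithDictionary(
#'   "Baritosis is pneumoconiosis caused by barium dust",
#'   baritosisFixture())
#' extractBetweenString(s, 1, nrow(mentions(s)))
#' @export
extractBetweenString <- function(sentence, first, second) {
  stopifnot(is(sentence, "AnnotatedSentence"))
  m <- sentence@mentions
  f <- m[first, ]; s <- m[second, ]
  if (f$end > s$start)
    stop("mentions overlap: first mention must end before the second starts",
         call. = FALSE)
  tolower(trimws(substr(sentence@text, f$end + 1L, s$start)))
}

.emptyInstances <- function() {
  data.frame(sentence_index = integer(0), subject = character(0),
             object = character(0), subject_type = character(0),
             object_type = character(0), label = character(0),
             between = character(0), subject_start = integer(0),
             object_start = integer(0), order = character(0),
             stringsAsFactors = FALSE)
}

#' Align a corpus against a relationship base (distant supervision)
#'
#' For every ordered pair of non-overlapping mentions within a sentence
#' (first mention before second) and every role `r` with
#' `concept(first)|r|concept(second)` in the relationship base, emits one
#' labeled relation instance. Semantic types of both arguments are filled in
#' from the TBox. Every emitted label is by construction a member of the
#' base, so aligning against a larger base (e.g. the inferred instead of the
#' explicit one) can only add instances.
#'
#' @param corpus a [Corpus-class].
#' @param rb a [RelationshipBase-class].
#' @param tbox a [TBox-class] (for semantic types).
#' @param bothOrders also align object-before-subject mention pairs
#'   (between-string unchanged; the `order` column records `"SO"`/`"OS"`).
#' @param dropAmbiguous drop pairs aligned with more than one role.
#' @param withNoneClass emit co-occurring pairs matching no role with the
#'   label `"NONE"`.
#' @return data.frame of instances with columns `sentence_index`, `subject`,
#'   `object`, `subject_type`, `object_type`, `label`, `between`,
#'   `subject_start`, `object_start`, `order`, deterministically ordered by
#'   (sentence, subject start, object start, label). Sentences containing a
#'   mention of a concept missing from the TBox are skipped with a warning.
#' @export
alignCorpus <- function(corpus, rb, tbox, bothOrders = FALSE,
                        dropAmbiguous = FALSE, withNoneClass = FALSE) {
  stopifnot(is(corpus, "Corpus"), is(rb, "RelationshipBase"), is(tbox, "TBox"))
  typeMap <- stats::setNames(tbox@concepts$semantic_type, tbox@concepts$id)
  tr <- rb@triples
  roleMap <- split(tr$role, paste(tr$subject, tr$object, sep = "\r"))
  rows <- list()
  for (si in seq_along(corpus@sentences)) {
    sent <- corpus@sentences[[si]]
    m <- sent@mentions
    if (!nrow(m)) next
    if (!all(m$concept %in% names(typeMap))) {
      warning(sprintf("sentence %d: unresolvable concept mention; skipped", si),
              call. = FALSE)
      next
    }
    if (nrow(m) < 2L) next
    for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
      if (m$end[i] > m$start[j]) next   # overlapping spans: no pair
      between <- extractBetweenString(sent, i, j)
      dirs <- list(c(i, j, "SO"))
      if (bothOrders) dirs <- c(dirs, list(c(j, i, "OS")))
      for (d in dirs) {
        su <- m$concept[as.integer(d[1])]; ob <- m$concept[as.integer(d[2])]
        rs <- roleMap[[paste(su, ob, sep = "\r")]]
        if (is.null(rs) && withNoneClass) rs <- "NONE"
        if (is.null(rs)) next
        if (dropAmbiguous && length(rs) > 1L) next
        for (r in .csort(rs)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sentence_index = si, subject = su, object = ob,
            subject_type = unname(typeMap[su]),
            object_type = unname(typeMap[ob]),
            label = r, between = between,
            subject_start = m$start[as.integer(d[1])],
            object_start = m$start[as.integer(d[2])],
            order = d[3], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(.emptyInstances())
  out <- do.call(rbind, rows)
  out <- out[order(out$sentence_index, out$subject_start, out$object_start,
                   out$label, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write relation-instance TSV files
#'
#' Serialization columns:
#' `sentence_index`, `subject`, `object`, `subject_type`, `object_type`,
#' `label`, `between` (tab-separated, with a header line).
#'
#' @param x an instance data.frame as returned by [alignCorpus()].
#' @param path file path.
#' @return `readInstances()`: the instance data.frame.
#' @name instanceIO
NULL

.instanceCols <- c("sentence_index", "subject", "object", "subject_type",
                   "object_type", "label", "between")

#' @rdname instanceIO
#' @export
writeInstances <- function(x, path) {
  df <- x[, .instanceCols, drop = FALSE]
  lines <- c(paste(.instanceCols, collapse = "\t"),
             do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname instanceIO
#' @export
readInstances <- function(path) {
  df <- read.delim(path, quote = "", stringsAsFactors = FALSE,
                   colClasses = c(sentence_index = "integer"))
  missing <- setdiff(.instanceCols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing instance columns %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df$between[is.na(df$between)] <- ""
  df
}
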