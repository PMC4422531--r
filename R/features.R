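# Boolean featurization of relation instances: bag-of-words, word n-grams,
# character n-grams over the between-string, plus semantic-type features for
# the two arguments. Feature names are namespaced (bow:, w<n>:, c<n>:,
# ltype:, rtype:) so lexical and semantic features can never collide.

.normWS <- function(x) gsub("[[:space:]]+", " ", x)

.tokens <- function(between) {
  s <- tolower(.normWS(trimws(between)))
  if (!nzchar(s)) return(character(0))
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Bag-of-words of a between-string
#'
#' Lowercases, tokenizes on whitespace, strips punctuation from token edges
#' and collapses duplicates (presence encoding).
#'
#' @param between the between-string.
#' @return character vector of distinct tokens (order of first occurrence).
#' @examples
#' bow("is pneumoconiosis caused by")
#' @export
bow <- function(between) unique(.tokens(between))

#' Word n-grams of a between-string
#'
#' Contiguous token sequences. With `scope = "exact"` only length-`n` grams
#' are produced; with `scope = "up_to"` all lengths `1..n`.
#'
#' @param between the between-string.
#' @param n n-gram length, >= 1.
#' @param scope `"exact"` or `"up_to"`.
#' @return character vector of distinct grams (tokens joined by one space).
#' @examples
#' wordNgrams("is pneumoconiosis caused by", 2)
#' @export
wordNgrams <- function(between, n, scope = c("exact", "up_to")) {
  scope <- match.arg(scope)
  stopifnot(n >= 1)
  toks <- .tokens(between)
  lens <- if (scope == "exact") n else seq_len(n)
  out <- character(0)
  for (len in lens) {
    k <- length(toks) - len + 1L
    if (k < 1L) next
    out <- c(out, vapply(seq_len(k), function(i)
      paste(toks[i:(i + len - 1L)], collapse = " "), character(1)))
  }
  unique(out)
}

#' Character n-grams of a between-string
#'
#' Sliding window over the lowercased string (internal whitespace normalized
#' to single spaces, no boundary padding); duplicates collapse.
#'
#' @inheritParams wordNgrams
#' @return character vector of distinct character grams.
#' @examples
#' length(charNgrams("is pneumoconiosis caused by", 3))  # 24 distinct trigrams
#' @export
charNgrams <- function(between, n, scope = c("exact", "up_to")) {
  scope <- match.arg(scope)
  stopifnot(n >= 1)
  s <- tolower(.normWS(trimws(between)))
  lens <- if (scope == "exact") n else seq_len(n)
  out <- character(0)
  nc <- nchar(s)
  for (len in lens) {
    if (nc < len) next
    out <- c(out, substring(s, seq_len(nc - len + 1L),
                            seq_len(nc - len + 1L) + len - 1L))
  }
  unique(out)
}

#' Type assignment: concept id to semantic type
#'
#' Builds the mapping used by the semantic features, either straight from the
#' TBox (every concept has exactly one semantic type) or overridden from a
#' two-column TSV file to emulate an alternative type system. An optional
#' grouping map collapses types into coarser groups.
#'
#' @param tbox a [TBox-class].
#' @param grouping named character vector mapping type -> group (types absent
#'   from the map are kept as-is).
#' @param file optional TSV path `concept_id<TAB>type` overriding the TBox
#'   types.
#' @return named character vector: concept id -> semantic type.
#' @export
typeAssignment <- function(tbox, grouping = NULL, file = NULL) {
  stopifnot(is(tbox, "TBox"))
  ta <- stats::setNames(tbox@concepts$semantic_type, tbox@concepts$id)
  if (!is.null(file)) {
    rec <- .readRecords(file)
    for (i in seq_along(rec$lines)) {
      f <- .fields(rec$lines[i], 2)
      if (!nzchar(f[1]) || !nzchar(f[2]))
        stop(sprintf("%s line %d: expected concept_id<TAB>type", file,
                     rec$lineno[i]), call. = FALSE)
      ta[f[1]] <- f[2]
    }
  }
  if (!is.null(grouping)) {
    hit <- ta %in% names(grouping)
    ta[hit] <- unname(grouping[ta[hit]])
  }
  ta
}

#' Semantic-type features of a relation instance
#'
#' Exactly two features: the semantic type of the subject (`ltype:`) and of
#' the object (`rtype:`), imposing explicit domain/range constraints on the
#' relation's arguments.
#'
#' @param subject,object concept ids.
#' @param ta named type assignment from [typeAssignment()].
#' @return character vector of two feature names.
#' @export
semanticTypeFeatures <- function(subject, object, ta) {
  for (id in c(subject, object)) if (is.na(ta[id]))
    stop(sprintf("no semantic type assigned for concept '%s'", id),
         call. = FALSE)
  c(paste0("ltype:", unname(ta[subject])),
    paste0("rtype:", unname(ta[object])))
}

#' Feature specification
#'
#' @param lexicalMode one of `"char_ngram"`, `"word_ngram"`, `"bow"`,
#'   `"none"`. Character 3-grams are the default lexical representation.
#' @param n n-gram length (ignored for `bow`/`none`).
#' @param ngramScope `"exact"` (only length-`n` grams, the default) or
#'   `"up_to"` (lengths `1..n`).
#' @param useTypes include semantic-type features.
#' @param typeGrouping optional named character vector collapsing types into
#'   groups (see [typeAssignment()]).
#' @return a `FeatureSpec` list.
#' @export
featureSpec <- function(lexicalMode = c("char_ngram", "word_ngram", "bow",
                                        "none"),
                        n = 3L, ngramScope = c("exact", "up_to"),
                        useTypes = TRUE, typeGrouping = NULL) {
  lexicalMode <- match.arg(lexicalMode)
  ngramScope <- match.arg(ngramScope)
  stopifnot(n >= 1)
  structure(list(lexicalMode = lexicalMode, n = as.integer(n),
                 ngramScope = ngramScope, useTypes = isTRUE(useTypes),
                 typeGrouping = typeGrouping),
            class = "FeatureSpec")
}

.lexicalFeatures <- function(between, spec) {
  switch(spec$lexicalMode,
    none = character(0),
    bow = {
      g <- bow(between)
      if (length(g)) paste0("bow:", g) else character(0)
    },
    word_ngram = {
      g <- wordNgrams(between, spec$n, spec$ngramScope)
      if (!length(g)) return(character(0))
      len <- vapply(strsplit(g, " ", fixed = TRUE), length, 0L)
      paste0("w", len, ":", g)
    },
    char_ngram = {
      g <- charNgrams(between, spec$n, spec$ngramScope)
      if (!length(g)) return(character(0))
      paste0("c", nchar(g), ":", g)
    })
}

#' Featurize relation instances
#'
#' Converts each instance into the set of feature names present (boolean
#' presence encoding) and collects the vocabulary as the sorted union of all
#' names. The instance labels are carried alongside.
#'
#' @param instances instance data.frame from [alignCorpus()] (columns
#'   `subject`, `object`, `between` and optionally `label`).
#' @param spec a [featureSpec()].
#' @param ta type assignment from [typeAssignment()]; required when
#'   `spec$useTypes` is `TRUE`.
#' @return a `FeatureSet`: list with `features` (list of character vectors),
#'   `vocabulary` (sorted), `labels` (or `NULL` for unlabeled instances).
#' @export
vectorizeInstances <- function(instances, spec = featureSpec(), ta = NULL) {
  stopifnot(inherits(spec, "FeatureSpec"))
  if (spec$useTypes && is.null(ta))
    stop("semantic-type features requested but no type assignment given",
         call. = FALSE)
  if (!is.null(ta) && !is.null(spec$typeGrouping)) {
    hit <- ta %in% names(spec$typeGrouping)
    ta[hit] <- unname(spec$typeGrouping[ta[hit]])
  }
  n <- nrow(instances)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    f <- .lexicalFeatures(instances$between[i], spec)
    if (spec$useTypes)
      f <- c(f, semanticTypeFeatures(instances$subject[i],
                                     instances$object[i], ta))
    feats[[i]] <- unique(f)
  }
  structure(list(features = feats,
                 vocabulary = .csort(unlist(feats, use.names = FALSE)),
                 labels = instances$label %||% NULL),
            class = "FeatureSet")
}

#' @export
print.FeatureSet <- function(x, ...) {
  cat(sprintf("FeatureSet: %d instances, %d features, %d classes\n",
              length(x$features), length(x$vocabulary),
              length(unique(x$labels))))
  invisible(x)
}

.arffQuote <- function(x) {
  needs <- grepl("[ ,{}%'\"\\\\]", x) | !nzchar(x)
  x[needs] <- paste0("'", gsub("'", "\\\\'", x[needs], fixed = FALSE), "'")
  x
}

#' Write a sparse ARFF file
#'
#' Weka-dialect sparse ARFF: one binary numeric attribute per vocabulary
#' entry (value 1 when the feature is present), plus a nominal `class`
#' attribute; data rows use the `{index value, ...}` sparse form. Output is
#' byte-deterministic for identical inputs.
#'
#' @param x a `FeatureSet` from [vectorizeInstances()], or a list of feature
#'   name vectors.
#' @param path output path.
#' @param vocabulary,labels override the feature set's vocabulary/labels.
#' @param relation `@relation` name.
#' @param vocabularyFile optional sidecar path: one feature name per line.
#' @return `path`, invisibly.
#' @export
writeArff <- function(x, path, vocabulary = NULL, labels = NULL,
                      relation = "relation_instances",
                      vocabularyFile = NULL) {
  feats <- if (inherits(x, "FeatureSet")) x$features else x
  vocabulary <- vocabulary %||% (if (inherits(x, "FeatureSet")) x$vocabulary
                                 else .csort(unlist(feats)))
  labels <- labels %||% (if (inherits(x, "FeatureSet")) x$labels else NULL)
  if (is.null(labels)) stop("labels are required for ARFF export", call. = FALSE)
  classes <- .csort(labels)
  header <- c(paste0("@relation ", .arffQuote(relation)), "",
              paste0("@attribute ", .arffQuote(vocabulary), " numeric"),
              paste0("@attribute class {",
                     paste(.arffQuote(classes), collapse = ","), "}"),
              "", "@data")
  k <- length(vocabulary)
  rows <- vapply(seq_along(feats), function(i) {
    idx <- sort(match(feats[[i]], vocabulary))
    idx <- idx[!is.na(idx)]
    ent <- c(paste(idx - 1L, "1"),
             paste(k, .arffQuote(labels[i])))
    paste0("{", paste(ent, collapse = ", "), "}")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  if (!is.null(vocabularyFile))
    writeLines(vocabulary, vocabularyFile, useBytes = TRUE)
  invisible(path)
}
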