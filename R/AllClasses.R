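# S4 containers for the ontology, corpus and definition objects.

.emptyExistentials <- function()
  data.frame(role = character(0), filler = character(0),
             stringsAsFactors = FALSE)

.emptyMentions <- function()
  data.frame(concept = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)

.emptyTriples <- function()
  data.frame(subject = character(0), role = character(0),
             object = character(0), stringsAsFactors = FALSE)

.badId <- function(x) !nzchar(x) | grepl("[|\t\n]", x)

#' TBox: a terminology in a restricted EL fragment
#'
#' A `TBox` holds named concepts (each with exactly one semantic type, as in
#' SNOMED CT), roles (with an optional role hierarchy), and flat primitive
#' inclusion axioms of the form
#' \eqn{A \sqsubseteq P_1 \sqcap \ldots \sqcap \exists R_1.B_1 \sqcap \ldots}
#' where all parents \eqn{P_i} and fillers \eqn{B_j} are concept names.
#' Only inclusions are representable, never equivalences, and fillers are
#' always named concepts (flat structure).
#'
#' @slot concepts data.frame with columns `id`, `label`, `semantic_type`.
#' @slot roles data.frame with columns `id`, `label`, `parent`
#'   (`NA` parent means the role is at the top of the role hierarchy).
#' @slot axioms list of axioms as returned by [axiom()].
#'
#' @seealso [parseTBox()], [subsumes()], [inferredRelationshipBase()]
#' @export
setClass("TBox",
  slots = c(concepts = "data.frame", roles = "data.frame", axioms = "list"))

setValidity("TBox", function(object) {
  msgs <- character(0)
  cs <- object@concepts
  rs <- object@roles
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df)))
      msgs <<- c(msgs, sprintf("%s must have columns %s", what,
                               paste(cols, collapse = ", ")))
  }
  need(cs, c("id", "label", "semantic_type"), "concepts")
  need(rs, c("id", "label", "parent"), "roles")
  if (length(msgs)) return(msgs)
  if (any(.badId(cs$id))) msgs <- c(msgs, "concept ids must be non-empty and free of '|'/tabs")
  if (anyDuplicated(cs$id)) msgs <- c(msgs, "duplicate concept ids")
  if (any(!nzchar(cs$semantic_type))) msgs <- c(msgs, "semantic_type must be non-empty")
  if (nrow(rs)) {
    if (any(.badId(rs$id))) msgs <- c(msgs, "role ids must be non-empty and free of '|'/tabs")
    if (anyDuplicated(rs$id)) msgs <- c(msgs, "duplicate role ids")
    hasParent <- !is.na(rs$parent) & nzchar(rs$parent)
    if (any(!rs$parent[hasParent] %in% rs$id))
      msgs <- c(msgs, "role parent not declared")
    if (any(hasParent) && .hasCycle(rs$id[hasParent], rs$parent[hasParent]))
      msgs <- c(msgs, "role hierarchy contains a cycle")
  }
  for (i in seq_along(object@axioms)) {
    ax <- object@axioms[[i]]
    if (!is.list(ax) || !all(c("subject", "parents", "existentials") %in% names(ax))) {
      msgs <- c(msgs, sprintf("axiom %d is not a valid axiom object", i)); next
    }
    if (!ax$subject %in% cs$id)
      msgs <- c(msgs, sprintf("axiom %d: unknown subject '%s'", i, ax$subject))
    if (!all(ax$parents %in% cs$id))
      msgs <- c(msgs, sprintf("axiom %d: unknown parent concept", i))
    ex <- ax$existentials
    if (!all(c("role", "filler") %in% names(ex))) {
      msgs <- c(msgs, sprintf("axiom %d: malformed existentials", i)); next
    }
    if (nrow(ex) && !all(ex$role %in% rs$id))
      msgs <- c(msgs, sprintf("axiom %d: unknown role", i))
    if (nrow(ex) && !all(ex$filler %in% cs$id))
      msgs <- c(msgs, sprintf("axiom %d: unknown filler concept", i))
    if (!length(ax$parents) && !nrow(ex))
      msgs <- c(msgs, sprintf("axiom %d: both named parents and existentials empty", i))
  }
  if (!length(msgs)) {
    edges <- .parentEdges(object)
    if (nrow(edges) && .hasCycle(edges$child, edges$parent))
      msgs <- c(msgs, "taxonomy (named-parent graph) contains a cycle")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a primitive-inclusion axiom
#'
#' @param subject concept id being defined.
#' @param parents character vector of named-parent concept ids.
#' @param existentials data.frame with columns `role`, `filler` giving the
#'   existential conjuncts \eqn{\exists role.filler}.
#' @return a plain list usable in the `axioms` slot of a [TBox-class].
#' @export
axiom <- function(subject, parents = character(0),
                  existentials = .emptyExistentials()) {
  existentials <- unique(data.frame(role = as.character(existentials$role),
                                    filler = as.character(existentials$filler),
                                    stringsAsFactors = FALSE))
  list(subject = as.character(subject),
       parents = unique(as.character(parents)),
       existentials = existentials)
}

#' Construct a TBox
#'
#' @param concepts data.frame with columns `id`, `label`, `semantic_type`.
#' @param roles data.frame with columns `id`, `label` and optionally `parent`.
#' @param axioms list of axioms built with [axiom()].
#' @return a validated [TBox-class] object.
#' @examples
#' tb <- TBox(
#'   concepts = data.frame(id = c("A", "B"), label = c("a", "b"),
#'                         semantic_type = c("t", "t")),
#'   roles = data.frame(id = "R", label = "r"),
#'   axioms = list(axiom("A", parents = "B")))
#' subsumes(tb, "B", "A")
#' @export
TBox <- function(concepts, roles = data.frame(id = character(0),
                                              label = character(0)),
                 axioms = list()) {
  concepts <- data.frame(id = as.character(concepts$id),
                         label = as.character(concepts$label),
                         semantic_type = as.character(concepts$semantic_type),
                         stringsAsFactors = FALSE)
  if (is.null(roles$parent)) roles$parent <- rep(NA_character_, nrow(roles))
  roles <- data.frame(id = as.character(roles$id),
                      label = as.character(roles$label),
                      parent = as.character(roles$parent),
                      stringsAsFactors = FALSE)
  roles$parent[!is.na(roles$parent) & !nzchar(roles$parent)] <- NA_character_
  obj <- new("TBox", concepts = concepts, roles = roles, axioms = axioms)
  validObject(obj)
  obj
}

#' RelationshipBase: a set of relation triples
#'
#' A set of triples `A|R|B`, each asserting that concept `A` stands in role
#' `R` to concept `B`. Provenance records whether the triples were read off
#' the axioms directly (`explicit`), derived by reasoning (`inferred`), or
#' supplied externally (`external`).
#'
#' @slot triples data.frame with columns `subject`, `role`, `object`;
#'   no duplicate rows.
#' @slot provenance one of `"explicit"`, `"inferred"`, `"external"`.
#' @seealso [explicitRelationshipBase()], [inferredRelationshipBase()]
#' @export
setClass("RelationshipBase",
  slots = c(triples = "data.frame", provenance = "character"))

setValidity("RelationshipBase", function(object) {
  msgs <- character(0)
  tr <- object@triples
  if (!all(c("subject", "role", "object") %in% names(tr)))
    return("triples must have columns subject, role, object")
  if (anyDuplicated(paste(tr$subject, tr$role, tr$object, sep = "|")))
    msgs <- c(msgs, "duplicate triples")
  if (!object@provenance %in% c("explicit", "inferred", "external"))
    msgs <- c(msgs, "provenance must be explicit, inferred or external")
  if (length(msgs)) msgs else TRUE
})

#' Construct a relationship base
#'
#' @param triples data.frame with columns `subject`, `role`, `object`.
#' @param provenance `"explicit"`, `"inferred"` or `"external"`.
#' @return a [RelationshipBase-class] object (triples deduplicated and sorted).
#' @export
relationshipBase <- function(triples, provenance = "external") {
  tr <- unique(data.frame(subject = as.character(triples$subject),
                          role = as.character(triples$role),
                          object = as.character(triples$object),
                          stringsAsFactors = FALSE))
  tr <- tr[order(tr$subject, tr$role, tr$object, method = "radix"), ,
           drop = FALSE]
  rownames(tr) <- NULL
  obj <- new("RelationshipBase", triples = tr, provenance = provenance)
  validObject(obj)
  obj
}

#' AnnotatedSentence: a sentence with concept mentions
#'
#' Character offsets are 0-based and half-open: a mention with `start = 0`,
#' `end = 9` covers the first nine characters of `text`.
#'
#' @slot text the raw sentence.
#' @slot mentions data.frame with columns `concept`, `start`, `end`,
#'   sorted by `start`.
#' @slot source free-text provenance tag.
#' @export
setClass("AnnotatedSentence",
  slots = c(text = "character", mentions = "data.frame", source = "character"))

setValidity("AnnotatedSentence", function(object) {
  msgs <- character(0)
  m <- object@mentions
  if (length(object@text) != 1L) return("text must be a single string")
  if (!all(c("concept", "start", "end") %in% names(m)))
    return("mentions must have columns concept, start, end")
  if (nrow(m)) {
    n <- nchar(object@text)
    if (any(m$start < 0L | m$start >= m$end | m$end > n))
      msgs <- c(msgs, "mention span out of bounds (need 0 <= start < end <= nchar(text))")
    if (is.unsorted(m$start))
      msgs <- c(msgs, "mentions must be sorted by start offset")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an annotated sentence
#'
#' @param text sentence string.
#' @param mentions data.frame with columns `concept`, `start`, `end`
#'   (0-based, half-open character offsets).
#' @param source free-text provenance tag.
#' @return an [AnnotatedSentence-class] object with mentions sorted by start.
#' @export
annotatedSentence <- function(text, mentions = .emptyMentions(), source = "") {
  mentions <- data.frame(concept = as.character(mentions$concept),
                         start = as.integer(mentions$start),
                         end = as.integer(mentions$end),
                         stringsAsFactors = FALSE)
  mentions <- mentions[order(mentions$start, mentions$end, mentions$concept,
                             method = "radix"), , drop = FALSE]
  rownames(mentions) <- NULL
  obj <- new("AnnotatedSentence", text = as.character(text)[1],
             mentions = mentions, source = as.character(source)[1])
  validObject(obj)
  obj
}

#' Corpus: a sequence of annotated sentences
#'
#' @slot sentences list of [AnnotatedSentence-class] objects.
#' @seealso [readCorpus()], [writeCorpus()], [annotateWithDictionary()]
#' @export
setClass("Corpus", slots = c(sentences = "list"))

setValidity("Corpus", function(object) {
  ok <- vapply(object@sentences, function(s) is(s, "AnnotatedSentence"),
               logical(1))
  if (all(ok)) TRUE else "all elements must be AnnotatedSentence objects"
})

#' Construct a corpus
#'
#' @param sentences list of [AnnotatedSentence-class] objects.
#' @return a [Corpus-class] object.
#' @export
corpus <- function(sentences = list()) {
  obj <- new("Corpus", sentences = sentences)
  validObject(obj)
  obj
}

#' CandidateDefinition: an assembled EL axiom for one concept
#'
#' The candidate definition
#' \eqn{A \sqsubseteq P_1 \sqcap \ldots \sqcap \exists R_1.B_1 \sqcap \ldots}
#' produced by turning predicted triples whose role is the designated is-a
#' role into named parents and all other triples into existential conjuncts.
#'
#' @slot subject the concept id being defined.
#' @slot namedParents character vector of parent concept ids.
#' @slot existentials data.frame with columns `role`, `filler`.
#' @seealso [assembleDefinition()], [readBackTriples()], [defPre()]
#' @export
setClass("CandidateDefinition",
  slots = c(subject = "character", namedParents = "character",
            existentials = "data.frame"))

setValidity("CandidateDefinition", function(object) {
  msgs <- character(0)
  if (length(object@subject) != 1L || !nzchar(object@subject))
    msgs <- c(msgs, "subject must be a single non-empty id")
  if (!all(c("role", "filler") %in% names(object@existentials)))
    msgs <- c(msgs, "existentials must have columns role, filler")
  else if (!length(object@namedParents) && !nrow(object@existentials))
    msgs <- c(msgs, "definition must have at least one conjunct")
  if (length(msgs)) msgs else TRUE
})

#' Construct a candidate definition
#'
#' @param subject concept id being defined.
#' @param namedParents character vector of parent concept ids.
#' @param existentials data.frame with columns `role`, `filler`.
#' @return a [CandidateDefinition-class] object (conjuncts deduplicated,
#'   deterministically ordered).
#' @export
candidateDefinition <- function(subject, namedParents = character(0),
                                existentials = .emptyExistentials()) {
  np <- .csort(as.character(namedParents))
  ex <- unique(data.frame(role = as.character(existentials$role),
                          filler = as.character(existentials$filler),
                          stringsAsFactors = FALSE))
  ex <- ex[order(ex$role, ex$filler, method = "radix"), , drop = FALSE]
  rownames(ex) <- NULL
  obj <- new("CandidateDefinition", subject = as.character(subject)[1],
             namedParents = np, existentials = ex)
  validObject(obj)
  obj
}
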