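# Accessors and show methods.

#' Accessors for ontology and corpus objects
#'
#' `concepts()`, `roles()` and `axioms()` return the three components of a
#' [TBox-class]; `triples()` and `provenance()` the components of a
#' [RelationshipBase-class]; `sentences()` and `mentions()` those of a
#' [Corpus-class] / [AnnotatedSentence-class].
#'
#' @param x the object.
#' @return the underlying data.frame or list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("concepts", function(x) standardGeneric("concepts"))
#' @rdname accessors
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))
#' @rdname accessors
#' @export
setGeneric("axioms", function(x) standardGeneric("axioms"))
#' @rdname accessors
#' @export
setGeneric("triples", function(x) standardGeneric("triples"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("sentences", function(x) standardGeneric("sentences"))
#' @rdname accessors
#' @export
setGeneric("mentions", function(x) standardGeneric("mentions"))

#' @rdname accessors
#' @export
setMethod("concepts", "TBox", function(x) x@concepts)
#' @rdname accessors
#' @export
setMethod("roles", "TBox", function(x) x@roles)
#' @rdname accessors
#' @export
setMethod("axioms", "TBox", function(x) x@axioms)
#' @rdname accessors
#' @export
setMethod("triples", "RelationshipBase", function(x) x@triples)
#' @rdname accessors
#' @export
setMethod("provenance", "RelationshipBase", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("sentences", "Corpus", function(x) x@sentences)
#' @rdname accessors
#' @export
setMethod("mentions", "AnnotatedSentence", function(x) x@mentions)

#' @describeIn accessors number of sentences in a corpus
#' @export
setMethod("length", "Corpus", function(x) length(x@sentences))

setMethod("show", "TBox", function(object) {
  cat(sprintf("TBox: %d concepts, %d roles, %d axioms\n",
              nrow(object@concepts), nrow(object@roles),
              length(object@axioms)))
  nex <- sum(vapply(object@axioms, function(a) nrow(a$existentials), 0L))
  cat(sprintf("  semantic types: %s\n",
              paste(.csort(object@concepts$semantic_type), collapse = ", ")))
  cat(sprintf("  existential conjuncts in axioms: %d\n", nex))
})

setMethod("show", "RelationshipBase", function(object) {
  cat(sprintf("RelationshipBase (%s): %d triples over %d roles\n",
              object@provenance, nrow(object@triples),
              length(unique(object@triples$role))))
})

setMethod("show", "AnnotatedSentence", function(object) {
  cat(sprintf("AnnotatedSentence (%d mentions): %s\n",
              nrow(object@mentions), object@text))
})

setMethod("show", "Corpus", function(object) {
  nm <- sum(vapply(object@sentences, function(s) nrow(s@mentions), 0L))
  cat(sprintf("Corpus: %d sentences, %d mentions\n",
              length(object@sentences), nm))
})

setMethod("show", "CandidateDefinition", function(object) {
  cat(renderDefinition(object), "\n")
})
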