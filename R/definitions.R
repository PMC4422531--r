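# Assembly of predicted triples into EL axioms and entailment-based scoring
# of candidate definitions against a reference terminology (DefPre).

#' Assemble predicted triples into a candidate definition
#'
#' Applies the transformation `{A|R_i|B_i} -> A SubClassOf П_i (R_i some B_i)`:
#' triples whose role equals `isaRole` become named parents, all others
#' become existential conjuncts; duplicates collapse. All triples must share
#' the subject.
#'
#' @param subject the concept id being defined.
#' @param triples data.frame with columns `subject`, `role`, `object`.
#' @param isaRole role id to interpret as is-a (`NULL` to treat every triple
#'   as existential).
#' @return a [CandidateDefinition-class].
#' @examples
#' tr <- data.frame(subject = "Baritosis",
#'                  role = c("Isa", "Causative_agent"),
#'                  object = c("Pneumoconiosis", "Barium_dust"))
#' assembleDefinition("Baritosis", tr, isaRole = "Isa")
#' @export
assembleDefinition <- function(subject, triples, isaRole = NULL) {
  if (is.null(triples) || nrow(triples) == 0L)
    stop("cannot assemble a definition from an empty triple set",
         call. = FALSE)
  if (!all(triples$subject == subject))
    stop("all triples must share the definition subject", call. = FALSE)
  isa <- if (is.null(isaRole)) rep(FALSE, nrow(triples))
         else triples$role == isaRole
  candidateDefinition(
    subject,
    namedParents = triples$object[isa],
    existentials = data.frame(role = triples$role[!isa],
                              filler = triples$object[!isa],
                              stringsAsFactors = FALSE))
}

#' Recover the triples of a candidate definition
#'
#' Exact inverse of [assembleDefinition()] after deduplication. Named
#' parents are emitted as `subject|isaRole|parent` triples; when `isaRole`
#' is `NULL` but parents are present, they are dropped with a warning.
#'
#' @param definition a [CandidateDefinition-class].
#' @param isaRole role id used for named parents.
#' @return data.frame with columns `subject`, `role`, `object`.
#' @export
readBackTriples <- function(definition, isaRole = NULL) {
  stopifnot(is(definition, "CandidateDefinition"))
  ex <- definition@existentials
  out <- data.frame(subject = rep(definition@subject, nrow(ex)),
                    role = ex$role, object = ex$filler,
                    stringsAsFactors = FALSE)
  np <- definition@namedParents
  if (length(np)) {
    if (is.null(isaRole)) {
      warning("definition has named parents but no is-a role was given; ",
              "dropping them", call. = FALSE)
    } else {
      out <- rbind(data.frame(subject = definition@subject, role = isaRole,
                              object = np, stringsAsFactors = FALSE), out)
    }
  }
  out <- unique(out)
  out <- out[order(out$subject, out$role, out$object, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune subsumed conjuncts from a definition
#'
#' Drops a named parent that subsumes another named parent of the same
#' definition (keeping the more specific one), and an existential `(R, B)`
#' when another `(R, B')` with the same role has a more specific filler
#' (`B` subsumes `B'`). The operation is idempotent and never changes the
#' entailed consequences of the definition.
#'
#' @param definition a [CandidateDefinition-class].
#' @param tbox a [TBox-class] resolving all referenced ids.
#' @return a pruned [CandidateDefinition-class].
#' @export
simplifyDefinition <- function(definition, tbox) {
  stopifnot(is(definition, "CandidateDefinition"), is(tbox, "TBox"))
  np <- definition@namedParents
  .checkConcept(tbox, c(definition@subject, np, definition@existentials$filler))
  if (nrow(definition@existentials)) .checkRole(tbox, definition@existentials$role)
  keepP <- rep(TRUE, length(np))
  for (i in seq_along(np)) for (j in seq_along(np)) {
    if (i != j && keepP[j] && np[i] != np[j] &&
        subsumes(tbox, np[i], np[j])) keepP[i] <- FALSE
  }
  ex <- definition@existentials
  keepE <- rep(TRUE, nrow(ex))
  for (i in seq_len(nrow(ex))) for (j in seq_len(nrow(ex))) {
    if (i != j && keepE[j] && ex$role[i] == ex$role[j] &&
        ex$filler[i] != ex$filler[j] &&
        subsumes(tbox, ex$filler[i], ex$filler[j])) keepE[i] <- FALSE
  }
  candidateDefinition(definition@subject, np[keepP],
                      ex[keepE, , drop = FALSE])
}

#' Render a definition as human-readable text
#'
#' One line of the form `A SubClassOf P1 and P2 and (R some B)`, with
#' conjuncts in deterministic order.
#'
#' @param definition a [CandidateDefinition-class].
#' @return a single string.
#' @export
renderDefinition <- function(definition) {
  stopifnot(is(definition, "CandidateDefinition"))
  ex <- definition@existentials
  conj <- c(definition@namedParents,
            if (nrow(ex)) paste0("(", ex$role, " some ", ex$filler, ")"))
  paste(definition@subject, "SubClassOf", paste(conj, collapse = " and "))
}

#' Serialize candidate definitions
#'
#' `format = "tsv"` writes the axioms.tsv dialect of [parseTBox()] (machine
#' round-trip); `format = "text"` writes one [renderDefinition()] line per
#' definition.
#'
#' @param definitions list of [CandidateDefinition-class] objects.
#' @param path output path.
#' @param format `"tsv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
writeDefinitions <- function(definitions, path, format = c("tsv", "text")) {
  format <- match.arg(format)
  lines <- vapply(definitions, function(d) {
    if (format == "text") return(renderDefinition(d))
    paste(d@subject,
          paste(d@namedParents, collapse = ","),
          .existentialField(d@existentials),
          sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Definition precision (DefPre) against a reference terminology
#'
#' Scores candidate relation triples by logical entailment: a candidate
#' `A|R|B` is correct iff the reference TBox entails
#' `A SubClassOf (R some B)`. The global precision is
#' \deqn{DefPre = |\{t \in Cands : TBox \models t\}| / |Cands|,}
#' computed over the pooled candidate triples. Per-concept precisions are
#' additionally aggregated two ways: `macro_precision` is the unweighted
#' mean over all concepts with at least one candidate (zero-precision
#' concepts included), and `macro_precision_nonzero` excludes concepts whose
#' every candidate fails. Candidates mentioning ids absent from the
#' reference score as not entailed, with a warning (out-of-vocabulary
#' predictions).
#'
#' @param candidates data.frame of candidate triples (`subject`, `role`,
#'   `object`), or a named list mapping concept id to such a data.frame.
#' @param reference a [TBox-class] used as the gold ontology.
#' @return a `DefPreReport`: list with `global_precision`, `macro_precision`,
#'   `macro_precision_nonzero`, `per_concept` (data.frame with
#'   `n_candidates`, `n_entailed`, `precision`, `all_entailed`),
#'   `n_zero_precision`, `n_concepts`.
#' @examples
#' cands <- data.frame(subject = "Baritosis", role = "Causative_agent",
#'                     object = "Dust")
#' defPre(cands, baritosisFixture())$global_precision   # 1: entailed
#' @export
defPre <- function(candidates, reference) {
  stopifnot(is(reference, "TBox"))
  if (is.list(candidates) && !is.data.frame(candidates))
    candidates <- do.call(rbind, unname(candidates))
  cand <- unique(data.frame(subject = as.character(candidates$subject),
                            role = as.character(candidates$role),
                            object = as.character(candidates$object),
                            stringsAsFactors = FALSE))
  if (!nrow(cand)) stop("no candidate triples to score", call. = FALSE)
  okC <- cand$subject %in% reference@concepts$id &
         cand$object %in% reference@concepts$id
  okR <- cand$role %in% reference@roles$id
  resolvable <- okC & okR
  if (any(!resolvable))
    warning(sprintf("%d candidate triple(s) reference ids unknown to the reference; scored as not entailed",
                    sum(!resolvable)), call. = FALSE)
  entailed <- logical(nrow(cand))
  if (any(resolvable))
    entailed[resolvable] <- entailsTriple(reference,
                                          cand$subject[resolvable],
                                          cand$role[resolvable],
                                          cand$object[resolvable])
  perConcept <- do.call(rbind, lapply(.csort(cand$subject), function(a) {
    sel <- cand$subject == a
    data.frame(concept = a, n_candidates = sum(sel),
               n_entailed = sum(entailed[sel]),
               precision = sum(entailed[sel]) / sum(sel),
               all_entailed = all(entailed[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(perConcept) <- NULL
  nonzero <- perConcept$precision > 0
  structure(list(
    global_precision = sum(entailed) / nrow(cand),
    macro_precision = mean(perConcept$precision),
    macro_precision_nonzero = if (any(nonzero))
      mean(perConcept$precision[nonzero]) else 0,
    per_concept = perConcept,
    n_zero_precision = sum(!nonzero),
    n_concepts = nrow(perConcept)), class = "DefPreReport")
}

#' @export
print.DefPreReport <- function(x, ...) {
  cat(sprintf(paste0("DefPreReport: global %.3f | macro %.3f ",
                     "(%.3f excluding %d zero-precision concept(s)) ",
                     "over %d concepts\n"),
              x$global_precision, x$macro_precision,
              x$macro_precision_nonzero, x$n_zero_precision, x$n_concepts))
  invisible(x)
}

#' Serialize a DefPre report to JSON
#'
#' @param report a `DefPreReport` from [defPre()].
#' @param path output path.
#' @return `path`, invisibly. Output is byte-deterministic.
#' @export
writeDefPreReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
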