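# Reasoning over the restricted EL fragment: flat primitive inclusions with
# named fillers. Entailment in this fragment reduces to a closed-form closure
# rule: A |= exists R.B holds iff some ancestor A' of A carries an explicit
# existential (R', B') with R' below R in the role hierarchy and B above B'
# in the taxonomy. Completeness for the fragment is enforced by oracle
# equivalence in the test suite rather than assumed.

# child -> parent edges of the taxonomy, pooled over all axioms
.parentEdges <- function(tbox) {
  axs <- tbox@axioms
  child <- character(0); parent <- character(0)
  for (ax in axs) {
    if (length(ax$parents)) {
      child <- c(child, rep(ax$subject, length(ax$parents)))
      parent <- c(parent, ax$parents)
    }
  }
  unique(data.frame(child = child, parent = parent, stringsAsFactors = FALSE))
}

# reflexive-transitive ancestor sets, computed by upward BFS per concept
.closureSets <- function(ids, from, to) {
  up <- split(to, factor(from, levels = ids))
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    seen <- id
    frontier <- id
    while (length(frontier)) {
      nxt <- unique(unlist(up[frontier], use.names = FALSE))
      nxt <- nxt[!nxt %in% seen]
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    out[[id]] <- seen
  }
  out
}

.conceptAncestors <- function(tbox) {
  e <- .parentEdges(tbox)
  .closureSets(tbox@concepts$id, e$child, e$parent)
}

.roleAncestors <- function(tbox) {
  rs <- tbox@roles
  has <- !is.na(rs$parent)
  .closureSets(rs$id, rs$id[has], rs$parent[has])
}

.checkConcept <- function(tbox, id, what = "concept") {
  bad <- !id %in% tbox@concepts$id
  if (any(bad))
    stop(sprintf("unknown %s id: %s", what,
                 paste(unique(id[bad]), collapse = ", ")), call. = FALSE)
}

.checkRole <- function(tbox, id) {
  bad <- !id %in% tbox@roles$id
  if (any(bad))
    stop(sprintf("unknown role id: %s",
                 paste(unique(id[bad]), collapse = ", ")), call. = FALSE)
}

#' Concept subsumption
#'
#' Tests whether `ancestor` subsumes `descendant`, i.e. whether `descendant`
#' reaches `ancestor` through the reflexive-transitive closure of the
#' named-parent edges of the taxonomy. The relation is reflexive:
#' every concept subsumes itself.
#'
#' @param tbox a [TBox-class].
#' @param ancestor,descendant concept ids (vectors of equal length recycle).
#' @return logical vector.
#' @examples
#' tb <- baritosisFixture()
#' subsumes(tb, "Dust", "Barium_dust")    # TRUE
#' subsumes(tb, "Barium_dust", "Dust")    # FALSE
#' @export
subsumes <- function(tbox, ancestor, descendant) {
  stopifnot(is(tbox, "TBox"))
  .checkConcept(tbox, c(ancestor, descendant))
  anc <- .conceptAncestors(tbox)
  n <- max(length(ancestor), length(descendant))
  ancestor <- rep_len(ancestor, n); descendant <- rep_len(descendant, n)
  vapply(seq_len(n), function(i) ancestor[i] %in% anc[[descendant[i]]],
         logical(1))
}

#' Role subsumption
#'
#' Reflexive-transitive closure over role parent edges: `ancestor` role
#' subsumes `descendant` role iff `descendant` reaches `ancestor` via its
#' parent chain. With a flat role set (no parents declared) this is identity.
#'
#' @param tbox a [TBox-class].
#' @param ancestor,descendant role ids.
#' @return logical vector.
#' @export
roleSubsumes <- function(tbox, ancestor, descendant) {
  stopifnot(is(tbox, "TBox"))
  .checkRole(tbox, c(ancestor, descendant))
  ranc <- .roleAncestors(tbox)
  n <- max(length(ancestor), length(descendant))
  ancestor <- rep_len(ancestor, n); descendant <- rep_len(descendant, n)
  vapply(seq_len(n), function(i) ancestor[i] %in% ranc[[descendant[i]]],
         logical(1))
}

#' Explicit relationship base
#'
#' Reads off the triples asserted directly in the axioms: one `A|R|B` per
#' existential conjunct \eqn{\exists R.B} in an axiom for subject `A`.
#'
#' @param tbox a [TBox-class].
#' @return a [RelationshipBase-class] with provenance `"explicit"`.
#' @examples
#' triples(explicitRelationshipBase(baritosisFixture()))
#' @export
explicitRelationshipBase <- function(tbox) {
  stopifnot(is(tbox, "TBox"))
  subject <- character(0); role <- character(0); object <- character(0)
  for (ax in tbox@axioms) {
    if (nrow(ax$existentials)) {
      subject <- c(subject, rep(ax$subject, nrow(ax$existentials)))
      role <- c(role, ax$existentials$role)
      object <- c(object, ax$existentials$filler)
    }
  }
  relationshipBase(data.frame(subject = subject, role = role, object = object,
                              stringsAsFactors = FALSE),
                   provenance = "explicit")
}

#' Inferred relationship base
#'
#' Materializes all entailed existential relationships
#' \eqn{\{A|R|B : \mathrm{TBox} \models A \sqsubseteq \exists R.B\}}
#' in the flat primitive-inclusion fragment. A triple is entailed iff some
#' axiom for an ancestor `A'` of `A` carries an existential `(R', B')` with
#' `R` subsuming `R'` and `B` subsuming `B'`. By monotonicity the explicit
#' base is always a subset of the inferred base.
#'
#' @param tbox a [TBox-class].
#' @return a [RelationshipBase-class] with provenance `"inferred"`.
#' @examples
#' triples(inferredRelationshipBase(baritosisFixture()))
#' @export
inferredRelationshipBase <- function(tbox) {
  stopifnot(is(tbox, "TBox"))
  anc <- .conceptAncestors(tbox)
  ranc <- .roleAncestors(tbox)
  ids <- tbox@concepts$id
  # descendants = inverse of the ancestor map
  desc <- stats::setNames(vector("list", length(ids)), ids)
  for (a in ids) for (p in anc[[a]])
    desc[[p]] <- c(desc[[p]], a)
  subject <- character(0); role <- character(0); object <- character(0)
  for (ax in tbox@axioms) {
    ex <- ax$existentials
    if (!nrow(ex)) next
    subs <- desc[[ax$subject]]
    for (k in seq_len(nrow(ex))) {
      rUp <- ranc[[ex$role[k]]]
      bUp <- anc[[ex$filler[k]]]
      grid <- expand.grid(subject = subs, role = rUp, object = bUp,
                          stringsAsFactors = FALSE)
      subject <- c(subject, grid$subject)
      role <- c(role, grid$role)
      object <- c(object, grid$object)
    }
  }
  relationshipBase(data.frame(subject = subject, role = role, object = object,
                              stringsAsFactors = FALSE),
                   provenance = "inferred")
}

#' Entailment of a single relationship triple
#'
#' Decides `TBox |= subject SubClassOf (role some object)` directly by the
#' closure rule, without materializing the inferred base. Equivalent to
#' membership in [inferredRelationshipBase()].
#'
#' @param tbox a [TBox-class].
#' @param subject,role,object triple components; equal-length vectors are
#'   tested element-wise.
#' @return logical vector.
#' @examples
#' tb <- baritosisFixture()
#' entailsTriple(tb, "Baritosis", "Causative_agent", "Dust")    # TRUE
#' entailsTriple(tb, "Dust", "Causative_agent", "Baritosis")    # FALSE
#' @export
entailsTriple <- function(tbox, subject, role, object) {
  stopifnot(is(tbox, "TBox"))
  .checkConcept(tbox, c(subject, object))
  .checkRole(tbox, role)
  anc <- .conceptAncestors(tbox)
  ranc <- .roleAncestors(tbox)
  axBySubject <- split(tbox@axioms,
                       vapply(tbox@axioms, `[[`, "", "subject"))
  n <- max(length(subject), length(role), length(object))
  subject <- rep_len(subject, n); role <- rep_len(role, n)
  object <- rep_len(object, n)
  vapply(seq_len(n), function(i) {
    for (a in anc[[subject[i]]]) {
      for (ax in axBySubject[[a]] %||% list()) {
        ex <- ax$existentials
        if (!nrow(ex)) next
        for (k in seq_len(nrow(ex))) {
          if (role[i] %in% ranc[[ex$role[k]]] &&
              object[i] %in% anc[[ex$filler[k]]]) return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
}
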