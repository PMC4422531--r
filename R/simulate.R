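# Seeded generator of synthetic terminologies and definitional corpora.
# It reproduces the statistical structure the learning pipeline exploits:
# a taxonomy tree whose top-level subtrees define the semantic types, roles
# with typed (domain, range) signatures whose pairwise overlap is
# controllable, and templated definitional sentences in which a per-role
# lexical pattern connects the two concept mentions, with configurable
# pattern noise. Generators are pure functions of the configuration
# (seed included).

.sylls <- c("ba", "be", "bo", "ca", "ce", "co", "da", "de", "do", "fa",
            "fe", "fo", "ga", "gi", "la", "le", "lo", "ma", "me", "mo",
            "na", "ne", "no", "pa", "pe", "po", "ra", "re", "ro", "sa",
            "se", "so", "ta", "te", "to", "va", "vi", "vo")

.patternPool <- function() {
  as.vector(outer(c("is", "was", "gets", "becomes", "remains"),
                  c("caused by", "linked to", "found in", "associated with",
                    "induced by", "located in", "triggered by", "produced by",
                    "derived from", "observed in", "related to",
                    "confined to"),
                  paste))
}

#' Simulation configuration
#'
#' @param seed integer seed; generators are pure functions of the full
#'   configuration including the seed.
#' @param nConcepts number of concepts in the taxonomy.
#' @param taxonomyBranching target mean children per internal node (soft
#'   constraint shaping the random taxonomy tree).
#' @param nRoles number of roles.
#' @param nTypes number of semantic types; the first `nTypes` concepts are
#'   the type roots and every descendant inherits its root's type.
#' @param typeOverlap theta in \[0, 1\]: target fraction of role pairs
#'   sharing their (domain type, range type) signature. 0 makes all
#'   signatures distinct; 1 collapses them onto one signature.
#' @param patternsPerRole lexical templates assigned to each role.
#' @param patternNoise probability in \[0, 1\] that a sentence uses a
#'   template belonging to a different role.
#' @param sentencesPerTriple sentences generated per relationship triple.
#' @param triplesPerRole explicit existential axioms sampled per role.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(seed = 1L, nConcepts = 60L, taxonomyBranching = 2,
                      nRoles = 3L, nTypes = 6L, typeOverlap = 0,
                      patternsPerRole = 3L, patternNoise = 0,
                      sentencesPerTriple = 2L, triplesPerRole = 12L) {
  stopifnot(nConcepts >= 1, nRoles >= 1, nTypes >= 1, patternsPerRole >= 1,
            sentencesPerTriple >= 1, triplesPerRole >= 1,
            taxonomyBranching >= 1,
            typeOverlap >= 0, typeOverlap <= 1,
            patternNoise >= 0, patternNoise <= 1)
  if (nConcepts < nTypes)
    stop("need at least one concept per semantic type", call. = FALSE)
  structure(list(seed = as.integer(seed), nConcepts = as.integer(nConcepts),
                 taxonomyBranching = taxonomyBranching,
                 nRoles = as.integer(nRoles), nTypes = as.integer(nTypes),
                 typeOverlap = typeOverlap,
                 patternsPerRole = as.integer(patternsPerRole),
                 patternNoise = patternNoise,
                 sentencesPerTriple = as.integer(sentencesPerTriple),
                 triplesPerRole = as.integer(triplesPerRole)),
            class = "SimConfig")
}

.intPartitions <- function(n, maxPart = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (k in seq.int(min(n, maxPart), 1L)) {
    for (rest in .intPartitions(n - k, k))
      out[[length(out) + 1L]] <- c(k, rest)
  }
  out
}

# partition nRoles into signature groups whose fraction of within-group role
# pairs is as close as possible to theta
.signatureGroups <- function(nRoles, theta) {
  if (nRoles == 1L) return(1L)
  parts <- .intPartitions(nRoles)
  frac <- vapply(parts, function(p) sum(choose(p, 2)) / choose(nRoles, 2), 0)
  sizes <- parts[[which.min(abs(frac - theta))]]
  rep(seq_along(sizes), times = sizes)
}

.makeLabel <- function(used) {
  repeat {
    w1 <- paste(sample(.sylls, sample(2:3, 1)), collapse = "")
    lab <- if (runif(1) < 0.4)
      paste(w1, paste(sample(.sylls, 2), collapse = ""))
    else w1
    if (!lab %in% used) return(lab)
  }
}

#' Simulate a typed terminology
#'
#' Generates a random taxonomy tree over `nConcepts` concepts whose first
#' `nTypes` nodes are type roots (their subtrees inherit the type), assigns
#' each role a (domain type, range type) signature with pairwise collision
#' rate as close as possible to `typeOverlap`, and samples
#' `triplesPerRole` flat existential axioms per role connecting
#' type-compatible concepts. Taxonomy edges are recorded as named-parent
#' axioms.
#'
#' @param config a [simConfig()].
#' @return a [TBox-class]. The role signature is recoverable from the types
#'   of the sampled argument pairs.
#' @export
simulateTBox <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$nConcepts
  nT <- config$nTypes
  groups <- .signatureGroups(config$nRoles, config$typeOverlap)
  if (length(unique(groups)) > nT * nT)
    stop(sprintf("infeasible typeOverlap: %d distinct signatures needed but only %d type pairs exist",
                 length(unique(groups)), nT * nT), call. = FALSE)

  ids <- sprintf("C%03d", seq_len(n))
  labels <- character(n)
  for (i in seq_len(n)) labels[i] <- .makeLabel(labels[seq_len(i - 1L)])
  types <- character(n)
  parent <- rep(NA_character_, n)
  children <- integer(n)
  types[seq_len(nT)] <- sprintf("T%02d", seq_len(nT))
  for (i in seq.int(nT + 1L, length.out = n - nT)) {
    pool <- seq_len(i - 1L)
    w <- ifelse(children[pool] < config$taxonomyBranching, 3, 1)
    p <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = w)
    parent[i] <- ids[p]
    children[p] <- children[p] + 1L
    types[i] <- types[p]
  }

  roleIds <- sprintf("R%02d", seq_len(config$nRoles))
  roleLabs <- vapply(seq_len(config$nRoles), function(i)
    paste0("rel", letters[(i - 1L) %% 26L + 1L], i), character(1))
  sigIdx <- sample.int(nT * nT, length(unique(groups)))
  domType <- sprintf("T%02d", (sigIdx - 1L) %/% nT + 1L)
  rngType <- sprintf("T%02d", (sigIdx - 1L) %% nT + 1L)
  sig <- data.frame(role = roleIds, domain = domType[groups],
                    range = rngType[groups], stringsAsFactors = FALSE)

  axs <- list()
  for (i in which(!is.na(parent)))
    axs[[length(axs) + 1L]] <- axiom(ids[i], parents = parent[i])
  for (k in seq_len(nrow(sig))) {
    dom <- ids[types == sig$domain[k]]
    rng <- ids[types == sig$range[k]]
    pairs <- expand.grid(A = dom, B = rng, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$A != pairs$B, , drop = FALSE]
    if (!nrow(pairs))
      stop(sprintf("no type-compatible concept pair for role %s", roleIds[k]),
           call. = FALSE)
    take <- pairs[sample.int(nrow(pairs), min(config$triplesPerRole,
                                              nrow(pairs))), , drop = FALSE]
    for (j in seq_len(nrow(take)))
      axs[[length(axs) + 1L]] <- axiom(
        take$A[j],
        existentials = data.frame(role = sig$role[k], filler = take$B[j],
                                  stringsAsFactors = FALSE))
  }

  TBox(concepts = data.frame(id = ids, label = labels, semantic_type = types,
                             stringsAsFactors = FALSE),
       roles = data.frame(id = roleIds, label = roleLabs,
                          parent = NA_character_, stringsAsFactors = FALSE),
       axioms = axs)
}

.rolePatterns <- function(config) {
  pool <- .patternPool()
  need <- config$nRoles * config$patternsPerRole
  if (need > length(pool))
    stop(sprintf("patternsPerRole too large: %d templates needed, %d available",
                 need, length(pool)), call. = FALSE)
  picked <- sample(pool, need)
  split(picked, rep(seq_len(config$nRoles), each = config$patternsPerRole))
}

#' Simulate a definitional corpus from a relationship base
#'
#' For every triple of the base, generates `sentencesPerTriple` sentences of
#' the form `<subject label> <template> <object label>.` where the template
#' is drawn from the triple's role (or, with probability `patternNoise`,
#' from a different role). Mentions are annotated exactly, so the gold
#' instances returned alongside are recoverable by alignment.
#'
#' @param tbox a [TBox-class] (typically from [simulateTBox()]).
#' @param rb a non-empty [RelationshipBase-class] to verbalize.
#' @param config the [simConfig()] used throughout the simulation.
#' @return list with `corpus` (a [Corpus-class]) and `gold` (an instance
#'   data.frame in the layout of [alignCorpus()]).
#' @export
simulateCorpus <- function(tbox, rb, config) {
  stopifnot(is(tbox, "TBox"), is(rb, "RelationshipBase"),
            inherits(config, "SimConfig"))
  tr <- rb@triples
  if (!nrow(tr)) stop("relationship base is empty", call. = FALSE)
  set.seed(config$seed + 1L)
  pats <- .rolePatterns(config)
  roleIds <- tbox@roles$id
  labMap <- stats::setNames(tbox@concepts$label, tbox@concepts$id)
  typeMap <- stats::setNames(tbox@concepts$semantic_type, tbox@concepts$id)
  sents <- list()
  gold <- list()
  for (i in seq_len(nrow(tr))) {
    for (s in seq_len(config$sentencesPerTriple)) {
      srcRole <- match(tr$role[i], roleIds)
      if (length(roleIds) > 1L && runif(1) < config$patternNoise) {
        srcRole <- sample(setdiff(seq_along(roleIds), srcRole), 1L)
      }
      tpl <- sample(pats[[srcRole]], 1L)
      sLab <- labMap[[tr$subject[i]]]
      oLab <- labMap[[tr$object[i]]]
      text <- paste0(sLab, " ", tpl, " ", oLab, ".")
      sStart <- 0L
      oStart <- nchar(sLab) + 1L + nchar(tpl) + 1L
      sents[[length(sents) + 1L]] <- annotatedSentence(
        text,
        data.frame(concept = c(tr$subject[i], tr$object[i]),
                   start = c(sStart, oStart),
                   end = c(nchar(sLab), oStart + nchar(oLab)),
                   stringsAsFactors = FALSE),
        source = "synthetic")
      gold[[length(gold) + 1L]] <- data.frame(
        sentence_index = length(sents), subject = tr$subject[i],
        object = tr$object[i],
        subject_type = unname(typeMap[tr$subject[i]]),
        object_type = unname(typeMap[tr$object[i]]),
        label = tr$role[i], between = tolower(tpl),
        subject_start = sStart, object_start = oStart, order = "SO",
        stringsAsFactors = FALSE)
    }
  }
  list(corpus = corpus(sents), gold = do.call(rbind, gold))
}

#' Simulate a coherent end-to-end benchmark
#'
#' One call producing a terminology, its explicit and inferred relationship
#' bases, a definitional corpus verbalizing the inferred base, and the gold
#' relation instances. All artifacts are mutually consistent: gold labels
#' are members of the inferred base, the explicit base is a subset of the
#' inferred one, and every corpus mention resolves against the terminology.
#'
#' @param config a [simConfig()].
#' @return list with elements `tbox`, `corpus`, `gold`, `exprb`, `infrb`.
#' @examples
#' bench <- simulateBenchmark(simConfig(seed = 7, nConcepts = 20,
#'                                      triplesPerRole = 3))
#' nrow(triples(bench$exprb)) <= nrow(triples(bench$infrb))
#' @export
simulateBenchmark <- function(config = simConfig()) {
  tbox <- simulateTBox(config)
  exprb <- explicitRelationshipBase(tbox)
  infrb <- inferredRelationshipBase(tbox)
  sim <- simulateCorpus(tbox, infrb, config)
  list(tbox = tbox, corpus = sim$corpus, gold = sim$gold,
       exprb = exprb, infrb = infrb)
}
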