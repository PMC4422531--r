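# TSV dialect for terminologies and pipe-separated triple files.
#
# concepts.tsv: id<TAB>label<TAB>semantic_type
# roles.tsv:    id<TAB>label<TAB>parent_id      (third column optional/empty)
# axioms.tsv:   subject<TAB>parent_ids<TAB>existentials
#               parent_ids: comma-separated concept ids
#               existentials: comma-separated role_id:filler_id pairs
# '#' starts a comment line; UTF-8 throughout.

.readRecords <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^[[:space:]]*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.fields <- function(line, n) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < n) f <- c(f, rep("", n - length(f)))
  trimws(f[seq_len(n)])
}

#' Parse a TBox from its three TSV files
#'
#' @param conceptsFile path to `concepts.tsv` (`id`, `label`,
#'   `semantic_type`).
#' @param rolesFile path to `roles.tsv` (`id`, `label`, optional `parent_id`).
#' @param axiomsFile path to `axioms.tsv` (`subject`, comma-separated parent
#'   ids, comma-separated `role:filler` pairs; either of the last two columns
#'   may be empty but not both).
#' @return a validated [TBox-class]. Unresolvable references raise an error
#'   naming the offending file line; a cyclic taxonomy raises a validation
#'   error.
#' @seealso [writeTBox()]
#' @export
parseTBox <- function(conceptsFile, rolesFile, axiomsFile) {
  cr <- .readRecords(conceptsFile)
  cid <- clab <- ctype <- character(length(cr$lines))
  for (i in seq_along(cr$lines)) {
    f <- .fields(cr$lines[i], 3)
    if (!nzchar(f[1]) || !nzchar(f[3]))
      stop(sprintf("%s line %d: concept needs non-empty id and semantic type",
                   conceptsFile, cr$lineno[i]), call. = FALSE)
    cid[i] <- f[1]; clab[i] <- f[2]; ctype[i] <- f[3]
  }
  if (anyDuplicated(cid))
    stop(sprintf("%s: duplicate concept id '%s'", conceptsFile,
                 cid[duplicated(cid)][1]), call. = FALSE)

  rr <- .readRecords(rolesFile)
  rid <- rlab <- rpar <- character(length(rr$lines))
  for (i in seq_along(rr$lines)) {
    f <- .fields(rr$lines[i], 3)
    if (!nzchar(f[1]))
      stop(sprintf("%s line %d: role needs a non-empty id",
                   rolesFile, rr$lineno[i]), call. = FALSE)
    rid[i] <- f[1]; rlab[i] <- f[2]; rpar[i] <- f[3]
  }
  for (i in seq_along(rid)) {
    if (nzchar(rpar[i]) && !rpar[i] %in% rid)
      stop(sprintf("%s line %d: unknown parent role '%s'",
                   rolesFile, rr$lineno[i], rpar[i]), call. = FALSE)
  }

  ar <- .readRecords(axiomsFile)
  axs <- vector("list", length(ar$lines))
  for (i in seq_along(ar$lines)) {
    f <- .fields(ar$lines[i], 3)
    ln <- ar$lineno[i]
    if (!f[1] %in% cid)
      stop(sprintf("%s line %d: unknown subject concept '%s'",
                   axiomsFile, ln, f[1]), call. = FALSE)
    parents <- if (nzchar(f[2])) trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
               else character(0)
    parents <- parents[nzchar(parents)]
    for (p in parents) if (!p %in% cid)
      stop(sprintf("%s line %d: unknown parent concept '%s'", axiomsFile, ln, p),
           call. = FALSE)
    ex <- .emptyExistentials()
    if (nzchar(f[3])) {
      pairs <- trimws(strsplit(f[3], ",", fixed = TRUE)[[1]])
      pairs <- pairs[nzchar(pairs)]
      for (p in pairs) {
        sep <- regexpr(":", p, fixed = TRUE)
        if (sep < 0)
          stop(sprintf("%s line %d: existential '%s' is not role:filler",
                       axiomsFile, ln, p), call. = FALSE)
        r <- trimws(substr(p, 1, sep - 1)); b <- trimws(substr(p, sep + 1, nchar(p)))
        if (!r %in% rid)
          stop(sprintf("%s line %d: unknown role '%s'", axiomsFile, ln, r),
               call. = FALSE)
        if (!b %in% cid)
          stop(sprintf("%s line %d: unknown filler concept '%s'",
                       axiomsFile, ln, b), call. = FALSE)
        ex <- rbind(ex, data.frame(role = r, filler = b,
                                   stringsAsFactors = FALSE))
      }
    }
    if (!length(parents) && !nrow(ex))
      stop(sprintf("%s line %d: axiom with neither parents nor existentials",
                   axiomsFile, ln), call. = FALSE)
    axs[[i]] <- axiom(f[1], parents, ex)
  }

  TBox(concepts = data.frame(id = cid, label = clab, semantic_type = ctype,
                             stringsAsFactors = FALSE),
       roles = data.frame(id = rid, label = rlab,
                          parent = ifelse(nzchar(rpar), rpar, NA_character_),
                          stringsAsFactors = FALSE),
       axioms = axs)
}

.existentialField <- function(ex) {
  if (!nrow(ex)) return("")
  paste(paste0(ex$role, ":", ex$filler), collapse = ",")
}

#' Write a TBox to its three TSV files
#'
#' Inverse of [parseTBox()].
#'
#' @param tbox a [TBox-class].
#' @param conceptsFile,rolesFile,axiomsFile output paths.
#' @return invisibly, the three paths.
#' @export
writeTBox <- function(tbox, conceptsFile, rolesFile, axiomsFile) {
  stopifnot(is(tbox, "TBox"))
  cs <- tbox@concepts
  writeLines(paste(cs$id, cs$label, cs$semantic_type, sep = "\t"),
             conceptsFile, useBytes = TRUE)
  rs <- tbox@roles
  writeLines(paste(rs$id, rs$label,
                   ifelse(is.na(rs$parent), "", rs$parent), sep = "\t"),
             rolesFile, useBytes = TRUE)
  axLines <- vapply(tbox@axioms, function(ax) {
    paste(ax$subject,
          paste(ax$parents, collapse = ","),
          .existentialField(ax$existentials),
          sep = "\t")
  }, character(1))
  writeLines(axLines, axiomsFile, useBytes = TRUE)
  invisible(c(conceptsFile, rolesFile, axiomsFile))
}

#' Read and write pipe-separated triple files
#'
#' Triple files carry one `A|R|B` per line, pipe-separated. `readTriples()`
#' returns a data.frame; `readRelationshipBase()` wraps it in a
#' [RelationshipBase-class]; `writeTriples()` accepts either form.
#'
#' @param path file path.
#' @param x a triple data.frame (`subject`, `role`, `object`) or a
#'   [RelationshipBase-class].
#' @param provenance provenance tag for `readRelationshipBase()`.
#' @return `readTriples()`: data.frame with columns `subject`, `role`,
#'   `object`.
#' @name tripleIO
NULL

#' @rdname tripleIO
#' @export
readTriples <- function(path) {
  rec <- .readRecords(path)
  out <- .emptyTriples()
  if (!length(rec$lines)) return(out)
  parts <- strsplit(rec$lines, "|", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad))
    stop(sprintf("%s line %d: expected 'A|R|B'", path,
                 rec$lineno[which(bad)[1]]), call. = FALSE)
  data.frame(subject = trimws(vapply(parts, `[[`, "", 1)),
             role = trimws(vapply(parts, `[[`, "", 2)),
             object = trimws(vapply(parts, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' @rdname tripleIO
#' @export
readRelationshipBase <- function(path, provenance = "external") {
  relationshipBase(readTriples(path), provenance = provenance)
}

#' @rdname tripleIO
#' @export
writeTriples <- function(x, path) {
  tr <- if (is(x, "RelationshipBase")) x@triples else x
  writeLines(paste(tr$subject, tr$role, tr$object, sep = "|"), path,
             useBytes = TRUE)
  invisible(path)
}
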