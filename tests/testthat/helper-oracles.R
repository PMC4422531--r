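# Independent oracles and generators used across the suite.

# Brute-force entailment oracle: enumerate every (A, R, B) candidate and test
# it by path enumeration in the taxonomy / role graphs, with reachability
# delegated to igraph (independent of the package's own BFS closure).
oracleInferredTriples <- function(tbox) {
  cs <- concepts(tbox)$id
  axs <- axioms(tbox)
  eds <- do.call(rbind, lapply(axs, function(a)
    if (length(a$parents))
      data.frame(from = a$subject, to = a$parents, stringsAsFactors = FALSE)
    else NULL))
  g <- if (is.null(eds))
    igraph::make_empty_graph(directed = TRUE) + igraph::vertices(cs)
  else igraph::graph_from_data_frame(eds, directed = TRUE,
                                     vertices = data.frame(name = cs))
  reach <- lapply(cs, function(v)
    names(igraph::subcomponent(g, v, mode = "out")))
  names(reach) <- cs
  rs <- roles(tbox)
  reds <- rs[!is.na(rs$parent), , drop = FALSE]
  rg <- if (!nrow(reds))
    igraph::make_empty_graph(directed = TRUE) + igraph::vertices(rs$id)
  else igraph::graph_from_data_frame(
    data.frame(from = reds$id, to = reds$parent, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = rs$id))
  rreach <- lapply(rs$id, function(v)
    names(igraph::subcomponent(rg, v, mode = "out")))
  names(rreach) <- rs$id
  out <- character(0)
  for (A in cs) for (R in rs$id) for (B in cs) {
    hit <- FALSE
    for (ax in axs) {
      if (!ax$subject %in% reach[[A]]) next
      ex <- ax$existentials
      for (k in seq_len(nrow(ex))) {
        if (R %in% rreach[[ex$role[k]]] && B %in% reach[[ex$filler[k]]]) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (hit) out <- c(out, paste(A, R, B, sep = "|"))
  }
  sort(out, method = "radix")
}

tripleKeys <- function(rb) {
  tr <- triples(rb)
  sort(paste(tr$subject, tr$role, tr$object, sep = "|"), method = "radix")
}

# Random small terminologies (<= 15 concepts, <= 3 roles, <= 2 existentials
# per axiom): parents always point to earlier ids, so the taxonomy is a DAG.
randomTBox <- function(seed) {
  set.seed(seed)
  n <- sample(3:15, 1)
  ids <- sprintf("N%02d", seq_len(n))
  nr <- sample(1:3, 1)
  rids <- sprintf("R%d", seq_len(nr))
  rparent <- rep(NA_character_, nr)
  if (nr > 1) for (i in 2:nr)
    if (runif(1) < 0.4) rparent[i] <- rids[sample.int(i - 1, 1)]
  axs <- list()
  for (i in seq_len(n)) {
    parents <- character(0)
    if (i > 1 && runif(1) < 0.7)
      parents <- sample(ids[seq_len(i - 1)], min(sample(1:2, 1), i - 1))
    nex <- sample(0:2, 1)
    ex <- data.frame(role = character(0), filler = character(0),
                     stringsAsFactors = FALSE)
    if (nex > 0)
      ex <- data.frame(role = sample(rids, nex, replace = TRUE),
                       filler = sample(ids, nex, replace = TRUE),
                       stringsAsFactors = FALSE)
    if (!length(parents) && !nrow(ex)) next
    axs[[length(axs) + 1]] <- axiom(ids[i], parents, ex)
  }
  TBox(concepts = data.frame(id = ids, label = tolower(ids),
                             semantic_type = "thing",
                             stringsAsFactors = FALSE),
       roles = data.frame(id = rids, label = rids, parent = rparent,
                          stringsAsFactors = FALSE),
       axioms = axs)
}

# Minimal sparse-ARFF reader used as the round-trip oracle for writeArff().
# Handles quoted attribute names (which may contain spaces and commas in the
# header); nominal class values are assumed comma-free, as role ids are.
parseSparseArff <- function(path) {
  lines <- readLines(path)
  unquote <- function(x) {
    x <- trimws(x)
    if (startsWith(x, "'")) gsub("\\\\'", "'", substr(x, 2, nchar(x) - 1))
    else x
  }
  dataAt <- which(trimws(lines) == "@data")
  attrs <- character(0)
  classes <- character(0)
  for (l in lines[seq_len(dataAt - 1)]) {
    l <- trimws(l)
    if (!startsWith(l, "@attribute")) next
    rest <- trimws(substring(l, nchar("@attribute") + 1))
    if (grepl("\\{", rest)) {
      vals <- sub("\\}\\s*$", "", sub("^[^{]*\\{", "", rest))
      classes <- unname(vapply(strsplit(vals, ",", fixed = TRUE)[[1]],
                               unquote, ""))
      attrs <- c(attrs, unquote(trimws(sub("\\{.*$", "", rest))))
    } else {
      attrs <- c(attrs, unquote(sub("\\s+numeric\\s*$", "", rest)))
    }
  }
  rows <- lines[(dataAt + 1):length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  k <- length(attrs) - 1L
  mat <- matrix(0, length(rows), k)
  colnames(mat) <- attrs[seq_len(k)]
  labs <- character(length(rows))
  for (i in seq_along(rows)) {
    body <- sub("^\\s*\\{", "", sub("\\}\\s*$", "", rows[i]))
    for (e in strsplit(body, ",", fixed = TRUE)[[1]]) {
      e <- trimws(e)
      sp <- regexpr(" ", e, fixed = TRUE)
      idx <- as.integer(substr(e, 1, sp - 1))
      val <- unquote(substring(e, sp + 1))
      if (idx == k) labs[i] <- val else mat[i, idx + 1L] <- as.numeric(val)
    }
  }
  list(attributes = attrs, matrix = mat, labels = labs, classes = classes)
}

# The printed example sentence with its two mentions supplied directly.
exampleSentence <- function() {
  annotatedSentence(
    "Baritosis is pneumoconiosis caused by barium dust",
    data.frame(concept = c("Baritosis", "Barium_dust"),
               start = c(0L, 38L), end = c(9L, 49L),
               stringsAsFactors = FALSE),
    source = "worked-example")
}

writeFixtureTBoxFiles <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("# demo terminology",
               "Baritosis\tBaritosis\tdisorder",
               "Pneumoconiosis\tpneumoconiosis\tdisorder",
               "Barium_dust\tbarium dust\tsubstance",
               "Dust\tdust\tsubstance"),
             file.path(dir, "concepts.tsv"))
  writeLines("Causative_agent\tcaused by\t", file.path(dir, "roles.tsv"))
  writeLines(c("Baritosis\tPneumoconiosis\tCausative_agent:Barium_dust",
               "Barium_dust\tDust\t"),
             file.path(dir, "axioms.tsv"))
  dir
}
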