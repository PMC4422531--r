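# Assembly of triples into EL axioms and DefPre scoring.

test_that("assembly reproduces the classic two-triple definition", {
  tr <- data.frame(subject = "Baritosis",
                   role = c("Isa", "Causative_agent"),
                   object = c("Pneumoconiosis", "Barium_dust"),
                   stringsAsFactors = FALSE)
  d <- assembleDefinition("Baritosis", tr, isaRole = "Isa")
  expect_equal(d@namedParents, "Pneumoconiosis")
  expect_equal(d@existentials,
               data.frame(role = "Causative_agent", filler = "Barium_dust",
                          stringsAsFactors = FALSE))
  expect_equal(renderDefinition(d),
               "Baritosis SubClassOf Pneumoconiosis and (Causative_agent some Barium_dust)")
  expect_equal(nrow(readBackTriples(d, isaRole = "Isa")), 2L)
})

test_that("a single non-isa triple gives the base existential form", {
  tr <- data.frame(subject = "A", role = "R", object = "B")
  d <- assembleDefinition("A", tr)
  expect_length(d@namedParents, 0L)
  expect_equal(renderDefinition(d), "A SubClassOf (R some B)")
})

test_that("multi-relation definitions keep every existential conjunct", {
  # five predicted triples, two roles repeated with different fillers
  tr <- data.frame(
    subject = "Fox_Fordyce",
    role = c("Finding_site", "Finding_site", "Causative_agent",
             "Causative_agent", "Associated_morphology"),
    object = c("Apocrine_glands", "Apocrine_ducts", "Obstruction",
               "Rupture", "Papular_eruptions"),
    stringsAsFactors = FALSE)
  d <- assembleDefinition("Fox_Fordyce", tr)
  expect_equal(nrow(d@existentials), 5L)
  expect_length(d@namedParents, 0L)
})

test_that("assembly rejects empty and mixed-subject triple sets", {
  expect_error(assembleDefinition("A", data.frame(subject = character(0),
                                                  role = character(0),
                                                  object = character(0))),
               "empty")
  expect_error(assembleDefinition("A", data.frame(subject = c("A", "B"),
                                                  role = "R", object = "C")),
               "share")
})

test_that("read-back inverts assembly on random triple sets", {
  set.seed(123)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    tr <- data.frame(subject = "S",
                     role = sample(c("Isa", "R1", "R2"), k, replace = TRUE),
                     object = sample(sprintf("B%d", 1:4), k, replace = TRUE),
                     stringsAsFactors = FALSE)
    d <- assembleDefinition("S", tr, isaRole = "Isa")
    dedup <- unique(tr)
    dedup <- dedup[order(dedup$subject, dedup$role, dedup$object,
                         method = "radix"), ]
    rownames(dedup) <- NULL
    expect_equal(readBackTriples(d, isaRole = "Isa"), dedup)
  }
})

test_that("parents-only definitions without an is-a role warn on read-back", {
  d <- candidateDefinition("A", namedParents = "B")
  expect_warning(tr <- readBackTriples(d), "named parents")
  expect_equal(nrow(tr), 0L)
})

test_that("simplification drops conjuncts subsumed within the definition", {
  tb <- baritosisFixture()
  d1 <- candidateDefinition("Baritosis",
                            namedParents = c("Dust", "Barium_dust"))
  expect_equal(simplifyDefinition(d1, tb)@namedParents, "Barium_dust")

  d2 <- candidateDefinition("Baritosis", existentials = data.frame(
    role = "Causative_agent", filler = c("Dust", "Barium_dust")))
  s2 <- simplifyDefinition(d2, tb)
  expect_equal(s2@existentials$filler, "Barium_dust")
  # idempotent
  expect_equal(simplifyDefinition(s2, tb), s2)
  # already minimal: unchanged
  d3 <- candidateDefinition("Baritosis", namedParents = "Pneumoconiosis")
  expect_equal(simplifyDefinition(d3, tb), d3)
})

test_that("simplification preserves the entailed consequences", {
  tb <- baritosisFixture()
  d <- candidateDefinition("Baritosis", existentials = data.frame(
    role = "Causative_agent", filler = c("Dust", "Barium_dust")))
  consequences <- function(def) {
    tbx <- TBox(concepts(tb), roles(tb),
                c(axioms(tb)[-1],   # replace the Baritosis axiom
                  list(axiom(def@subject, def@namedParents,
                             def@existentials))))
    tr <- triples(inferredRelationshipBase(tbx))
    tr <- tr[tr$subject == def@subject, ]
    paste(tr$subject, tr$role, tr$object, sep = "|")
  }
  expect_setequal(consequences(simplifyDefinition(d, tb)), consequences(d))
})

test_that("DefPre scores candidates by entailment, not explicit mention", {
  tb <- baritosisFixture()
  rep1 <- defPre(data.frame(subject = "Baritosis", role = "Causative_agent",
                            object = "Dust"), tb)
  expect_equal(rep1$global_precision, 1.0)   # inferred, though never asserted

  tb2 <- TBox(concepts(tb),
              rbind(roles(tb),
                    data.frame(id = "Finding_site", label = "found in",
                               parent = NA_character_)),
              axioms(tb))
  cands <- data.frame(subject = "Baritosis",
                      role = c("Causative_agent", "Finding_site"),
                      object = "Dust", stringsAsFactors = FALSE)
  rep2 <- defPre(cands, tb2)
  expect_equal(rep2$global_precision, 0.5)
  expect_equal(rep2$macro_precision, 0.5)
  expect_equal(rep2$n_zero_precision, 0L)
})

test_that("zero-precision concepts are counted and averaged both ways", {
  tb <- baritosisFixture()
  cands <- data.frame(
    subject = c("Baritosis", "Pneumoconiosis"),
    role = "Causative_agent",
    object = c("Barium_dust", "Baritosis"),  # second is wrong
    stringsAsFactors = FALSE)
  rep <- defPre(cands, tb)
  expect_equal(rep$n_zero_precision, 1L)
  expect_equal(rep$macro_precision, 0.5)          # zeros included
  expect_equal(rep$macro_precision_nonzero, 1.0)  # zeros excluded
  expect_equal(rep$global_precision, 0.5)
  expect_equal(rep$per_concept$all_entailed, c(TRUE, FALSE))
})

test_that("explicit candidates always score a perfect DefPre", {
  for (seed in c(2, 14)) {
    tb <- randomTBox(seed)
    exp <- triples(explicitRelationshipBase(tb))
    if (!nrow(exp)) next
    rep <- defPre(exp, tb)
    expect_equal(rep$global_precision, 1.0)
    expect_equal(rep$macro_precision, 1.0)
  }
})

test_that("DefPre is monotone under reference growth", {
  tb <- baritosisFixture()
  cands <- data.frame(subject = c("Baritosis", "Baritosis"),
                      role = "Causative_agent",
                      object = c("Dust", "Pneumoconiosis"),
                      stringsAsFactors = FALSE)
  before <- defPre(cands, tb)
  grown <- TBox(concepts(tb), roles(tb), c(axioms(tb), list(
    axiom("Baritosis", existentials = data.frame(
      role = "Causative_agent", filler = "Pneumoconiosis")))))
  after <- defPre(cands, grown)
  expect_gte(after$global_precision, before$global_precision)
  expect_gte(after$macro_precision, before$macro_precision)
})

test_that("out-of-vocabulary candidates score as not entailed with a warning", {
  tb <- baritosisFixture()
  cands <- data.frame(subject = c("Baritosis", "Martian_flu"),
                      role = "Causative_agent",
                      object = c("Barium_dust", "Dust"),
                      stringsAsFactors = FALSE)
  expect_warning(rep <- defPre(cands, tb), "unknown to the reference")
  expect_equal(rep$global_precision, 0.5)
})

test_that("definition serializations round-trip and render readably", {
  defs <- list(
    candidateDefinition("Baritosis", "Pneumoconiosis",
                        data.frame(role = "Causative_agent",
                                   filler = "Barium_dust")),
    candidateDefinition("Barium_dust", "Dust"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDefinitions(defs, tsv, "tsv")
  dir <- writeFixtureTBoxFiles(withr::local_tempdir())
  tb <- parseTBox(file.path(dir, "concepts.tsv"), file.path(dir, "roles.tsv"),
                  tsv)   # machine round-trip through the axiom dialect
  expect_length(axioms(tb), 2L)
  expect_equal(axioms(tb)[[1]]$parents, "Pneumoconiosis")
  txt <- withr::local_tempfile(fileext = ".txt")
  writeDefinitions(defs, txt, "text")
  expect_equal(readLines(txt)[2], "Barium_dust SubClassOf Dust")
})
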