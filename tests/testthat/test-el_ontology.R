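# Reasoning over the restricted EL fragment.

test_that("parseTBox reads the TSV dialect and enforces referential integrity", {
  dir <- writeFixtureTBoxFiles(withr::local_tempdir())
  tb <- parseTBox(file.path(dir, "concepts.tsv"), file.path(dir, "roles.tsv"),
                  file.path(dir, "axioms.tsv"))
  expect_equal(nrow(concepts(tb)), 4L)
  expect_equal(nrow(roles(tb)), 1L)
  expect_length(axioms(tb), 2L)
  expect_equal(concepts(tb)$semantic_type[concepts(tb)$id == "Baritosis"],
               "disorder")

  # degenerate: one concept, no axioms
  writeLines("A\ta\tt", file.path(dir, "c1.tsv"))
  writeLines(character(0), file.path(dir, "r0.tsv"))
  writeLines(character(0), file.path(dir, "a0.tsv"))
  tb1 <- parseTBox(file.path(dir, "c1.tsv"), file.path(dir, "r0.tsv"),
                   file.path(dir, "a0.tsv"))
  expect_equal(nrow(concepts(tb1)), 1L)
  expect_length(axioms(tb1), 0L)

  # axiom referencing an undeclared concept: load error naming the line
  writeLines("A\tB\t", file.path(dir, "a_bad.tsv"))
  expect_error(parseTBox(file.path(dir, "c1.tsv"), file.path(dir, "r0.tsv"),
                         file.path(dir, "a_bad.tsv")),
               "line 1.*unknown parent concept")

  # taxonomy cycle: validation error
  writeLines(c("A\ta\tt", "B\tb\tt"), file.path(dir, "c2.tsv"))
  writeLines(c("A\tB\t", "B\tA\t"), file.path(dir, "a_cyc.tsv"))
  expect_error(parseTBox(file.path(dir, "c2.tsv"), file.path(dir, "r0.tsv"),
                         file.path(dir, "a_cyc.tsv")),
               "cycle")
})

test_that("subsumption follows the reflexive-transitive named-parent closure", {
  tb <- baritosisFixture()
  expect_true(subsumes(tb, "Dust", "Barium_dust"))
  expect_true(subsumes(tb, "Baritosis", "Baritosis"))
  expect_false(subsumes(tb, "Barium_dust", "Dust"))
  expect_true(subsumes(tb, "Pneumoconiosis", "Baritosis"))
  expect_error(subsumes(tb, "Dust", "NoSuchThing"), "unknown concept")
})

test_that("role subsumption follows the role parent chain", {
  tb <- TBox(concepts = data.frame(id = "A", label = "a", semantic_type = "t"),
             roles = data.frame(id = c("R2", "R1"), label = c("r2", "r1"),
                                parent = c(NA, "R2")),
             axioms = list(axiom("A", existentials = data.frame(role = "R1",
                                                                filler = "A"))))
  expect_true(roleSubsumes(tb, "R1", "R1"))
  expect_true(roleSubsumes(tb, "R2", "R1"))
  expect_false(roleSubsumes(tb, "R1", "R2"))
  # the hierarchy propagates into entailment: A|R1|A explicit implies A|R2|A
  expect_true(entailsTriple(tb, "A", "R2", "A"))
})

test_that("explicit base reads off existential conjuncts with set semantics", {
  tb <- baritosisFixture()
  exp <- explicitRelationshipBase(tb)
  expect_equal(provenance(exp), "explicit")
  expect_equal(triples(exp),
               data.frame(subject = "Baritosis", role = "Causative_agent",
                          object = "Barium_dust", stringsAsFactors = FALSE))

  # only taxonomic axioms -> empty base
  tax <- TBox(concepts = data.frame(id = c("A", "B"), label = c("a", "b"),
                                    semantic_type = "t"),
              axioms = list(axiom("A", parents = "B")))
  expect_equal(nrow(triples(explicitRelationshipBase(tax))), 0L)

  # two axioms sharing one existential -> the triple appears once
  ex <- data.frame(role = "Causative_agent", filler = "Dust")
  dup <- TBox(concepts = concepts(tb), roles = roles(tb),
              axioms = list(axiom("Baritosis", existentials = ex),
                            axiom("Baritosis", parents = "Pneumoconiosis",
                                  existentials = ex)))
  expect_equal(nrow(triples(explicitRelationshipBase(dup))), 1L)
})

test_that("inferred base lifts fillers through the taxonomy", {
  tb <- baritosisFixture()
  inf <- inferredRelationshipBase(tb)
  keys <- tripleKeys(inf)
  expect_true("Baritosis|Causative_agent|Dust" %in% keys)
  expect_equal(keys, c("Baritosis|Causative_agent|Barium_dust",
                       "Baritosis|Causative_agent|Dust"))
  expect_true(all(tripleKeys(explicitRelationshipBase(tb)) %in% keys))
})

test_that("entailsTriple agrees with inferred-base membership", {
  tb <- baritosisFixture()
  expect_true(entailsTriple(tb, "Baritosis", "Causative_agent", "Dust"))
  expect_true(entailsTriple(tb, "Baritosis", "Causative_agent", "Barium_dust"))
  expect_false(entailsTriple(tb, "Dust", "Causative_agent", "Baritosis"))
  expect_error(entailsTriple(tb, "Baritosis", "Finding_site", "Dust"),
               "unknown role")
})

test_that("inferred base matches the brute-force oracle on random terminologies", {
  for (seed in 1:50) {
    tb <- randomTBox(seed)
    got <- tripleKeys(inferredRelationshipBase(tb))
    expect_identical(got, oracleInferredTriples(tb),
                     label = sprintf("seed %d", seed))
    expect_true(all(tripleKeys(explicitRelationshipBase(tb)) %in% got),
                label = sprintf("monotonicity, seed %d", seed))
    # pointwise entailment is consistent with the materialized base
    tr <- triples(inferredRelationshipBase(tb))
    if (nrow(tr))
      expect_true(all(entailsTriple(tb, tr$subject, tr$role, tr$object)))
  }
})

test_that("subsumption is reflexive and transitive on random terminologies", {
  for (seed in c(3, 11, 27)) {
    tb <- randomTBox(seed)
    ids <- concepts(tb)$id
    expect_true(all(subsumes(tb, ids, ids)))
    for (a in ids) for (b in ids) for (c in ids) {
      if (subsumes(tb, a, b) && subsumes(tb, b, c))
        expect_true(subsumes(tb, a, c))
    }
  }
})

test_that("inferred base is invariant under axiom reordering", {
  for (seed in c(5, 19)) {
    tb <- randomTBox(seed)
    set.seed(seed + 1000)
    perm <- sample(seq_along(axioms(tb)))
    tb2 <- TBox(concepts(tb), roles(tb), axioms(tb)[perm])
    expect_identical(tripleKeys(inferredRelationshipBase(tb)),
                     tripleKeys(inferredRelationshipBase(tb2)))
  }
})

test_that("TBox validity rejects broken inputs", {
  cs <- data.frame(id = c("A", "B"), label = c("a", "b"), semantic_type = "t")
  expect_error(TBox(cs, axioms = list(axiom("A"))), "empty")
  expect_error(TBox(data.frame(id = c("A", "A"), label = "a",
                               semantic_type = "t")),
               "duplicate")
  expect_error(TBox(cs, axioms = list(axiom("C", parents = "A"))),
               "unknown subject")
  expect_error(TBox(cs, axioms = list(axiom("A", parents = "B"),
                                      axiom("B", parents = "A"))),
               "cycle")
})
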