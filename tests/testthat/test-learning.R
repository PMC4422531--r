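# Relation classification and cross-validated macro-F evaluation.

separableToy <- function() {
  feats <- list(c("ltype:t1", "rtype:t2"), c("ltype:t1", "rtype:t2"),
                c("ltype:t3", "rtype:t4"), c("ltype:t3", "rtype:t4"))
  list(features = feats, labels = c("R1", "R1", "R2", "R2"))
}

test_that("a separable two-class toy is fit perfectly", {
  toy <- separableToy()
  m <- trainRelationModel(toy$features, toy$labels)
  expect_equal(predictRelations(m, toy$features), toy$labels)
})

test_that("disjoint type pairs make classes separable from two features each", {
  bench <- simulateBenchmark(simConfig(seed = 4))   # typeOverlap = 0
  inst <- alignCorpus(bench$corpus, bench$infrb, bench$tbox)
  fs <- vectorizeInstances(inst, featureSpec(lexicalMode = "none"),
                           typeAssignment(bench$tbox))
  model <- trainRelationModel(fs)
  expect_equal(predictRelations(model, fs), fs$labels)  # training accuracy 100%

  # the printed example under a disjoint-type model predicts its relation:
  # a two-role terminology whose (domain, range) signatures do not overlap
  tb <- TBox(
    concepts = data.frame(
      id = c("Baritosis", "Pneumoconiosis", "Barium_dust", "Dust", "Lung"),
      label = c("Baritosis", "pneumoconiosis", "barium dust", "dust", "lung"),
      semantic_type = c("disorder", "disorder", "substance", "substance",
                        "body_structure")),
    roles = data.frame(id = c("Causative_agent", "Finding_site"),
                       label = c("caused by", "found in")),
    axioms = list(axiom("Baritosis", "Pneumoconiosis", data.frame(
      role = c("Causative_agent", "Finding_site"),
      filler = c("Barium_dust", "Lung")))))
  train <- data.frame(
    subject = "Baritosis",
    object = rep(c("Barium_dust", "Lung"), each = 3),
    label = rep(c("Causative_agent", "Finding_site"), each = 3),
    between = "", stringsAsFactors = FALSE)
  fs2 <- vectorizeInstances(train, featureSpec(lexicalMode = "none"),
                            typeAssignment(tb))
  m2 <- trainRelationModel(fs2)
  exInst <- alignCorpus(corpus(list(exampleSentence())),
                        explicitRelationshipBase(tb), tb)
  exFs <- vectorizeInstances(exInst, featureSpec(lexicalMode = "none"),
                             typeAssignment(tb))
  expect_equal(predictRelations(m2, exFs), "Causative_agent")
})

test_that("training rejects degenerate inputs, tolerates conflicting labels", {
  toy <- separableToy()
  expect_error(trainRelationModel(toy$features, rep("R1", 4)),
               "at least two classes")
  expect_error(trainRelationModel(list(character(0), character(0)),
                                  c("R1", "R2")), "vocabulary")
  conflict <- trainRelationModel(toy$features[c(1, 1, 3, 3)],
                                 c("R1", "R2", "R1", "R2"))
  expect_length(predictRelations(conflict, toy$features), 4L)
  # all-absent vector gets some fixed class, stable across calls
  blank <- list(character(0))
  m <- trainRelationModel(separableToy()$features, separableToy()$labels)
  expect_identical(predictRelations(m, blank), predictRelations(m, blank))
  # unseen features are silently ignored
  expect_equal(predictRelations(m, list(c("ltype:t1", "rtype:t2", "c3:zzz"))),
               "R1")
})

test_that("all four algorithms train and predict behind one interface", {
  toy <- separableToy()
  for (alg in c("linear_svm", "logistic_regression", "naive_bayes",
                "random_forest")) {
    m <- trainRelationModel(toy$features, toy$labels,
                            learnerConfig(algorithm = alg, seed = 3))
    expect_equal(predictRelations(m, toy$features), toy$labels,
                 label = alg)
  }
})

test_that("cross-validation reports pooled per-class metrics and macro-F", {
  bench <- simulateBenchmark(simConfig(seed = 6))
  inst <- alignCorpus(bench$corpus, bench$infrb, bench$tbox)
  fs <- vectorizeInstances(inst, featureSpec(lexicalMode = "none"),
                           typeAssignment(bench$tbox))
  cv <- crossValidate(fs, config = learnerConfig(seed = 2))
  expect_equal(cv$macro_f, 1.0)       # separable: types determine the role
  expect_equal(cv$folds, 10L)
  # invariants of the report
  expect_equal(cv$macro_f, mean(cv$per_class$f1))
  expect_equal(unname(rowSums(cv$confusion)), cv$per_class$support)
  expect_equal(sum(cv$confusion), length(fs$labels))
  # recompute per-class F1 from the confusion matrix independently
  for (k in seq_len(nrow(cv$confusion))) {
    tp <- cv$confusion[k, k]
    p <- if (sum(cv$confusion[, k]) > 0) tp / sum(cv$confusion[, k]) else 0
    r <- if (sum(cv$confusion[k, ]) > 0) tp / sum(cv$confusion[k, ]) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(cv$per_class$f1[k], f)
  }
})

test_that("permuted labels score near chance on a balanced three-class set", {
  set.seed(99)
  n <- 60
  feats <- lapply(seq_len(n), function(i)
    paste0("bow:w", sample(20, 5)))
  labels <- sample(rep(c("R1", "R2", "R3"), n / 3))
  cv <- crossValidate(feats, labels, learnerConfig(seed = 7), folds = 5)
  expect_lt(abs(cv$macro_f - 1 / 3), 0.18)
})

test_that("cross-validation is deterministic and adapts the fold count", {
  bench <- simulateBenchmark(simConfig(seed = 9, nConcepts = 30,
                                       triplesPerRole = 4))
  inst <- alignCorpus(bench$corpus, bench$infrb, bench$tbox)
  fs <- vectorizeInstances(inst, featureSpec(), typeAssignment(bench$tbox))
  cv1 <- crossValidate(fs, config = learnerConfig(seed = 5))
  cv2 <- crossValidate(fs, config = learnerConfig(seed = 5))
  expect_identical(cv1, cv2)

  toy <- separableToy()   # two instances per class < 10 folds
  expect_warning(cvSmall <- crossValidate(toy$features, toy$labels,
                                          learnerConfig(seed = 1)),
                 "reducing to 2 folds")
  expect_equal(cvSmall$folds, 2L)
  expect_error(crossValidate(toy$features[1:2], toy$labels[1:2]),
               "too few")
})

test_that("CV reports serialize deterministically to JSON", {
  toy <- separableToy()
  suppressWarnings({
    cv <- crossValidate(toy$features, toy$labels, learnerConfig(seed = 1))
  })
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeCVReport(cv, p1); writeCVReport(cv, p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::fromJSON(p1)
  expect_equal(parsed$macro_f, cv$macro_f)
})
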