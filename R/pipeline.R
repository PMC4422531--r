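# End-to-end pipeline: annotate -> align -> featurize -> cross-validate ->
# train -> predict -> assemble -> DefPre, with all intermediate artifacts
# and a machine-readable run manifest written to an output directory.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full definition-generation pipeline
#'
#' Executes the whole chain on an annotated (or raw) corpus: sentences
#' without mentions are annotated with the dictionary annotator, mention
#' pairs are aligned against the relationship base by distant supervision,
#' instances are featurized and evaluated by stratified cross-validation, a
#' model trained on all instances predicts a role for every instance, the
#' predicted triples are assembled into one candidate definition per subject
#' concept, and the candidates are scored against the reference terminology
#' by entailment (DefPre). All intermediate artifacts and a run manifest
#' (seed, package version, artifact hashes, stage counts) are written to
#' `outDir`; reruns with identical inputs and seed produce byte-identical
#' ARFF, CV-report and DefPre-report files.
#'
#' @param tbox a [TBox-class] (annotation dictionary, semantic types, and
#'   default reference ontology).
#' @param corpus a [Corpus-class]; sentences with no mentions are annotated
#'   against `tbox`.
#' @param rb a [RelationshipBase-class] used for distant supervision.
#' @param outDir output directory (created if missing).
#' @param spec a [featureSpec()].
#' @param config a [learnerConfig()].
#' @param reference reference [TBox-class] for DefPre (defaults to `tbox`).
#' @param isaRole optional role id treated as is-a when assembling
#'   definitions.
#' @param folds cross-validation folds.
#' @param bothOrders,dropAmbiguous,withNoneClass alignment flags, see
#'   [alignCorpus()].
#' @return list with `cv` (`CVReport`), `defpre` (`DefPreReport`),
#'   `instances`, `predictions`, `definitions` (list of
#'   [CandidateDefinition-class]), `model`, and `manifest`.
#' @export
runPipeline <- function(tbox, corpus, rb, outDir,
                        spec = featureSpec(), config = learnerConfig(),
                        reference = tbox, isaRole = NULL, folds = 10L,
                        bothOrders = FALSE, dropAmbiguous = FALSE,
                        withNoneClass = FALSE) {
  stopifnot(is(tbox, "TBox"), is(corpus, "Corpus"),
            is(rb, "RelationshipBase"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  corpus <- .stage("annotate", {
    sents <- lapply(corpus@sentences, function(s)
      if (nrow(s@mentions)) s else annotateWithDictionary(s@text, tbox))
    corpus(sents)
  })
  counts$sentences <- length(corpus)
  writeCorpus(corpus, file.path(outDir, "corpus.jsonl"))

  instances <- .stage("align",
    alignCorpus(corpus, rb, tbox, bothOrders = bothOrders,
                dropAmbiguous = dropAmbiguous,
                withNoneClass = withNoneClass))
  counts$instances <- nrow(instances)
  counts$relationship_base <- nrow(rb@triples)
  message(sprintf("align: %d instances from %d sentences against %d %s triples",
                  nrow(instances), length(corpus), nrow(rb@triples),
                  rb@provenance))
  if (!nrow(instances))
    stop("pipeline stage 'align' failed: no instances aligned", call. = FALSE)
  writeInstances(instances, file.path(outDir, "instances.tsv"))

  fs <- .stage("featurize", {
    ta <- typeAssignment(tbox, grouping = spec$typeGrouping)
    vectorizeInstances(instances, spec, ta)
  })
  counts$features <- length(fs$vocabulary)
  writeArff(fs, file.path(outDir, "instances.arff"),
            vocabularyFile = file.path(outDir, "vocabulary.txt"))

  cv <- .stage("cross-validate", crossValidate(fs, config = config,
                                               folds = folds))
  writeCVReport(cv, file.path(outDir, "cv_report.json"))

  model <- .stage("train", trainRelationModel(fs, config = config))
  pred <- .stage("predict", predictRelations(model, fs))
  predictions <- instances
  predictions$label <- pred
  writeInstances(predictions, file.path(outDir, "predictions.tsv"))

  candTriples <- unique(data.frame(subject = predictions$subject,
                                   role = predictions$label,
                                   object = predictions$object,
                                   stringsAsFactors = FALSE))
  definitions <- .stage("assemble", {
    lapply(split(candTriples, candTriples$subject), function(tr)
      assembleDefinition(tr$subject[1], tr, isaRole = isaRole))
  })
  counts$definitions <- length(definitions)
  writeDefinitions(definitions, file.path(outDir, "definitions.tsv"), "tsv")
  writeDefinitions(definitions, file.path(outDir, "definitions.txt"), "text")

  defpre <- .stage("defpre", defPre(candTriples, reference))
  writeDefPreReport(defpre, file.path(outDir, "defpre_report.json"))

  artifacts <- c("corpus.jsonl", "instances.tsv", "instances.arff",
                 "vocabulary.txt", "cv_report.json", "predictions.tsv",
                 "definitions.tsv", "definitions.txt", "defpre_report.json")
  manifest <- list(
    package = "eldef",
    version = as.character(utils::packageVersion("eldef")),
    seed = config$seed,
    algorithm = config$algorithm,
    lexical_mode = spec$lexicalMode,
    use_types = spec$useTypes,
    counts = counts,
    artifact_md5 = as.list(tools::md5sum(file.path(outDir, artifacts))))
  names(manifest$artifact_md5) <- artifacts
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(cv = cv, defpre = defpre, instances = instances,
       predictions = predictions, definitions = definitions, model = model,
       manifest = manifest)
}
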