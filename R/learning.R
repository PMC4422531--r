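# Multi-class relation classification over boolean feature vectors.
# The reference learner is a linear-kernel SVM with complexity C = 1.0
# (the setting of a sequential-minimal-optimization linear SVM); logistic
# regression, naive Bayes and random forests are optional plugins behind the
# same interface. Evaluation is macro-averaged F-measure under stratified
# k-fold cross-validation with pooled fold predictions.

#' Learner configuration
#'
#' @param algorithm `"linear_svm"` (default and reference), or
#'   `"logistic_regression"`, `"naive_bayes"`, `"random_forest"`.
#' @param complexity SVM complexity parameter C (cost of constraint
#'   violation), default 1.0.
#' @param epsilon SMO-style epsilon parameter recorded with the model,
#'   default 1.0e-12 (provenance field; underlying solvers keep their own
#'   numerical tolerances).
#' @param seed integer seed governing fold assignment and any stochastic
#'   learner.
#' @return a `LearnerConfig` list.
#' @export
learnerConfig <- function(algorithm = c("linear_svm", "logistic_regression",
                                        "naive_bayes", "random_forest"),
                          complexity = 1.0, epsilon = 1.0e-12, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(complexity > 0, epsilon > 0)
  structure(list(algorithm = algorithm, complexity = complexity,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "LearnerConfig")
}

.featureMatrix <- function(feats, vocabulary) {
  m <- matrix(0, nrow = length(feats), ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(feats)) {
    idx <- match(feats[[i]], vocabulary)
    idx <- idx[!is.na(idx)]
    m[i, idx] <- 1
  }
  m
}

.asFeatureList <- function(x) {
  if (inherits(x, "FeatureSet")) x$features else x
}

.fit <- function(m, y, config) {
  set.seed(config$seed)
  colnames(m) <- paste0("f", seq_len(ncol(m)))   # syntactic names for formula learners
  switch(config$algorithm,
    linear_svm = e1071::svm(x = m, y = y, kernel = "linear",
                            cost = config$complexity, scale = FALSE),
    logistic_regression = {
      if (!requireNamespace("nnet", quietly = TRUE))
        stop("logistic_regression requires the 'nnet' package", call. = FALSE)
      df <- data.frame(m, check.names = FALSE)
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200,
                     MaxNWts = 1e6)
    },
    naive_bayes = {
      df <- as.data.frame(lapply(as.data.frame(m), factor,
                                 levels = c("0", "1")))
      e1071::naiveBayes(x = df, y = y, laplace = 1)
    },
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("random_forest requires the 'randomForest' package", call. = FALSE)
      randomForest::randomForest(x = as.data.frame(m), y = y)
    })
}

.fitPredict <- function(fit, m, config, classes) {
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  p <- switch(config$algorithm,
    linear_svm = predict(fit, m),
    logistic_regression = predict(fit, newdata = data.frame(m, check.names = FALSE)),
    naive_bayes = predict(fit, as.data.frame(
      lapply(as.data.frame(m), factor, levels = c("0", "1")))),
    random_forest = predict(fit, as.data.frame(m)))
  as.character(p)
}

#' Train a relation classifier
#'
#' @param x a `FeatureSet` from [vectorizeInstances()], or a list of feature
#'   name vectors.
#' @param labels class labels (role ids); taken from the feature set when
#'   omitted.
#' @param config a [learnerConfig()].
#' @param vocabulary feature vocabulary; taken from the feature set (or the
#'   union of names) when omitted.
#' @return a `RelationModel` holding the fitted learner, its vocabulary and
#'   its class list. Prediction projects inputs onto the training vocabulary,
#'   silently ignoring unseen features. Training requires at least two
#'   classes and a non-empty vocabulary.
#' @export
trainRelationModel <- function(x, labels = NULL, config = learnerConfig(),
                               vocabulary = NULL) {
  feats <- .asFeatureList(x)
  labels <- labels %||% (if (inherits(x, "FeatureSet")) x$labels else NULL)
  if (is.null(labels) || length(labels) != length(feats))
    stop("labels must be given for every instance", call. = FALSE)
  vocabulary <- vocabulary %||%
    (if (inherits(x, "FeatureSet")) x$vocabulary
     else .csort(unlist(feats, use.names = FALSE)))
  classes <- .csort(labels)
  if (length(classes) < 2L)
    stop("training requires at least two classes", call. = FALSE)
  if (!length(vocabulary))
    stop("training requires a non-empty feature vocabulary", call. = FALSE)
  m <- .featureMatrix(feats, vocabulary)
  y <- factor(labels, levels = classes)
  fit <- .fit(m, y, config)
  structure(list(config = config, vocabulary = vocabulary, classes = classes,
                 fit = fit), class = "RelationModel")
}

#' @export
print.RelationModel <- function(x, ...) {
  cat(sprintf("RelationModel (%s): %d features, classes: %s\n",
              x$config$algorithm, length(x$vocabulary),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict relation labels
#'
#' @param model a `RelationModel` from [trainRelationModel()].
#' @param x a `FeatureSet` or list of feature name vectors.
#' @return character vector of predicted role ids, one per instance;
#'   deterministic given the model.
#' @export
predictRelations <- function(model, x) {
  stopifnot(inherits(model, "RelationModel"))
  feats <- .asFeatureList(x)
  if (!length(feats)) return(character(0))
  m <- .featureMatrix(feats, model$vocabulary)
  .fitPredict(model$fit, m, model$config, model$classes)
}

.classMetrics <- function(confusion) {
  classes <- rownames(confusion)
  tp <- diag(confusion)
  predicted <- colSums(confusion)
  actual <- rowSums(confusion)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(actual > 0, tp / actual, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = classes, precision = unname(precision),
             recall = unname(recall), f1 = unname(f1),
             support = unname(actual), stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation with macro-averaged F-measure
#'
#' Folds are stratified by class and derived from the seed only. Per-class
#' precision/recall/F1 are computed over the pooled predictions of all folds
#' and the macro F-measure is their unweighted mean; a class with no true
#' and no predicted positives scores F1 = 0. If some class has fewer
#' instances than `folds`, the fold count is reduced (with a warning) to the
#' smallest class size (minimum 2).
#'
#' @inheritParams trainRelationModel
#' @param folds number of folds (default 10).
#' @return a `CVReport`: list with `per_class` (data.frame), `macro_f`,
#'   `confusion` (true x predicted count matrix), `folds`, `seed`,
#'   `algorithm`.
#' @export
crossValidate <- function(x, labels = NULL, config = learnerConfig(),
                          folds = 10L) {
  feats <- .asFeatureList(x)
  labels <- labels %||% (if (inherits(x, "FeatureSet")) x$labels else NULL)
  vocabulary <- if (inherits(x, "FeatureSet")) x$vocabulary
                else .csort(unlist(feats, use.names = FALSE))
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  n <- length(labels)
  if (n < 4L) stop("too few instances to cross-validate", call. = FALSE)
  classes <- .csort(labels)
  if (length(classes) < 2L)
    stop("cross-validation requires at least two classes", call. = FALSE)
  minSupport <- min(table(labels))
  folds <- as.integer(folds)
  if (minSupport < folds) {
    folds <- max(2L, as.integer(minSupport))
    warning(sprintf("smallest class has %d instances; reducing to %d folds",
                    minSupport, folds), call. = FALSE)
  }
  set.seed(config$seed)
  fold <- integer(n)
  for (cl in classes) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  pred <- character(n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    yTr <- factor(labels[tr])
    if (nlevels(yTr) < 2L)
      stop("a training fold collapsed to a single class", call. = FALSE)
    m <- .featureMatrix(feats[tr], vocabulary)
    fit <- .fit(m, yTr, config)
    pred[!tr] <- .fitPredict(fit, .featureMatrix(feats[!tr], vocabulary),
                             config, levels(yTr))
  }
  confusion <- table(factor(labels, levels = classes),
                     factor(pred, levels = classes))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  perClass <- .classMetrics(confusion)
  structure(list(per_class = perClass,
                 macro_f = mean(perClass$f1),
                 confusion = confusion,
                 folds = folds, seed = config$seed,
                 algorithm = config$algorithm),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport (%s, %d-fold, seed %d): macro-F = %.3f\n",
              x$algorithm, x$folds, x$seed, x$macro_f))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Serialize a cross-validation report to JSON
#'
#' @param report a `CVReport` from [crossValidate()].
#' @param path output path.
#' @return `path`, invisibly. Output is byte-deterministic.
#' @export
writeCVReport <- function(report, path) {
  out <- list(algorithm = report$algorithm, folds = report$folds,
              seed = report$seed, macro_f = report$macro_f,
              per_class = report$per_class,
              classes = rownames(report$confusion),
              confusion = unname(apply(report$confusion, 1, as.integer,
                                       simplify = FALSE)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
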