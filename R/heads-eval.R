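# Classification heads, patient-level stratified cross-validation,
# fold-ensembled inference, and the evaluation metrics.

#' Patient-level stratified K folds
#'
#' Assigns every patient to exactly one fold (so all of a patient's slides
#' stay together), stratifying on the patient's label: within each label the
#' shuffled patients are dealt round-robin, so per-fold label counts differ
#' by at most 1. The plan is deterministic given `seed` and is meant to be
#' shared across all model trainings.
#'
#' @param labels per-patient labels, named by patient id.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A [FoldPlan-class].
#' @export
stratifiedPatientFolds <- function(labels, k = 5L, seed = 1L) {
  if (is.null(names(labels))) stop("labels must be named by patient id")
  k <- as.integer(k)
  tab <- table(labels)
  if (min(tab) < k)
    stop("too few patients of the rarest label (", min(tab),
         ") for ", k, " folds")
  set.seed(seed)
  assignment <- integer(length(labels))
  names(assignment) <- names(labels)
  for (lv in names(tab)) {
    ids <- sample(names(labels)[labels == lv])
    assignment[ids] <- rep_len(seq_len(k), length(ids))
  }
  new("FoldPlan", k = k, assignment = assignment,
      stratifyOn = as.character(labels)[match(names(assignment), names(labels))])
}

#' Train an L2-regularised logistic classification head
#'
#' Ridge-penalized logistic regression on slide embeddings with the
#' reference hyper-parameters: inverse regularization `C = 7`, up to 10,000
#' iterations, and balanced class weighting (losses rescaled inversely to
#' class frequency).
#'
#' @param X n x D matrix of slide embeddings.
#' @param y binary 0/1 labels.
#' @param C inverse regularization strength (default 7).
#' @param maxIter maximum solver iterations (default 10,000).
#' @param classWeight `"balanced"` (default) or `"none"`.
#' @return An object of class `iccaHead` with elements `coef`, `intercept`.
#' @export
trainHead <- function(X, y, C = 7, maxIter = 10000L,
                      classWeight = c("balanced", "none")) {
  classWeight <- match.arg(classWeight)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("degenerate labels: need both classes")
  w <- if (classWeight == "balanced") balancedWeights(y) else NULL
  fit <- ridgeLogistic(as.matrix(X), y, C = C, maxIter = maxIter, weights = w)
  structure(list(coef = fit$coef, intercept = fit$intercept,
                 C = C, classWeight = classWeight),
            class = "iccaHead")
}

#' Predicted probabilities of a logistic head
#' @param head an `iccaHead` from [trainHead()].
#' @param X n x D embedding matrix.
#' @return numeric vector of probabilities.
#' @export
predictHead <- function(head, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(head$coef))
    stop("embedding dimension does not match the head")
  as.numeric(stats::plogis(X %*% head$coef + head$intercept))
}

#' Area under the ROC curve
#'
#' Probability that a uniformly random positive outranks a uniformly random
#' negative, counting ties as 1/2 (mid-rank definition); invariant under
#' strictly monotone transforms of the scores.
#'
#' @param labels binary 0/1 labels (both classes required).
#' @param scores numeric scores.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(labels, scores) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("AUC needs both classes present")
  r <- rank(scores)          # average ranks handle ties
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity of binary predictions.
#'
#' @param labels binary 0/1 labels.
#' @param predictions binary 0/1 predictions.
#' @return balanced accuracy in [0, 1].
#' @export
balancedAccuracy <- function(labels, predictions) {
  y <- as.integer(labels); p <- as.integer(predictions)
  if (length(unique(y)) < 2L) stop("balanced accuracy needs both classes")
  sens <- mean(p[y == 1L] == 1L)
  spec <- mean(p[y == 0L] == 0L)
  (sens + spec) / 2
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of the per-class F1 scores of binary predictions; a class
#' with no predicted and no true members contributes 0.
#'
#' @inheritParams balancedAccuracy
#' @return macro-F1 in [0, 1].
#' @export
f1Macro <- function(labels, predictions) {
  y <- as.integer(labels); p <- as.integer(predictions)
  f1 <- vapply(c(0L, 1L), function(cl) {
    tp <- sum(p == cl & y == cl)
    fp <- sum(p == cl & y != cl)
    fn <- sum(p != cl & y == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

.metricRow <- function(y, prob, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  c(auc = aucScore(y, prob),
    balanced_accuracy = balancedAccuracy(y, pred),
    f1_macro = f1Macro(y, pred))
}

#' Patient-level stratified cross-validation of a logistic head
#'
#' Trains one head per fold on the slides of the training-fold patients and
#' scores the held-out slides; out-of-fold probabilities are pooled and
#' reported both at slide level and at patient level (a patient's score is
#' the mean probability over their slides). The fold plan is reused
#' bit-identically by every model type.
#'
#' @param X n x D matrix of slide embeddings, one row per slide.
#' @param patientIds patient id of each slide (row of `X`).
#' @param labels per-patient binary 0/1 labels, named by patient id.
#' @param plan a [FoldPlan-class] covering all patients.
#' @param C,maxIter,classWeight passed to [trainHead()].
#' @param threshold probability cutoff for balanced accuracy / F1.
#' @return A list of class `iccaEval` with elements `slide` and `patient`
#'   (named metric vectors), `perFold` (per-fold slide metrics with mean and
#'   sd), `oof` (out-of-fold probabilities per slide) and `models` (the k
#'   fold heads, for fold-ensembled inference).
#' @export
crossValidate <- function(X, patientIds, labels, plan, C = 7,
                          maxIter = 10000L, classWeight = "balanced",
                          threshold = 0.5) {
  stopifnot(is(plan, "FoldPlan"))
  X <- as.matrix(X)
  patientIds <- as.character(patientIds)
  if (!all(patientIds %in% names(plan@assignment)))
    stop("fold plan does not cover all patients")
  if (!all(patientIds %in% names(labels)))
    stop("labels missing for some patients")
  foldOfSlide <- plan@assignment[patientIds]
  ySlide <- as.integer(labels[patientIds])
  prob <- rep(NA_real_, nrow(X))
  models <- vector("list", plan@k)
  perFold <- matrix(NA_real_, plan@k, 3,
                    dimnames = list(NULL, c("auc", "balanced_accuracy", "f1_macro")))
  for (f in seq_len(plan@k)) {
    tr <- foldOfSlide != f
    te <- !tr
    stopifnot(!any(patientIds[tr] %in% patientIds[te]))  # leakage guard
    if (length(unique(ySlide[tr])) < 2L || length(unique(ySlide[te])) < 2L)
      stop("fold ", f, " has a single class; cannot evaluate")
    models[[f]] <- trainHead(X[tr, , drop = FALSE], ySlide[tr], C = C,
                             maxIter = maxIter, classWeight = classWeight)
    prob[te] <- predictHead(models[[f]], X[te, , drop = FALSE])
    perFold[f, ] <- .metricRow(ySlide[te], prob[te], threshold)
  }
  pats <- unique(patientIds)
  pProb <- vapply(pats, function(p) mean(prob[patientIds == p]), numeric(1))
  yPat <- as.integer(labels[pats])
  structure(list(
    slide = .metricRow(ySlide, prob, threshold),
    patient = .metricRow(yPat, pProb, threshold),
    perFold = data.frame(fold = seq_len(plan@k), perFold),
    foldMean = colMeans(perFold), foldSd = apply(perFold, 2, stats::sd),
    oof = data.frame(patient_id = patientIds, fold = unname(foldOfSlide),
                     label = ySlide, prob = prob),
    models = models), class = "iccaEval")
}

#' @export
print.iccaEval <- function(x, ...) {
  cat("Cross-validated evaluation\n")
  cat(sprintf("  slide level:   AUC %.3f, balanced accuracy %.3f, macro-F1 %.3f\n",
              x$slide["auc"], x$slide["balanced_accuracy"], x$slide["f1_macro"]))
  cat(sprintf("  patient level: AUC %.3f, balanced accuracy %.3f, macro-F1 %.3f\n",
              x$patient["auc"], x$patient["balanced_accuracy"], x$patient["f1_macro"]))
  cat(sprintf("  per-fold AUC: %s (mean %.3f +/- %.3f)\n",
              paste(sprintf("%.2f", x$perFold$auc), collapse = " "),
              x$foldMean["auc"], x$foldSd["auc"]))
  invisible(x)
}

#' Patient-level stratified cross-validation of the MIL model
#'
#' Same harness as [crossValidate()] but training a gated-attention MIL
#' model per fold on the bags of the training-fold patients.
#'
#' @param bags list of [milBag()] objects (one per slide).
#' @param labels per-patient binary 0/1 labels, named by patient id.
#' @param plan a [FoldPlan-class].
#' @param threshold probability cutoff for balanced accuracy / F1.
#' @param ... passed to [trainMIL()] (epochs, lr, hidden, seed, ...).
#' @return A list of class `iccaEval` (see [crossValidate()]); `models`
#'   holds the k fold MIL models.
#' @export
milCrossValidate <- function(bags, labels, plan, threshold = 0.5, ...) {
  stopifnot(is(plan, "FoldPlan"))
  patientIds <- vapply(bags, function(b) b@patientId, character(1))
  foldOfSlide <- plan@assignment[patientIds]
  ySlide <- as.integer(labels[patientIds])
  prob <- rep(NA_real_, length(bags))
  models <- vector("list", plan@k)
  perFold <- matrix(NA_real_, plan@k, 3,
                    dimnames = list(NULL, c("auc", "balanced_accuracy", "f1_macro")))
  for (f in seq_len(plan@k)) {
    tr <- which(foldOfSlide != f)
    te <- which(foldOfSlide == f)
    models[[f]] <- trainMIL(bags[tr], ...)
    prob[te] <- milPredict(models[[f]], bags[te])
    perFold[f, ] <- .metricRow(ySlide[te], prob[te], threshold)
  }
  pats <- unique(patientIds)
  pProb <- vapply(pats, function(p) mean(prob[patientIds == p]), numeric(1))
  yPat <- as.integer(labels[pats])
  structure(list(
    slide = .metricRow(ySlide, prob, threshold),
    patient = .metricRow(yPat, pProb, threshold),
    perFold = data.frame(fold = seq_len(plan@k), perFold),
    foldMean = colMeans(perFold), foldSd = apply(perFold, 2, stats::sd),
    oof = data.frame(patient_id = patientIds, fold = unname(foldOfSlide),
                     label = ySlide, prob = prob),
    models = models), class = "iccaEval")
}

#' Fold-ensembled inference on an external set
#'
#' Averages the probabilities predicted by the k fold models (logistic heads
#' or MIL models) on external samples.
#'
#' @param models list of k fold models from [crossValidate()] or
#'   [milCrossValidate()].
#' @param X external slide embeddings (for heads) or a list of bags (for MIL
#'   models).
#' @return numeric vector: the arithmetic mean of the k probability vectors.
#' @export
ensembleInference <- function(models, X) {
  probs <- lapply(models, function(m) {
    if (inherits(m, "iccaHead")) predictHead(m, X)
    else if (is(m, "AttentionMILModel")) milPredict(m, X)
    else stop("unsupported model type")
  })
  rowMeans(do.call(cbind, probs))
}
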