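# Transcriptomic class assignment: gene filtering, quantile normalization,
# gene-wise centring, signature-mean scoring, argmax class. The pipeline
# order is filter -> quantile normalize -> center -> score -> argmax.

#' Filter genes by quantification rate
#'
#' Keeps the genes quantified (value > 0) in at least `minFraction` of
#' samples (default 50%).
#'
#' @param expr genes x samples nonnegative matrix with gene-id rownames.
#' @param minFraction minimum fraction of samples with a nonzero value.
#' @return The filtered matrix.
#' @export
filterGenes <- function(expr, minFraction = 0.5) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 1L) stop("at least one sample is required")
  keep <- rowMeans(expr > 0) >= minFraction
  if (!any(keep)) stop("all genes removed by the quantification filter")
  expr[keep, , drop = FALSE]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one distribution: the across-sample
#' mean of sorted values. Ties within a sample receive the mean of their
#' target quantile values. Delegates to [limma::normalizeQuantiles()].
#'
#' @param expr genes x samples matrix.
#' @return The normalized matrix; all columns share one multiset of values.
#' @export
quantileNormalize <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Gene-wise centring (no variance scaling)
#'
#' Subtracts each gene's across-sample mean; variances are untouched.
#' Idempotent.
#'
#' @param expr genes x samples matrix.
#' @return The centred matrix (row means 0 within 1e-9).
#' @export
genewiseCenter <- function(expr) {
  expr <- as.matrix(expr)
  sweep(expr, 1L, rowMeans(expr))
}

#' Signature-mean scores per sample
#'
#' For each of the five class signatures, the mean centred expression of the
#' signature genes present in the matrix, per sample.
#'
#' @param exprCentered centred genes x samples matrix (see
#'   [genewiseCenter()]).
#' @param signatures named list of gene-id vectors; names must be the five
#'   iCCA classes.
#' @return samples x 5 matrix of scores (columns in [ICCA_CLASSES] order).
#' @export
signatureScores <- function(exprCentered, signatures) {
  exprCentered <- as.matrix(exprCentered)
  if (!setequal(names(signatures), ICCA_CLASSES))
    stop("signatures must be named by the five iCCA classes")
  scores <- vapply(ICCA_CLASSES, function(cl) {
    genes <- intersect(signatures[[cl]], rownames(exprCentered))
    if (!length(genes))
      stop("signature '", cl, "' has no genes left after filtering")
    colMeans(exprCentered[genes, , drop = FALSE])
  }, numeric(ncol(exprCentered)))
  scores <- matrix(scores, ncol = 5L,
                   dimnames = list(colnames(exprCentered), ICCA_CLASSES))
  scores
}

#' Assign the transcriptomic class by argmax score
#'
#' Each sample is assigned the class with the highest signature-mean score.
#' Exact ties are flagged and broken by the canonical class order
#' ([ICCA_CLASSES]).
#'
#' @param scores samples x 5 score matrix from [signatureScores()].
#' @return data.frame with `sample_id`, the five score columns,
#'   `assigned_class` and `tie_flag`.
#' @export
assignClass <- function(scores) {
  scores <- matrix(as.matrix(scores), ncol = 5L,
                   dimnames = list(rownames(as.matrix(scores)), ICCA_CLASSES))
  if (!all(is.finite(scores))) stop("non-finite signature score")
  best <- apply(scores, 1L, which.max)       # first max = canonical order
  tie <- apply(scores, 1L, function(s) sum(s == max(s)) > 1L)
  out <- data.frame(sample_id = rownames(scores) %||% seq_len(nrow(scores)),
                    scores, assigned_class = ICCA_CLASSES[best],
                    tie_flag = tie, row.names = NULL, check.names = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full transcriptomic classification pipeline
#'
#' Runs filter (genes quantified in >= 50% of samples), quantile
#' normalization, gene-wise centring, signature-mean scoring and argmax
#' assignment, in that order.
#'
#' @param expr genes x samples nonnegative matrix.
#' @param signatures named list of five signature gene sets.
#' @param minFraction quantification filter threshold.
#' @return The [assignClass()] data.frame.
#' @export
classifyExpression <- function(expr, signatures, minFraction = 0.5) {
  x <- filterGenes(expr, minFraction)
  x <- quantileNormalize(x)
  x <- genewiseCenter(x)
  assignClass(signatureScores(x, signatures))
}
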