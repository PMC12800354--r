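# Internal helpers shared across modules.

# Numerically safe softmax.
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Dihedral transform of an image patch
#'
#' Applies one of the 8 symmetries of the square (identity, rotations by 90,
#' 180, 270 degrees, and the same four after a horizontal flip) to an
#' `H x W x 3` array. Used as the per-tile augmentation inside a view.
#'
#' @param patch an `H x W x 3` array (square for rotations to preserve shape).
#' @param k transform index in 1..8; 1 is the identity.
#' @return The transformed patch array.
#' @export
dihedral <- function(patch, k) {
  stopifnot(length(dim(patch)) == 3L, k %in% 1:8)
  rot90 <- function(a) {            # counter-clockwise quarter turn
    a <- aperm(a, c(2L, 1L, 3L))
    a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  }
  if (k > 4L) patch <- patch[, rev(seq_len(dim(patch)[2])), , drop = FALSE]
  r <- (k - 1L) %% 4L
  while (r > 0L) { patch <- rot90(patch); r <- r - 1L }
  patch
}

# Derive a reproducible sub-seed (kept below 2^31) from a base seed.
subSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

# L2-penalized weighted logistic regression via glmnet (ridge, unpenalized
# intercept). C parameterizes the inverse penalty as in the usual
# sum-of-losses + ||beta||^2 / (2C) objective; glmnet's per-observation
# scaling makes the matching lambda 1 / (C * n).
ridgeLogistic <- function(X, y, C = 7, maxIter = 10000L, weights = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit a logistic head")
  if (is.null(weights)) weights <- rep(1, n)
  if (min(table(y)) < 2L)   # below glmnet's per-class minimum
    return(irlsRidgeLogistic(X, y, C = C, weights = weights,
                             maxIter = maxIter))
  lam <- 1 / (C * n)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = c(lam * 100, lam * 10, lam),
                        weights = weights, standardize = FALSE,
                        thresh = 1e-12, maxit = as.integer(maxIter))
  co <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  list(intercept = co[1], coef = co[-1])
}

# Damped Newton/IRLS solver for the same penalized weighted likelihood;
# used where glmnet's per-class sample minimum is not met.
irlsRidgeLogistic <- function(X, y, C = 7, weights = NULL, maxIter = 10000L) {
  X1 <- cbind(1, as.matrix(X))
  if (is.null(weights)) weights <- rep(1, nrow(X1))
  beta <- rep(0, ncol(X1))
  pen <- c(0, rep(1 / C, ncol(X1) - 1L))
  for (it in seq_len(min(maxIter, 500L))) {
    p <- stats::plogis(as.numeric(X1 %*% beta))
    g <- as.numeric(crossprod(X1, weights * (p - y))) + pen * beta
    H <- crossprod(X1 * (weights * p * (1 - p) + 1e-10), X1) + diag(pen)
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < 1e-10) break
  }
  list(intercept = beta[1], coef = beta[-1])
}

# "balanced" observation weights: n / (2 * n_class), as in class_weight
# rebalancing of a binary logistic loss.
balancedWeights <- function(y) {
  n <- length(y)
  tab <- table(factor(y, levels = c(0, 1)))
  w <- n / (2 * as.numeric(tab[as.character(y)]))
  as.numeric(w)
}
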