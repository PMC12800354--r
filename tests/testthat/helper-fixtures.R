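# Shared fixtures, built once per test run.

# Small cohort with strong texture signal, reused by several module tests.
tinyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(cohortConfig(
        nPatients = 8L, imageSize = 448L, textureEffect = 2,
        biopsyFraction = 0, slidesPerPatientRange = c(1L, 2L), seed = 42L))
    cache
  }
})

# Two-class cohort under the evaluation geometry (672 px, 30% tumour):
# tumour blobs are concentrated in single grid cells, so tiles are cleanly
# tumour or non-tumour.
twoClassCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(cohortConfig(
        nPatients = 10L, imageSize = 672L, textureEffect = 2,
        classPrevalences = c(0.5, 0, 0, 0.5, 0),
        tumourFractionRange = c(0.3, 0.3),
        slidesPerPatientRange = c(1L, 2L), seed = 43L))
    cache
  }
})

# Flat-colour patch with optional Gaussian noise.
flatPatch <- function(value = 128, side = 224L, noiseSd = 0, seed = 1L) {
  set.seed(seed)
  a <- array(value + stats::rnorm(side * side * 3, 0, noiseSd),
             dim = c(side, side, 3L))
  pmin(pmax(round(a), 0), 255)
}

# Independent brute-force Otsu: try all 255 thresholds, maximize the
# between-class variance computed from first principles.
bruteForceOtsu <- function(h) {
  lev <- 0:255
  p <- h / sum(h)
  best <- -Inf; bestT <- NA_integer_
  for (t in 1:255) {
    lo <- 1:t; hi <- (t + 1):256
    w1 <- sum(p[lo]); w2 <- sum(p[hi])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(p[lo] * lev[lo]) / w1
    m2 <- sum(p[hi] * lev[hi]) / w2
    sb <- w1 * w2 * (m1 - m2)^2
    if (sb > best + 1e-12) { best <- sb; bestT <- t }
  }
  bestT
}

# Independent Fisher 2x2 p-value by full hypergeometric enumeration.
enumFisher <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(a, r1, r2, c1)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# Independent Newton solver for the weighted, L2-penalized logistic
# likelihood: minimizes sum_i w_i loss_i + ||beta||^2 / (2C), intercept
# unpenalized.
newtonRidgeLogistic <- function(X, y, C = 7, weights = NULL, iter = 200L) {
  X1 <- cbind(1, as.matrix(X))
  if (is.null(weights)) weights <- rep(1, nrow(X1))
  beta <- rep(0, ncol(X1))
  pen <- c(0, rep(1 / C, ncol(X1) - 1L))
  for (it in seq_len(iter)) {
    eta <- as.numeric(X1 %*% beta)
    p <- stats::plogis(eta)
    g <- as.numeric(crossprod(X1, weights * (p - y))) + pen * beta
    W <- weights * p * (1 - p)
    H <- crossprod(X1 * W, X1) + diag(pen)
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < 1e-12) break
  }
  list(intercept = beta[1], coef = beta[-1])
}

# Gaussian-feature bags for the MIL toy benchmark: positive bags contain a
# `signalFrac` fraction of instances shifted by `shift` in the first
# dimensions.
toyBags <- function(nBags = 200L, nInst = 20L, D = 16L, signalFrac = 0.2,
                    shift = 2, seed = 1L) {
  set.seed(seed)
  bags <- vector("list", nBags)
  signal <- vector("list", nBags)
  for (i in seq_len(nBags)) {
    y <- as.integer(i %% 2L == 0L)
    H <- matrix(stats::rnorm(nInst * D), nInst, D)
    sig <- rep(FALSE, nInst)
    if (y == 1L) {
      sig[seq_len(ceiling(signalFrac * nInst))] <- TRUE
      H[sig, 1:4] <- H[sig, 1:4] + shift
    }
    bags[[i]] <- milBag(H, y, slideId = paste0("B", i),
                        patientId = paste0("P", i))
    signal[[i]] <- sig
  }
  list(bags = bags, signal = signal)
}
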