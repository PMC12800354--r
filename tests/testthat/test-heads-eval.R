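# Heads, folds, cross-validation, ensembling and metrics.

test_that("stratified patient folds balance labels and stay patient-level", {
  labs <- stats::setNames(rep(c(1L, 0L), each = 5), sprintf("P%02d", 1:10))
  plan <- stratifiedPatientFolds(labs, k = 5L, seed = 3L)
  tab <- table(plan@stratifyOn, foldAssignment(plan))
  expect_true(all(tab == 1L))   # each fold: exactly 1 positive, 1 negative

  # the printed discovery prevalence: 246 patients, 90 positive, 5 folds
  labs246 <- stats::setNames(c(rep(1L, 90), rep(0L, 156)), sprintf("P%03d", 1:246))
  plan246 <- stratifiedPatientFolds(labs246, k = 5L, seed = 1L)
  posPerFold <- table(foldAssignment(plan246)[labs246 == 1L])
  expect_true(all(posPerFold == 18L))   # floor(90/5) structure

  expect_error(stratifiedPatientFolds(
    stats::setNames(c(1L, rep(0L, 9)), sprintf("P%02d", 1:10)), k = 5L),
    "too few")
})

test_that("fold plans are deterministic and reused identically", {
  labs <- stats::setNames(sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4)),
                          sprintf("P%02d", 1:40))
  p1 <- stratifiedPatientFolds(labs, seed = 5L)
  p2 <- stratifiedPatientFolds(labs, seed = 5L)
  expect_identical(foldAssignment(p1), foldAssignment(p2))
})

test_that("logistic head matches an independent penalized-likelihood fit", {
  set.seed(21)
  n <- 300
  X <- matrix(stats::rnorm(n * 5), n, 5)
  y <- stats::rbinom(n, 1, stats::plogis(X[, 1] - 0.5 * X[, 2]))
  skip_if(length(unique(y)) < 2)
  h <- trainHead(X, y, C = 7, classWeight = "none")
  o <- newtonRidgeLogistic(X, y, C = 7)
  expect_equal(h$coef, o$coef, tolerance = 1e-4)
  expect_equal(h$intercept, o$intercept, tolerance = 1e-4)

  # balanced weighting on imbalanced labels shifts the intercept toward the
  # minority class, as the weighted-likelihood oracle predicts
  yImb <- c(rep(1L, 30), rep(0L, 270))
  hB <- trainHead(X, yImb, C = 7, classWeight = "balanced")
  oB <- newtonRidgeLogistic(X, yImb, C = 7, weights = {
    w <- ifelse(yImb == 1L, n / (2 * 30), n / (2 * 270)); w })
  expect_equal(hB$coef, oB$coef, tolerance = 1e-4)
  expect_equal(hB$intercept, oB$intercept, tolerance = 1e-4)
  hU <- trainHead(X, yImb, C = 7, classWeight = "none")
  expect_gt(hB$intercept, hU$intercept)  # shifted in the log prior-odds direction

  expect_error(trainHead(X, rep(1L, n)), "degenerate")
})

test_that("separable data reach training AUC 1", {
  X <- rbind(c(-1, 0), c(1, 0))
  y <- c(0L, 1L)
  h <- trainHead(X, y, classWeight = "none")
  expect_equal(aucScore(y, predictHead(h, X)), 1)
})

test_that("metrics match their definitions", {
  expect_equal(aucScore(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  # invariance under strictly monotone transforms
  s <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(aucScore(c(0, 0, 1, 1), qlogis(s)), 0.75)
  expect_equal(aucScore(c(0, 1), c(0.3, 0.3)), 0.5)  # tie counts 1/2
  expect_error(aucScore(c(1, 1), c(0.2, 0.3)), "both")

  y <- c(rep(0L, 90), rep(1L, 10))
  expect_equal(balancedAccuracy(y, rep(0L, 100)), 0.5)  # all-majority
  expect_equal(balancedAccuracy(y, y), 1)
  expect_equal(f1Macro(y, y), 1)
  expect_equal(aucScore(y, y), 1)
})

test_that("auc agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:20) {
    y <- stats::rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(50), 2)   # duplicates force tie handling
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(aucScore(y, s), ref, tolerance = 1e-12)
  }
})

test_that("cross-validation is leakage-free and scores informative embeddings", {
  set.seed(31)
  nPat <- 40L
  pats <- sprintf("P%02d", 1:nPat)
  labs <- stats::setNames(rep(c(0L, 1L), each = nPat / 2), pats)
  slidesPer <- sample(1:3, nPat, replace = TRUE)
  patientIds <- rep(pats, slidesPer)
  n <- length(patientIds)
  X <- matrix(stats::rnorm(n * 6, sd = 0.3), n, 6)
  X[, 1] <- X[, 1] + 3 * labs[patientIds]    # perfectly informative direction
  plan <- stratifiedPatientFolds(labs, seed = 2L)
  cv <- crossValidate(X, patientIds, labs, plan)
  expect_equal(unname(cv$slide["auc"]), 1)
  expect_equal(unname(cv$patient["auc"]), 1)
  expect_equal(unname(cv$patient["balanced_accuracy"]), 1)
  expect_equal(unname(cv$patient["f1_macro"]), 1)
  # multi-slide patients never span folds
  spread <- tapply(cv$oof$fold, cv$oof$patient_id,
                   function(f) length(unique(f)))
  expect_true(all(spread == 1L))
})

test_that("label-independent embeddings give chance-level cross-validated AUC", {
  set.seed(33)
  nPat <- 200L
  pats <- sprintf("P%03d", 1:nPat)
  labs <- stats::setNames(rep(c(0L, 1L), each = nPat / 2), pats)
  X <- matrix(stats::rnorm(nPat * 8), nPat, 8)
  plan <- stratifiedPatientFolds(labs, seed = 4L)
  cv <- crossValidate(X, pats, labs, plan)
  expect_gte(unname(cv$patient["auc"]), 0.4)
  expect_lte(unname(cv$patient["auc"]), 0.6)
})

test_that("fold-ensembled inference averages probabilities", {
  set.seed(41)
  X <- matrix(stats::rnorm(60), 10, 6)
  h <- trainHead(matrix(stats::rnorm(120), 20, 6), rep(c(0L, 1L), 10),
                 classWeight = "none")
  same <- ensembleInference(rep(list(h), 5), X)
  expect_equal(same, predictHead(h, X), tolerance = 1e-12)

  expect_equal(mean(c(0.2, 0.4, 0.6, 0.8, 1.0)), 0.6)  # the averaging rule
  heads <- lapply(1:5, function(i) {
    hh <- h; hh$intercept <- c(-2, -1, 0, 1, 2)[i]; hh
  })
  manual <- rowMeans(vapply(heads, function(hh) predictHead(hh, X),
                            numeric(10)))
  expect_equal(ensembleInference(heads, X), manual, tolerance = 1e-12)

  hBad <- h; hBad$coef <- h$coef[-1]
  expect_error(ensembleInference(list(h, hBad), X), "dimension")
})

test_that("the fold ensemble is at least as good as the worst fold model", {
  set.seed(51)
  ok <- 0L
  for (rep in 1:20) {
    nPat <- 60L
    pats <- sprintf("P%03d", 1:nPat)
    labs <- stats::setNames(rep(c(0L, 1L), each = nPat / 2), pats)
    X <- matrix(stats::rnorm(nPat * 6, sd = 1), nPat, 6)
    X[, 1] <- X[, 1] + 1.2 * labs[pats]
    plan <- stratifiedPatientFolds(labs, seed = rep)
    cv <- crossValidate(X, pats, labs, plan)
    Xext <- matrix(stats::rnorm(nPat * 6), nPat, 6)
    yext <- stats::rbinom(nPat, 1, 0.5)
    Xext[, 1] <- Xext[, 1] + 1.2 * yext
    if (length(unique(yext)) < 2) next
    ensAuc <- aucScore(yext, ensembleInference(cv$models, Xext))
    minAuc <- min(vapply(cv$models, function(m)
      aucScore(yext, predictHead(m, Xext)), numeric(1)))
    ok <- ok + as.integer(ensAuc >= minAuc - 1e-9)
  }
  expect_gte(ok, 18L)
})
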