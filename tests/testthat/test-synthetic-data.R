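# Synthetic cohort generator: determinism, sampling structure, masks,
# expression and survival simulators.

test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohortConfig(nPatients = 2L, imageSize = 448L,
                      slidesPerPatientRange = c(1L, 2L), seed = 11L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(cohortSlides(a)[[1]]@image, cohortSlides(b)[[1]]@image)
  expect_identical(cohortSlides(a)[[1]]@tumourMask,
                   cohortSlides(b)[[1]]@tumourMask)
  expect_identical(cohortExpression(a), cohortExpression(b))
  expect_identical(cohortSurvival(a), cohortSurvival(b))
})

test_that("configuration invariants are enforced", {
  expect_error(cohortConfig(classPrevalences = c(0.5, 0.5, 0.1, 0, 0)),
               "sum to 1")
  expect_error(cohortConfig(slidesPerPatientRange = c(0L, 3L)), "lower bound")
  expect_error(cohortConfig(hazardByClass = c(-1, 1, 1, 1, 1)), "positive")
  expect_error(cohortConfig(dropoutRate = 1.2), "probability")
  expect_error(cohortConfig(nGenes = 100L, signatureSize = 50L),
               "5 \\* signatureSize")
})

test_that("class frequencies match the configured prevalences (binomial check)", {
  cfg <- cohortConfig(nPatients = 500L, imageSize = 448L,
                      slidesPerPatientRange = c(1L, 1L), biopsyFraction = 1,
                      seed = 7L)
  co <- generateCohort(cfg)
  freq <- table(factor(cohortClinical(co)$true_class, levels = ICCA_CLASSES))
  p <- cfg@classPrevalences
  se <- sqrt(p * (1 - p) / 500)
  expect_true(all(abs(freq / 500 - p) <= 3 * se))
})

test_that("tumour masks cover exactly the painted tumour and lie in tissue", {
  co <- tinyCohort()
  s <- cohortSlides(co)[[1]]
  tm <- tissueMask(s@image)
  # tumour pixels are tissue pixels (painted darker than background)
  expect_gte(mean(tm@mask[s@tumourMask == 1L]), 0.99)
  # mask is binary and nonzero only inside the slide's tissue area
  expect_true(all(s@tumourMask %in% c(0L, 1L)))
  expect_gt(sum(s@tumourMask), 0)
})

test_that("biopsy slides have less tissue than surgical slides", {
  cfg <- cohortConfig(nPatients = 6L, imageSize = 448L, biopsyFraction = 0.5,
                      slidesPerPatientRange = c(2L, 2L), seed = 5L)
  co <- generateCohort(cfg)
  areas <- vapply(cohortSlides(co), function(s)
    sum(tissueMask(s@image)@mask), numeric(1))
  types <- vapply(cohortSlides(co), function(s) s@sampleType, character(1))
  skip_if(length(unique(types)) < 2L)
  expect_lt(max(areas[types == "biopsy"]), min(areas[types == "surgical"]))
})

test_that("zero texture effect leaves tumour texture exchangeable across classes", {
  cfg <- cohortConfig(nPatients = 14L, imageSize = 448L, textureEffect = 0,
                      classPrevalences = c(0.5, 0, 0, 0.5, 0),
                      slidesPerPatientRange = c(1L, 1L), biopsyFraction = 0,
                      tumourFractionRange = c(0.4, 0.4), seed = 9L)
  co <- generateCohort(cfg)
  # per-slide mean tumour intensity: between-class spread comparable to
  # within-class spread (no class signal beyond slide-level stain noise)
  m <- vapply(cohortSlides(co), function(s) {
    mean(s@image[, , 1][s@tumourMask == 1L])
  }, numeric(1))
  cl <- vapply(cohortSlides(co), function(s) s@trueClass, character(1))
  skip_if(length(unique(cl)) < 2L)
  fit <- stats::oneway.test(m ~ factor(cl), var.equal = TRUE)
  expect_gt(fit$p.value, 0.01)
})

test_that("expression simulator plants recoverable disjoint signatures", {
  cfg <- cohortConfig(nPatients = 200L, expressionEffect = 2, seed = 21L)
  set.seed(1)
  classes <- stats::setNames(sample(ICCA_CLASSES, 200, replace = TRUE),
                             sprintf("P%03d", 1:200))
  sim <- simulateExpression(cfg, classes)
  sigs <- sim$signatures
  expect_length(unlist(sigs), 5L * cfg@signatureSize)
  expect_equal(anyDuplicated(unlist(sigs)), 0L)   # disjoint
  calls <- classifyExpression(sim$expression, sigs)
  expect_gte(mean(calls$assigned_class == classes[calls$sample_id]), 0.95)
})

test_that("null expression effect gives chance-level class recovery", {
  cfg <- cohortConfig(nPatients = 200L, expressionEffect = 0, seed = 22L)
  set.seed(2)
  classes <- stats::setNames(sample(ICCA_CLASSES, 200, replace = TRUE),
                             sprintf("P%03d", 1:200))
  sim <- simulateExpression(cfg, classes)
  calls <- classifyExpression(sim$expression, sim$signatures)
  acc <- mean(calls$assigned_class == classes[calls$sample_id])
  expect_gt(acc, 0.08)
  expect_lt(acc, 0.35)
})

test_that("dropout-induced gene loss matches the binomial tail oracle", {
  cfg <- cohortConfig(nPatients = 10L, dropoutRate = 0.6, nGenes = 2000L,
                      expressionEffect = 0, seed = 23L)
  classes <- stats::setNames(rep(ICCA_CLASSES[1], 10), sprintf("P%03d", 1:10))
  sim <- simulateExpression(cfg, classes)
  # counts are essentially never zero before dropout, so
  # P(gene kept) = P(Binom(10, 1 - 0.6) >= 5)
  pKeep <- stats::pbinom(4, 10, 0.4, lower.tail = FALSE)
  observed <- mean(rowMeans(sim$expression > 0) >= 0.5)
  se <- sqrt(pKeep * (1 - pKeep) / 2000)
  expect_lt(abs(observed - pKeep), 4 * se)
})

test_that("survival simulator has calibrated null, power and censoring", {
  # null: equal hazards -> log-rank statistic has mean ~ df = 1
  cfgNull <- cohortConfig(nPatients = 40L,
                          hazardByClass = rep(0.02, 5), censorRate = 0)
  stat <- vapply(1:200, function(s) {
    cfg <- cohortConfig(nPatients = 40L, hazardByClass = rep(0.02, 5),
                        censorRate = 0, seed = s)
    classes <- stats::setNames(rep(ICCA_CLASSES[1:2], each = 20),
                               sprintf("P%03d", 1:40))
    sv <- simulateSurvival(classes, cfg)
    logrankTest(sv$time, sv$event, classes)$statistic
  }, numeric(1))
  expect_gt(mean(stat), 0.7)
  expect_lt(mean(stat), 1.4)

  # configured censoring rate is honoured in expectation
  cfgC <- cohortConfig(nPatients = 400L, censorRate = 0.3, seed = 31L)
  classesC <- stats::setNames(sample(ICCA_CLASSES, 400, replace = TRUE),
                              sprintf("P%03d", 1:400))
  svC <- simulateSurvival(classesC, cfgC)
  expect_lt(abs(mean(svC$event == 0L) - 0.3), 3 * sqrt(0.3 * 0.7 / 400))

  # degenerate: full censoring -> no events -> log-rank refuses
  cfg1 <- cohortConfig(nPatients = 20L, censorRate = 1, seed = 32L)
  classes1 <- stats::setNames(rep(ICCA_CLASSES[1:2], each = 10),
                              sprintf("P%03d", 1:20))
  sv1 <- simulateSurvival(classes1, cfg1)
  expect_true(all(sv1$event == 0L))
  expect_error(logrankTest(sv1$time, sv1$event, classes1), "zero events")
})

test_that("cohort structure invariants hold", {
  co <- tinyCohort()
  pats <- unique(vapply(cohortSlides(co), function(s) s@patientId, character(1)))
  expect_setequal(colnames(cohortExpression(co)), pats)
  expect_true(all(pats %in% cohortClinical(co)$patient_id))
  rna <- vapply(cohortSlides(co), function(s) s@rnaLinked, character(1))
  byPat <- tapply(rna == "RNA+",
                  vapply(cohortSlides(co), function(s) s@patientId, character(1)),
                  sum)
  expect_true(all(byPat == 1L))  # exactly one RNA+ slide per patient
})
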