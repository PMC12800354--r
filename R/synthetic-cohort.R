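# Synthetic multi-modal iCCA cohort: slides, expression, survival, clinical.
#
# Slides are painted rasters: near-white background, one class-independent
# non-tumour tissue motif, and a compact tumour region whose texture
# parameters (chroma, dark-dot density for immune infiltrate, pale-streak
# density for fibrosis) deviate from a shared base in a class-conditional
# way, scaled by textureEffect. Per-slide stain shifts and density jitter
# model slide-to-slide variability independent of class.

# Per-class texture deviations, per unit of textureEffect.
.classTextureDev <- function() {
  list(
    chroma = rbind(
      "hepatic stem-like"   = c( 8, -4,  2),
      "tumour classical"    = c(-8,  2, -6),
      "inflammatory stroma" = c(-2, -2,  4),
      "immune classical"    = c(-4, -6,  6),
      "desert-like"         = c( 6,  8,  2)),
    dots    = c(0, 0.0015, 0.001, 0.004, -0.0015),
    streaks = c(0, -0.05, 0.25, 0, -0.08)
  )
}

.TUMOUR_BASE   <- list(mean = c(185, 150, 180), sd = 18,
                       dots = 0.004, streaks = 0.2)
.TISSUE_BASE   <- list(mean = c(210, 175, 205), sd = 14)
.BACKGROUND    <- 248
.PATCH         <- 224L

# Paint one slide. Returns list(image = integer HxWx3, mask = integer HxW).
.renderSlide <- function(S, sampleType, tumourFrac, classIdx, effect) {
  dev <- .classTextureDev()
  img <- array(0, dim = c(S, S, 3L))
  for (ch in 1:3)
    img[, , ch] <- .BACKGROUND + stats::rnorm(S * S, 0, 2)

  cols <- matrix(rep(seq_len(S), each = S), nrow = S)   # x of each pixel
  rows <- matrix(rep(seq_len(S), times = S), nrow = S)  # y of each pixel

  nTilesSide <- S %/% .PATCH
  if (sampleType == "surgical") {
    # radii keep every quadrant of the smallest (448 px) canvas above the
    # 50% tissue-fraction cut, so a surgical slide always yields patches
    rx <- stats::runif(1, 0.41, 0.48) * S
    ry <- stats::runif(1, 0.41, 0.48) * S
    cx <- S / 2; cy <- S / 2
    tissue <- ((cols - cx) / rx)^2 + ((rows - cy) / ry)^2 <= 1
    # tumour seed: a patch-grid cell centre well inside the tissue ellipse,
    # so at least one full patch is dominated by tumour
    centers <- (.PATCH %/% 2L) + .PATCH * (seq_len(nTilesSide) - 1L)
    cand <- expand.grid(x = centers, y = centers)
    nr <- ((cand$x - cx) / rx)^2 + ((cand$y - cy) / ry)^2
    inner <- which(nr <= 0.25)
    pick <- if (length(inner)) sample(rep(inner, 2L), 1L) else which.min(nr)
    tcx <- cand$x[pick]
    tcy <- cand$y[pick]
  } else {
    # biopsy: one narrow core aligned with a patch-grid row
    tr <- sample(nTilesSide, 1L)
    y0 <- (tr - 1L) * .PATCH + 28L
    stripRows <- y0 + seq_len(168L)
    xMargin <- round(0.08 * S)
    tissue <- matrix(FALSE, S, S)
    tissue[stripRows, (xMargin + 1):(S - xMargin)] <- TRUE
    centers <- (.PATCH %/% 2L) + .PATCH * (seq_len(nTilesSide) - 1L)
    inner <- centers[centers > xMargin + 120 & centers < S - xMargin - 120]
    if (!length(inner)) inner <- centers[which.min(abs(centers - S / 2))]
    tcx <- sample(rep(inner, 2L), 1L)
    tcy <- y0 + 84L
  }

  tissueIdx <- which(tissue)
  stain <- stats::rnorm(3, 0, 8)

  # non-tumour tissue: shared glandular motif, identical across classes
  motif <- 10 * sin(2 * pi * cols / 40) * sin(2 * pi * rows / 40)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[tissueIdx] <- .TISSUE_BASE$mean[ch] + stain[ch] + motif[tissueIdx] +
      stats::rnorm(length(tissueIdx), 0, .TISSUE_BASE$sd)
    img[, , ch] <- plane
  }

  # tumour = nearest-k tissue pixels from the seed centre (compact blob)
  nTum <- round(tumourFrac * length(tissueIdx))
  mask <- matrix(0L, S, S)
  if (nTum > 0) {
    d2 <- (cols[tissueIdx] - tcx)^2 + (rows[tissueIdx] - tcy)^2
    tumIdx <- tissueIdx[order(d2)[seq_len(nTum)]]
    mask[tumIdx] <- 1L

    chroma <- .TUMOUR_BASE$mean + effect * dev$chroma[classIdx, ]
    dotDen <- max(0, .TUMOUR_BASE$dots +
                    effect * dev$dots[classIdx]) * exp(stats::rnorm(1, 0, 0.25))
    stkDen <- max(0, .TUMOUR_BASE$streaks +
                    effect * dev$streaks[classIdx]) * exp(stats::rnorm(1, 0, 0.25))

    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tumIdx] <- chroma[ch] + stain[ch] +
        stats::rnorm(nTum, 0, .TUMOUR_BASE$sd)
      img[, , ch] <- plane
    }

    # immune-infiltrate-like dark dots (2x2, clipped to the tumour mask)
    nDots <- round(dotDen * nTum)
    if (nDots > 0) {
      seeds <- sample(tumIdx, min(nDots, nTum))
      sy <- (seeds - 1L) %% S + 1L
      sx <- (seeds - 1L) %/% S + 1L
      dy <- c(0L, 1L, 0L, 1L); dx <- c(0L, 0L, 1L, 1L)
      py <- rep(sy, each = 4L) + dy
      px <- rep(sx, each = 4L) + dx
      okp <- py >= 1L & py <= S & px >= 1L & px <= S
      didx <- (px[okp] - 1L) * S + py[okp]
      didx <- didx[mask[didx] == 1L]
      dcol <- c(70, 60, 130)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[didx] <- dcol[ch] + stats::rnorm(length(didx), 0, 6)
        img[, , ch] <- plane
      }
    }

    # fibrosis-like pale streaks (short thick line segments in the tumour)
    nStk <- round(stkDen * nTum / 2000)
    if (nStk > 0) {
      scol <- c(235, 205, 215)
      for (s in seq_len(nStk)) {
        c0 <- sample(tumIdx, 1L)
        scy <- (c0 - 1L) %% S + 1L
        scx <- (c0 - 1L) %/% S + 1L
        th <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 30, 80)
        t <- seq(-len / 2, len / 2, by = 0.5)
        off <- c(-1L, 0L, 1L)
        py <- round(outer(scy + t * sin(th), off * cos(th), `+`))
        px <- round(outer(scx + t * cos(th), -off * sin(th), `+`))
        okp <- py >= 1 & py <= S & px >= 1 & px <= S
        sidx <- unique((px[okp] - 1L) * S + py[okp])
        sidx <- sidx[mask[sidx] == 1L]
        if (length(sidx)) for (ch in 1:3) {
          plane <- img[, , ch]
          plane[sidx] <- scol[ch] + stats::rnorm(length(sidx), 0, 5)
          img[, , ch] <- plane
        }
      }
    }
  }

  img <- round(clamp255(img))
  storage.mode(img) <- "integer"
  list(image = img, mask = mask)
}

#' Generate a synthetic multi-modal iCCA cohort
#'
#' Draws patient classes from the configured prevalences, renders 1 or more
#' synthetic slides per patient (biopsy cores or surgical specimens; tumour
#' pixels recorded exactly in the tumour mask), simulates class-structured
#' expression counts with dropout via [simulateExpression()], and simulates
#' class-dependent censored survival via [simulateSurvival()]. Deterministic
#' given the configuration (including its seed).
#'
#' @param config a [cohortConfig()] object.
#' @return A [SyntheticCohort-class] with one RNA-linked expression sample
#'   per patient.
#' @examples
#' co <- generateCohort(cohortConfig(nPatients = 4, imageSize = 448L, seed = 7))
#' co
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)

  n <- config@nPatients
  classIdx <- sample.int(5L, n, replace = TRUE, prob = config@classPrevalences)
  classes <- ICCA_CLASSES[classIdx]
  patientIds <- sprintf("P%03d", seq_len(n))
  names(classes) <- patientIds

  r <- config@slidesPerPatientRange
  nSlides <- sample(seq(r[1], r[2]), n, replace = TRUE)

  slides <- vector("list", sum(nSlides))
  si <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(nSlides[i])) {
      sampleType <- if (stats::runif(1) < config@biopsyFraction) "biopsy" else "surgical"
      tf <- stats::runif(1, config@tumourFractionRange[1], config@tumourFractionRange[2])
      rs <- .renderSlide(config@imageSize, sampleType, tf, classIdx[i],
                         config@textureEffect)
      si <- si + 1L
      slides[[si]] <- new("SlideRecord",
                          slideId = sprintf("%s_S%02d", patientIds[i], j),
                          patientId = patientIds[i],
                          image = rs$image, tumourMask = rs$mask,
                          sampleType = sampleType,
                          rnaLinked = if (j == 1L) "RNA+" else "RNA-",
                          trueClass = classes[i])
    }
  }

  expr <- simulateExpression(config, classes)
  surv <- simulateSurvival(classes, config)
  clinical <- data.frame(
    patient_id = patientIds,
    true_class = unname(classes),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.57, 0.43)),
    n_slides = nSlides,
    stringsAsFactors = FALSE)

  new("SyntheticCohort", slides = slides,
      expression = expr$expression, signatures = expr$signatures,
      survival = surv, clinical = clinical, config = config)
}

#' Simulate class-structured expression counts with dropout
#'
#' Five disjoint gene signatures of `signatureSize` genes each are planted
#' among `nGenes` genes. A patient of class k has its class-k signature genes
#' shifted upward by `expressionEffect` on the log scale. Counts follow a
#' rounded log-normal model; every entry is then independently zeroed with
#' probability `dropoutRate`.
#'
#' @param config a [cohortConfig()].
#' @param classes character vector of per-patient class labels (one of
#'   [ICCA_CLASSES]), named by patient id.
#' @return A list with `expression` (genes x patients integer matrix) and
#'   `signatures` (named list of gene-id vectors, one per class).
#' @export
simulateExpression <- function(config, classes) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  if (!all(classes %in% ICCA_CLASSES))
    stop("classes must be drawn from the five iCCA classes")
  if (is.null(names(classes)))
    names(classes) <- sprintf("P%03d", seq_along(classes))
  set.seed(subSeed(config@seed, 1L))

  G <- config@nGenes
  geneIds <- sprintf("g%05d", seq_len(G))
  sigGenes <- sample(G, 5L * config@signatureSize)  # disjoint by construction
  signatures <- split(geneIds[sigGenes],
                      rep(ICCA_CLASSES, each = config@signatureSize))
  signatures <- signatures[ICCA_CLASSES]

  mu <- stats::rnorm(G, 3, 0.8)
  n <- length(classes)
  logx <- matrix(stats::rnorm(G * n, 0, 0.7), G, n) + mu
  for (k in seq_along(ICCA_CLASSES)) {
    who <- which(classes == ICCA_CLASSES[k])
    if (length(who)) {
      rows <- match(signatures[[k]], geneIds)
      logx[rows, who] <- logx[rows, who] + config@expressionEffect
    }
  }
  counts <- round(exp(logx))
  if (config@dropoutRate > 0) {
    drop <- matrix(stats::runif(G * n) < config@dropoutRate, G, n)
    counts[drop] <- 0
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(geneIds, names(classes))
  list(expression = counts, signatures = signatures)
}

#' Simulate class-dependent censored survival
#'
#' Event times are exponential with the class hazard. Censoring times are
#' independent exponentials with rate `hazard * r / (1 - r)` where `r` is
#' `censorRate`, so that a fraction `r` of patients is censored in
#' expectation regardless of class. The observed time is the minimum of the
#' two, in months; the event indicator is 1 when the event precedes
#' censoring. With `censorRate = 1` every patient is censored at an
#' independent exponential visit time.
#'
#' @param classes character vector of per-patient class labels, named by
#'   patient id.
#' @param config a [cohortConfig()].
#' @return A data.frame with columns `patient_id`, `time` (months), `event`.
#' @export
simulateSurvival <- function(classes, config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  if (is.null(names(classes)))
    names(classes) <- sprintf("P%03d", seq_along(classes))
  set.seed(subSeed(config@seed, 2L))
  hz <- config@hazardByClass[match(classes, ICCA_CLASSES)]
  r <- config@censorRate
  tEvent <- stats::rexp(length(classes), rate = hz)
  if (r >= 1) {
    time <- stats::rexp(length(classes), rate = hz)
    event <- rep(0L, length(classes))
  } else if (r <= 0) {
    time <- tEvent
    event <- rep(1L, length(classes))
  } else {
    tCens <- stats::rexp(length(classes), rate = hz * r / (1 - r))
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
  }
  data.frame(patient_id = names(classes), time = time, event = event,
             stringsAsFactors = FALSE)
}
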