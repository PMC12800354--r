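# End-to-end orchestration: preprocess every slide of a cohort, featurize
# its kept tiles under the requested ROI protocols, build slide embeddings
# and MIL bags, and evaluate with the shared fold plan.

#' Preprocess and featurize a whole cohort
#'
#' For every slide: Otsu tissue detection, tessellation into 224-pixel
#' patches, ROI protocols (`none` always; `mask` when requested, using the
#' recorded tumour mask; `learned` when a [TileFilterModel-class] is
#' supplied), then the 8 dihedral-variant features of every tissue-kept tile
#' (computed once and reused by all views), slide embeddings per protocol,
#' and identity-transform feature matrices for the MIL bags.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param protocols subset of `c("none", "mask", "learned")`.
#' @param nViews views per slide embedding (default 100).
#' @param viewFraction tile fraction per view (default 0.25).
#' @param minTissueFraction tessellation keep threshold.
#' @param minTumourFraction mask-protocol keep threshold.
#' @param tileFilter optional [TileFilterModel-class] for the learned
#'   protocol.
#' @param seed base seed for the view sampling (one sub-seed per slide).
#' @param verbose print a dot per slide.
#' @return A list of class `iccaFeatures`: `slides` (data.frame of slide_id,
#'   patient_id, true_class, sample_type, n_tiles per protocol),
#'   `embeddings` (per protocol: slides x 64 matrix), `tileFeatures` (per
#'   protocol: list of per-slide identity-feature matrices) and `grids`.
#' @export
cohortFeatures <- function(cohort, protocols = c("none", "mask"),
                           nViews = 100L, viewFraction = 0.25,
                           minTissueFraction = 0.5, minTumourFraction = 0.5,
                           tileFilter = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(is(cohort, "SyntheticCohort"))
  protocols <- match.arg(protocols, c("none", "mask", "learned"),
                         several.ok = TRUE)
  if ("learned" %in% protocols && is.null(tileFilter))
    stop("the learned protocol needs a tileFilter model")
  slides <- cohort@slides
  nS <- length(slides)
  emb <- lapply(protocols, function(p) matrix(NA_real_, nS, .FEATURE_DIM))
  names(emb) <- protocols
  tf <- lapply(protocols, function(p) vector("list", nS))
  names(tf) <- protocols
  grids <- vector("list", nS)
  meta <- data.frame(slide_id = character(nS), patient_id = character(nS),
                     true_class = character(nS), sample_type = character(nS),
                     stringsAsFactors = FALSE)
  for (p in protocols) meta[[paste0("n_tiles_", p)]] <- NA_integer_

  for (i in seq_len(nS)) {
    s <- slides[[i]]
    tm <- tissueMask(s@image)
    grid <- tessellate(tm, minTissueFraction = minTissueFraction)
    if ("mask" %in% protocols)
      grid <- applyMaskFilter(grid, s@tumourMask, minTumourFraction)
    keptTiles <- extractTiles(s@image, grid, "none")
    feats <- .tileTransformFeatures(keptTiles)   # 8 x 64 x nKept
    if ("learned" %in% protocols) {
      idFeat <- t(feats[1L, , , drop = TRUE])
      if (dim(feats)[3] == 1L) idFeat <- matrix(feats[1L, , 1L], nrow = 1L)
      grid <- applyLearnedFilter(grid, tileFilter, idFeat)
    }
    keptIdx <- which(grid@keep$none)
    for (p in protocols) {
      sel <- which(grid@keep[[p]][keptIdx])      # indices into keptTiles
      if (!length(sel))
        stop("empty slide ", s@slideId, " under protocol '", p, "'")
      sub <- feats[, , sel, drop = FALSE]
      e <- embedSlide(sub, nViews = nViews, viewFraction = viewFraction,
                      seed = subSeed(seed, i))
      emb[[p]][i, ] <- e@vector
      idf <- t(sub[1L, , , drop = TRUE])
      if (length(sel) == 1L) idf <- matrix(sub[1L, , 1L], nrow = 1L)
      tf[[p]][[i]] <- idf
      meta[[paste0("n_tiles_", p)]][i] <- length(sel)
    }
    grids[[i]] <- grid
    meta$slide_id[i] <- s@slideId
    meta$patient_id[i] <- s@patientId
    meta$true_class[i] <- s@trueClass
    meta$sample_type[i] <- s@sampleType
    if (verbose) cat(".")
  }
  if (verbose) cat("\n")
  for (p in protocols) rownames(emb[[p]]) <- meta$slide_id
  structure(list(slides = meta, embeddings = emb, tileFeatures = tf,
                 grids = grids), class = "iccaFeatures")
}

#' @export
print.iccaFeatures <- function(x, ...) {
  cat(sprintf("iccaFeatures: %d slides, protocols: %s\n",
              nrow(x$slides), paste(names(x$embeddings), collapse = ", ")))
  invisible(x)
}

#' Build one-vs-rest MIL bags from cohort features
#'
#' One bag per slide: the identity-transform features of the tiles kept
#' under `protocol`, labelled 1 when the patient's class is `taskClass`.
#'
#' @param features an `iccaFeatures` from [cohortFeatures()].
#' @param taskClass the positive class (one of [ICCA_CLASSES]).
#' @param protocol which ROI protocol's tiles to use.
#' @return list of [milBag()] objects.
#' @export
cohortBags <- function(features, taskClass, protocol = "none") {
  stopifnot(taskClass %in% ICCA_CLASSES,
            protocol %in% names(features$tileFeatures))
  m <- features$slides
  lapply(seq_len(nrow(m)), function(i) {
    milBag(features$tileFeatures[[protocol]][[i]],
           as.integer(m$true_class[i] == taskClass),
           slideId = m$slide_id[i], patientId = m$patient_id[i])
  })
}

#' One-vs-rest patient labels of a cohort
#' @param cohort a [SyntheticCohort-class].
#' @param taskClass the positive class.
#' @return named 0/1 integer vector, one entry per patient.
#' @export
cohortLabels <- function(cohort, taskClass) {
  stopifnot(taskClass %in% ICCA_CLASSES)
  cl <- cohort@clinical
  stats::setNames(as.integer(cl$true_class == taskClass), cl$patient_id)
}

#' Sample labelled tile features for the learned filter
#'
#' Draws random tissue tiles across the cohort and labels each by its
#' majority content under the recorded tumour mask ("tumour" when the tumour
#' fraction reaches `minTumourFraction`, "non-tumour" otherwise — mixed
#' tiles included, as a rater labelling randomly extracted tiles would),
#' then featurizes them, producing the training set of [trainTileFilter()].
#'
#' @param cohort a [SyntheticCohort-class].
#' @param n number of labelled tiles (default 3000, capped by availability).
#' @param minTissueFraction,minTumourFraction tessellation thresholds.
#' @param seed sampling seed.
#' @return list with `features` (n x 64) and `labels`
#'   ("tumour"/"non-tumour").
#' @export
sampleLabelledTiles <- function(cohort, n = 3000L, minTissueFraction = 0.5,
                                minTumourFraction = 0.5, seed = 1L) {
  set.seed(seed)
  cand <- list()
  for (s in cohort@slides) {
    tm <- tissueMask(s@image)
    grid <- tessellate(tm, minTissueFraction = minTissueFraction)
    grid <- applyMaskFilter(grid, s@tumourMask, minTumourFraction)
    ps <- grid@patchSize
    tfrac <- apply(grid@coords, 1L, function(cc)
      mean(s@tumourMask[(cc[2] + 1L):(cc[2] + ps),
                        (cc[1] + 1L):(cc[1] + ps)] != 0))
    keptIdx <- which(grid@keep$none)
    for (i in keptIdx) {
      lab <- if (tfrac[i] >= minTumourFraction) "tumour" else "non-tumour"
      cand[[length(cand) + 1L]] <- list(slide = s, coord = grid@coords[i, ],
                                        ps = ps, lab = lab)
    }
  }
  if (length(cand) < 2L) stop("not enough labelled tiles in the cohort")
  take <- sample(length(cand), min(n, length(cand)))
  feats <- t(vapply(cand[take], function(cd) {
    cc <- cd$coord
    featurizeTile(cd$slide@image[(cc[2] + 1L):(cc[2] + cd$ps),
                                 (cc[1] + 1L):(cc[1] + cd$ps), , drop = FALSE])
  }, numeric(.FEATURE_DIM)))
  list(features = feats, labels = vapply(cand[take], `[[`, character(1), "lab"))
}

#' Run the synthetic evaluation study
#'
#' The package's end-to-end benchmark: a synthetic cohort of `nPatients`
#' patients (texture effect 2, 30% tumour tissue per slide, i.e. about 70%
#' non-tumour tiles), preprocessing and embedding under the no-filter and
#' tumour-mask ROI protocols, and patient-level stratified 5-fold
#' cross-validation of (a) the C = 7 balanced logistic heads on the slide
#' embeddings and (b) the gated-attention MIL model on the tile bags, for
#' the dominant-class (hepatic stem-like) one-vs-rest task. Also computes a
#' permutation null: the mean head AUC over `nShuffles` relabelings of the
#' patients.
#'
#' @param seed integer seed driving every random choice.
#' @param nPatients cohort size (default 60).
#' @param nViews views per slide embedding.
#' @param nShuffles label shuffles for the permutation null.
#' @param verbose print progress.
#' @return list with the cohort-level results: patient- and slide-level AUCs
#'   per model and protocol, the protocol effects, and the shuffled-label
#'   AUC.
#' @export
runEvaluationStudy <- function(seed = 1L, nPatients = 60L, nViews = 100L,
                               nShuffles = 10L, verbose = FALSE) {
  cfg <- cohortConfig(nPatients = nPatients, textureEffect = 2,
                      tumourFractionRange = c(0.3, 0.3),
                      seed = subSeed(seed, 101L))
  cohort <- generateCohort(cfg)
  feats <- cohortFeatures(cohort, protocols = c("none", "mask"),
                          nViews = nViews, seed = subSeed(seed, 7L),
                          verbose = verbose)
  task <- ICCA_CLASSES[1]
  labels <- cohortLabels(cohort, task)
  plan <- stratifiedPatientFolds(labels, k = 5L, seed = subSeed(seed, 13L))

  heads <- lapply(feats$embeddings, function(E)
    crossValidate(E, feats$slides$patient_id, labels, plan))
  mil <- lapply(names(feats$tileFeatures), function(p)
    milCrossValidate(cohortBags(feats, task, p), labels, plan,
                     seed = subSeed(seed, 17L)))
  names(mil) <- names(feats$tileFeatures)

  shuffAuc <- vapply(seq_len(nShuffles), function(s) {
    set.seed(subSeed(seed, 29L + s))
    sl <- stats::setNames(sample(unname(labels)), names(labels))
    pl <- stratifiedPatientFolds(sl, k = 5L, seed = subSeed(seed, 31L + s))
    cv <- crossValidate(feats$embeddings$mask, feats$slides$patient_id, sl, pl)
    cv$patient["auc"]
  }, numeric(1))

  list(
    cohort = cohort, features = feats, plan = plan,
    heads = heads, mil = mil,
    head_auc_none = unname(heads$none$patient["auc"]),
    head_auc_mask = unname(heads$mask$patient["auc"]),
    head_auc_none_slide = unname(heads$none$slide["auc"]),
    head_auc_mask_slide = unname(heads$mask$slide["auc"]),
    mil_auc_none = unname(mil$none$patient["auc"]),
    mil_auc_mask = unname(mil$mask$patient["auc"]),
    head_protocol_effect = unname(heads$mask$patient["auc"] - heads$none$patient["auc"]),
    mil_protocol_effect = unname(mil$mask$patient["auc"] - mil$none$patient["auc"]),
    shuffled_auc = mean(shuffAuc))
}
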