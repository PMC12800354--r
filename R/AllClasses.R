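#' The five iCCA transcriptomic classes
#'
#' Canonical order of the five expression-defined intrahepatic
#' cholangiocarcinoma subtypes. This order is also the documented
#' tie-break order of [assignClass()].
#'
#' @export
ICCA_CLASSES <- c(
  "hepatic stem-like", "tumour classical", "inflammatory stroma",
  "immune classical", "desert-like"
)

## ---------------------------------------------------------------------------
## CohortConfig
## ---------------------------------------------------------------------------

#' @rdname CohortConfig
#' @export
setClass("CohortConfig", representation(
  nPatients            = "integer",
  classPrevalences     = "numeric",
  slidesPerPatientRange = "integer",
  biopsyFraction       = "numeric",
  imageSize            = "integer",
  tumourFractionRange  = "numeric",
  textureEffect        = "numeric",
  nGenes               = "integer",
  signatureSize        = "integer",
  expressionEffect     = "numeric",
  dropoutRate          = "numeric",
  hazardByClass        = "numeric",
  censorRate           = "numeric",
  seed                 = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  p <- object@classPrevalences
  if (length(p) != 5L || any(p < 0) || any(p > 1))
    msg <- c(msg, "classPrevalences must be 5 probabilities in [0,1]")
  else if (abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "classPrevalences must sum to 1 (within 1e-9)")
  r <- object@slidesPerPatientRange
  if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
    msg <- c(msg, "slidesPerPatientRange must be an integer interval with lower bound >= 1")
  if (length(object@hazardByClass) != 5L || any(object@hazardByClass <= 0))
    msg <- c(msg, "hazardByClass must be 5 positive rates")
  for (nm in c("biopsyFraction", "dropoutRate", "censorRate")) {
    v <- slot(object, nm)
    if (length(v) != 1L || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a probability in [0,1]", nm))
  }
  if (object@textureEffect < 0) msg <- c(msg, "textureEffect must be >= 0")
  if (object@expressionEffect < 0) msg <- c(msg, "expressionEffect must be >= 0")
  tf <- object@tumourFractionRange
  if (length(tf) != 2L || tf[1] < 0 || tf[2] > 1 || tf[2] < tf[1])
    msg <- c(msg, "tumourFractionRange must be an ordered interval inside [0,1]")
  if (object@imageSize < 448L)
    msg <- c(msg, "imageSize must be at least 448 (two 224-pixel patch rows)")
  if (object@nGenes < 5L * object@signatureSize)
    msg <- c(msg, "nGenes must be at least 5 * signatureSize (disjoint signatures)")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic iCCA cohort generator
#'
#' Bundles every knob of the synthetic cohort: cohort composition, slide
#' rendering, expression simulation and survival simulation. Defaults encode
#' the study conditions the pipeline is evaluated under: class prevalences
#' anchored on the printed discovery-set frequencies (37% hepatic stem-like,
#' 4% desert-like), 1-5 slides per patient, and per-class overall-survival
#' hazards set from the reported median survivals (about 49, 21, 31, 43 and
#' 43 months).
#'
#' @param nPatients number of patients.
#' @param classPrevalences probabilities of the five classes, in the order of
#'   [ICCA_CLASSES]; must sum to 1.
#' @param slidesPerPatientRange inclusive integer range of slides per patient.
#' @param biopsyFraction probability a slide is a biopsy (small tissue core)
#'   rather than a surgical specimen.
#' @param imageSize side of the square synthetic slide, in pixels (>= 448).
#' @param tumourFractionRange range of the proportion of tissue pixels that
#'   are tumour on each slide.
#' @param textureEffect scalar >= 0 scaling the class-conditional deviation of
#'   tumour texture from the shared base texture; 0 makes tumour texture
#'   identically distributed across classes.
#' @param nGenes number of simulated genes (>= 5 * signatureSize).
#' @param signatureSize genes per class signature (signatures are disjoint).
#' @param expressionEffect log-scale upward shift of a patient's own class
#'   signature genes; 0 removes the expression class structure.
#' @param dropoutRate probability each expression entry is independently
#'   zeroed (technical dropout).
#' @param hazardByClass exponential event hazards (per month) for the five
#'   classes, in [ICCA_CLASSES] order.
#' @param censorRate probability a patient is censored before the event.
#' @param seed integer seed; the whole cohort is deterministic given the
#'   configuration.
#'
#' @return A validated `CohortConfig` object.
#' @seealso [generateCohort()]
#' @examples
#' cfg <- cohortConfig(nPatients = 10, seed = 1)
#' cfg
#' @export
cohortConfig <- function(nPatients = 60L,
                         classPrevalences = c(0.37, 0.13, 0.21, 0.25, 0.04),
                         slidesPerPatientRange = c(1L, 5L),
                         biopsyFraction = 0.3,
                         imageSize = 672L,
                         tumourFractionRange = c(0.3, 0.6),
                         textureEffect = 1,
                         nGenes = 2000L,
                         signatureSize = 50L,
                         expressionEffect = 2,
                         dropoutRate = 0.2,
                         hazardByClass = log(2) / c(49, 21, 31, 43, 43),
                         censorRate = 0.3,
                         seed = 1L) {
  cp <- as.numeric(classPrevalences)
  if (is.null(names(cp)) && length(cp) == 5L) names(cp) <- ICCA_CLASSES
  hz <- as.numeric(hazardByClass)
  if (is.null(names(hz)) && length(hz) == 5L) names(hz) <- ICCA_CLASSES
  new("CohortConfig",
      nPatients = as.integer(nPatients),
      classPrevalences = cp,
      slidesPerPatientRange = as.integer(slidesPerPatientRange),
      biopsyFraction = as.numeric(biopsyFraction),
      imageSize = as.integer(imageSize),
      tumourFractionRange = as.numeric(tumourFractionRange),
      textureEffect = as.numeric(textureEffect),
      nGenes = as.integer(nGenes),
      signatureSize = as.integer(signatureSize),
      expressionEffect = as.numeric(expressionEffect),
      dropoutRate = as.numeric(dropoutRate),
      hazardByClass = hz,
      censorRate = as.numeric(censorRate),
      seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPatients, "patients,",
      paste0(object@slidesPerPatientRange, collapse = "-"), "slides/patient\n")
  cat("  prevalences:", paste(sprintf("%s=%.2f", abbreviate(names(object@classPrevalences), 8),
                                      object@classPrevalences), collapse = " "), "\n")
  cat(sprintf("  image %dpx, tumour fraction [%.2f, %.2f], texture effect %.2g\n",
              object@imageSize, object@tumourFractionRange[1],
              object@tumourFractionRange[2], object@textureEffect))
  cat(sprintf("  %d genes, %d/signature, expression effect %.2g, dropout %.2f\n",
              object@nGenes, object@signatureSize, object@expressionEffect,
              object@dropoutRate))
  cat(sprintf("  censor rate %.2f, seed %d\n", object@censorRate, object@seed))
})

## ---------------------------------------------------------------------------
## SlideRecord / SyntheticCohort
## ---------------------------------------------------------------------------

#' @rdname SlideRecord
#' @export
setClass("SlideRecord", representation(
  slideId    = "character",
  patientId  = "character",
  image      = "array",
  tumourMask = "ANY",       # integer/logical matrix or NULL
  sampleType = "character", # "biopsy" or "surgical"
  rnaLinked  = "character", # "RNA+" or "RNA-"
  trueClass  = "character"
))

setValidity("SlideRecord", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be an H x W x 3 array")
  if (!is.null(object@tumourMask)) {
    m <- object@tumourMask
    if (!identical(dim(m), d[1:2]))
      msg <- c(msg, "tumourMask must match the image plane dimensions")
    else if (!all(m %in% c(0L, 1L)))
      msg <- c(msg, "tumourMask must be binary")
  }
  if (!object@sampleType %in% c("biopsy", "surgical"))
    msg <- c(msg, "sampleType must be 'biopsy' or 'surgical'")
  if (!object@rnaLinked %in% c("RNA+", "RNA-"))
    msg <- c(msg, "rnaLinked must be 'RNA+' or 'RNA-'")
  if (!object@trueClass %in% ICCA_CLASSES)
    msg <- c(msg, "trueClass must be one of the five iCCA classes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SlideRecord", function(object) {
  d <- dim(object@image)
  cat(sprintf("SlideRecord %s (patient %s, %s, %s): %dx%d, class '%s', %s\n",
              object@slideId, object@patientId, object@sampleType,
              object@rnaLinked, d[1], d[2], object@trueClass,
              if (is.null(object@tumourMask)) "no mask" else "with tumour mask"))
})

#' @rdname SyntheticCohort
#' @export
setClass("SyntheticCohort", representation(
  slides     = "list",
  expression = "matrix",
  signatures = "list",
  survival   = "data.frame",
  clinical   = "data.frame",
  config     = "CohortConfig"
))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  pats <- unique(vapply(object@slides, function(s) s@patientId, character(1)))
  if (!setequal(colnames(object@expression), pats) ||
      ncol(object@expression) != length(pats))
    msg <- c(msg, "expression must hold exactly one sample per patient")
  if (!all(pats %in% object@clinical$patient_id))
    msg <- c(msg, "every slide's patient must appear in the clinical table")
  if (!all(c("patient_id", "time", "event") %in% colnames(object@survival)))
    msg <- c(msg, "survival needs columns patient_id, time, event")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d patients, %d slides, %d x %d expression\n",
              nrow(object@clinical), length(object@slides),
              nrow(object@expression), ncol(object@expression)))
  print(table(object@clinical$true_class))
})

#' Accessors for SyntheticCohort
#'
#' `cohortSlides()` returns the list of [SlideRecord-class] objects,
#' `cohortExpression()` the genes x patients count matrix,
#' `cohortSignatures()` the named list of class signature gene sets,
#' `cohortSurvival()` and `cohortClinical()` the per-patient tables.
#'
#' @param x a [SyntheticCohort-class].
#' @return See the description for each accessor.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortSlides <- function(x) x@slides
#' @rdname cohort-accessors
#' @export
cohortExpression <- function(x) x@expression
#' @rdname cohort-accessors
#' @export
cohortSignatures <- function(x) x@signatures
#' @rdname cohort-accessors
#' @export
cohortSurvival <- function(x) x@survival
#' @rdname cohort-accessors
#' @export
cohortClinical <- function(x) x@clinical

## ---------------------------------------------------------------------------
## TissueMask / PatchGrid / TileFilterModel
## ---------------------------------------------------------------------------

#' @rdname tissueMask
#' @export
setClass("TissueMask", representation(
  mask      = "matrix",
  threshold = "numeric",
  method    = "character"
))

setValidity("TissueMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (object@threshold < 0 || object@threshold > 255)
    msg <- c(msg, "threshold must lie in [0, 255]")
  if (!identical(object@method, "otsu")) msg <- c(msg, "method must be 'otsu'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask %dx%d (otsu threshold %g): %.1f%% tissue\n",
              nrow(object@mask), ncol(object@mask), object@threshold,
              100 * mean(object@mask)))
})

#' PatchGrid: the non-overlapping tessellation of one slide
#'
#' Records every cell of the regular, non-overlapping patch grid anchored at
#' pixel (0,0): upper-left corners (0-based, half-open windows
#' `[x, x + patchSize)`), the tissue fraction of each cell, and per-protocol
#' keep flags (`none` = tissue filter only, `mask` = tumour-annotation
#' filter, `learned` = learned tile filter; the latter two are `NA` until
#' [applyMaskFilter()] / [applyLearnedFilter()] are run).
#'
#' @seealso [tessellate()]
#' @export
setClass("PatchGrid", representation(
  patchSize      = "integer",
  coords         = "matrix",    # n x 2, columns x, y (0-based)
  tissueFraction = "numeric",
  keep           = "data.frame",
  imageDim       = "integer",   # H, W
  minTissueFraction = "numeric"
))

setValidity("PatchGrid", function(object) {
  msg <- character()
  ps <- object@patchSize
  xy <- object@coords
  if (ncol(xy) != 2L) msg <- c(msg, "coords must have two columns (x, y)")
  if (any(xy %% ps != 0)) msg <- c(msg, "coords must lie on the patch-size grid")
  if (any(xy[, 1] + ps > object@imageDim[2]) ||
      any(xy[, 2] + ps > object@imageDim[1]))
    msg <- c(msg, "all windows must lie inside the image")
  if (anyDuplicated(xy)) msg <- c(msg, "coords must not overlap")
  if (!all(c("none", "mask", "learned") %in% colnames(object@keep)))
    msg <- c(msg, "keep must have columns none, mask, learned")
  if (nrow(object@keep) != nrow(xy) ||
      length(object@tissueFraction) != nrow(xy))
    msg <- c(msg, "per-patch vectors must align with coords")
  km <- object@keep$mask; kl <- object@keep$learned
  if (any(km & !object@keep$none, na.rm = TRUE) ||
      any(kl & !object@keep$none, na.rm = TRUE))
    msg <- c(msg, "mask/learned keeps must be subsets of the tissue keeps")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PatchGrid", function(object) {
  k <- object@keep
  cat(sprintf("PatchGrid: %d cells of %dpx on a %dx%d slide\n",
              nrow(object@coords), object@patchSize,
              object@imageDim[1], object@imageDim[2]))
  cat(sprintf("  kept: none=%d, mask=%s, learned=%s\n", sum(k$none),
              if (all(is.na(k$mask))) "unset" else sum(k$mask, na.rm = TRUE),
              if (all(is.na(k$learned))) "unset" else sum(k$learned, na.rm = TRUE)))
})

#' Number of kept patches under a protocol
#' @param grid a [PatchGrid-class].
#' @param protocol one of `"none"`, `"mask"`, `"learned"`.
#' @return integer count of kept patches.
#' @export
keptPatches <- function(grid, protocol = c("none", "mask", "learned")) {
  protocol <- match.arg(protocol)
  k <- grid@keep[[protocol]]
  if (all(is.na(k)))
    stop("protocol '", protocol, "' has not been applied to this grid")
  sum(k, na.rm = TRUE)
}

#' @rdname trainTileFilter
#' @export
setClass("TileFilterModel", representation(
  weights      = "numeric",
  bias         = "numeric",
  threshold    = "numeric",
  trainingSize = "integer"
))

setValidity("TileFilterModel", function(object) {
  if (object@threshold <= 0 || object@threshold >= 1)
    "threshold must lie in (0,1)" else TRUE
})

setMethod("show", "TileFilterModel", function(object) {
  cat(sprintf("TileFilterModel: %d features, threshold %.2f, trained on %d tiles\n",
              length(object@weights), object@threshold, object@trainingSize))
})

## ---------------------------------------------------------------------------
## SlideEmbedding
## ---------------------------------------------------------------------------

#' @rdname slideEmbedding
#' @export
setClass("SlideEmbedding", representation(
  vector = "numeric",
  nViews = "integer"
))

setValidity("SlideEmbedding", function(object) {
  if (!all(is.finite(object@vector))) return("embedding must be finite")
  n2 <- sqrt(sum(object@vector^2))
  if (abs(n2 - 1) > 1e-9) return("embedding must have unit Euclidean norm")
  TRUE
})

setMethod("show", "SlideEmbedding", function(object) {
  cat(sprintf("SlideEmbedding: D=%d, %d views, ||.||2 = %.9f\n",
              length(object@vector), object@nViews,
              sqrt(sum(object@vector^2))))
})

#' @rdname slideEmbedding
#' @param x a `SlideEmbedding`.
#' @export
embeddingVector <- function(x) x@vector

## ---------------------------------------------------------------------------
## MIL
## ---------------------------------------------------------------------------

#' @rdname milBag
#' @export
setClass("Bag", representation(
  instances = "matrix",
  label     = "integer",
  slideId   = "character",
  patientId = "character"
))

setValidity("Bag", function(object) {
  msg <- character()
  if (nrow(object@instances) < 1L) msg <- c(msg, "a bag needs at least one instance")
  if (!all(is.finite(object@instances))) msg <- c(msg, "instances must be finite")
  if (!object@label %in% c(0L, 1L)) msg <- c(msg, "label must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MIL bag
#'
#' A bag is the instance-level representation of one slide: the feature
#' matrix of its kept tiles, with the slide-level binary label.
#'
#' @param instances n x D tile-feature matrix.
#' @param label 0/1 slide label.
#' @param slideId,patientId identifiers.
#' @return A `Bag` object.
#' @export
milBag <- function(instances, label, slideId = "slide", patientId = "patient") {
  new("Bag", instances = as.matrix(instances), label = as.integer(label),
      slideId = as.character(slideId), patientId = as.character(patientId))
}

setMethod("show", "Bag", function(object) {
  cat(sprintf("Bag %s (patient %s): %d instances x %d features, label %d\n",
              object@slideId, object@patientId, nrow(object@instances),
              ncol(object@instances), object@label))
})

#' @rdname trainMIL
#' @export
setClass("AttentionMILModel", representation(
  V      = "matrix",
  U      = "matrix",
  w      = "numeric",
  headW  = "numeric",
  headB  = "numeric",
  hidden = "integer"
))

setValidity("AttentionMILModel", function(object) {
  msg <- character()
  if (!identical(dim(object@V), dim(object@U)))
    msg <- c(msg, "V and U must share dimensions (hidden x D)")
  if (nrow(object@V) != object@hidden || length(object@w) != object@hidden)
    msg <- c(msg, "attention vector w must have length 'hidden'")
  if (length(object@headW) != ncol(object@V))
    msg <- c(msg, "head weights must have length D")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AttentionMILModel", function(object) {
  cat(sprintf("AttentionMILModel: gated attention, D=%d, hidden=%d\n",
              ncol(object@V), object@hidden))
})

## ---------------------------------------------------------------------------
## FoldPlan
## ---------------------------------------------------------------------------

#' @rdname stratifiedPatientFolds
#' @export
setClass("FoldPlan", representation(
  k          = "integer",
  assignment = "integer",   # named by patient id
  stratifyOn = "character"  # label per patient, same names
))

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by patient id")
  if (any(object@assignment < 1L) || any(object@assignment > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  tab <- table(object@stratifyOn, object@assignment)
  if (nrow(tab) > 0 && any(apply(tab, 1, function(r) diff(range(r))) > 1L))
    msg <- c(msg, "per-fold class counts must differ by at most 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d folds over %d patients\n", object@k,
              length(object@assignment)))
  print(table(label = object@stratifyOn, fold = object@assignment))
})

#' @rdname stratifiedPatientFolds
#' @param plan a `FoldPlan`.
#' @export
foldAssignment <- function(plan) plan@assignment
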