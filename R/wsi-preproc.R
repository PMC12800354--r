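# Tissue detection, tessellation and the three ROI protocols.

#' Otsu threshold of a 256-level grayscale histogram
#'
#' Returns the threshold `t` in 1..255 maximizing the between-class variance
#' of the split into levels `< t` versus levels `>= t`. Exact ties are broken
#' by the lowest maximizing level.
#'
#' @param histogram 256 nonnegative counts for levels 0..255.
#' @return The integer threshold level.
#' @examples
#' h <- integer(256); h[11] <- 50; h[201] <- 50  # mass at levels 10 and 200
#' otsuThreshold(h)  # 11: lowest of the tied maximizers
#' @export
otsuThreshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0))
    stop("histogram must be 256 nonnegative counts")
  occupied <- which(histogram > 0)
  if (length(occupied) < 2L)
    stop("degenerate histogram: fewer than two occupied levels")
  p <- histogram / sum(histogram)
  levels <- 0:255
  w1 <- cumsum(p)                       # weight of {0..t}
  m1 <- cumsum(p * levels)              # unnormalized mean of {0..t}
  mT <- m1[256]
  # candidate thresholds t = 1..255 split at {0..t-1} vs {t..255}
  w <- w1[1:255]
  m <- m1[1:255]
  sb <- rep(0, 255)
  ok <- w > 0 & w < 1
  sb[ok] <- (mT * w[ok] - m[ok])^2 / (w[ok] * (1 - w[ok]))
  which.max(sb)                          # lowest maximizer
}

#' Detect tissue on a slide by Otsu thresholding
#'
#' Converts the image to grayscale (unweighted channel mean), computes the
#' Otsu threshold of its 256-level histogram, and marks as tissue every
#' pixel strictly darker than the threshold (the background is assumed
#' bright).
#'
#' @param image an `H x W x 3` raster with values in 0..255.
#' @return A [TissueMask-class].
#' @export
tissueMask <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L || d[1] == 0 || d[2] == 0)
    stop("image must be a nonempty H x W x 3 array")
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  lev <- pmin(pmax(floor(gray), 0), 255)
  h <- tabulate(as.integer(lev) + 1L, nbins = 256L)
  t <- otsuThreshold(h)
  new("TissueMask", mask = matrix(lev < t, d[1], d[2]),
      threshold = as.numeric(t), method = "otsu")
}

#' Tessellate a tissue mask into non-overlapping patches
#'
#' Enumerates the regular grid of non-overlapping `patchSize` windows
#' anchored at pixel (0,0) (margins that do not fit a full window are
#' clipped, never padded), records each cell's tissue fraction, and keeps
#' under the no-filter protocol the cells with tissue fraction at or above
#' `minTissueFraction`.
#'
#' @param mask a [TissueMask-class] (or a logical matrix).
#' @param patchSize patch side in pixels (default 224).
#' @param minTissueFraction minimum tissue fraction for a cell to be kept.
#' @return A [PatchGrid-class].
#' @export
tessellate <- function(mask, patchSize = 224L, minTissueFraction = 0.5) {
  m <- if (is(mask, "TissueMask")) mask@mask else mask
  stopifnot(is.matrix(m))
  patchSize <- as.integer(patchSize)
  H <- nrow(m); W <- ncol(m)
  if (patchSize > H || patchSize > W)
    stop("patchSize larger than the image")
  xs <- seq(0L, W - patchSize, by = patchSize)
  ys <- seq(0L, H - patchSize, by = patchSize)
  coords <- cbind(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
  frac <- apply(coords, 1L, function(cc) {
    mean(m[(cc[2] + 1L):(cc[2] + patchSize), (cc[1] + 1L):(cc[1] + patchSize)])
  })
  keep <- data.frame(none = frac >= minTissueFraction,
                     mask = NA, learned = NA)
  new("PatchGrid", patchSize = patchSize, coords = coords,
      tissueFraction = as.numeric(frac), keep = keep,
      imageDim = c(H, W), minTissueFraction = minTissueFraction)
}

#' Apply the tumour-annotation (mask) ROI protocol
#'
#' Marks as kept under the mask protocol every tissue-kept patch whose
#' tumour-pixel fraction (tumour pixels / patch area) is at least
#' `minTumourFraction`. The tumour mask stands in for an expert pathologist's
#' tumour annotation.
#'
#' @param grid a [PatchGrid-class].
#' @param tumourMask binary matrix of the same shape as the slide.
#' @param minTumourFraction minimum tumour fraction (default 0.5).
#' @return The grid with its `mask` keep column filled in.
#' @export
applyMaskFilter <- function(grid, tumourMask, minTumourFraction = 0.5) {
  stopifnot(is(grid, "PatchGrid"))
  if (!identical(dim(tumourMask), as.integer(grid@imageDim)) &&
      !identical(dim(tumourMask), grid@imageDim))
    stop("tumour mask shape does not match the slide")
  ps <- grid@patchSize
  tf <- apply(grid@coords, 1L, function(cc) {
    mean(tumourMask[(cc[2] + 1L):(cc[2] + ps), (cc[1] + 1L):(cc[1] + ps)] != 0)
  })
  grid@keep$mask <- grid@keep$none & tf >= minTumourFraction
  validObject(grid)
  grid
}

#' Train the learned tile filter
#'
#' L2-regularised logistic regression separating tumour from non-tumour
#' tiles, trained on labelled tile features (3,000 labelled tiles in the
#' reference protocol).
#'
#' @param features n x D tile-feature matrix.
#' @param labels per-tile labels: 1/`"tumour"` vs 0/`"non-tumour"`.
#' @param C inverse regularization strength.
#' @param threshold probability cutoff of the resulting filter.
#' @return A [TileFilterModel-class].
#' @export
trainTileFilter <- function(features, labels, C = 1, threshold = 0.5) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "tumour") else as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("both tumour and non-tumour tiles are required")
  fit <- ridgeLogistic(features, y, C = C)
  new("TileFilterModel", weights = fit$coef, bias = fit$intercept,
      threshold = threshold, trainingSize = nrow(as.matrix(features)))
}

#' Predict tumour probabilities with a tile filter
#' @param model a [TileFilterModel-class].
#' @param features n x D tile-feature matrix.
#' @return numeric vector of tumour probabilities.
#' @export
tileFilterProb <- function(model, features) {
  stopifnot(is(model, "TileFilterModel"))
  X <- as.matrix(features)
  if (ncol(X) != length(model@weights))
    stop("feature dimension does not match the tile filter")
  as.numeric(stats::plogis(X %*% model@weights + model@bias))
}

#' Apply the learned ROI protocol
#'
#' Marks as kept under the learned protocol every tissue-kept patch whose
#' predicted tumour probability reaches the model threshold. `features` must
#' hold one row per tissue-kept patch, in grid order.
#'
#' @param grid a [PatchGrid-class].
#' @param model a [TileFilterModel-class].
#' @param features feature matrix aligned with the tissue-kept patches.
#' @return The grid with its `learned` keep column filled in.
#' @export
applyLearnedFilter <- function(grid, model, features) {
  stopifnot(is(grid, "PatchGrid"), is(model, "TileFilterModel"))
  keptIdx <- which(grid@keep$none)
  X <- as.matrix(features)
  if (nrow(X) != length(keptIdx))
    stop("features misaligned: expected one row per tissue-kept patch (",
         length(keptIdx), "), got ", nrow(X))
  p <- tileFilterProb(model, X)
  learned <- rep(FALSE, nrow(grid@coords))
  learned[keptIdx] <- p >= model@threshold
  grid@keep$learned <- learned
  validObject(grid)
  grid
}

#' Extract kept patches from a slide image
#'
#' @param image `H x W x 3` raster the grid was computed on.
#' @param grid a [PatchGrid-class].
#' @param protocol which keep column to use.
#' @return A list of `patchSize x patchSize x 3` arrays, named by
#'   `"x_y"` of the patch corner; empty slides raise an error.
#' @export
extractTiles <- function(image, grid, protocol = c("none", "mask", "learned")) {
  protocol <- match.arg(protocol)
  k <- grid@keep[[protocol]]
  if (all(is.na(k))) stop("protocol '", protocol, "' not applied to this grid")
  idx <- which(!is.na(k) & k)
  if (!length(idx))
    stop("empty slide: no patches kept under protocol '", protocol, "'")
  ps <- grid@patchSize
  out <- lapply(idx, function(i) {
    cc <- grid@coords[i, ]
    image[(cc[2] + 1L):(cc[2] + ps), (cc[1] + 1L):(cc[1] + ps), , drop = FALSE]
  })
  names(out) <- sprintf("%d_%d", grid@coords[idx, 1], grid@coords[idx, 2])
  out
}
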