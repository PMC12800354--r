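# Deterministic tile featurization and the view-ensembled slide embedding:
# embeddings are ensembled over views (default 100), then L2-normalized.

.FEATURE_DIM <- 64L

.grayQuant <- function(gray) pmin(floor(gray / 32), 7)  # 8 levels, 0..7

# Six co-occurrence summaries of a normalized 8x8 joint table.
.cooccurStats <- function(p) {
  i <- rep(0:7, times = 8); j <- rep(0:7, each = 8)
  contrast <- sum(p * (i - j)^2)
  dissim   <- sum(p * abs(i - j))
  homog    <- sum(p / (1 + (i - j)^2))
  energy   <- sum(p^2)
  nz <- p > 0
  entropy  <- -sum(p[nz] * log(p[nz]))
  mi <- sum(p * i); mj <- sum(p * j)
  si <- sqrt(sum(p * (i - mi)^2)); sj <- sqrt(sum(p * (j - mj)^2))
  corr <- if (si > 0 && sj > 0) sum(p * (i - mi) * (j - mj)) / (si * sj) else 0
  c(contrast = contrast, dissimilarity = dissim, homogeneity = homog,
    energy = energy, entropy = entropy, correlation = corr)
}

#' Featurize one tile
#'
#' Deterministic 64-dimensional handcrafted descriptor of a 224 x 224 x 3
#' patch: per-channel mean and standard deviation (6), per-channel 8-bin
#' intensity histograms (24), an 8-bin gradient-magnitude histogram over
#' pixels with nonzero gradient (8, all-zero for a constant patch), and 26
#' gray-level co-occurrence summaries (6 statistics for each of 4 offsets,
#' plus the mean and standard deviation of the quantized gray levels).
#' Histogram blocks are normalized to sum to 1 (or to 0 when empty).
#'
#' @param patch a `224 x 224 x 3` raster with values in 0..255 (any square
#'   side is accepted; 224 is the working patch size).
#' @return Named numeric vector of length 64.
#' @export
featurizeTile <- function(patch) {
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L || d[1] != d[2])
    stop("patch must be a square H x H x 3 array")
  v <- numeric(0)
  for (ch in 1:3) v <- c(v, mean(patch[, , ch]))
  for (ch in 1:3) v <- c(v, stats::sd(patch[, , ch]))
  for (ch in 1:3) {
    b <- tabulate(pmin(floor(patch[, , ch] / 32), 7) + 1L, nbins = 8L)
    v <- c(v, b / sum(b))
  }
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  H <- d[1]
  # central differences: the magnitude multiset is exactly invariant under
  # all 8 dihedral transforms of the patch
  gx <- (gray[2:(H - 1), 3:H] - gray[2:(H - 1), 1:(H - 2)]) / 2
  gy <- (gray[3:H, 2:(H - 1)] - gray[1:(H - 2), 2:(H - 1)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mag <- mag[mag > 0]
  gbreaks <- c(0, 2, 4, 8, 16, 32, 64, 128, Inf)
  if (length(mag)) {
    gb <- tabulate(findInterval(mag, gbreaks, left.open = TRUE), nbins = 8L)
    v <- c(v, gb / sum(gb))
  } else v <- c(v, rep(0, 8))
  q <- .grayQuant(gray)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- 1:(H - dr); c1 <- if (dc >= 0) 1:(H - dc) else (1 - dc):H
    a <- q[r1, c1]
    b <- q[r1 + dr, c1 + dc]
    tab <- tabulate(a * 8L + b + 1L, nbins = 64L)
    v <- c(v, .cooccurStats(tab / sum(tab)))
  }
  v <- c(v, mean(q) / 7, stats::sd(q) / 7)
  names(v) <- c(paste0("mean_", c("R", "G", "B")), paste0("sd_", c("R", "G", "B")),
                paste0("hist_", rep(c("R", "G", "B"), each = 8), rep(1:8, 3)),
                paste0("grad", 1:8),
                paste0("glcm_", rep(c("h", "v", "d1", "d2"), each = 6),
                       "_", rep(c("con", "dis", "hom", "ene", "ent", "cor"), 4)),
                "q_mean", "q_sd")
  stopifnot(length(v) == .FEATURE_DIM)
  v
}

#' Sample one view of a slide's kept tiles
#'
#' A view is a random subset of `ceiling(fraction * n)` kept tiles, sampled
#' without replacement, each paired with a random dihedral transform
#' (flips and 90-degree rotations) applied before featurization.
#'
#' @param nTiles number of kept tiles on the slide.
#' @param fraction fraction of tiles per view (default 0.25).
#' @return A data.frame with columns `tile` (index) and `transform` (1..8).
#' @export
sampleView <- function(nTiles, fraction = 0.25) {
  if (nTiles < 1L) stop("empty slide: no kept tiles to sample a view from")
  m <- ceiling(fraction * nTiles)
  tiles <- sample.int(nTiles, m)
  data.frame(tile = tiles, transform = sample.int(8L, m, replace = TRUE))
}

#' Ensemble view embeddings into a slide embedding
#'
#' Each view embedding is the mean of its tile features; the slide vector is
#' the mean over views, then L2-normalized.
#'
#' @param views a matrix of view embeddings (rows = views) or a list of
#'   numeric vectors.
#' @return A [SlideEmbedding-class] of unit Euclidean norm.
#' @examples
#' ensembleViews(rbind(c(1, 0), c(0, 1), c(1, 1)))  # -> (sqrt(2)/2, sqrt(2)/2)
#' @export
ensembleViews <- function(views) {
  if (is.list(views)) views <- do.call(rbind, views)
  views <- as.matrix(views)
  if (nrow(views) < 1L) stop("at least one view is required")
  v <- colMeans(views)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("zero vector after view averaging; cannot normalize")
  new("SlideEmbedding", vector = as.numeric(v / nrm), nViews = nrow(views))
}

# Features of every (tile, dihedral transform) pair: 8 x 64 x nTiles cache.
.tileTransformFeatures <- function(tiles) {
  vapply(tiles, function(tl) {
    t(vapply(1:8, function(k) featurizeTile(dihedral(tl, k)),
             numeric(.FEATURE_DIM)))
  }, matrix(0, 8, .FEATURE_DIM))
}

#' Compute the view-ensembled embedding of one slide
#'
#' Draws `nViews` random views of the slide's kept tiles (random 25% tile
#' subsets with per-tile dihedral augmentation by default), mean-pools tile
#' features within each view, averages over views and L2-normalizes.
#'
#' @param tiles list of kept tile arrays (see [extractTiles()]), or a
#'   precomputed `8 x 64 x nTiles` feature cache from all dihedral variants.
#' @param nViews number of views to ensemble (default 100).
#' @param viewFraction fraction of tiles per view.
#' @param seed integer seed making the view sampling reproducible.
#' @return A [SlideEmbedding-class].
#' @export
embedSlide <- function(tiles, nViews = 100L, viewFraction = 0.25, seed = 1L) {
  feats <- if (is.array(tiles) && length(dim(tiles)) == 3L) tiles
           else .tileTransformFeatures(tiles)
  nT <- dim(feats)[3]
  if (nT < 1L) stop("empty slide: no kept tiles")
  set.seed(seed)
  views <- t(vapply(seq_len(nViews), function(v) {
    vw <- sampleView(nT, viewFraction)
    f <- vapply(seq_len(nrow(vw)),
                function(i) feats[vw$transform[i], , vw$tile[i]],
                numeric(.FEATURE_DIM))
    rowMeans(as.matrix(f))
  }, numeric(.FEATURE_DIM)))
  ensembleViews(views)
}
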