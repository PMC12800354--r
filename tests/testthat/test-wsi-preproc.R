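# Tissue detection, tessellation and the ROI protocols.

test_that("otsu threshold honours the tie rule and rejects degenerate input", {
  h <- integer(256); h[11] <- 50; h[201] <- 50   # mass at levels 10 and 200
  expect_identical(otsuThreshold(h), 11L)
  h1 <- integer(256); h1[100] <- 10
  expect_error(otsuThreshold(h1), "degenerate")
  expect_error(otsuThreshold(rep(0L, 100)), "256")
})

test_that("otsu equals brute-force between-class variance maximization", {
  set.seed(101)
  for (i in 1:200) {
    h <- integer(256)
    occ <- sample(256, sample(2:16, 1))
    h[occ] <- sample(1:100, length(occ), replace = TRUE)
    expect_identical(otsuThreshold(h), bruteForceOtsu(h))
  }
})

test_that("tissue mask separates dark tissue from bright background", {
  expect_error(tissueMask(array(255, dim = c(32, 32, 3))), "degenerate")

  img <- array(250, dim = c(64, 64, 3))
  img[20:50, 10:40, ] <- 80                     # painted dark blob
  tm <- tissueMask(img)
  blob <- matrix(FALSE, 64, 64); blob[20:50, 10:40] <- TRUE
  expect_gte(mean(tm@mask[blob]), 0.99)
  expect_lte(mean(tm@mask[!blob]), 0.01)

  # inversion flips the mask (up to the threshold-side asymmetry)
  inv <- 255 - img
  tmInv <- tissueMask(inv)
  expect_gte(mean(tmInv@mask[!blob]), 0.99)
  expect_lte(mean(tmInv@mask[blob]), 0.01)
})

test_that("tessellation enumerates the exact non-overlapping grid", {
  allTissue <- matrix(TRUE, 448, 448)
  g <- tessellate(allTissue, 224L, 0.5)
  expect_equal(nrow(g@coords), 4L)
  expect_setequal(sprintf("%d_%d", g@coords[, 1], g@coords[, 2]),
                  c("0_0", "224_0", "0_224", "224_224"))
  expect_true(all(g@keep$none))

  # partial margins are clipped, never padded
  g2 <- tessellate(matrix(TRUE, 230, 224), 224L, 0.5)
  expect_equal(nrow(g2@coords), 1L)
  expect_equal(unname(g2@coords[1, ]), c(0L, 0L))

  expect_error(tessellate(matrix(TRUE, 100, 100), 224L), "larger")
})

test_that("tessellation tissue fractions equal a brute-force pixel count", {
  set.seed(55)
  m <- matrix(stats::runif(448 * 672) < 0.4, 448, 672)
  g <- tessellate(m, 224L, 0.3)
  for (i in seq_len(nrow(g@coords))) {
    cc <- g@coords[i, ]
    cnt <- 0L
    for (x in (cc[1] + 1L):(cc[1] + 224L))
      cnt <- cnt + sum(m[(cc[2] + 1L):(cc[2] + 224L), x])
    expect_equal(g@tissueFraction[i], cnt / 224^2)
    expect_equal(g@keep$none[i], cnt / 224^2 >= 0.3)
  }
})

test_that("mask protocol keeps by tumour fraction and guards empty slides", {
  m <- matrix(TRUE, 448, 448)
  g <- tessellate(m, 224L, 0.5)
  img <- array(100, dim = c(448, 448, 3))

  gAll <- applyMaskFilter(g, matrix(1L, 448, 448))
  expect_identical(gAll@keep$mask, gAll@keep$none)

  gNone <- applyMaskFilter(g, matrix(0L, 448, 448))
  expect_equal(sum(gNone@keep$mask), 0L)
  expect_error(extractTiles(img, gNone, "mask"), "empty slide")

  expect_error(applyMaskFilter(g, matrix(0L, 100, 100)), "shape")

  # random mask against an independent per-cell pixel count
  set.seed(77)
  tum <- matrix(as.integer(stats::runif(448 * 448) < 0.5), 448, 448)
  gR <- applyMaskFilter(g, tum, 0.5)
  for (i in seq_len(nrow(gR@coords))) {
    cc <- gR@coords[i, ]
    frac <- mean(tum[(cc[2] + 1L):(cc[2] + 224L), (cc[1] + 1L):(cc[1] + 224L)])
    expect_equal(unname(gR@keep$mask[i]), unname(gR@keep$none[i] && frac >= 0.5))
  }
})

test_that("learned tile filter separates separable tiles and fails on null labels", {
  set.seed(9)
  n <- 600
  X <- matrix(stats::rnorm(n * 8), n, 8)
  y <- rep(c(0L, 1L), each = n / 2)
  X[y == 1L, 1:2] <- X[y == 1L, 1:2] + 3
  tr <- sample(n, n / 2)
  model <- trainTileFilter(X[tr, ], y[tr])
  acc <- mean((tileFilterProb(model, X[-tr, ]) >= 0.5) == (y[-tr] == 1L))
  expect_gte(acc, 0.95)

  yShuf <- sample(y)
  m2 <- trainTileFilter(X[tr, ], yShuf[tr])
  acc2 <- mean((tileFilterProb(m2, X[-tr, ]) >= 0.5) == (yShuf[-tr] == 1L))
  expect_lt(abs(acc2 - 0.5), 0.12)

  expect_error(trainTileFilter(X, rep(1L, n)), "both")
})

test_that("learned protocol respects subset/threshold limits and alignment", {
  m <- matrix(TRUE, 448, 448)
  g <- tessellate(m, 224L, 0.5)
  nKept <- sum(g@keep$none)
  feats <- matrix(stats::rnorm(nKept * 4), nKept, 4)

  # near-zero threshold keeps every tissue patch (no-filter limit)
  mLow <- new("TileFilterModel", weights = rep(0, 4), bias = 0,
              threshold = 1e-9, trainingSize = 10L)
  gLow <- applyLearnedFilter(g, mLow, feats)
  expect_identical(gLow@keep$learned, gLow@keep$none)

  expect_error(applyLearnedFilter(g, mLow, feats[-1, , drop = FALSE]),
               "misaligned")
})

test_that("learned filter approximates the tumour-mask protocol on synthetic slides", {
  co <- twoClassCohort()  # textureEffect = 2, 30% tumour per slide
  lab <- sampleLabelledTiles(co, n = 400L, seed = 3L)
  expect_true(all(c("tumour", "non-tumour") %in% lab$labels))
  filt <- trainTileFilter(lab$features, lab$labels)
  feats <- cohortFeatures(co, protocols = c("none", "mask", "learned"),
                          nViews = 10L, tileFilter = filt, seed = 4L)
  jac <- vapply(feats$grids, function(g) {
    a <- g@keep$mask; b <- g@keep$learned
    if (sum(a | b) == 0) return(NA_real_)
    sum(a & b) / sum(a | b)
  }, numeric(1))
  expect_gte(mean(jac, na.rm = TRUE), 0.8)
  # protocol keeps are always subsets of the tissue keeps
  for (g in feats$grids) {
    expect_true(all(!g@keep$mask | g@keep$none))
    expect_true(all(!g@keep$learned | g@keep$none))
  }
})
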