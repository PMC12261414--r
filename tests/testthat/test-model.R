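test_that("encoder applies the feed-forward map row-wise", {
  mod <- milModel(inputDim = 2, nClasses = 2, hiddenDim = 1, seed = 1)
  mod@params$Wx1 <- matrix(c(1, -1), 1, 2)
  mod@params$bx1 <- matrix(0, 1, 1)
  expect_equal(drop(encodeCells(matrix(c(3, 1), 1, 2), mod)), 2)
  # relu(0) = 0 for zero input and zero bias, any weights
  expect_true(all(encodeCells(matrix(0, 4, 2), mod) == 0))
  # duplicated rows map to duplicated outputs
  X <- matrix(rnorm(4), 2, 2)
  H <- encodeCells(X[c(1, 2, 1), ], mod)
  expect_identical(H[1, ], H[3, ])
  expect_error(encodeCells(matrix(0, 2, 5), mod), "features")
})

test_that("cell attention is a within-type softmax with the expected values", {
  # logits e = (1, 0) -> softmax = (0.7311, 0.2689)
  Hi <- matrix(c(1, 0), 2, 1)
  a <- cellAttention(Hi, w = 1, b = 0)
  expect_equal(a, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-10)
  expect_equal(a, c(0.7311, 0.2689), tolerance = 1e-4)
  # zero weights give uniform attention; singleton gives 1
  expect_equal(cellAttention(matrix(rnorm(6), 3, 2), w = c(0, 0)),
               rep(1 / 3, 3))
  expect_equal(cellAttention(matrix(rnorm(2), 1, 2), w = rnorm(2)), 1)
  # shift invariance: adding a constant to every logit changes nothing
  Hi <- matrix(rnorm(10), 5, 2)
  w <- rnorm(2)
  expect_equal(cellAttention(Hi, w, b = 0), cellAttention(Hi, w, b = 137),
               tolerance = 1e-7)
})

test_that("cell aggregation is the weighted row sum", {
  expect_equal(aggregateCells(matrix(c(4, 0, 0, 4), 2, 2, byrow = TRUE),
                              c(0.75, 0.25)), c(3, 1))
  expect_equal(aggregateCells(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                              c(0.5, 0.5)), c(0.5, 0.5))
  # convexity: identical cells reproduce that cell for any weights
  Hi <- matrix(rep(c(2, -1), each = 3), 3, 2)
  a <- cellAttention(Hi, rnorm(2))
  expect_equal(aggregateCells(Hi, a), c(2, -1))
})

test_that("cell-type attention softmaxes over present types only", {
  # logits (2, 0, 0) -> (0.7869, 0.1065, 0.1065)
  Ht <- matrix(c(2, 0, 0), 1, 3)
  beta <- cellTypeAttention(Ht, v = 1)
  expect_equal(beta, exp(c(2, 0, 0)) / sum(exp(c(2, 0, 0))), tolerance = 1e-10)
  expect_equal(beta, c(0.7869, 0.1065, 0.1065), tolerance = 1e-3)
  expect_equal(cellTypeAttention(matrix(rnorm(4), 4, 1), v = rnorm(4)), 1)
  expect_equal(cellTypeAttention(matrix(rnorm(12), 4, 3), v = rep(0, 4)),
               rep(1 / 3, 3))
})

test_that("hierarchical representation satisfies the normalization chain", {
  for (seed in 1:5) {
    set.seed(seed)
    mod <- randomModel(m = 4, d = 3, mode = if (seed %% 2) "HA" else "CTA",
                       seed = seed, attScale = 1)
    s <- randomSample(n = sample(2:9, 1), m = 4, nTypes = 3)
    r <- sampleRepresentation(mod, s)
    for (a in r$alpha) expect_equal(sum(a), 1, tolerance = 1e-6)
    expect_equal(sum(r$beta), 1, tolerance = 1e-6)
    expect_equal(sum(r$gamma), 1, tolerance = 1e-6)
    # h computed from gamma equals h computed from beta
    H <- encodeCells(s@X, mod)
    expect_equal(drop(crossprod(H, r$gamma)), r$h, tolerance = 1e-6)
  }
})

test_that("absent cell types get no weight and a single type gets all of it", {
  mod <- randomModel(m = 3, d = 4, mode = "HA", seed = 2)
  # bag containing only type 3 of a 5-type vocabulary
  s <- milSample(matrix(rnorm(9), 3, 3), rep(3L, 3), 1L, "only3")
  r <- sampleRepresentation(mod, s)
  expect_equal(r$presentTypes, 3L)
  expect_equal(r$beta, 1)
  expect_equal(r$h, drop(r$typeReprs))
})

test_that("forward pass is invariant to cell order", {
  mod <- randomModel(m = 4, d = 3, mode = "HA", seed = 3)
  set.seed(42)
  s <- randomSample(n = 8, m = 4, nTypes = 3, id = "perm")
  perm <- sample(8)
  s2 <- milSample(s@X[perm, ], s@cellType[perm], s@label, "perm2")
  r1 <- sampleRepresentation(mod, s)
  r2 <- sampleRepresentation(mod, s2)
  expect_equal(r1$h, r2$h, tolerance = 1e-6)
  expect_equal(r1$proba, r2$proba, tolerance = 1e-6)
  expect_equal(sort(r1$gamma), sort(r2$gamma), tolerance = 1e-6)
})

test_that("mode equivalences hold exactly", {
  set.seed(7)
  s <- randomSample(n = 7, m = 4, nTypes = 3)
  sOne <- milSample(s@X, rep(1L, 7), 1L, "onetype")
  for (layers in 1:2) {
    ha <- randomModel(m = 4, d = 3, mode = "HA", layers = layers, seed = 11)
    # HA with w = 0 reduces to CTA (uniform alpha = mean pooling per type)
    ha0 <- ha; ha0@params$w <- ha0@params$w * 0
    cta <- ha0; cta@mode <- "CTA"
    expect_equal(sampleRepresentation(ha0, s)$h,
                 sampleRepresentation(cta, s)$h, tolerance = 1e-6)
    # cellAtt with w = 0 reduces to meanPool
    ca0 <- ha0; ca0@mode <- "cellAtt"
    mp <- ha0; mp@mode <- "meanPool"
    expect_equal(ablationRepresentation(ca0, s)$h,
                 ablationRepresentation(mp, s)$h, tolerance = 1e-6)
    # cellAtt equals HA when the bag has a single cell type
    ca <- ha; ca@mode <- "cellAtt"
    expect_equal(ablationRepresentation(ca, sOne)$h,
                 sampleRepresentation(ha, sOne)$h, tolerance = 1e-6)
  }
})

test_that("prediction heads give calibrated edge cases", {
  mod <- randomModel(m = 3, d = 2, mode = "CTA", seed = 5)
  s <- randomSample(n = 4, m = 3)
  # zero head -> 0.5 / 0.5 through the sigmoid
  mod@params$wbar <- mod@params$wbar * 0
  mod@params$bbar <- matrix(0, 1, 1)
  expect_equal(drop(predictProba(mod, s)), c(0.5, 0.5))
  # logit forced to 1 -> sigmoid(1)
  mod@params$bbar <- matrix(1, 1, 1)
  expect_equal(drop(predictProba(mod, s))[2], 1 / (1 + exp(-1)),
               tolerance = 1e-10)
  # zero softmax head -> uniform over C classes
  mc <- randomModel(m = 3, C = 3, mode = "CTA", d = 2, binary = FALSE, seed = 6)
  mc@params$W <- mc@params$W * 0
  expect_equal(drop(predictProba(mc, s)), rep(1 / 3, 3))
})

test_that("cross-entropy loss matches closed forms and rejects bad labels", {
  expect_equal(crossEntropyLoss(matrix(c(0.5, 0.5), 1, 2), 1L), log(2))
  expect_equal(crossEntropyLoss(rbind(c(1, 0), c(0, 1)), c(1L, 2L)), 0)
  expect_error(crossEntropyLoss(matrix(c(0.5, 0.5), 1, 2), 3L), "range")
})

test_that("R forward, compiled forward and straight-line oracle agree", {
  for (seed in 1:8) {
    set.seed(seed)
    mode <- c("CTA", "HA", "meanPool", "cellAtt")[(seed %% 4) + 1]
    layers <- (seed %% 2) + 1
    binary <- seed %% 3 != 0
    C <- if (binary) 2 else 3
    mod <- randomModel(m = 3, C = C, mode = mode, d = 4, layers = layers,
                       binary = binary, seed = seed * 13, attScale = 1)
    s <- randomSample(n = sample(1:5, 1), m = 3, nTypes = 2, label = 1L)
    o <- oracleForward(s@X, s@cellType, mod@params, mode = mode,
                       nLayers = layers, binary = binary)
    f <- if (mode %in% c("CTA", "HA")) sampleRepresentation(mod, s)
         else ablationRepresentation(mod, s)
    expect_equal(f$h, o$h, tolerance = 1e-6)
    expect_equal(f$proba, o$proba, tolerance = 1e-6)
    # compiled path used by predictProba agrees too
    expect_equal(drop(predictProba(mod, s)), o$proba, tolerance = 1e-6)
  }
})

test_that("model checkpoints round-trip losslessly", {
  mod <- randomModel(m = 5, d = 3, mode = "HA", layers = 2, seed = 9)
  mod@cellTypeNames <- c("a", "b")
  mod@classNames <- c("neg", "pos")
  path <- tempfile(fileext = ".rds")
  saveModel(mod, path)
  back <- loadModel(path)
  expect_identical(back@params, mod@params)
  expect_identical(back@mode, mod@mode)
  expect_identical(back@cellTypeNames, mod@cellTypeNames)
  s <- randomSample(n = 3, m = 5)
  expect_identical(predictProba(back, s), predictProba(mod, s))
})
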