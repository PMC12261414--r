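test_that("both logit decompositions reproduce the forward-pass logit", {
  for (seed in 1:6) {
    set.seed(seed)
    mode <- if (seed %% 2) "HA" else "CTA"
    binary <- seed %% 3 != 0
    mod <- randomModel(m = 4, C = if (binary) 2 else 3, mode = mode, d = 3,
                       binary = binary, seed = seed * 7, attScale = 1)
    s <- randomSample(n = sample(3:8, 1), m = 4, nTypes = 3)
    dec <- decompose(mod, s)
    expect_equal(colSums(dec$perCellLogits) + dec$bias, dec$totalLogit,
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(colSums(dec$perTypeLogits) + dec$bias, dec$totalLogit,
                 tolerance = 1e-5, ignore_attr = TRUE)
    # within-type sums of cell logits equal the type logit
    for (i in dec$presentTypes) {
      rows <- which(s@cellType == i)
      expect_equal(colSums(dec$perCellLogits[rows, , drop = FALSE]),
                   dec$perTypeLogits[i, ], tolerance = 1e-5,
                   ignore_attr = TRUE)
    }
  }
})

test_that("decomposition edge cases behave", {
  mod <- randomModel(m = 3, d = 3, mode = "CTA", seed = 4)
  # single present type carries the whole logit minus bias
  s <- milSample(matrix(rnorm(6), 2, 3), c(2L, 2L), 1L, "single")
  dec <- decompose(mod, s)
  expect_equal(dec$perTypeLogits[2, ], dec$totalLogit - dec$bias,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(dec$perTypeLogits[1, ], 0) # absent type contributes nothing
  # zero head: all contributions vanish, total equals bias
  mod0 <- mod; mod0@params$wbar <- mod0@params$wbar * 0
  dec0 <- decompose(mod0, s)
  expect_true(all(dec0$perCellLogits == 0))
  expect_equal(dec0$totalLogit, dec0$bias)
  # ablation modes decompose over cells only
  mp <- mod; mp@mode <- "meanPool"
  dmp <- decompose(mp, s)
  expect_false(dmp$hierarchical)
  expect_null(dmp$perTypeLogits)
  expect_equal(colSums(dmp$perCellLogits) + dmp$bias, dmp$totalLogit,
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("the fast per-type logit path matches decompose()", {
  co <- signalCohort(seed = 8)
  mod <- fitMIL(co, mode = "HA", hiddenDim = 5, config = quickTrain(), seed = 2)
  fast <- hierMIL:::.typeLogitMatrix(mod, co, useCpp = TRUE)
  ref <- hierMIL:::.typeLogitMatrix(mod, co, useCpp = FALSE)
  expect_equal(fast, ref, tolerance = 1e-10)
})

test_that("importance scores match the class-contrast formula", {
  # three samples, one type: positives {0.6, 0.8}, negative {0.2} -> 0.5
  co <- milCohort(list(
    milSample(matrix(0, 1, 1), 1L, 2L, "p1"),
    milSample(matrix(0, 1, 1), 1L, 2L, "p2"),
    milSample(matrix(0, 1, 1), 1L, 1L, "n1")),
    cellTypeNames = "t", classNames = c("neg", "pos"))
  L <- matrix(c(0.6, 0.8, 0.2), 3, 1)
  expect_equal(unname(importanceScores(co, typeLogits = L)), 0.5)
  # identical logits in both classes -> zero
  expect_equal(unname(importanceScores(co, typeLogits = matrix(1, 3, 1))), 0)
  # swapping the class labels negates kappa
  sw <- hierMIL:::.withLabels(co, c(1L, 1L, 2L))
  expect_equal(importanceScores(sw, typeLogits = L),
               -importanceScores(co, typeLogits = L))
  # linearity: scaling all logits scales kappa
  expect_equal(importanceScores(co, typeLogits = 3 * L),
               3 * importanceScores(co, typeLogits = L))
})

test_that("importance scores agree with the straight-line oracle", {
  co <- signalCohort(seed = 9)
  mod <- fitMIL(co, mode = "CTA", hiddenDim = 4, config = quickTrain(), seed = 3)
  expect_equal(unname(importanceScores(co, mod)), unname(oracleKappa(co, mod)),
               tolerance = 1e-6)
})

test_that("one-vs-rest multi-class scores reduce to the binary score", {
  co <- signalCohort(seed = 10)
  mod <- fitMIL(co, mode = "HA", hiddenDim = 4, config = quickTrain(), seed = 5)
  expect_equal(importanceScoresMulticlass(co, mod, "class2"),
               importanceScores(co, mod))
  # for a single-logit head the two one-vs-rest contrasts coincide: the
  # negated component and the swapped group contrast cancel
  expect_equal(importanceScoresMulticlass(co, mod, "class1"),
               importanceScores(co, mod))
  expect_error(importanceScoresMulticlass(co, mod, "nosuch"), "unknown")
})

test_that("a dominant class-specific type logit maximizes its kappa", {
  # three classes; class-1 samples carry a large type-2 contribution through
  # cells with inflated features mapped by a fixed softmax-head model
  # all non-driver cells are zero, so their relu representations and hence
  # their type logits vanish; only type 2 in class-1 samples contributes
  mk <- function(label, boost, id) {
    X <- matrix(0, 6, 3)
    ty <- rep(1:3, each = 2)
    if (boost) X[ty == 2, ] <- 5
    milSample(X, ty, label, id)
  }
  co <- milCohort(c(lapply(1:3, function(r) mk(1L, TRUE, paste0("a", r))),
                    lapply(1:3, function(r) mk(2L, FALSE, paste0("b", r))),
                    lapply(1:3, function(r) mk(3L, FALSE, paste0("c", r)))),
                  cellTypeNames = paste0("t", 1:3),
                  classNames = paste0("class", 1:3))
  mod <- randomModel(m = 3, C = 3, mode = "CTA", d = 4, binary = FALSE,
                     seed = 31)
  k <- importanceScoresMulticlass(co, mod, "class1")
  expect_equal(names(which.max(abs(k))), "t2")
})

test_that("permutation test p-values follow the add-one estimator", {
  # deterministic trainer: the model is fixed, so the permutation test
  # reduces to a label-permutation test of the type-logit class contrast
  set.seed(33)
  co <- signalCohort(seed = 12, S = c(8, 8))
  frozen <- fitMIL(co, mode = "CTA", hiddenDim = 4, config = quickTrain(),
                   seed = 17)
  trainFun <- function(cohort, seed) frozen
  rep1 <- permutationTest(co, trainFun, nPerm = 99, seed = 5)
  driver <- which.max(abs(rep1@kappa))
  # the observed driver contrast exceeds every permuted one
  expect_equal(unname(rep1@pRaw[driver]), 1 / 100)
  expect_true(all(rep1@pAdj >= rep1@pRaw))
  # BH keeps the p-value ranking
  ord <- order(rep1@pRaw)
  expect_true(all(diff(rep1@pAdj[ord]) >= -1e-12))
  expect_identical(unname(rep1@critical), unname(rep1@pAdj <= rep1@alpha))
  # determinism: identical seed, identical report
  rep2 <- permutationTest(co, trainFun, nPerm = 99, seed = 5)
  expect_identical(rep1@pRaw, rep2@pRaw)
  expect_identical(rep1@nullKappas, rep2@nullKappas)
  expect_error(permutationTest(co, trainFun, nPerm = 5), "19")
})

test_that("cell types are ranked by decreasing score with name tie-breaks", {
  rp <- new("ImportanceReport",
            kappa = c(b = 0.13, a = 0.17, c = -0.02),
            nullKappas = matrix(0, 19, 3), pRaw = c(b = 0.5, a = 0.2, c = 0.9),
            pAdj = c(b = 0.75, a = 0.6, c = 0.9),
            critical = c(b = FALSE, a = FALSE, c = FALSE),
            nPermutations = 19L, correctionMethod = "BH", alpha = 0.05,
            sided = "two.sided", seed = 1L, targetClass = NA_character_)
  tab <- rankCellTypes(rp)
  expect_equal(tab$cellType, c("a", "b", "c"))
  expect_equal(tab$kappa, c(0.17, 0.13, -0.02))
  # all-equal scores fall back to alphabetical order
  rp@kappa[] <- 0.1
  expect_equal(rankCellTypes(rp)$cellType, c("a", "b", "c"))
})

test_that("importance report writers produce readable artifacts", {
  co <- signalCohort(seed = 13, S = c(5, 5))
  frozen <- fitMIL(co, mode = "CTA", hiddenDim = 4, config = quickTrain(),
                   seed = 19)
  rp <- permutationTest(co, function(c, s) frozen, nPerm = 19, seed = 3)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  dtsv <- tempfile(fileext = ".tsv")
  writeImportanceTSV(rp, tsv)
  writeImportanceJSON(rp, js)
  writeDecompositionTSV(frozen, co, dtsv)
  tab <- read.delim(tsv)
  expect_named(tab, c("cell_type", "kappa", "p_raw", "p_adj", "critical"))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n_permutations, 19L)
  expect_equal(length(parsed$kappa), length(rp@kappa))
  dd <- read.delim(dtsv)
  expect_equal(nrow(dd), nSamples(co) * length(cellTypeNames(co)))
})
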