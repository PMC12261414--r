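#' Exact logit decomposition of a prediction
#'
#' Because pooling and the classification head are both linear, the
#' pre-activation logit of a sample decomposes exactly into per-cell
#' contributions `gamma_ij * (W h_ij)` and, equivalently, per-cell-type
#' contributions `beta_i * (W h_i)`, plus the head bias. Both sums reproduce
#' the forward-pass logit.
#'
#' For the ablation modes only the cell-level decomposition exists (there
#' are no type representations); `perTypeLogits` is then `NULL` and
#' `hierarchical` is `FALSE`.
#'
#' @param object a [MILModel].
#' @param sample a [MILSample].
#' @param ... unused.
#' @return A list of class `milDecomposition` with elements `sampleId`,
#'   `hierarchical`, `perCellLogits` (cells x C; one column for the sigmoid
#'   head), `perTypeLogits` (types x C over the full vocabulary, zero rows
#'   for absent types, or `NULL`), `presentTypes`, `bias`, `totalLogit`.
#' @export
setMethod("decompose", "MILModel", function(object, sample, ...) {
  f <- .forwardSample(object, sample)
  p <- object@params
  headW <- if (object@binaryHead) t(p$wbar) else p$W       # C x d
  bias <- if (object@binaryHead) p$bbar[1, 1] else p$bhead[, 1]
  cellProj <- f$H %*% t(headW)                             # N x C
  hier <- object@mode %in% c("CTA", "HA")
  if (hier) {
    perCell <- cellProj * f$gamma
    I <- max(length(object@cellTypeNames), max(sample@cellType))
    nc <- ncol(cellProj)
    perType <- matrix(0, I, nc)
    typeProj <- t(f$typeReprs) %*% t(headW)                # T x C
    perType[f$presentTypes, ] <- typeProj * f$beta
    if (length(object@cellTypeNames) == I)
      rownames(perType) <- object@cellTypeNames
  } else {
    wts <- if (object@mode == "meanPool") rep(1 / nrow(f$H), nrow(f$H))
           else f$alphaFlat
    perCell <- cellProj * wts
    perType <- NULL
  }
  structure(list(sampleId = sample@sampleId, hierarchical = hier,
                 perCellLogits = perCell, perTypeLogits = perType,
                 presentTypes = if (hier) f$presentTypes else integer(),
                 bias = bias, totalLogit = f$logits),
            class = "milDecomposition")
})

# per-type logit matrix for a cohort: S x I (binary head) or S x I x C array
# (softmax head). Absent types contribute 0. Fast path through the C++
# forward; decompose() is the reference implementation (tested to agree).
.typeLogitMatrix <- function(model, cohort, useCpp = TRUE) {
  if (!model@mode %in% c("CTA", "HA"))
    stop("per-type logits require CTA or HA mode", call. = FALSE)
  I <- length(cellTypeNames(cohort))
  S <- nSamples(cohort)
  if (useCpp) {
    flat <- .typeLogitsCpp(.cohortMatrices(cohort), .cohortTypes(cohort),
                           model@params, .cppConfig(model), I)
    if (model@binaryHead) {
      dimnames(flat) <- list(sampleIds(cohort), cellTypeNames(cohort))
      return(flat)
    }
    arr <- array(flat, dim = c(S, I, model@nClasses),
                 dimnames = list(sampleIds(cohort), cellTypeNames(cohort),
                                 classNames(cohort)))
    return(arr)
  }
  nc <- if (model@binaryHead) 1L else model@nClasses
  out <- array(0, dim = c(S, I, nc))
  for (s in seq_len(S)) {
    dec <- decompose(model, cohort@samples[[s]])
    out[s, , ] <- dec$perTypeLogits
  }
  if (model@binaryHead) {
    dim(out) <- c(S, I)
    dimnames(out) <- list(sampleIds(cohort), cellTypeNames(cohort))
  } else {
    dimnames(out) <- list(sampleIds(cohort), cellTypeNames(cohort),
                          classNames(cohort))
  }
  out
}

#' Cell-type importance scores
#'
#' The importance score of cell type i is the class contrast of the mean
#' type-level logit contribution:
#' `kappa_i = mean(l_si, s in positive class) - mean(l_si, s in negative
#' class)`, where `l_si = beta_si * w' h_si` is the sample's type-i logit
#' contribution. Samples lacking type i contribute `l_si = 0` while the
#' class sizes stay at the full counts, which preserves the decomposition
#' identity `sum_i l_si = z`.
#'
#' @param cohort a [MILCohort] with two classes; the second class name is
#'   the positive class.
#' @param model a fitted [MILModel] with the sigmoid head, in CTA or HA
#'   mode. Alternatively supply `typeLogits`.
#' @param typeLogits optional precomputed samples x types logit matrix (as
#'   from per-sample [decompose()] output); overrides `model`.
#' @return Named numeric vector of importance scores, one per cell type.
#' @export
importanceScores <- function(cohort, model = NULL, typeLogits = NULL) {
  if (is.null(typeLogits)) {
    stopifnot(is(model, "MILModel"))
    if (!model@binaryHead)
      stop("importanceScores needs the sigmoid head; use ",
           "importanceScoresMulticlass() for softmax-head models",
           call. = FALSE)
    typeLogits <- .typeLogitMatrix(model, cohort)
  }
  labs <- sampleLabels(cohort)
  if (length(classNames(cohort)) != 2L)
    stop("importanceScores requires a binary cohort", call. = FALSE)
  pos <- labs == 2L
  if (!any(pos) || !all(c(1L, 2L) %in% labs))
    stop("both classes must contain at least one sample", call. = FALSE)
  colMeans(typeLogits[pos, , drop = FALSE]) -
    colMeans(typeLogits[!pos, , drop = FALSE])
}

#' One-vs-rest multi-class importance scores
#'
#' Generalizes the binary importance score to C classes by contrasting the
#' target class's logit component: mean over samples of the target class
#' minus mean over all other samples. This one-vs-rest construction is this
#' package's own generalization (reported as such in the output metadata of
#' [permutationTest()]); with C = 2 and the positive class as target it
#' reduces exactly to [importanceScores()].
#'
#' @param cohort a [MILCohort].
#' @param model a fitted [MILModel] in CTA or HA mode.
#' @param targetClass class name (or 1-based index) whose component is
#'   contrasted.
#' @return Named numeric vector of importance scores per cell type.
#' @export
importanceScoresMulticlass <- function(cohort, model, targetClass) {
  stopifnot(is(model, "MILModel"))
  cn <- classNames(cohort)
  tc <- if (is.character(targetClass)) match(targetClass, cn)
        else as.integer(targetClass)
  if (is.na(tc) || tc < 1L || tc > length(cn))
    stop("unknown target class: ", targetClass, call. = FALSE)
  L <- .typeLogitMatrix(model, cohort)
  comp <- if (model@binaryHead) {
    # single logit: +l is the positive-class component, -l the negative's
    if (tc == 2L) L else -L
  } else {
    L[, , tc]
  }
  labs <- sampleLabels(cohort)
  inTarget <- labs == tc
  if (!any(inTarget) || all(inTarget))
    stop("target class and its complement must both be non-empty",
         call. = FALSE)
  colMeans(comp[inTarget, , drop = FALSE]) -
    colMeans(comp[!inTarget, , drop = FALSE])
}

#' Permutation test for critical cell types
#'
#' Fits the model on the true labels to obtain observed importance scores,
#' then repeatedly permutes the sample labels, refits from a fresh seeded
#' initialization, and recomputes the scores to build a per-type null
#' distribution. Empirical p-values use the add-one estimator
#' `p_i = (1 + #\{permutations with |kappa_perm,i| >= |kappa_obs,i|\}) /
#' (nPerm + 1)` (two-sided by default), followed by multiple-testing
#' correction; a cell type is called critical when its adjusted p-value is
#' at most `alpha`.
#'
#' Refits reuse the architecture and optimizer settings frozen in
#' `trainFun` rather than re-tuning hyperparameters per permutation. A fit
#' that fails (non-finite loss) is retried once with a fresh seed.
#'
#' @param cohort a binary [MILCohort] (or multi-class with `targetClass`).
#' @param trainFun callable `(cohort, seed) -> fitted MILModel`; see
#'   [milTrainer()].
#' @param nPerm number of label permutations (>= 19).
#' @param alpha significance level for the criticality call.
#' @param correction `"BH"` (Benjamini-Hochberg, default), `"holm"` or
#'   `"bonferroni"`.
#' @param sided `"two.sided"` (default) or `"greater"`.
#' @param targetClass for multi-class cohorts / softmax heads: the class
#'   whose one-vs-rest score is tested.
#' @param seed master seed; every source of randomness (fit initializations,
#'   batch shuffles, label permutations) derives from it.
#' @return An [ImportanceReport].
#' @export
permutationTest <- function(cohort, trainFun, nPerm = 99L, alpha = 0.05,
                            correction = c("BH", "holm", "bonferroni"),
                            sided = c("two.sided", "greater"),
                            targetClass = NULL, seed = 1L) {
  correction <- match.arg(toupper(correction[1L]),
                          c("BH", "HOLM", "BONFERRONI"))
  correction <- c(BH = "BH", HOLM = "holm", BONFERRONI = "bonferroni")[correction]
  sided <- match.arg(sided)
  nPerm <- as.integer(nPerm)
  if (nPerm < 19L) stop("nPerm must be at least 19")
  labs <- sampleLabels(cohort)
  seeds <- deriveSeeds(seed, 3L * (nPerm + 1L))
  fitSeeds <- seeds[seq_len(nPerm + 1L)]
  permSeeds <- seeds[(nPerm + 2L):(2L * nPerm + 1L)]
  retrySeeds <- seeds[(2L * nPerm + 2L):(3L * nPerm + 3L)]

  fitOnce <- function(co, s, retry) {
    tryCatch(trainFun(co, s), error = function(e) {
      message("fit failed (", conditionMessage(e), "); re-seeding once")
      trainFun(co, retry)
    })
  }
  obsModel <- fitOnce(cohort, fitSeeds[1L], retrySeeds[1L])
  kObs <- if (is.null(targetClass)) importanceScores(cohort, obsModel)
          else importanceScoresMulticlass(cohort, obsModel, targetClass)
  I <- length(kObs)
  nulls <- matrix(NA_real_, nPerm, I,
                  dimnames = list(NULL, names(kObs)))
  for (k in seq_len(nPerm)) {
    set.seed(permSeeds[k])
    permLabs <- sample(labs)
    if (length(unique(permLabs)) < 2L) permLabs <- rev(labs) # unreachable guard
    coPerm <- .withLabels(cohort, permLabs)
    mPerm <- fitOnce(coPerm, fitSeeds[k + 1L], retrySeeds[k + 1L])
    nulls[k, ] <- if (is.null(targetClass)) importanceScores(coPerm, mPerm)
                  else importanceScoresMulticlass(coPerm, mPerm, targetClass)
  }
  exceed <- if (sided == "two.sided") {
    colSums(abs(nulls) >= matrix(abs(kObs), nPerm, I, byrow = TRUE))
  } else {
    colSums(nulls >= matrix(kObs, nPerm, I, byrow = TRUE))
  }
  pRaw <- (1 + exceed) / (nPerm + 1)
  pAdj <- stats::p.adjust(pRaw, method = correction)
  new("ImportanceReport", kappa = kObs, nullKappas = nulls,
      pRaw = setNames(pRaw, names(kObs)), pAdj = setNames(pAdj, names(kObs)),
      critical = setNames(pAdj <= alpha, names(kObs)),
      nPermutations = nPerm, correctionMethod = correction,
      alpha = alpha, sided = sided, seed = as.integer(seed),
      targetClass = if (is.null(targetClass)) NA_character_
                    else as.character(targetClass))
}

#' Rank cell types by importance score
#'
#' @param report an [ImportanceReport].
#' @return A `data.frame` with columns `cellType`, `kappa`, `pRaw`, `pAdj`,
#'   `critical`, sorted by decreasing score with ties broken alphabetically.
#' @export
setMethod("rankCellTypes", "ImportanceReport", function(report) {
  nm <- names(report@kappa)
  if (is.null(nm)) nm <- paste0("type", seq_along(report@kappa))
  ord <- order(-report@kappa, nm)
  data.frame(cellType = nm[ord], kappa = unname(report@kappa[ord]),
             pRaw = unname(report@pRaw[ord]), pAdj = unname(report@pAdj[ord]),
             critical = unname(report@critical[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
})

setMethod("show", "ImportanceReport", function(object) {
  cat("ImportanceReport:", length(object@kappa), "cell types,",
      object@nPermutations, "permutations,", object@sided, "p-values,",
      object@correctionMethod, "correction, alpha =", object@alpha, "\n")
  if (!is.na(object@targetClass))
    cat("  one-vs-rest target class:", object@targetClass,
        "(package's own multi-class generalization)\n")
  cat("  critical:", sum(object@critical), "of", length(object@critical), "\n")
  print(head(rankCellTypes(object), 8L))
})

#' Write interpretability outputs
#'
#' `writeImportanceTSV()` writes the ranked table (cell_type, kappa, p_raw,
#' p_adj, critical); `writeImportanceJSON()` dumps the full report including
#' null draws; `writeDecompositionTSV()` writes per-sample per-type logit
#' contributions (sample_id, cell_type, logit_contribution).
#'
#' @param report an [ImportanceReport].
#' @param path output file path.
#' @param model,cohort fitted model and cohort for the per-sample table.
#' @return The path, invisibly.
#' @export
writeImportanceTSV <- function(report, path) {
  tab <- rankCellTypes(report)
  names(tab) <- c("cell_type", "kappa", "p_raw", "p_adj", "critical")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeImportanceTSV
#' @export
writeImportanceJSON <- function(report, path) {
  jsonlite::write_json(
    list(kappa = as.list(report@kappa),
         p_raw = as.list(report@pRaw), p_adj = as.list(report@pAdj),
         critical = as.list(report@critical),
         null_kappas = report@nullKappas,
         n_permutations = report@nPermutations,
         correction = report@correctionMethod, alpha = report@alpha,
         sided = report@sided, seed = report@seed,
         target_class = report@targetClass,
         multiclass_score_is_one_vs_rest = !is.na(report@targetClass)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeImportanceTSV
#' @export
writeDecompositionTSV <- function(model, cohort, path) {
  L <- .typeLogitMatrix(model, cohort)
  if (length(dim(L)) == 3L) L <- L[, , model@nClasses]
  tab <- data.frame(
    sample_id = rep(rownames(L), times = ncol(L)),
    cell_type = rep(colnames(L), each = nrow(L)),
    logit_contribution = as.vector(L), stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
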