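#' Create an untrained hierarchical attention MIL model
#'
#' Builds a [MILModel] with seeded, fan-in-scaled random parameters. The
#' attention vectors `w` and `v` start at small scale so that early training
#' behaves like mean pooling; encoder and head weights are scaled by
#' `1/sqrt(fan-in)`; biases start at zero.
#'
#' @param inputDim number of input features m.
#' @param nClasses number of classes C.
#' @param mode aggregation architecture: `"CTA"`, `"HA"`, `"meanPool"` or
#'   `"cellAtt"` (case/hyphen-insensitive).
#' @param hiddenDim width d of the cell representation.
#' @param nHiddenLayers 1 or 2 encoder layers.
#' @param nonlinearity `"relu"` (default) or `"tanh"`.
#' @param binaryHead use the sigmoid head (requires C = 2); by default C = 2
#'   uses the sigmoid head and C > 2 the softmax head. Forcing
#'   `binaryHead = FALSE` with C = 2 yields a two-logit softmax head, which
#'   the one-vs-rest multi-class importance score expects.
#' @param cellTypeNames,classNames vocabularies (usually copied from the
#'   training cohort).
#' @param seed integer RNG seed for the initialization.
#' @return An untrained [MILModel].
#' @examples
#' mod <- milModel(inputDim = 5, nClasses = 2, mode = "HA", hiddenDim = 4)
#' @export
milModel <- function(inputDim, nClasses, mode = "CTA", hiddenDim = 32L,
                     nHiddenLayers = 1L, nonlinearity = "relu",
                     binaryHead = nClasses == 2L,
                     cellTypeNames = character(), classNames = character(),
                     seed = 1L) {
  mode <- normalizeMode(mode)
  m <- as.integer(inputDim); d <- as.integer(hiddenDim)
  C <- as.integer(nClasses)
  if (d < 1L || m < 1L || C < 2L)
    stop("inputDim and hiddenDim must be >= 1 and nClasses >= 2")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  params <- list(
    Wx1 = matrix(rnorm(d * m, sd = 1 / sqrt(m)), d, m),
    bx1 = matrix(0, d, 1))
  if (nHiddenLayers == 2L) {
    params$Wx2 <- matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d)
    params$bx2 <- matrix(0, d, 1)
  }
  params$w <- matrix(rnorm(d, sd = 0.01), d, 1)
  params$b <- matrix(0, 1, 1)
  params$v <- matrix(rnorm(d, sd = 0.01), d, 1)
  params$bprime <- matrix(0, 1, 1)
  if (isTRUE(binaryHead)) {
    params$wbar <- matrix(rnorm(d, sd = 1 / sqrt(d)), d, 1)
    params$bbar <- matrix(0, 1, 1)
  } else {
    params$W <- matrix(rnorm(C * d, sd = 1 / sqrt(d)), C, d)
    params$bhead <- matrix(0, C, 1)
  }
  new("MILModel", mode = mode, nHiddenLayers = as.integer(nHiddenLayers),
      hiddenDim = d, inputDim = m, nClasses = C,
      nonlinearity = nonlinearity, binaryHead = isTRUE(binaryHead),
      params = params, cellTypeNames = as.character(cellTypeNames),
      classNames = as.character(classNames), seed = as.integer(seed))
}

#' Encode cells into the hidden representation
#'
#' Applies the feed-forward encoder `phi(Wx x + bx)` row-wise (composed twice
#' for two hidden layers) to a cells-by-features matrix.
#'
#' @param X numeric matrix, cells x features.
#' @param model a [MILModel] whose `inputDim` matches `ncol(X)`.
#' @return Numeric matrix, cells x `hiddenDim`.
#' @export
encodeCells <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != model@inputDim)
    stop("X has ", ncol(X), " features but the model expects ",
         model@inputDim, call. = FALSE)
  stopifnotFinite(X, "X")
  phi <- if (model@nonlinearity == "relu") relu else tanh
  p <- model@params
  H <- phi(sweep(X %*% t(p$Wx1), 2, p$bx1[, 1], `+`))
  if (model@nHiddenLayers == 2L)
    H <- phi(sweep(H %*% t(p$Wx2), 2, p$bx2[, 1], `+`))
  H
}

#' Within-type cell attention weights
#'
#' Softmax over the cells of one type of the scores `w' h_ij + b`. The bias
#' cancels inside the softmax but is retained in the parameterization.
#'
#' @param Hi numeric matrix, cells-of-one-type x d.
#' @param w numeric d-vector (or d x 1 matrix).
#' @param b numeric scalar.
#' @return Positive weights summing to one, one per row of `Hi`.
#' @export
cellAttention <- function(Hi, w, b = 0) {
  Hi <- as.matrix(Hi)
  if (nrow(Hi) < 1L) stop("cellAttention requires at least one cell")
  softmax(drop(Hi %*% as.numeric(w)) + as.numeric(b))
}

#' Aggregate cell representations into a type representation
#'
#' @param Hi numeric matrix, cells x d.
#' @param alpha weights summing to one (use `rep(1/n, n)` for CTA-style mean
#'   pooling).
#' @return Numeric d-vector, the weighted sum of the rows of `Hi`.
#' @export
aggregateCells <- function(Hi, alpha) {
  Hi <- as.matrix(Hi)
  if (length(alpha) != nrow(Hi)) stop("alpha must have one weight per cell")
  drop(crossprod(Hi, alpha))
}

#' Cell-type attention weights
#'
#' Softmax over the present cell types of the scores `v' h_i + b'`. Absent
#' types (zero cells) must be excluded before calling; they receive no
#' weight.
#'
#' @param typeReprs numeric matrix with one column per present type (d x T),
#'   or a list of d-vectors.
#' @param v numeric d-vector.
#' @param bprime numeric scalar.
#' @return Positive weights over the present types, summing to one.
#' @export
cellTypeAttention <- function(typeReprs, v, bprime = 0) {
  Ht <- if (is.list(typeReprs)) do.call(cbind, typeReprs) else as.matrix(typeReprs)
  if (ncol(Ht) < 1L) stop("sample has no present cell types")
  softmax(drop(crossprod(Ht, as.numeric(v))) + as.numeric(bprime))
}

# full R-side forward pass for one bag; reference implementation mirrored by
# the C++ kernels (tests assert agreement). Returns all intermediates.
.forwardSample <- function(model, sample) {
  H <- encodeCells(sample@X, model)
  p <- model@params
  d <- model@hiddenDim
  mode <- model@mode
  out <- list(H = H)
  if (mode == "meanPool") {
    out$h <- colMeans(H)
  } else if (mode == "cellAtt") {
    a <- cellAttention(H, p$w, p$b)
    out$alphaFlat <- a
    out$h <- aggregateCells(H, a)
  } else {
    types <- sort(unique(sample@cellType))
    groups <- lapply(types, function(i) which(sample@cellType == i))
    alphas <- vector("list", length(types))
    Ht <- matrix(0, d, length(types))
    for (t in seq_along(types)) {
      Hi <- H[groups[[t]], , drop = FALSE]
      alphas[[t]] <- if (mode == "HA") cellAttention(Hi, p$w, p$b)
                     else rep(1 / nrow(Hi), nrow(Hi))
      Ht[, t] <- aggregateCells(Hi, alphas[[t]])
    }
    beta <- cellTypeAttention(Ht, p$v, p$bprime)
    out$presentTypes <- types
    out$groups <- groups
    out$alpha <- alphas
    out$beta <- beta
    out$typeReprs <- Ht
    out$h <- drop(Ht %*% beta)
    gamma <- numeric(nrow(H))
    for (t in seq_along(types))
      gamma[groups[[t]]] <- beta[t] * alphas[[t]]
    out$gamma <- gamma
  }
  if (model@binaryHead) {
    z <- drop(crossprod(p$wbar, out$h)) + p$bbar[1, 1]
    pp <- 1 / (1 + exp(-z))
    out$logits <- z
    out$proba <- c(1 - pp, pp)
  } else {
    z <- drop(p$W %*% out$h + p$bhead[, 1])
    out$logits <- z
    out$proba <- softmax(z)
  }
  out
}

#' Sample representation and attention record
#'
#' Runs the hierarchical forward pass on one bag and returns the sample
#' representation `h = sum_i beta_i h_i = sum_ij gamma_ij h_ij` together
#' with the full attention record (per-type `alpha`, type weights `beta`,
#' combined weights `gamma = beta * alpha`, type representations).
#'
#' @param object a [MILModel] in `"CTA"` or `"HA"` mode (use
#'   [ablationRepresentation()] for the ablation modes).
#' @param sample a [MILSample].
#' @param ... unused.
#' @return A list with elements `h`, `alpha` (list over present types),
#'   `beta`, `gamma` (per cell), `typeReprs` (d x T matrix), `presentTypes`
#'   (type ids), `proba` and `logits`.
#' @export
setMethod("sampleRepresentation", "MILModel", function(object, sample, ...) {
  if (!object@mode %in% c("CTA", "HA"))
    stop("sampleRepresentation requires CTA or HA mode; see ",
         "ablationRepresentation()", call. = FALSE)
  f <- .forwardSample(object, sample)
  list(h = f$h, alpha = f$alpha, beta = f$beta, gamma = f$gamma,
       typeReprs = f$typeReprs, presentTypes = f$presentTypes,
       groups = f$groups, proba = f$proba, logits = f$logits)
})

#' Sample representation under the ablation architectures
#'
#' `meanPool` averages all cell representations (pseudo-bulk); `cellAtt`
#' applies one flat softmax attention over all cells, ignoring cell types.
#'
#' @param model a [MILModel] in `"meanPool"` or `"cellAtt"` mode.
#' @param sample a [MILSample].
#' @return A list with `h`, `proba`, `logits`, and for `cellAtt` the flat
#'   attention weights `alphaFlat`.
#' @export
ablationRepresentation <- function(model, sample) {
  if (!model@mode %in% c("meanPool", "cellAtt"))
    stop("ablationRepresentation requires meanPool or cellAtt mode")
  f <- .forwardSample(model, sample)
  list(h = f$h, alphaFlat = f$alphaFlat, proba = f$proba, logits = f$logits)
}

#' Predicted class probabilities
#'
#' @param object a [MILModel].
#' @param newdata a [MILCohort] or a single [MILSample].
#' @param ... unused.
#' @return Numeric matrix, samples x classes (columns named when the model
#'   carries class names); rows sum to one.
#' @export
setMethod("predictProba", "MILModel", function(object, newdata, ...) {
  if (is(newdata, "MILSample")) {
    ctn <- if (length(object@cellTypeNames)) object@cellTypeNames
           else paste0("type", seq_len(max(newdata@cellType)))
    cls <- if (length(object@classNames)) object@classNames
           else paste0("class", seq_len(object@nClasses))
    newdata <- new("MILCohort", samples = list(newdata), cellTypeNames = ctn,
                   classNames = cls,
                   featureNames = paste0("f", seq_len(object@inputDim)))
  }
  P <- .predictCpp(.cohortMatrices(newdata), .cohortTypes(newdata),
                   object@params, .cppConfig(object))
  rownames(P) <- sampleIds(newdata)
  if (length(object@classNames) == ncol(P)) colnames(P) <- object@classNames
  P
})

#' Cross-entropy loss
#'
#' `L = -sum_s log p_s[y_s]`, with probabilities clamped at 1e-12 before the
#' log.
#'
#' @param probs numeric matrix, samples x classes.
#' @param labels integer vector of 1-based class labels.
#' @return Non-negative scalar; zero iff every correct-class probability is 1.
#' @export
crossEntropyLoss <- function(probs, labels) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > ncol(probs)))
    stop("label out of range 1..", ncol(probs))
  -sum(log(pmax(probs[cbind(seq_along(labels), labels)], 1e-12)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the configuration, all
#' parameter matrices and the vocabularies; the round trip is lossless.
#'
#' @param model a [MILModel].
#' @param path file path.
#' @return `loadModel()` returns the restored [MILModel].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "MILModel"))
  saveRDS(list(format = "hierMIL-checkpoint", version = 1L,
               mode = model@mode, nHiddenLayers = model@nHiddenLayers,
               hiddenDim = model@hiddenDim, inputDim = model@inputDim,
               nClasses = model@nClasses, nonlinearity = model@nonlinearity,
               binaryHead = model@binaryHead, params = model@params,
               cellTypeNames = model@cellTypeNames,
               classNames = model@classNames, seed = model@seed),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "hierMIL-checkpoint"))
    stop("not a hierMIL checkpoint: ", path)
  new("MILModel", mode = x$mode, nHiddenLayers = x$nHiddenLayers,
      hiddenDim = x$hiddenDim, inputDim = x$inputDim, nClasses = x$nClasses,
      nonlinearity = x$nonlinearity, binaryHead = x$binaryHead,
      params = x$params, cellTypeNames = x$cellTypeNames,
      classNames = x$classNames, seed = x$seed)
}

setMethod("show", "MILModel", function(object) {
  cat("MILModel (", object@mode, "): ", object@inputDim, " features -> d=",
      object@hiddenDim, " (", object@nHiddenLayers, " hidden layer",
      if (object@nHiddenLayers > 1L) "s", ", ", object@nonlinearity, "), ",
      if (object@binaryHead) "sigmoid" else "softmax", " head, C=",
      object@nClasses, "\n", sep = "")
})
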