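# internal numerics shared across the package

# overflow-safe softmax; shift by the max logit
softmax <- function(e) {
  z <- exp(e - max(e))
  z / sum(z)
}

relu <- function(x) pmax(x, 0)

.modeCode <- c(CTA = 0L, HA = 1L, meanPool = 2L, cellAtt = 3L)
.nonlinCode <- c(relu = 0L, tanh = 1L)

# accepts CLI-style spellings too (cta, mean-pool, MEAN_POOL, ...)
normalizeMode <- function(mode) {
  key <- gsub("[-_]", "", tolower(mode))
  map <- c(cta = "CTA", ha = "HA", meanpool = "meanPool", cellatt = "cellAtt",
           cellattention = "cellAtt", meanpooling = "meanPool")
  out <- map[key]
  if (is.na(out))
    stop("unknown mode '", mode,
         "'; use one of CTA, HA, meanPool, cellAtt", call. = FALSE)
  unname(out)
}

# configuration list consumed by the C++ kernels
.cppConfig <- function(model) {
  list(mode = unname(.modeCode[model@mode]),
       nLayers = model@nHiddenLayers,
       d = model@hiddenDim,
       m = model@inputDim,
       C = model@nClasses,
       nonlin = unname(.nonlinCode[model@nonlinearity]),
       binary = model@binaryHead)
}

# independent child seeds (< 2^31) from one master seed
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.cohortMatrices <- function(cohort) lapply(cohort@samples, function(s) s@X)
.cohortTypes <- function(cohort) lapply(cohort@samples, function(s) s@cellType)

stopifnotFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
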