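# Straight-line reference implementation of the model, written with explicit
# loops and plain softmax (no max-shift), sharing no code with the package.
# Used to cross-check the vectorized R and compiled forward paths.

oracleSoftmax <- function(e) {
  z <- exp(e)
  z / sum(z)
}

oracleForward <- function(X, types, params, mode = "CTA", nLayers = 1,
                          nonlin = "relu", binary = TRUE) {
  phi <- function(z) if (nonlin == "relu") ifelse(z > 0, z, 0) else tanh(z)
  N <- nrow(X)
  d <- nrow(params$Wx1)
  H <- matrix(0, N, d)
  for (j in seq_len(N)) {
    z <- numeric(d)
    for (a in seq_len(d)) {
      acc <- params$bx1[a, 1]
      for (q in seq_len(ncol(X))) acc <- acc + params$Wx1[a, q] * X[j, q]
      z[a] <- acc
    }
    H[j, ] <- phi(z)
  }
  if (nLayers == 2) {
    H2 <- matrix(0, N, d)
    for (j in seq_len(N)) {
      z <- numeric(d)
      for (a in seq_len(d)) {
        acc <- params$bx2[a, 1]
        for (q in seq_len(d)) acc <- acc + params$Wx2[a, q] * H[j, q]
        z[a] <- acc
      }
      H2[j, ] <- phi(z)
    }
    H <- H2
  }

  w <- params$w[, 1]; b <- params$b[1, 1]
  v <- params$v[, 1]; bp <- params$bprime[1, 1]

  typeLogit <- NULL
  if (mode %in% c("CTA", "HA")) {
    present <- sort(unique(types))
    Tn <- length(present)
    Ht <- matrix(0, d, Tn)
    for (t in seq_len(Tn)) {
      rows <- which(types == present[t])
      alpha <- if (mode == "HA") {
        e <- numeric(length(rows))
        for (j in seq_along(rows)) e[j] <- sum(w * H[rows[j], ]) + b
        oracleSoftmax(e)
      } else rep(1 / length(rows), length(rows))
      for (j in seq_along(rows))
        Ht[, t] <- Ht[, t] + alpha[j] * H[rows[j], ]
    }
    eT <- numeric(Tn)
    for (t in seq_len(Tn)) eT[t] <- sum(v * Ht[, t]) + bp
    beta <- oracleSoftmax(eT)
    h <- numeric(d)
    for (t in seq_len(Tn)) h <- h + beta[t] * Ht[, t]
    if (binary) {
      typeLogit <- numeric(Tn)
      for (t in seq_len(Tn))
        typeLogit[t] <- beta[t] * sum(params$wbar[, 1] * Ht[, t])
      names(typeLogit) <- present
    }
  } else if (mode == "meanPool") {
    h <- colMeans(H)
  } else { # cellAtt
    e <- numeric(N)
    for (j in seq_len(N)) e[j] <- sum(w * H[j, ]) + b
    alpha <- oracleSoftmax(e)
    h <- numeric(d)
    for (j in seq_len(N)) h <- h + alpha[j] * H[j, ]
  }

  if (binary) {
    z <- sum(params$wbar[, 1] * h) + params$bbar[1, 1]
    pp <- 1 / (1 + exp(-z))
    list(h = h, logits = z, proba = c(1 - pp, pp), typeLogit = typeLogit)
  } else {
    z <- drop(params$W %*% h) + params$bhead[, 1]
    list(h = h, logits = z, proba = oracleSoftmax(z), typeLogit = NULL)
  }
}

# importance score computed straight from the oracle's per-type logits
oracleKappa <- function(cohort, model) {
  I <- length(cellTypeNames(cohort))
  labs <- sampleLabels(cohort)
  L <- matrix(0, nSamples(cohort), I)
  for (s in seq_len(nSamples(cohort))) {
    sm <- cohort@samples[[s]]
    o <- oracleForward(sm@X, sm@cellType, model@params, mode = model@mode,
                       nLayers = model@nHiddenLayers,
                       nonlin = model@nonlinearity, binary = TRUE)
    L[s, as.integer(names(o$typeLogit))] <- o$typeLogit
  }
  colMeans(L[labs == 2L, , drop = FALSE]) -
    colMeans(L[labs == 1L, , drop = FALSE])
}
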