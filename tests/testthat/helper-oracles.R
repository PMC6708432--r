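# Independent oracles, written as direct scalar transcriptions so they share
# no code path with the package implementations they check.

# Weir & Cockerham (1984) theta for one biallelic locus. `groups` is a list
# of dosage vectors (0/1/2, NA = missing), one per population.
wcThetaOracle <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  r <- length(groups)
  n <- vapply(groups, length, numeric(1))
  if (any(n == 0)) return(list(a = NA, b = NA, c = NA, theta = NA))
  p <- vapply(groups, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(groups, function(g) mean(g == 1), numeric(1))
  nbar <- mean(n)
  if (nbar <= 1) return(list(a = NA, b = NA, c = NA, theta = NA))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- if (a + b + cc == 0) NA else a / (a + b + cc)
  list(a = a, b = b, c = cc, theta = theta)
}

# Brute-force 1 - Q_inter for one locus: expand each dosage into two allele
# copies and enumerate every ordered pair of distinct individuals and every
# pair of allele draws.
qinterBruteOracle <- function(dosages) {
  dosages <- dosages[!is.na(dosages)]
  n <- length(dosages)
  if (n < 2) return(NA_real_)
  alleles <- lapply(dosages, function(g) c(rep(1, g), rep(0, 2 - g)))
  tot <- 0; cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (ai in alleles[[i]]) for (aj in alleles[[j]]) {
      tot <- tot + (ai == aj)
      cnt <- cnt + 1
    }
  }
  1 - tot / cnt
}

# Dense PCA + LDA transcription: mean-impute, center, PCA via eigen of the
# covariance matrix, then LDA by the non-symmetric eigenproblem of
# solve(W) %*% B with vectors normalized to unit within-group variance.
# Returns discriminant coordinates of the training samples.
pcaLdaOracle <- function(X, groups, nPca, nDa) {
  groups <- factor(groups)
  for (j in seq_len(ncol(X))) {
    mu <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mu
  }
  Xc <- sweep(X, 2, colMeans(X), "-")
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  load <- ev$vectors[, seq_len(nPca), drop = FALSE]
  S <- Xc %*% load
  levs <- levels(groups)
  r <- length(levs)
  n <- nrow(S)
  means <- matrix(0, r, nPca)
  for (k in seq_len(r)) means[k, ] <- colMeans(S[groups == levs[k], , drop = FALSE])
  W <- matrix(0, nPca, nPca)
  for (k in seq_len(r)) {
    rows <- which(groups == levs[k])
    for (i in rows) {
      d <- S[i, ] - means[k, ]
      W <- W + outer(d, d)
    }
  }
  W <- W / (n - r)
  grand <- colMeans(S)
  B <- matrix(0, nPca, nPca)
  for (k in seq_len(r)) {
    d <- means[k, ] - grand
    B <- B + sum(groups == levs[k]) * outer(d, d)
  }
  B <- B / (r - 1)
  eg <- eigen(solve(W) %*% B)
  ord <- order(Re(eg$values), decreasing = TRUE)[seq_len(nDa)]
  A <- Re(eg$vectors[, ord, drop = FALSE])
  for (j in seq_len(nDa))
    A[, j] <- A[, j] / sqrt(drop(t(A[, j]) %*% W %*% A[, j]))
  list(coords = S %*% A, eigenvalues = Re(eg$values)[ord])
}

# Compare coordinate matrices up to per-axis sign flips.
expect_equal_up_to_sign <- function(got, want, tol = 1e-8) {
  expect_equal(dim(got), dim(want))
  for (j in seq_len(ncol(want))) {
    d1 <- max(abs(got[, j] - want[, j]))
    d2 <- max(abs(got[, j] + want[, j]))
    expect_lt(min(d1, d2), tol)
  }
}
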