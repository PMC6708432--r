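#' @importFrom stats p.adjust
NULL

## Resolve a grouping argument: either the name of a colData column or a
## vector of labels, one per sample. Returns a factor.
.resolveGroups <- function(x, groups) {
  if (length(groups) == 1L && is.character(groups) &&
      groups %in% names(colData(x)))
    groups <- colData(x)[[groups]]
  if (length(groups) != ncol(x))
    stop("grouping must name a colData column or give one label per sample")
  factor(groups)
}

## Per-group, per-locus sufficient statistics from a dosage matrix
## (samples x loci): non-missing counts, alt-allele frequencies, and
## observed heterozygote fractions. Each is an r x L matrix.
.groupLocusStats <- function(X, groups) {
  M <- matrix(0, length(groups), nlevels(groups)) # samples x r indicator
  M[cbind(seq_along(groups), as.integer(groups))] <- 1
  nonmiss <- !is.na(X)
  X0 <- X; X0[!nonmiss] <- 0
  het <- (X == 1); het[!nonmiss] <- FALSE
  n <- crossprod(M, nonmiss * 1)                  # r x L
  s <- crossprod(M, X0)
  h <- crossprod(M, het * 1)
  p <- s / (2 * n)
  hf <- h / n
  list(n = n, p = p, h = hf, levels = levels(groups))
}

#' Observed heterozygosity per group
#'
#' Per locus, the fraction of non-missing individuals in the group that are
#' heterozygous (dosage 1); averaged over the loci with at least one
#' non-missing call in the group.
#'
#' @param x A [SnpGenotypes-class] object.
#' @param groups name of a `colData` column (e.g. `"region"`) or a vector of
#'   group labels, one per sample.
#' @return named numeric vector, one value per group (`NA` for a group with
#'   no usable data).
#' @export
observedHet <- function(x, groups) {
  g <- .resolveGroups(x, groups)
  st <- .groupLocusStats(dosageMatrix(x, samplesInRows = TRUE), g)
  ho <- st$h
  ho[st$n == 0] <- NA
  out <- rowMeans(ho, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  stats::setNames(out, st$levels)
}

#' Expected heterozygosity per group (small-sample corrected)
#'
#' Uses the Nei-Chesser unbiased within-group gene diversity per locus,
#' `Hs = n/(n-1) * (1 - p^2 - q^2 - Ho/(2n))` with `n` the non-missing
#' individuals at the locus; loci with `n < 2` in the group are skipped.
#' The per-group value is the mean over usable loci.
#'
#' @inheritParams observedHet
#' @return named numeric vector, one value per group.
#' @export
expectedHet <- function(x, groups) {
  g <- .resolveGroups(x, groups)
  st <- .groupLocusStats(dosageMatrix(x, samplesInRows = TRUE), g)
  n <- st$n; p <- st$p; ho <- st$h
  hs <- (n / (n - 1)) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
  hs[n < 2] <- NA
  out <- rowMeans(hs, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  stats::setNames(out, st$levels)
}

#' Within-group inbreeding coefficient
#'
#' `Gis = 1 - Ho/He` from the multi-locus averages of [observedHet()] and
#' [expectedHet()]. Negative values indicate heterozygote excess. Groups
#' with `He = 0` get `NA`.
#'
#' @inheritParams observedHet
#' @return named numeric vector, one value per group.
#' @export
inbreedingCoef <- function(x, groups) {
  ho <- observedHet(x, groups)
  he <- expectedHet(x, groups)
  out <- 1 - ho / he
  out[!is.na(he) & he == 0] <- NA_real_
  out
}

#' Gene diversity among individuals (1 - Q_inter)
#'
#' Per locus, `Q_inter` is the mean over ordered pairs of distinct
#' non-missing individuals of the probability that an allele drawn from one
#' matches an allele drawn from the other; for dosages `(gi, gj)` this is
#' `(gi*gj + (2-gi)*(2-gj)) / 4`. The statistic is `1 - Q_inter`, averaged
#' over loci with at least two usable individuals in the group.
#'
#' @inheritParams observedHet
#' @return named numeric vector, one value per group.
#' @export
geneDiversity <- function(x, groups) {
  g <- .resolveGroups(x, groups)
  X <- dosageMatrix(x, samplesInRows = TRUE)
  out <- vapply(levels(g), function(lev) {
    Xg <- X[g == lev, , drop = FALSE]
    vals <- apply(Xg, 2, function(col) {
      col <- col[!is.na(col)]
      n <- length(col)
      if (n < 2) return(NA_real_)
      s <- sum(col); s2 <- sum(col^2)
      # sum over ordered pairs i != j of [gi*gj + (2-gi)(2-gj)]/4
      cross <- s^2 - s2
      t <- 2 - col; ts <- sum(t); ts2 <- sum(t^2)
      crossT <- ts^2 - ts2
      q <- (cross + crossT) / (4 * n * (n - 1))
      1 - q
    })
    m <- mean(vals, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  }, numeric(1))
  out
}

#' Descriptive diversity statistics table
#'
#' One row per group: sample count, observed heterozygosity, expected
#' heterozygosity, inbreeding coefficient `Gis`, and gene diversity
#' `1 - Q_inter`.
#'
#' @inheritParams observedHet
#' @return data.frame with columns group, n, Ho, He, Gis, Div.
#' @export
diversityStats <- function(x, groups) {
  g <- .resolveGroups(x, groups)
  data.frame(group = levels(g),
             n = as.integer(table(g)),
             Ho = observedHet(x, g),
             He = expectedHet(x, g),
             Gis = inbreedingCoef(x, g),
             Div = geneDiversity(x, g),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Weir-Cockerham (1984) variance components for biallelic loci, vectorized
## over loci. Inputs are r x L matrices of per-group non-missing counts n,
## alt-allele frequencies p, and heterozygote fractions h. Groups with
## n == 0 at a locus make that locus undefined.
.wcComponents <- function(n, p, h) {
  r <- nrow(n)
  defined <- colSums(n > 0) == r
  nbar <- colSums(n) / r
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - matrix(pbar, r, length(pbar), byrow = TRUE))^2) /
    ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  a[!defined] <- NA; b[!defined] <- NA; c[!defined] <- NA
  # nbar == 1 (single individual per group on average) leaves a/b undefined
  bad <- defined & nbar <= 1
  a[bad] <- NA; b[bad] <- NA; c[bad] <- NA
  list(a = a, b = b, c = c)
}

#' Per-locus Weir-Cockerham F_ST
#'
#' Computes the Weir & Cockerham (1984) variance components for each
#' biallelic locus across `r >= 2` groups and the method-of-moments
#' estimator `theta = a / (a + b + c)`. Loci where `a + b + c = 0` (for
#' example, monomorphic everywhere) or where some group has no non-missing
#' call are reported with `NA` theta; negative estimates are reported as
#' computed, not clamped.
#'
#' @inheritParams observedHet
#' @return data.frame with columns locus_id, a, b, c, theta.
#' @export
wcFst <- function(x, groups) {
  g <- .resolveGroups(x, groups)
  if (nlevels(g) < 2) stop("need at least two groups")
  st <- .groupLocusStats(dosageMatrix(x, samplesInRows = TRUE), g)
  comp <- .wcComponents(st$n, st$p, st$h)
  denom <- comp$a + comp$b + comp$c
  theta <- ifelse(!is.na(denom) & denom != 0, comp$a / denom, NA_real_)
  data.frame(locus_id = rownames(x),
             a = comp$a, b = comp$b, c = comp$c, theta = theta,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multilocus Weir-Cockerham F_ST (ratio of sums)
#'
#' Aggregates per-locus variance components as `sum(a) / sum(a + b + c)`
#' over loci with defined components.
#'
#' @param locusFst data.frame from [wcFst()] (columns a, b, c).
#' @return single numeric estimate (`NA` if no locus is defined).
#' @export
multilocusFst <- function(locusFst) {
  ok <- !is.na(locusFst$a)
  if (!any(ok)) return(NA_real_)
  denom <- sum(locusFst$a[ok] + locusFst$b[ok] + locusFst$c[ok])
  if (denom == 0) return(NA_real_)
  sum(locusFst$a[ok]) / denom
}

## Fast two-group multilocus theta for permutation testing. X: samples x
## loci dosage; z: 0/1 indicator of group 1 membership. Totals over both
## groups are precomputed once by the caller.
.twoGroupTheta <- function(bigX, totals, z, L) {
  g1 <- as.vector(crossprod(bigX, z))
  n1 <- g1[seq_len(L)]; s1 <- g1[L + seq_len(L)]; h1 <- g1[2 * L + seq_len(L)]
  n2 <- totals$n - n1; s2 <- totals$s - s1; h2 <- totals$h - h1
  n <- rbind(n1, n2)
  p <- rbind(s1 / (2 * n1), s2 / (2 * n2))
  h <- rbind(h1 / n1, h2 / n2)
  comp <- .wcComponents(n, p, h)
  ok <- !is.na(comp$a)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!any(ok) || denom == 0) return(NA_real_)
  sum(comp$a[ok]) / denom
}

#' Pairwise permutation-tested F_ST
#'
#' For each unordered pair of groups, the observed statistic is the
#' multilocus Weir-Cockerham ratio-of-sums F_ST over the two groups. The
#' null distribution is built by permuting individuals between the two
#' groups (sizes preserved) and recomputing; `p = (1 + #{perm >= obs}) /
#' (1 + nPerm)`, so p is never zero. Significance uses a Bonferroni-adjusted
#' threshold `alpha / nPairs`.
#'
#' @inheritParams observedHet
#' @param nPerm number of permutations per pair (>= 1).
#' @param alpha familywise significance level.
#' @param seed optional integer seed for the permutations.
#' @return data.frame with one row per pair: group1, group2, fst, p_value,
#'   significant (after Bonferroni), n_permutations.
#' @export
pairwiseFst <- function(x, groups, nPerm = 10000, alpha = 0.05, seed = NULL) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- .resolveGroups(x, groups)
  if (any(table(g) < 2)) stop("every group needs at least 2 individuals")
  X <- dosageMatrix(x, samplesInRows = TRUE)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    fst = NA_real_, p_value = NA_real_,
                    significant = NA, n_permutations = as.integer(nPerm),
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    sel <- g %in% pairs[, k]
    Xp <- X[sel, , drop = FALSE]
    gp <- droplevels(g[sel])
    L <- ncol(Xp)
    nonmiss <- !is.na(Xp) * 1
    X0 <- Xp; X0[is.na(Xp)] <- 0
    het <- (Xp == 1) * 1; het[is.na(Xp)] <- 0
    bigX <- cbind(nonmiss, X0, het)                 # samples x 3L
    totals <- list(n = colSums(nonmiss), s = colSums(X0), h = colSums(het))
    z <- as.numeric(gp == levels(gp)[1])
    obs <- .twoGroupTheta(bigX, totals, z, L)
    perm <- vapply(seq_len(nPerm), function(i)
      .twoGroupTheta(bigX, totals, sample(z), L), numeric(1))
    res$fst[k] <- obs
    res$p_value[k] <- (1 + sum(perm >= obs, na.rm = TRUE)) / (1 + nPerm)
  }
  res$significant <- bonferroni(res$p_value, alpha = alpha)
  res
}

#' Bonferroni significance flags
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param alpha familywise significance level.
#' @return logical vector: `p <= alpha / length(p)`.
#' @export
bonferroni <- function(p, alpha = 0.05) {
  stopifnot(length(p) >= 1, all(p > 0 & p <= 1))
  p <= alpha / length(p)
}
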