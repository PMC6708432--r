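#' @importFrom stats kmeans cov
NULL

## Centered/scaled, mean-imputed dosage matrix (samples x loci) plus the
## imputation/centering values. Scaling is off by default: divisors of 1.
.prepDosage <- function(X, center = NULL, scaling = NULL, scale = FALSE) {
  if (is.null(center)) {
    center <- colMeans(X, na.rm = TRUE)
    center[is.nan(center)] <- 0
  }
  if (is.null(scaling)) {
    if (scale) {
      scaling <- apply(X, 2, stats::sd, na.rm = TRUE)
      scaling[is.na(scaling) | scaling == 0] <- 1
    } else scaling <- rep(1, ncol(X))
  }
  for (j in which(colSums(is.na(X)) > 0))
    X[is.na(X[, j]), j] <- center[j]
  Xc <- sweep(sweep(X, 2, center, "-"), 2, scaling, "/")
  list(X = Xc, center = center, scaling = scaling)
}

#' Estimate the number of genetic clusters by K-means with BIC
#'
#' Dosages are mean-imputed, centered and projected onto the leading
#' principal components; K-means is run for each K in `kMin:kMax` with
#' `nStarts` restarts, and a Bayesian information criterion
#' `BIC(K) = n * ln(WSS_K / n) + K * ln(n)` is computed from the total
#' within-cluster sum of squares. The selected K minimizes BIC; the whole
#' curve is returned for elbow inspection.
#'
#' @param x A [SnpGenotypes-class] object.
#' @param kMin,kMax range of K to assess (`kMax < n_samples`).
#' @param nPca number of principal components to retain before clustering;
#'   `NULL` retains all.
#' @param nStarts K-means restarts per K.
#' @param seed optional integer seed.
#' @return list with `BIC` (data.frame K, WSS, BIC), `assignments` (list of
#'   integer vectors, one per K), and `selectedK`.
#' @export
findClusters <- function(x, kMin = 1, kMax, nPca = NULL, nStarts = 20,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (kMax >= ncol(x)) stop("kMax must be smaller than the number of samples")
  prep <- .prepDosage(dosageMatrix(x, samplesInRows = TRUE))
  sv <- svd(prep$X)
  keep <- which(sv$d > 1e-8)
  if (!is.null(nPca)) keep <- keep[seq_len(min(nPca, length(keep)))]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  n <- nrow(scores)
  ks <- kMin:kMax
  wss <- numeric(length(ks))
  assign <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k == 1) {
      wss[i] <- sum(scale(scores, scale = FALSE)^2)
      assign[[i]] <- rep(1L, n)
    } else {
      km <- tryCatch(
        kmeans(scores, centers = k, nstart = nStarts, iter.max = 100),
        error = function(e) NULL)   # fewer distinct points than centers
      if (is.null(km)) {
        wss[i] <- NA
        assign[[i]] <- rep(NA_integer_, n)
      } else {
        wss[i] <- km$tot.withinss
        assign[[i]] <- km$cluster
      }
    }
  }
  bic <- n * log(wss / n) + ks * log(n)
  bic[is.na(bic)] <- Inf   # K exceeded the number of distinct points
  names(assign) <- paste0("K", ks)
  list(BIC = data.frame(K = ks, WSS = wss, BIC = bic),
       assignments = assign,
       selectedK = ks[which.min(bic)])
}

## Fix discriminant-axis signs deterministically: the largest-magnitude
## loading of each axis (through the full loci -> DA map) is made positive.
.fixSigns <- function(pcLoad, daCoef, centroids) {
  full <- pcLoad %*% daCoef
  for (j in seq_len(ncol(daCoef))) {
    i <- which.max(abs(full[, j]))
    if (full[i, j] < 0) {
      daCoef[, j] <- -daCoef[, j]
      centroids[, j] <- -centroids[, j]
    }
  }
  list(daCoef = daCoef, centroids = centroids)
}

#' Fit a discriminant analysis of principal components
#'
#' Missing dosages are imputed with the per-locus mean, the matrix is
#' centered (optionally unit-variance scaled), reduced to `nPca` principal
#' components, and a linear discriminant analysis is solved in PC space as
#' the generalized eigenproblem of between-group versus pooled within-group
#' covariance. Discriminant axes are scaled so the pooled within-group
#' covariance in discriminant space is the identity, and axis signs are
#' fixed by making the largest-magnitude locus loading positive. If the
#' within-group covariance is singular it is shrunk toward its diagonal
#' (ridge constant 1e-6 times the mean diagonal) with a warning.
#'
#' @param x A [SnpGenotypes-class] object (training data).
#' @param groups name of a `colData` column or a vector of group labels.
#' @param nPca number of principal components to retain (>= 1).
#' @param nDa number of discriminant axes (default: groups - 1).
#' @param scale logical, unit-variance scale loci (default centers only).
#' @return A [DapcModel-class] object.
#' @export
dapcFit <- function(x, groups, nPca, nDa = NULL, scale = FALSE) {
  g <- .resolveGroups(x, groups)
  if (any(table(g) < 2)) stop("every group needs at least 2 members")
  if (nPca < 1) stop("nPca must be >= 1")
  X <- dosageMatrix(x, samplesInRows = TRUE)
  prep <- .prepDosage(X, scale = scale)
  nPca <- min(nPca, nrow(X) - 1L, ncol(X))
  sv <- svd(prep$X, nu = nPca, nv = nPca)
  pos <- sv$d[seq_len(nPca)] > 1e-8
  pcLoad <- sv$v[, pos, drop = FALSE]
  nPca <- sum(pos)
  scores <- prep$X %*% pcLoad                        # n x nPca
  levs <- levels(g)
  r <- length(levs)
  if (is.null(nDa)) nDa <- r - 1L
  nDa <- as.integer(min(nDa, r - 1L, nPca))
  means <- do.call(rbind, lapply(levs, function(lev)
    colMeans(scores[g == lev, , drop = FALSE])))       # r x nPca
  rownames(means) <- levs
  grand <- colMeans(scores)
  n <- nrow(scores)
  # pooled within-group covariance, denominator n - r
  W <- matrix(0, nPca, nPca)
  for (lev in levs) {
    sc <- scores[g == lev, , drop = FALSE]
    sc <- sweep(sc, 2, means[lev, ], "-")
    W <- W + crossprod(sc)
  }
  W <- W / (n - r)
  # between-group covariance, denominator r - 1
  Bm <- sweep(means, 2, grand, "-")
  B <- crossprod(Bm * sqrt(as.vector(table(g)))) / (r - 1)
  ok <- tryCatch({ solve(W); TRUE }, error = function(e) FALSE)
  if (!ok || kappa(W) > 1e12) {
    warning("within-group covariance near-singular; shrinking toward its diagonal")
    W <- W + diag(1e-6 * mean(diag(W)), nPca)
  }
  # symmetric whitening solve of the generalized eigenproblem W^-1 B
  eW <- eigen(W, symmetric = TRUE)
  Wi <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, 1e-12)), nPca) %*%
    t(eW$vectors)
  eB <- eigen(Wi %*% B %*% Wi, symmetric = TRUE)
  daCoef <- Wi %*% eB$vectors[, seq_len(nDa), drop = FALSE]
  eig <- eB$values[seq_len(nDa)]
  centroids <- means %*% daCoef
  fx <- .fixSigns(pcLoad, daCoef, centroids)
  dimnames(fx$centroids) <- list(levs, paste0("DA", seq_len(nDa)))
  new("DapcModel",
      loci = rownames(x),
      centering = unname(prep$center),
      scaling = unname(prep$scaling),
      pcLoadings = pcLoad,
      daCoefficients = fx$daCoef,
      groupCentroids = fx$centroids,
      groupLabels = levs,
      nPca = as.integer(nPca),
      nDa = nDa,
      eigenvalues = eig)
}

#' Predict source populations for supplemental individuals
#'
#' Supplemental individuals are transformed with the centering and scaling
#' of the fitted model (missing cells, and loci absent from the supplemental
#' data, are imputed at the training means), projected through the retained
#' PC loadings and discriminant coefficients, and assigned by a softmax of
#' minus half the squared Euclidean distance to each group centroid in
#' discriminant space (equal priors, spherical unit covariance).
#'
#' @param model A [DapcModel-class] object.
#' @param x A [SnpGenotypes-class] with loci a subset of the model's loci.
#' @return data.frame with sample_id, one posterior column per group,
#'   `assigned` (label of the maximum posterior), and the discriminant
#'   coordinates as columns `DA1..`; samples with 100% missing data get
#'   all-`NA` rows.
#' @export
dapcPredict <- function(model, x) {
  Xin <- dosageMatrix(x, samplesInRows = TRUE)
  extra <- setdiff(colnames(Xin), model@loci)
  if (length(extra))
    stop("supplemental loci absent from the model: ",
         paste(head(extra, 5), collapse = ", "))
  n <- nrow(Xin)
  X <- matrix(NA_real_, n, length(model@loci),
              dimnames = list(rownames(Xin), model@loci))
  X[, colnames(Xin)] <- Xin
  allMissing <- rowSums(!is.na(X)) == 0
  for (j in seq_len(ncol(X)))
    X[is.na(X[, j]), j] <- model@centering[j]
  Xc <- sweep(sweep(X, 2, model@centering, "-"), 2, model@scaling, "/")
  da <- Xc %*% model@pcLoadings %*% model@daCoefficients
  d2 <- outer(rowSums(da^2), rep(1, nrow(model@groupCentroids))) -
    2 * da %*% t(model@groupCentroids) +
    outer(rep(1, n), rowSums(model@groupCentroids^2))
  lw <- -d2 / 2
  lw <- lw - apply(lw, 1, max)
  post <- exp(lw) / rowSums(exp(lw))
  colnames(post) <- model@groupLabels
  assigned <- model@groupLabels[max.col(post, ties.method = "first")]
  post[allMissing, ] <- NA
  assigned[allMissing] <- NA
  da[allMissing, ] <- NA
  colnames(da) <- paste0("DA", seq_len(model@nDa))
  data.frame(sample_id = colnames(x), post, assigned = assigned, da,
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Cross-validate the number of retained principal components
#'
#' For each candidate `nPca` on a grid up to `maxPca`, repeats `nReps`
#' stratified training/hold-out splits, fits the DAPC on the training
#' portion and records the hold-out assignment success. The optimum
#' minimizes the root-mean-squared error of `1 - success`; ties break
#' toward fewer PCs.
#'
#' @inheritParams dapcFit
#' @param maxPca largest candidate number of PCs.
#' @param trainingFraction fraction of each group used for training.
#' @param nReps replicates per candidate.
#' @param grid optional integer vector of candidate `nPca` values.
#' @param seed optional integer seed.
#' @return list with `optimalPca`, `curve` (data.frame nPca, meanSuccess,
#'   rmse), and `successes` (matrix nReps x candidates).
#' @export
dapcXval <- function(x, groups, maxPca = 200, trainingFraction = 0.9,
                     nReps = 30, grid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- .resolveGroups(x, groups)
  maxPca <- min(maxPca, ncol(x), nrow(x))
  if (is.null(grid))
    grid <- unique(pmax(1, round(seq(1, maxPca, length.out = min(8, maxPca)))))
  succ <- matrix(NA_real_, nReps, length(grid))
  for (rep in seq_len(nReps)) {
    repeat {
      trainIdx <- unlist(lapply(levels(g), function(lev) {
        idx <- which(g == lev)
        sample(idx, max(2, round(trainingFraction * length(idx))))
      }))
      if (all(table(g[trainIdx]) >= 2) &&
          length(trainIdx) < ncol(x)) break
    }
    testIdx <- setdiff(seq_len(ncol(x)), trainIdx)
    for (j in seq_along(grid)) {
      np <- min(grid[j], length(trainIdx) - 1L)
      fit <- dapcFit(x[, trainIdx], g[trainIdx], nPca = np)
      pred <- dapcPredict(fit, x[, testIdx])
      succ[rep, j] <- mean(pred$assigned == as.character(g[testIdx]),
                           na.rm = TRUE)
    }
  }
  rmse <- sqrt(colMeans((1 - succ)^2))
  curve <- data.frame(nPca = grid, meanSuccess = colMeans(succ), rmse = rmse)
  best <- grid[which(rmse == min(rmse))]
  list(optimalPca = min(best), curve = curve, successes = succ)
}

#' Serialize / restore a DapcModel as JSON
#'
#' @param model A [DapcModel-class] object.
#' @param path file path for the JSON document.
#' @return `writeDapcModel` returns `path` invisibly; `readDapcModel`
#'   returns the restored [DapcModel-class].
#' @export
writeDapcModel <- function(model, path) {
  doc <- list(schema = "snpAssign/DapcModel/1",
              loci = model@loci,
              centering = model@centering,
              scaling = model@scaling,
              pcLoadings = model@pcLoadings,
              daCoefficients = model@daCoefficients,
              groupCentroids = model@groupCentroids,
              groupLabels = model@groupLabels,
              nPca = model@nPca, nDa = model@nDa,
              eigenvalues = model@eigenvalues)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDapcModel
#' @export
readDapcModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "snpAssign/DapcModel/1"))
    stop("unrecognized model schema")
  cent <- as.matrix(doc$groupCentroids)
  rownames(cent) <- doc$groupLabels
  colnames(cent) <- paste0("DA", seq_len(doc$nDa))
  new("DapcModel",
      loci = doc$loci, centering = doc$centering, scaling = doc$scaling,
      pcLoadings = as.matrix(doc$pcLoadings),
      daCoefficients = as.matrix(doc$daCoefficients),
      groupCentroids = cent, groupLabels = doc$groupLabels,
      nPca = as.integer(doc$nPca), nDa = as.integer(doc$nDa),
      eigenvalues = as.numeric(doc$eigenvalues))
}
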