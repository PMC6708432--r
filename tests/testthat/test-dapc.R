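test_that("cluster search recovers well-separated groups and null structure", {
  # two groups fixed at opposite homozygotes on many loci: perfect separation
  d <- rbind(matrix(0L, 15, 40), matrix(2L, 15, 40))
  gm <- makeGm(d)
  fc <- findClusters(gm, kMin = 1, kMax = 5, seed = 1)
  expect_equal(fc$selectedK, 2)
  part <- fc$assignments$K2
  expect_true(length(unique(part[1:15])) == 1 &&
                length(unique(part[16:30])) == 1 &&
                part[1] != part[16])
  # single panmictic blob: BIC minimized at K = 1
  gm0 <- simulateSnpDataset(nPops = 1, samplesPerPop = 40, nLoci = 150,
                            Fst = 0, missingRate = 0, seed = 2)
  fc0 <- findClusters(gm0, kMin = 1, kMax = 5, seed = 3)
  expect_equal(fc0$selectedK, 1)
})

test_that("cluster search recovers simulated population labels", {
  gm <- simulateSnpDataset(nPops = 4, samplesPerPop = 40, nLoci = 800,
                           Fst = 0.10, seed = 4)
  fc <- findClusters(gm, kMin = 1, kMax = 8, seed = 5)
  expect_true(fc$selectedK %in% 3:4)
  ari <- mclust::adjustedRandIndex(fc$assignments$K4,
                                   sampleMeta(gm)$region)
  expect_gte(ari, 0.9)
})

test_that("discriminant coordinates match the dense PCA+LDA transcription", {
  set.seed(6)
  d <- matrix(sample(0:2, 12 * 6, replace = TRUE), 12, 6)
  d[1:6, 1] <- 0L; d[7:12, 1] <- 2L   # give the groups real signal
  groups <- rep(c("a", "b"), each = 6)
  gm <- makeGm(d, region = groups)
  fit <- dapcFit(gm, "region", nPca = 4)
  pred <- dapcPredict(fit, gm)
  want <- pcaLdaOracle(d, groups, nPca = 4, nDa = 1)
  expect_equal_up_to_sign(as.matrix(pred$DA1), as.matrix(want$coords),
                          tol = 1e-8)
  expect_equal(fit@eigenvalues, want$eigenvalues, tolerance = 1e-8)
})

test_that("oracle agreement holds across random toy instances with 3 groups", {
  set.seed(7)
  for (i in 1:5) {
    d <- matrix(sample(0:2, 18 * 8, replace = TRUE), 18, 8)
    groups <- rep(c("a", "b", "c"), each = 6)
    gm <- makeGm(d, region = groups)
    fit <- dapcFit(gm, "region", nPca = 5)
    pred <- dapcPredict(fit, gm)
    want <- pcaLdaOracle(d, groups, nPca = 5, nDa = 2)
    expect_equal_up_to_sign(as.matrix(pred[, c("DA1", "DA2")]),
                            want$coords, tol = 1e-6)
  }
})

test_that("a fixed-difference locus separates groups completely", {
  set.seed(8)
  base <- matrix(sample(0:2, 20 * 10, replace = TRUE), 20, 10)
  base[, 1] <- rep(c(0L, 2L), each = 10)
  gm <- makeGm(base, region = rep(c("a", "b"), each = 10))
  fit <- dapcFit(gm, "region", nPca = 8)
  pred <- dapcPredict(fit, gm)
  expect_equal(pred$assigned, rep(c("a", "b"), each = 10))
  expect_true(all(pmax(pred$a, pred$b) > 0.99))
})

test_that("posteriors are valid probabilities and reprojection is exact", {
  gm <- simulateSnpDataset(nPops = 3, samplesPerPop = 20, nLoci = 300,
                           Fst = 0.1, seed = 9)
  fit <- dapcFit(gm, "region", nPca = 20)
  pred <- dapcPredict(fit, gm)
  post <- as.matrix(pred[, fit@groupLabels])
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  expect_true(all(post >= 0))
  expect_equal(pred$assigned,
               fit@groupLabels[max.col(post, ties.method = "first")])
  # projecting the training data twice gives identical coordinates
  pred2 <- dapcPredict(fit, gm)
  expect_identical(pred$DA1, pred2$DA1)
})

test_that("an individual midway between centroids splits its posterior", {
  # two groups differing only in allele frequency; a supplemental genotype
  # exactly at the grand mean projects midway
  d <- rbind(matrix(0L, 10, 20), matrix(2L, 10, 20))
  gm <- makeGm(d, region = rep(c("a", "b"), each = 10))
  fit <- suppressWarnings(dapcFit(gm, "region", nPca = 2))
  mid <- matrix(1L, 1, 20)
  rownames(mid) <- "between"
  colnames(mid) <- rownames(gm)
  gmMid <- makeGm(mid)
  pred <- dapcPredict(fit, gmMid)
  expect_equal(pred$a, 0.5, tolerance = 1e-6)
  expect_equal(pred$b, 0.5, tolerance = 1e-6)
})

test_that("supplemental samples with entirely missing data are flagged NA", {
  d <- rbind(matrix(0L, 6, 10), matrix(2L, 6, 10))
  gm <- makeGm(d, region = rep(c("a", "b"), each = 6))
  fit <- suppressWarnings(dapcFit(gm, "region", nPca = 3))
  supp <- matrix(NA_integer_, 1, 10,
                 dimnames = list("ghost", rownames(gm)))
  pred <- dapcPredict(fit, makeGm(supp))
  expect_true(is.na(pred$assigned))
  expect_true(all(is.na(pred[, c("a", "b")])))
})

test_that("prediction handles supplemental data with a subset of model loci", {
  gm <- simulateSnpDataset(nPops = 2, samplesPerPop = 25, nLoci = 200,
                           Fst = 0.2, seed = 10)
  fit <- dapcFit(gm, "region", nPca = 15)
  sub <- gm[1:120, 26:50]   # fewer loci, group-2 samples only
  pred <- dapcPredict(fit, sub)
  expect_equal(nrow(pred), 25)
  expect_gt(mean(pred$assigned == "pop2"), 0.8)
  # loci unknown to the model are rejected
  alien <- makeGm(matrix(0L, 2, 3))
  expect_error(dapcPredict(fit, alien), "absent")
})

test_that("cross-validation prefers few PCs under perfect separation and finds chance under random labels", {
  d <- rbind(matrix(0L, 20, 30), matrix(2L, 20, 30))
  gm <- makeGm(d, region = rep(c("a", "b"), each = 20))
  xv <- suppressWarnings(
    dapcXval(gm, "region", maxPca = 20, nReps = 5, seed = 11))
  expect_true(all(xv$curve$meanSuccess > 0.99))
  expect_equal(xv$optimalPca, min(xv$curve$nPca))

  gm0 <- simulateSnpDataset(nPops = 1, samplesPerPop = 40, nLoci = 100,
                            Fst = 0, missingRate = 0, seed = 12)
  set.seed(13)
  lab <- sample(rep(c("a", "b"), each = 20))
  xv0 <- dapcXval(gm0, lab, maxPca = 20, nReps = 10, seed = 14)
  expect_lt(abs(mean(xv0$curve$meanSuccess) - 0.5), 0.2)
})

test_that("assignment accuracy increases with population divergence", {
  acc <- vapply(c(0.01, 0.05, 0.15), function(F) {
    gm <- simulateSnpDataset(nPops = 4, samplesPerPop = 25, nLoci = 400,
                             Fst = F, seed = 15)
    g <- sampleMeta(gm)$region
    set.seed(16)
    hold <- unlist(lapply(split(seq_along(g), g), function(i)
      sample(i, length(i) %/% 5)))
    fit <- dapcFit(gm[, -hold], g[-hold], nPca = 30)
    pred <- dapcPredict(fit, gm[, hold])
    mean(pred$assigned == g[hold])
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("models survive a JSON round trip", {
  gm <- simulateSnpDataset(nPops = 3, samplesPerPop = 15, nLoci = 120,
                           Fst = 0.1, seed = 17)
  fit <- dapcFit(gm, "region", nPca = 10)
  tmp <- withr::local_tempfile(fileext = ".json")
  writeDapcModel(fit, tmp)
  back <- readDapcModel(tmp)
  p1 <- dapcPredict(fit, gm)
  p2 <- dapcPredict(back, gm)
  expect_equal(p1, p2, tolerance = 1e-12)
})
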