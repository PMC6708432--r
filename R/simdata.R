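#' @importFrom stats runif rbeta rbinom rnorm
NULL

#' Replicate-assay error model
#'
#' Parameters for [simulateReplicates()]: `dropout` is the probability that
#' a heterozygote replicate reads as a random homozygote (allelic dropout,
#' equal split between the two homozygotes), `failure` the probability a
#' replicate returns no call at all. Confidence scores for called
#' replicates follow a two-component law: clean calls draw from
#' `Beta(cleanShape1, cleanShape2)` (concentrated near 0.97 by default) and
#' dropout-affected calls from the more diffuse `Beta(noisyShape1,
#' noisyShape2)`, so the confidence-threshold logic of [callTest()] is
#' exercised.
#'
#' @param dropout,failure probabilities in \[0, 1\].
#' @param cleanShape1,cleanShape2,noisyShape1,noisyShape2 Beta parameters
#'   of the confidence law.
#' @return list of class `"assayErrorModel"`.
#' @export
assayErrorModel <- function(dropout = 0.05, failure = 0.1,
                            cleanShape1 = 200, cleanShape2 = 6,
                            noisyShape1 = 8, noisyShape2 = 2) {
  stopifnot(dropout >= 0, dropout <= 1, failure >= 0, failure <= 1)
  structure(list(dropout = dropout, failure = failure,
                 cleanShape1 = cleanShape1, cleanShape2 = cleanShape2,
                 noisyShape1 = noisyShape1, noisyShape2 = noisyShape2),
            class = "assayErrorModel")
}

#' Simulate a multi-population SNP dataset under the Balding-Nichols model
#'
#' Per locus, an ancestral alternate-allele frequency `p` is drawn uniformly
#' from `freqRange`; each population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` so that the expected differentiation
#' among populations is approximately `F` (populations with `F = 0` keep
#' `p` exactly). Individuals carry two gene copies; with admixture enabled
#' each copy picks its source population from the individual's Dirichlet
#' ancestry proportions. Missing calls are introduced completely at random.
#' Loci are assigned round-robin to `nScaffolds` scaffolds with increasing
#' positions spaced 1000 bp apart, and ref/alt alleles are drawn as
#' distinct nucleotides.
#'
#' The defaults mirror a range-wide insect ddRAD study: four regional
#' populations, 50 individuals each, 2,000 biallelic loci, low-moderate
#' differentiation, and 5% missing data.
#'
#' @param nPops number of populations.
#' @param samplesPerPop integer, recycled to `nPops`.
#' @param nLoci number of biallelic loci.
#' @param Fst per-population divergence parameter(s) in \[0, 1), recycled.
#' @param admixAlpha optional Dirichlet concentration for per-individual
#'   admixture proportions; `NULL` (default) gives unadmixed individuals.
#' @param freqRange `(lo, hi)` range for the uniform ancestral frequencies.
#' @param missingRate fraction of cells set missing, completely at random.
#' @param nScaffolds number of reference scaffolds loci are spread over.
#' @param seed integer seed governing all draws.
#' @return A [SnpGenotypes-class]; `metadata(.)$truth` records the ground
#'   truth: `ancestralFreq`, `popFreq` (loci x pops), `admixture`
#'   (individuals x pops), `trueGenotypes` (pre-missingness dosage matrix),
#'   and `popLabels`.
#' @export
simulateSnpDataset <- function(nPops = 4, samplesPerPop = 50, nLoci = 2000,
                               Fst = 0.05, admixAlpha = NULL,
                               freqRange = c(0.1, 0.9), missingRate = 0.05,
                               nScaffolds = 500, seed = 1) {
  stopifnot(freqRange[1] > 0, freqRange[2] < 1,
            freqRange[1] <= freqRange[2],
            missingRate >= 0, missingRate <= 1)
  set.seed(seed)
  samplesPerPop <- rep_len(samplesPerPop, nPops)
  Fst <- rep_len(Fst, nPops)
  n <- sum(samplesPerPop)
  popLabels <- paste0("pop", seq_len(nPops))
  popOf <- rep(popLabels, samplesPerPop)

  p <- runif(nLoci, freqRange[1], freqRange[2])
  popFreq <- matrix(NA_real_, nLoci, nPops,
                    dimnames = list(NULL, popLabels))
  for (k in seq_len(nPops)) {
    if (Fst[k] == 0) {
      popFreq[, k] <- p
    } else {
      shape <- (1 - Fst[k]) / Fst[k]
      popFreq[, k] <- rbeta(nLoci, p * shape, (1 - p) * shape)
    }
  }

  # per-individual admixture proportions (rows sum to 1)
  Q <- matrix(0, n, nPops, dimnames = list(NULL, popLabels))
  if (is.null(admixAlpha)) {
    Q[cbind(seq_len(n), match(popOf, popLabels))] <- 1
  } else {
    for (i in seq_len(n)) {
      alpha <- rep(admixAlpha, nPops)
      alpha[match(popOf[i], popLabels)] <- alpha[match(popOf[i], popLabels)] +
        1  # bias toward the labelled population
      gam <- stats::rgamma(nPops, shape = alpha)
      Q[i, ] <- gam / sum(gam)
    }
  }

  # two gene copies per individual; each copy picks a source population
  geno <- matrix(0L, n, nLoci)
  for (copy in 1:2) {
    src <- matrix(0L, n, nLoci)
    u <- matrix(runif(n * nLoci), n, nLoci)
    cum <- t(apply(Q, 1, cumsum))
    src <- matrix(1L, n, nLoci)
    for (k in seq_len(nPops - 1))
      src <- src + (u > cum[, k])
    pk <- matrix(popFreq[cbind(rep(seq_len(nLoci), each = n),
                               as.vector(src))], n, nLoci)
    geno <- geno + (matrix(runif(n * nLoci), n, nLoci) < pk)
  }
  storage.mode(geno) <- "integer"

  sampleIds <- sprintf("ind%03d", seq_len(n))
  locusIds <- sprintf("L%04d", seq_len(nLoci))
  dimnames(geno) <- list(sampleIds, locusIds)

  obs <- geno
  if (missingRate > 0)
    obs[matrix(runif(n * nLoci), n, nLoci) < missingRate] <- NA_integer_

  scaffold <- paste0("scaffold", ((seq_len(nLoci) - 1) %% nScaffolds) + 1)
  position <- 1000L * ((seq_len(nLoci) - 1) %/% nScaffolds) + 500L
  nts <- c("A", "C", "G", "T")
  refIdx <- sample.int(4, nLoci, replace = TRUE)
  altIdx <- ((refIdx - 1 + sample.int(3, nLoci, replace = TRUE)) %% 4) + 1

  meta <- data.frame(population = popOf, region = popOf, role = "wild",
                     stringsAsFactors = FALSE)
  gm <- SnpGenotypes(t(obs), scaffold = scaffold, position = position,
                     ref = nts[refIdx], alt = nts[altIdx],
                     sampleData = meta)
  metadata(gm)$truth <- list(
    ancestralFreq = p, popFreq = popFreq, admixture = Q,
    trueGenotypes = geno, popLabels = popOf)
  gm
}

#' Simulate replicated assay calls from true genotypes
#'
#' Per (sample, locus, replicate): with probability `failure` the reaction
#' returns no call; otherwise the called genotype equals the truth, except
#' that heterozygotes drop to one of the two homozygotes with probability
#' `dropout` (equal split). Confidence scores come from the model's
#' two-component Beta law: the clean component for faithful calls and the
#' diffuse component for dropout-affected calls.
#'
#' @param x A [SnpGenotypes-class]; truth is taken from
#'   `metadata(x)$truth$trueGenotypes` when present, otherwise from the
#'   observed dosages.
#' @param model an [assayErrorModel()].
#' @param nReps replicates per (sample, locus).
#' @param seed integer seed.
#' @return list with `calls` (long data.frame sample_id, assay_id,
#'   replicate, genotype, confidence), `assayFlags` (all separation flags
#'   `TRUE`), and `truth` (the sample x locus true dosage matrix).
#' @export
simulateReplicates <- function(x, model = assayErrorModel(), nReps = 3,
                               seed = 1) {
  set.seed(seed)
  truth <- metadata(x)$truth$trueGenotypes
  if (is.null(truth)) truth <- dosageMatrix(x, samplesInRows = TRUE)
  n <- nrow(truth); L <- ncol(truth)
  long <- expand.grid(replicate = seq_len(nReps),
                      sample_id = rownames(truth),
                      assay_id = colnames(truth),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tru <- truth[cbind(match(long$sample_id, rownames(truth)),
                     match(long$assay_id, colnames(truth)))]
  m <- nrow(long)
  fail <- runif(m) < model$failure
  isHet <- !is.na(tru) & tru == 1
  drop <- isHet & (runif(m) < model$dropout)
  called <- tru
  called[drop] <- sample(c(0L, 2L), sum(drop), replace = TRUE)
  conf <- rbeta(m, model$cleanShape1, model$cleanShape2)
  conf[drop] <- rbeta(sum(drop), model$noisyShape1, model$noisyShape2)
  called[fail | is.na(tru)] <- NA_integer_
  conf[is.na(called)] <- NA_real_
  calls <- data.frame(sample_id = long$sample_id, assay_id = long$assay_id,
                      replicate = long$replicate, genotype = called,
                      confidence = conf, stringsAsFactors = FALSE)
  flags <- data.frame(assay_id = colnames(truth), separation_flag = TRUE,
                      stringsAsFactors = FALSE)
  list(calls = calls, assayFlags = flags, truth = truth)
}

#' Write a seeded benchmark fixture set
#'
#' Emits a small, fully self-consistent benchmark to `outdir`: a VCF and
#' sample-metadata CSV from a simulated 4-population dataset, a
#' replicate-call CSV with the default error model, a reference FASTA whose
#' bases agree with every locus's ref allele, a machine-readable truth JSON,
#' and a copy of the per-assay QC count table shipped with the package.
#' Regenerating with the same seed produces byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed.
#' @param nPops,samplesPerPop,nLoci,nScaffolds scaled-down dataset shape.
#' @return invisible character vector of the files written.
#' @export
writeFixtures <- function(outdir, seed = 1, nPops = 4, samplesPerPop = 12,
                          nLoci = 200, nScaffolds = 40) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gm <- simulateSnpDataset(nPops = nPops, samplesPerPop = samplesPerPop,
                           nLoci = nLoci, Fst = 0.1,
                           nScaffolds = nScaffolds, seed = seed)
  vcf <- file.path(outdir, "genotypes.vcf")
  writeSnpVcf(gm, vcf)
  metaCsv <- file.path(outdir, "samples.csv")
  write.csv(sampleMeta(gm), metaCsv, row.names = FALSE, quote = FALSE)

  rep <- simulateReplicates(gm, seed = seed + 1)
  callsCsv <- file.path(outdir, "replicate_calls.csv")
  rc <- rep$calls
  rc$genotype <- ifelse(is.na(rc$genotype), "NC", as.character(rc$genotype))
  rc$confidence <- ifelse(is.na(rc$confidence), "",
                          formatC(rc$confidence, digits = 6, format = "f"))
  write.csv(rc, callsCsv, row.names = FALSE, quote = FALSE)

  # reference scaffolds consistent with the loci
  li <- lociInfo(gm)
  set.seed(seed + 2)
  scafs <- unique(li$scaffold)
  fa <- vapply(scafs, function(sc) {
    maxPos <- max(li$position[li$scaffold == sc])
    len <- maxPos + 200L
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    here <- li[li$scaffold == sc, ]
    s[here$position] <- here$ref
    paste(s, collapse = "")
  }, character(1))
  fasta <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fa), fasta)

  truthJson <- file.path(outdir, "truth.json")
  tr <- metadata(gm)$truth
  jsonlite::write_json(
    list(ancestralFreq = tr$ancestralFreq, popFreq = tr$popFreq,
         popLabels = tr$popLabels, trueGenotypes = tr$trueGenotypes,
         loci = li),
    truthJson, digits = NA)

  qcSrc <- system.file("extdata", "assay_qc_counts.csv",
                       package = "snpAssign")
  qcDst <- file.path(outdir, "assay_qc_counts.csv")
  file.copy(qcSrc, qcDst, overwrite = TRUE)
  invisible(c(vcf, metaCsv, callsCsv, fasta, truthJson, qcDst))
}
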