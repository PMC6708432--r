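#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData rowRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

.VALID_ROLES <- c("wild", "rearing", "validation", "test", "control")

#' SnpGenotypes: biallelic SNP dosage matrix with locus and sample annotation
#'
#' `SnpGenotypes` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are biallelic SNP loci (a `GRanges` whose seqnames are reference
#' scaffolds, with `ref` and `alt` allele columns), columns are individuals,
#' and the single `"dosage"` assay holds the count of the alternate allele:
#' 0 (homozygous reference), 1 (heterozygous), 2 (homozygous alternate), or
#' `NA` for a missing call. Sample metadata (`population`, `region`, `role`)
#' lives in `colData`.
#'
#' @slot ... see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [SnpGenotypes()] the constructor, [readSnpVcf()], [filterGenotypes()]
#' @export
setClass("SnpGenotypes", contains = "RangedSummarizedExperiment")

setValidity("SnpGenotypes", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "locus ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  rr <- rowRanges(object)
  if (!all(c("ref", "alt") %in% names(S4Vectors::mcols(rr))))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' allele columns")
  else if (any(as.character(rr$ref) == as.character(rr$alt)))
    msg <- c(msg, "ref and alt alleles must differ at every locus")
  if (any(start(rr) < 1))
    msg <- c(msg, "positions must be >= 1 (1-based coordinates)")
  if ("role" %in% names(colData(object))) {
    role <- colData(object)$role
    if (!all(is.na(role) | role %in% .VALID_ROLES))
      msg <- c(msg, paste0("role must be one of: ",
                           paste(.VALID_ROLES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param dosage integer matrix of alternate-allele counts, loci in rows and
#'   samples in columns, values in \{0, 1, 2, NA\}. Must have row and column
#'   names (locus and sample ids).
#' @param scaffold character vector of reference scaffold names, one per locus.
#' @param position integer vector of 1-based locus positions on the scaffold.
#' @param ref,alt single-nucleotide reference and alternate alleles per locus.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata
#'   (columns such as `population`, `region`, `role`), rownames matching
#'   sample ids.
#'
#' @return A [SnpGenotypes-class] object.
#' @examples
#' gm <- SnpGenotypes(
#'   dosage = matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                   dimnames = list(c("L1", "L2"), c("S1", "S2"))),
#'   scaffold = c("sc1", "sc2"), position = c(101L, 55L),
#'   ref = c("A", "C"), alt = c("G", "T"))
#' gm
#' @export
SnpGenotypes <- function(dosage, scaffold, position, ref, alt,
                         sampleData = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage matrix must have locus rownames and sample colnames")
  rr <- GRanges(seqnames = scaffold,
                ranges = IRanges(start = as.integer(position), width = 1L),
                ref = as.character(ref), alt = as.character(alt))
  names(rr) <- rownames(dosage)
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(dosage))
  } else {
    DataFrame(sampleData, row.names = colnames(dosage))
  }
  se <- SummarizedExperiment(assays = SimpleList(dosage = dosage),
                             rowRanges = rr, colData = cd)
  new("SnpGenotypes", se)
}

setMethod("show", "SnpGenotypes", function(object) {
  d <- assay(object, "dosage")
  miss <- if (length(d)) mean(is.na(d)) else NA_real_
  cat("SnpGenotypes with", nrow(object), "loci and", ncol(object),
      "samples\n")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  cat("  scaffolds:", length(unique(as.character(seqnames(rowRanges(object))))),
      "\n")
  if ("region" %in% names(colData(object))) {
    tb <- table(colData(object)$region)
    cat("  regions:", paste(sprintf("%s(%d)", names(tb), tb), collapse = " "),
        "\n")
  }
  invisible(NULL)
})

#' DapcModel: a fitted discriminant analysis of principal components
#'
#' Holds everything needed to project supplemental individuals through a
#' fitted DAPC: per-locus centering/scaling (which double as the imputation
#' values for missing dosages), retained principal-component loadings,
#' discriminant coefficients, and group centroids in discriminant space.
#'
#' @slot loci character, locus ids in model order.
#' @slot centering numeric, per-locus mean dosage used for centering and for
#'   imputing missing calls.
#' @slot scaling numeric, per-locus divisor (all 1 when scaling is off).
#' @slot pcLoadings matrix, loci x nPca principal-component loadings.
#' @slot daCoefficients matrix, nPca x nDa discriminant coefficients, scaled
#'   so pooled within-group covariance in discriminant space is the identity.
#' @slot groupCentroids matrix, groups x nDa centroids.
#' @slot groupLabels character group labels.
#' @slot nPca,nDa integer, number of retained PCs / discriminant axes.
#' @slot eigenvalues numeric, discriminant eigenvalues (nonincreasing).
#' @export
setClass("DapcModel", representation(
  loci = "character",
  centering = "numeric",
  scaling = "numeric",
  pcLoadings = "matrix",
  daCoefficients = "matrix",
  groupCentroids = "matrix",
  groupLabels = "character",
  nPca = "integer",
  nDa = "integer",
  eigenvalues = "numeric"
))

setValidity("DapcModel", function(object) {
  msg <- character()
  L <- length(object@loci)
  if (length(object@centering) != L || length(object@scaling) != L)
    msg <- c(msg, "centering/scaling must have one entry per locus")
  if (nrow(object@pcLoadings) != L)
    msg <- c(msg, "pcLoadings must have one row per locus")
  if (ncol(object@pcLoadings) != object@nPca)
    msg <- c(msg, "pcLoadings must have nPca columns")
  if (!identical(dim(object@daCoefficients),
                 c(object@nPca, object@nDa)))
    msg <- c(msg, "daCoefficients must be nPca x nDa")
  g <- length(object@groupLabels)
  if (object@nDa > g - 1L)
    msg <- c(msg, "nDa must be <= number of groups - 1")
  if (nrow(object@groupCentroids) != g ||
      ncol(object@groupCentroids) != object@nDa)
    msg <- c(msg, "groupCentroids must be groups x nDa")
  ev <- object@eigenvalues
  if (length(ev) != object@nDa)
    msg <- c(msg, "one eigenvalue per discriminant axis")
  if (length(ev) > 1 && any(diff(ev) > 1e-8))
    msg <- c(msg, "eigenvalues must be nonincreasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DapcModel", function(object) {
  cat("DapcModel:", length(object@loci), "loci,",
      object@nPca, "PCs,", object@nDa, "discriminant axes\n")
  cat("  groups:", paste(object@groupLabels, collapse = ", "), "\n")
  cat("  eigenvalues:",
      paste(signif(object@eigenvalues, 4), collapse = " "), "\n")
  invisible(NULL)
})
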