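#' @importFrom utils read.csv write.csv
NULL

#' Extract the dosage matrix
#'
#' @param x A [SnpGenotypes-class] object.
#' @param samplesInRows logical; if `TRUE` return samples x loci (the
#'   orientation used by the multivariate methods), otherwise loci x samples
#'   as stored.
#' @return Integer matrix of alternate-allele dosages with `NA` for missing.
#' @export
dosageMatrix <- function(x, samplesInRows = FALSE) {
  d <- assay(x, "dosage")
  if (samplesInRows) t(d) else d
}

#' Per-locus annotation as a data.frame
#'
#' @param x A [SnpGenotypes-class] object.
#' @return data.frame with columns locus_id, scaffold, position, ref, alt.
#' @export
lociInfo <- function(x) {
  rr <- rowRanges(x)
  data.frame(locus_id = names(rr),
             scaffold = as.character(seqnames(rr)),
             position = start(rr),
             ref = rr$ref, alt = rr$alt,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample metadata as a data.frame
#'
#' @param x A [SnpGenotypes-class] object.
#' @return data.frame with a `sample_id` column plus whatever metadata
#'   columns are attached.
#' @export
sampleMeta <- function(x) {
  cd <- as.data.frame(colData(x))
  cbind(data.frame(sample_id = colnames(x), stringsAsFactors = FALSE),
        cd, row.names = NULL)
}

#' Read a VCF of biallelic SNPs into a SnpGenotypes object
#'
#' Only the GT field is used. Genotypes are mapped to alternate-allele
#' dosage: `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> `NA`
#' (phased separators are accepted). Multi-allelic records and non-diploid
#' GT values are rejected with an error naming the offending locus.
#'
#' @param path path to a VCF (v4.x) file, optionally gzipped.
#' @param sampleData optional per-sample metadata `data.frame` (as from
#'   [readSampleMeta()]) joined to the VCF samples by `sample_id`.
#' @return A [SnpGenotypes-class] object; scaffold = CHROM, position = POS
#'   (1-based), locus ids from the ID column (or `CHROM_POS` when ID is ".").
#' @export
readSnpVcf <- function(path, sampleData = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(chrom, "_", pos)[is.na(ids) | ids == "."]
  bad <- which(grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L)
  if (length(bad))
    stop("multi-allelic or non-SNP record(s) not supported: ",
         paste(ids[head(bad, 5)], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(ids, names(gt)))
  ok <- is.na(gt) | gt %in% c("0/0", "0|0", "0/1", "0|1",
                              "1/0", "1|0", "1/1", "1|1", "./.", ".|.")
  if (!all(ok)) {
    i <- which(!ok, arr.ind = TRUE)[1, 1]
    stop("non-diploid or unsupported GT at locus ", ids[i])
  }
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = list(ids, colnames(gt)))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "0|1", "1/0", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  gm <- SnpGenotypes(dos, scaffold = chrom, position = pos,
                     ref = ref, alt = alt)
  if (!is.null(sampleData)) gm <- attachSampleMeta(gm, sampleData)
  gm
}

#' Write a SnpGenotypes object to a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT so that
#' `readSnpVcf(writeSnpVcf(x, f))` round-trips calls, scaffolds, positions
#' and alleles exactly.
#'
#' @param x A [SnpGenotypes-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSnpVcf <- function(x, path) {
  li <- lociInfo(x)
  d <- dosageMatrix(x)
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d)] <- code[d[!is.na(d)] + 1L]
  body <- paste(li$scaffold, li$position, li$locus_id, li$ref, li$alt,
                ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(x)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample metadata CSV
#'
#' Expects a header with at least `sample_id`, `population`, `region`,
#' `role`; `role` must be one of wild, rearing, validation, test, control.
#'
#' @param path CSV file path.
#' @return data.frame of sample metadata.
#' @export
readSampleMeta <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "region", "role")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(m$role), .VALID_ROLES)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  m
}

#' Attach sample metadata to a SnpGenotypes object
#'
#' Joins by sample id. Genotyped samples absent from the metadata are
#' reported via a warning and retained with NA metadata; metadata rows with
#' no matching sample are dropped (also reported).
#'
#' @param x A [SnpGenotypes-class] object.
#' @param meta data.frame with a `sample_id` column.
#' @return `x` with populated `colData`.
#' @export
attachSampleMeta <- function(x, meta) {
  idx <- match(colnames(x), meta$sample_id)
  unmatched <- colnames(x)[is.na(idx)]
  if (length(unmatched))
    warning("samples without metadata: ", paste(unmatched, collapse = ", "))
  extra <- setdiff(meta$sample_id, colnames(x))
  if (length(extra))
    warning("metadata rows without genotypes (dropped): ",
            paste(extra, collapse = ", "))
  cols <- setdiff(names(meta), "sample_id")
  cd <- DataFrame(meta[idx, cols, drop = FALSE], row.names = colnames(x))
  colData(x)[cols] <- cd
  validObject(x)
  x
}

#' Minor allele frequency per locus
#'
#' MAF is computed over non-missing calls: `p_alt = sum(dosage) /
#' (2 * n_nonmissing)`, returned as `min(p_alt, 1 - p_alt)`. Loci with no
#' non-missing calls get `NA`.
#'
#' @param x A [SnpGenotypes-class] object.
#' @return named numeric vector of per-locus MAF.
#' @export
mafPerLocus <- function(x) {
  d <- dosageMatrix(x)
  n <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * n)
  p[n == 0] <- NA_real_
  pmin(p, 1 - p)
}

#' Per-locus and per-sample missingness
#'
#' @param x A [SnpGenotypes-class] object.
#' @return named numeric vector of missing-call fractions.
#' @export
locusMissingness <- function(x) rowMeans(is.na(dosageMatrix(x)))

#' @rdname locusMissingness
#' @export
sampleMissingness <- function(x) colMeans(is.na(dosageMatrix(x)))

#' Two-stage dataset-assembly filter
#'
#' Stage 1 drops individuals whose missing-call fraction (over all loci) is
#' strictly greater than `maxIndMissing`. Stage 2, on the remaining
#' individuals, drops loci whose missing fraction is strictly greater than
#' `maxLocusMissing` or whose minor allele frequency is strictly less than
#' `minMaf` (MAF over non-missing calls of retained individuals). Equality
#' always retains. The filter report is attached to the result's
#' `metadata()` under `"filterReport"`.
#'
#' @param x A [SnpGenotypes-class] object.
#' @param maxIndMissing,maxLocusMissing,minMaf thresholds in \[0, 1\].
#' @return Filtered [SnpGenotypes-class]; `metadata(.)$filterReport` lists
#'   counts dropped at each stage.
#' @export
filterGenotypes <- function(x, maxIndMissing = 0.5, maxLocusMissing = 0.2,
                            minMaf = 0.01) {
  stopifnot(maxIndMissing >= 0, maxIndMissing <= 1,
            maxLocusMissing >= 0, maxLocusMissing <= 1,
            minMaf >= 0, minMaf <= 1)
  indMiss <- sampleMissingness(x)
  keepInd <- indMiss <= maxIndMissing
  x1 <- x[, keepInd]
  if (ncol(x1) == 0)
    stop("no individuals left after the missingness filter")
  locMiss <- locusMissingness(x1)
  maf <- mafPerLocus(x1)
  keepLoc <- locMiss <= maxLocusMissing & !is.na(maf) & maf >= minMaf
  out <- x1[keepLoc, ]
  if (nrow(out) == 0)
    stop("no loci left after the locus filters")
  metadata(out)$filterReport <- list(
    individuals_in = ncol(x), individuals_dropped = sum(!keepInd),
    loci_in = nrow(x), loci_dropped_missing = sum(locMiss > maxLocusMissing),
    loci_dropped_maf = sum(locMiss <= maxLocusMissing &
                             (is.na(maf) | maf < minMaf)),
    loci_out = nrow(out), individuals_out = ncol(out),
    thresholds = c(maxIndMissing = maxIndMissing,
                   maxLocusMissing = maxLocusMissing, minMaf = minMaf))
  out
}
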