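#' Rank loci by per-locus F_ST
#'
#' Sorts loci by theta, descending; loci with undefined theta are excluded.
#' Ties break by (scaffold, position) lexicographic order so the ranking is
#' deterministic.
#'
#' @param locusFst data.frame from [wcFst()] (columns locus_id, theta).
#' @param loci per-locus annotation from [lociInfo()] (columns locus_id,
#'   scaffold, position) used for tie-breaking and carried into the output.
#' @return data.frame locus_id, scaffold, position, theta, rank.
#' @export
rankLoci <- function(locusFst, loci) {
  m <- merge(locusFst[, c("locus_id", "theta")], loci, by = "locus_id")
  m <- m[!is.na(m$theta), , drop = FALSE]
  if (nrow(m) == 0) stop("no locus has a defined theta")
  ord <- order(-m$theta, m$scaffold, m$position)
  m <- m[ord, c("locus_id", "scaffold", "position", "theta"), drop = FALSE]
  m$rank <- seq_len(nrow(m))
  rownames(m) <- NULL
  m
}

#' Select a diagnostic panel from ranked loci
#'
#' Greedy scan down the ranking, skipping any locus whose scaffold is
#' already represented (when `onePerScaffold`), until `panelSize` loci are
#' selected or the ranking is exhausted (a shortfall is a warning, not an
#' error).
#'
#' @param ranked output of [rankLoci()].
#' @param panelSize target number of panel loci (>= 1).
#' @param onePerScaffold logical, enforce at most one locus per scaffold.
#' @return data.frame of selected loci (locus_id, scaffold, position, theta,
#'   rank), in selection order.
#' @export
selectPanel <- function(ranked, panelSize, onePerScaffold = TRUE) {
  stopifnot(panelSize >= 1)
  take <- logical(nrow(ranked))
  seen <- character()
  for (i in seq_len(nrow(ranked))) {
    if (sum(take) == panelSize) break
    if (onePerScaffold && ranked$scaffold[i] %in% seen) next
    take[i] <- TRUE
    seen <- c(seen, ranked$scaffold[i])
  }
  if (sum(take) < panelSize)
    warning("only ", sum(take), " of ", panelSize,
            " requested loci could be selected")
  out <- ranked[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check that a panel reproduces the full-data population structure
#'
#' Fits DAPC with identical groups on the full dataset and on the panel
#' subset, then reports (1) the agreement rate of maximum-posterior
#' training assignments between the two fits, (2) the adjusted Rand index
#' between the two assignment partitions, and (3) pairwise multilocus F_ST
#' computed on the panel loci alongside the genomewide values (panel F_ST
#' is expected to be inflated when selection was by theta).
#'
#' @param x A [SnpGenotypes-class] object.
#' @param groups grouping as in [dapcFit()].
#' @param panel data.frame from [selectPanel()] (column locus_id).
#' @param nPcaFull,nPcaPanel PCs to retain for the full / panel fits.
#' @return list with `agreement`, `ari`, and `fst` (data.frame pair,
#'   fst_panel, fst_full).
#' @export
panelConcordance <- function(x, groups, panel, nPcaFull, nPcaPanel) {
  g <- .resolveGroups(x, groups)
  if (nrow(panel) < nlevels(g) - 1)
    warning("panel smaller than groups - 1; discriminant axes are limited")
  missing <- setdiff(panel$locus_id, rownames(x))
  if (length(missing))
    stop("panel loci absent from the dataset: ",
         paste(head(missing, 5), collapse = ", "))
  xPanel <- x[panel$locus_id, ]
  fitFull <- dapcFit(x, g, nPca = nPcaFull)
  fitPanel <- dapcFit(xPanel, g, nPca = min(nPcaPanel, nrow(xPanel)))
  predFull <- dapcPredict(fitFull, x)
  predPanel <- dapcPredict(fitPanel, xPanel)
  agree <- mean(predFull$assigned == predPanel$assigned)
  ari <- mclust::adjustedRandIndex(predFull$assigned, predPanel$assigned)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  fst <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    fst_panel = NA_real_, fst_full = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    sel <- g %in% pairs[, k]
    gk <- droplevels(g[sel])
    fst$fst_panel[k] <- multilocusFst(wcFst(xPanel[, sel], gk))
    fst$fst_full[k] <- multilocusFst(wcFst(x[, sel], gk))
  }
  list(agreement = agree, ari = ari, fst = fst)
}

#' Extract flanking sequences around panel SNPs for assay design
#'
#' For each locus, takes up to `flank` bases either side of the SNP from the
#' reference scaffold and marks the site in bracket notation `[ref/alt]`.
#' Flanks are truncated only at scaffold edges; the reference base at the
#' SNP position must equal the locus's recorded reference allele.
#'
#' @param fasta path to a reference FASTA, or a [Biostrings::DNAStringSet].
#' @param loci data.frame with locus_id, scaffold, position, ref, alt
#'   (as from [lociInfo()] subset to the panel).
#' @param flank bases to take on each side (default 100).
#' @return data.frame locus_id, scaffold, position, sequence (with the
#'   `[ref/alt]` site marker), left_flank_len, right_flank_len.
#' @export
extractFlanks <- function(fasta, loci, flank = 100) {
  ref <- if (methods::is(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  out <- loci[, c("locus_id", "scaffold", "position")]
  out$sequence <- NA_character_
  out$left_flank_len <- NA_integer_
  out$right_flank_len <- NA_integer_
  for (i in seq_len(nrow(loci))) {
    sc <- loci$scaffold[i]
    if (!sc %in% names(ref))
      stop("scaffold not found in FASTA: ", sc)
    seqlen <- Biostrings::width(ref[sc])
    pos <- loci$position[i]
    base <- as.character(Biostrings::subseq(ref[[sc]], pos, pos))
    if (base != loci$ref[i])
      stop("reference base mismatch at ", sc, ":", pos,
           " (FASTA has ", base, ", locus ", loci$locus_id[i],
           " expects ", loci$ref[i], ")")
    lo <- max(1L, pos - flank)
    hi <- min(seqlen, pos + flank)
    left <- if (pos > lo)
      as.character(Biostrings::subseq(ref[[sc]], lo, pos - 1L)) else ""
    right <- if (hi > pos)
      as.character(Biostrings::subseq(ref[[sc]], pos + 1L, hi)) else ""
    out$sequence[i] <- paste0(left, "[", loci$ref[i], "/", loci$alt[i], "]",
                              right)
    out$left_flank_len[i] <- nchar(left)
    out$right_flank_len[i] <- nchar(right)
  }
  rownames(out) <- NULL
  out
}

#' Write flank records as a FASTA with bracket-notation headers
#'
#' @param flanks data.frame from [extractFlanks()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeFlankFasta <- function(flanks, path) {
  lines <- as.vector(rbind(
    sprintf(">%s pos=%s:%d", flanks$locus_id, flanks$scaffold,
            flanks$position),
    flanks$sequence))
  writeLines(lines, path)
  invisible(path)
}
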