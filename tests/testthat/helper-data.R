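# Build a SnpGenotypes from a samples x loci dosage matrix with minimal
# locus annotation (one scaffold per locus unless given).
makeGm <- function(dosage, scaffold = NULL, position = NULL,
                   region = NULL) {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("loc%03d", seq_len(L))
  if (is.null(scaffold)) scaffold <- paste0("sc", seq_len(L))
  if (is.null(position)) position <- rep(100L, L)
  meta <- if (is.null(region)) NULL else
    data.frame(region = region, population = region, role = "wild")
  SnpGenotypes(t(dosage), scaffold = scaffold, position = position,
               ref = rep("A", L), alt = rep("G", L), sampleData = meta)
}

# Long-form replicate rows for one sample x assay.
repRows <- function(geno, conf, sample = "s1", assay = "a1") {
  data.frame(sample_id = sample, assay_id = assay,
             replicate = seq_along(geno),
             genotype = geno, confidence = conf, stringsAsFactors = FALSE)
}
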