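## Consensus genotype calling from triplicate assay data.
##
## Replicate calls come in long form: one row per
## (sample_id, assay_id, replicate) with genotype coded as alt-allele
## dosage 0/1/2 and NA for a failed reaction (no_call), plus a confidence
## in [0,1] for called replicates. Fewer than 3 recorded replicates are
## treated as no_calls for the absent slots.

.padReplicates <- function(geno, conf) {
  if (length(geno) > 3) stop("more than 3 replicates for one sample x assay")
  length(geno) <- 3L
  length(conf) <- 3L
  list(geno = geno, conf = conf)
}

.validationOne <- function(geno, conf, ref, highConf) {
  if (is.na(ref))
    return(c("not_assessable", "no_reference"))
  p <- .padReplicates(geno, conf)
  geno <- p$geno; conf <- p$conf
  called <- !is.na(geno)
  if (!any(called))
    return(c("failed_amplification", "no_calls"))
  nMatch <- sum(called & geno == ref)
  nContra <- sum(called & geno != ref)
  if (nMatch >= 2 && nContra == 0)
    return(c("validated", "match_no_contradiction"))
  if (nMatch == 2 && nContra == 1) {
    if (all(conf[called & geno == ref] > highConf))
      return(c("validated", "overruled_contradiction"))
    return(c("failed_validation", "contradiction_not_overruled"))
  }
  if (nMatch == 1 && nContra == 0)
    return(c("validated", "single_replicate"))
  if (nMatch == 1 && nContra >= 1)
    return(c("failed_validation", "single_match_with_contradiction"))
  c("failed_validation", "no_match")
}

.testOne <- function(geno, conf, sepFlag, highConf, midConf) {
  p <- .padReplicates(geno, conf)
  geno <- p$geno; conf <- p$conf
  called <- !is.na(geno)
  nCalled <- sum(called)
  if (nCalled == 0)
    return(list(genotype = NA_integer_, reason = "no_amplification",
                nUsed = 0L))
  if (length(unique(geno[called])) > 1)
    return(list(genotype = NA_integer_, reason = "conflict",
                nUsed = nCalled))
  gt <- geno[called][1]
  if (nCalled == 3)
    return(list(genotype = gt, reason = NA_character_, nUsed = 3L))
  cf <- conf[called]
  if (all(cf > highConf))
    return(list(genotype = gt, reason = NA_character_, nUsed = nCalled))
  if (isTRUE(sepFlag) && all(cf > midConf & cf <= highConf))
    return(list(genotype = gt, reason = NA_character_, nUsed = nCalled))
  list(genotype = NA_integer_, reason = "low_confidence", nUsed = nCalled)
}

#' Validation-mode consensus calling against reference genotypes
#'
#' Applies the triplicate validation rules per (sample, assay): all
#' replicates failing to call is a `failed_amplification`; at least two
#' replicates matching the reference genotype with no contradicting call is
#' `validated`; two matching calls overrule one contradiction only when
#' both matching calls have confidence strictly above `highConf`; a single
#' matching call validates when the other replicates produced no call.
#' One match alongside a contradicting call is conservatively a
#' `failed_validation` (detail `single_match_with_contradiction`).
#' Pairs whose reference genotype is missing are `not_assessable`.
#'
#' @param calls data.frame with columns sample_id, assay_id, replicate,
#'   genotype (0/1/2 dosage, NA = no call), confidence (in \[0,1\]).
#' @param refGenotypes data.frame with sample_id, assay_id, genotype: the
#'   reference (e.g. sequencing-derived) genotypes; missing pairs or NA
#'   genotypes are treated as unknown.
#' @param highConf confidence threshold for overruling (strict `>`).
#' @return data.frame sample_id, assay_id, reference_genotype, outcome
#'   (validated / failed_amplification / failed_validation /
#'   not_assessable), detail.
#' @export
callValidation <- function(calls, refGenotypes, highConf = 0.95) {
  key <- paste(calls$sample_id, calls$assay_id, sep = "\r")
  refKey <- paste(refGenotypes$sample_id, refGenotypes$assay_id, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  out <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    ref <- refGenotypes$genotype[match(k, refKey)]
    v <- .validationOne(calls$genotype[idx], calls$confidence[idx],
                        ref, highConf)
    data.frame(sample_id = calls$sample_id[idx[1]],
               assay_id = calls$assay_id[idx[1]],
               reference_genotype = ref,
               outcome = v[1], detail = v[2], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test-mode consensus calling for specimens of unknown genotype
#'
#' All three replicates calling the same genotype yields that genotype; any
#' disagreement among called replicates is missing data (`conflict`); all
#' replicates failing is missing (`no_amplification`). One or two agreeing
#' calls with the remainder failing yield a genotype only if every call's
#' confidence is strictly above `highConf`, or if the assay's cluster
#' separation flag is set and every call's confidence lies in
#' `(midConf, highConf]`; otherwise missing (`low_confidence`).
#'
#' @inheritParams callValidation
#' @param assayFlags data.frame with assay_id and logical separation_flag
#'   (operator-judged "very distinct" cluster separation); assays absent
#'   from the table default to `FALSE`.
#' @param highConf,midConf confidence thresholds (strict `>` comparisons;
#'   the mid band is `(midConf, highConf]`).
#' @return data.frame sample_id, assay_id, genotype (NA when missing),
#'   missing_reason (conflict / no_amplification / low_confidence),
#'   n_replicates_used.
#' @export
callTest <- function(calls, assayFlags = NULL, highConf = 0.95,
                     midConf = 0.80) {
  flagOf <- function(assay) {
    if (is.null(assayFlags)) return(FALSE)
    i <- match(assay, assayFlags$assay_id)
    if (is.na(i)) FALSE else isTRUE(assayFlags$separation_flag[i])
  }
  key <- paste(calls$sample_id, calls$assay_id, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  out <- lapply(groups, function(idx) {
    assay <- calls$assay_id[idx[1]]
    v <- .testOne(calls$genotype[idx], calls$confidence[idx],
                  flagOf(assay), highConf, midConf)
    data.frame(sample_id = calls$sample_id[idx[1]], assay_id = assay,
               genotype = v$genotype, missing_reason = v$reason,
               n_replicates_used = v$nUsed, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize validation outcomes per assay and overall
#'
#' @param outcomes data.frame from [callValidation()].
#' @param excludeAssays character vector of assay ids dropped from all
#'   summaries (e.g. assays that consistently failed).
#' @return list with `perAssay` (assay_id, total, validated,
#'   failed_amplification, failed_validation, validation_rate,
#'   genotyping_success, adjusted_rate) and `overall` (the same totals and
#'   rates pooled, plus mean/min/max of the per-assay rates). Rates are
#'   fractions; `adjusted_rate` excludes failed amplifications from the
#'   denominator. Pairs that were `not_assessable` are ignored.
#' @export
summarizeValidation <- function(outcomes, excludeAssays = character()) {
  o <- outcomes[!(outcomes$assay_id %in% excludeAssays) &
                  outcomes$outcome != "not_assessable", , drop = FALSE]
  per <- do.call(rbind, lapply(split(o, o$assay_id), function(d) {
    tot <- nrow(d)
    val <- sum(d$outcome == "validated")
    fa <- sum(d$outcome == "failed_amplification")
    fv <- sum(d$outcome == "failed_validation")
    data.frame(assay_id = d$assay_id[1], total = tot, validated = val,
               failed_amplification = fa, failed_validation = fv,
               validation_rate = val / tot,
               genotyping_success = (tot - fa) / tot,
               adjusted_rate = if (tot > fa) val / (tot - fa) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  tot <- sum(per$total); val <- sum(per$validated)
  fa <- sum(per$failed_amplification); fv <- sum(per$failed_validation)
  overall <- list(
    total = tot, validated = val, failed_amplification = fa,
    failed_validation = fv,
    validation_rate = val / tot,
    adjusted_rate = if (tot > fa) val / (tot - fa) else NA_real_,
    mean_genotyping_success = mean(per$genotyping_success),
    min_genotyping_success = min(per$genotyping_success),
    max_genotyping_success = max(per$genotyping_success),
    mean_validation_rate = mean(per$validation_rate),
    min_validation_rate = min(per$validation_rate),
    max_validation_rate = max(per$validation_rate))
  list(perAssay = per, overall = overall)
}

#' Summarize test-mode consensus calls per assay and overall
#'
#' @param calls data.frame from [callTest()].
#' @param excludeAssays assay ids dropped from all summaries.
#' @return list with `perAssay` (successful, missing by reason, call_rate,
#'   n_sub3 = successful calls made from fewer than 3 replicates) and
#'   `overall` (pooled counts and call rate).
#' @export
summarizeTest <- function(calls, excludeAssays = character()) {
  cc <- calls[!(calls$assay_id %in% excludeAssays), , drop = FALSE]
  per <- do.call(rbind, lapply(split(cc, cc$assay_id), function(d) {
    succ <- sum(!is.na(d$genotype))
    data.frame(assay_id = d$assay_id[1], total = nrow(d),
               successful = succ,
               missing_conflict = sum(!is.na(d$missing_reason) &
                                        d$missing_reason == "conflict"),
               missing_no_amplification =
                 sum(!is.na(d$missing_reason) &
                       d$missing_reason == "no_amplification"),
               missing_low_confidence =
                 sum(!is.na(d$missing_reason) &
                       d$missing_reason == "low_confidence"),
               call_rate = succ / nrow(d),
               n_sub3 = sum(!is.na(d$genotype) & d$n_replicates_used < 3),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  overall <- list(
    total = sum(per$total), successful = sum(per$successful),
    missing_conflict = sum(per$missing_conflict),
    missing_no_amplification = sum(per$missing_no_amplification),
    missing_low_confidence = sum(per$missing_low_confidence),
    call_rate = sum(per$successful) / sum(per$total),
    n_sub3 = sum(per$n_sub3))
  list(perAssay = per, overall = overall)
}

#' Check positive-control and no-template-control reactions
#'
#' Positive controls are scored by the fraction of reactions that failed to
#' call and the fraction of called reactions matching the control's
#' expected genotype (0 for a reference-allele control, 1 heterozygote,
#' 2 alternate). NTC samples must produce no calls: any call is reported
#' as contamination.
#'
#' @param calls replicate-level data.frame (sample_id, assay_id, replicate,
#'   genotype, confidence).
#' @param controls data.frame with sample_id and type in
#'   \{reference, alternate, heterozygote, ntc\}.
#' @return data.frame sample_id, type, n_reactions, n_failed, failure_rate,
#'   n_matching, match_rate, contamination (NTC only).
#' @export
controlCheck <- function(calls, controls) {
  expOf <- c(reference = 0L, heterozygote = 1L, alternate = 2L)
  out <- lapply(seq_len(nrow(controls)), function(i) {
    sid <- controls$sample_id[i]; type <- controls$type[i]
    d <- calls[calls$sample_id == sid, , drop = FALSE]
    nFail <- sum(is.na(d$genotype))
    called <- d$genotype[!is.na(d$genotype)]
    if (type == "ntc") {
      data.frame(sample_id = sid, type = type, n_reactions = nrow(d),
                 n_failed = nFail, failure_rate = NA_real_,
                 n_matching = NA_integer_, match_rate = NA_real_,
                 contamination = length(called) > 0,
                 stringsAsFactors = FALSE)
    } else {
      exp <- expOf[[type]]
      data.frame(sample_id = sid, type = type, n_reactions = nrow(d),
                 n_failed = nFail, failure_rate = nFail / nrow(d),
                 n_matching = sum(called == exp),
                 match_rate = if (length(called)) mean(called == exp)
                 else NA_real_,
                 contamination = FALSE, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a replicate-call CSV
#'
#' Expects columns sample_id, assay_id, replicate, genotype, confidence with
#' genotype in \{0, 1, 2, NC\} (NC = no call).
#'
#' @param path CSV file path.
#' @return data.frame with genotype as integer dosage (NA for NC).
#' @export
readReplicateCalls <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(genotype = "character"))
  need <- c("sample_id", "assay_id", "replicate", "genotype", "confidence")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("replicate-call file is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(d$genotype), c("0", "1", "2", "NC", NA))
  if (length(bad))
    stop("unsupported genotype code(s): ", paste(bad, collapse = ", "))
  g <- d$genotype
  g[!is.na(g) & g == "NC"] <- NA_character_
  d$genotype <- as.integer(g)
  d
}

#' Expand a per-assay QC count table into row-level records
#'
#' Utility for count-level QC tables (one row per assay with counts of
#' validated genotypes, failed amplifications, high- and low-confidence
#' miscalls, and per-assay test-specimen outcomes). Returns synthetic
#' per-genotype rows suitable for [summarizeValidation()] and
#' [summarizeTest()], so that the printed aggregate rates can be recomputed
#' from counts alone.
#'
#' @param counts data.frame with columns assay_id, validated, val_total,
#'   fail, miscall_high, miscall_low, test_genotyped, test_total, conflict,
#'   miss, geno_lt3.
#' @return list with `validation` (outcome rows) and `test` (call rows).
#' @export
expandQcCounts <- function(counts) {
  rep1 <- function(assay, outcome, n) {
    if (n == 0) return(NULL)
    data.frame(sample_id = paste0(assay, "_v", seq_len(n)),
               assay_id = assay, reference_genotype = 0L,
               outcome = outcome, detail = "from_counts",
               stringsAsFactors = FALSE)
  }
  val <- do.call(rbind, unlist(lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$assay_id[i]
    list(rep1(a, "validated", counts$validated[i]),
         rep1(a, "failed_amplification", counts$fail[i]),
         rep1(a, "failed_validation",
              counts$miscall_high[i] + counts$miscall_low[i]))
  }), recursive = FALSE))
  rownames(val) <- NULL
  rep2 <- function(assay, genotype, reason, nUsed, n) {
    if (n == 0) return(NULL)
    data.frame(sample_id = paste0(assay, "_t", seq_len(n)),
               assay_id = assay, genotype = genotype,
               missing_reason = reason, n_replicates_used = nUsed,
               stringsAsFactors = FALSE)
  }
  test <- do.call(rbind, unlist(lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$assay_id[i]
    nFull <- counts$test_genotyped[i] - counts$geno_lt3[i]
    list(rep2(a, 0L, NA_character_, 3L, nFull),
         rep2(a, 0L, NA_character_, 2L, counts$geno_lt3[i]),
         rep2(a, NA_integer_, "conflict", 3L, counts$conflict[i]),
         rep2(a, NA_integer_, "no_amplification", 0L, counts$miss[i]))
  }), recursive = FALSE))
  rownames(test) <- NULL
  list(validation = val, test = test)
}
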