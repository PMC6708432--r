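# Genotypes are alt-allele dosages: 0 = hom ref, 1 = het, 2 = hom alt;
# NA = no call. Reference genotypes come from the sequencing dataset.

refOf <- function(g) data.frame(sample_id = "s1", assay_id = "a1",
                                genotype = g)

test_that("validation mode follows the triplicate decision table", {
  # two high-confidence matches overrule one contradiction
  v <- callValidation(repRows(c(0L, 0L, 1L), c(0.99, 0.97, 0.90)), refOf(0L))
  expect_equal(v$outcome, "validated")
  expect_equal(v$detail, "overruled_contradiction")
  # ... but not when a matching call lacks high confidence
  v2 <- callValidation(repRows(c(0L, 0L, 1L), c(0.99, 0.94, 0.90)), refOf(0L))
  expect_equal(v2$outcome, "failed_validation")
  # a single call validates when the other replicates failed
  v3 <- callValidation(repRows(c(0L, NA, NA), c(0.99, NA, NA)), refOf(0L))
  expect_equal(v3$outcome, "validated")
  expect_equal(v3$detail, "single_replicate")
  # consistent wrong genotype: failed validation
  v4 <- callValidation(repRows(c(1L, 1L, 1L), c(0.99, 0.98, 0.99)), refOf(0L))
  expect_equal(v4$outcome, "failed_validation")
  # no calls at all: failed amplification
  v5 <- callValidation(repRows(rep(NA_integer_, 3), rep(NA_real_, 3)),
                       refOf(0L))
  expect_equal(v5$outcome, "failed_amplification")
  # two matches, no contradiction (third failed): validated
  v6 <- callValidation(repRows(c(0L, 0L, NA), c(0.90, 0.85, NA)), refOf(0L))
  expect_equal(v6$outcome, "validated")
  # one match plus one contradiction: conservative failure, own detail code
  v7 <- callValidation(repRows(c(0L, 2L, NA), c(0.99, 0.99, NA)), refOf(0L))
  expect_equal(v7$outcome, "failed_validation")
  expect_equal(v7$detail, "single_match_with_contradiction")
  # unknown reference: not assessable
  v8 <- callValidation(repRows(c(0L, 0L, 0L), c(0.99, 0.99, 0.99)),
                       refOf(NA_integer_))
  expect_equal(v8$outcome, "not_assessable")
})

test_that("test mode calls unanimity, codes conflicts as missing, and gates partial calls", {
  flags <- data.frame(assay_id = "a1", separation_flag = FALSE)
  flagsOn <- data.frame(assay_id = "a1", separation_flag = TRUE)

  t1 <- callTest(repRows(c(0L, 0L, 0L), c(0.99, 0.98, 0.97)), flags)
  expect_equal(t1$genotype, 0L)
  expect_equal(t1$n_replicates_used, 3L)

  t2 <- callTest(repRows(c(0L, 0L, 1L), c(0.99, 0.98, 0.97)), flags)
  expect_true(is.na(t2$genotype))
  expect_equal(t2$missing_reason, "conflict")

  t3 <- callTest(repRows(rep(NA_integer_, 3), rep(NA_real_, 3)), flags)
  expect_equal(t3$missing_reason, "no_amplification")

  # single high-confidence call is accepted
  t4 <- callTest(repRows(c(0L, NA, NA), c(0.97, NA, NA)), flags)
  expect_equal(t4$genotype, 0L)
  expect_equal(t4$n_replicates_used, 1L)

  # mid-confidence call needs the separation flag
  t5 <- callTest(repRows(c(0L, NA, NA), c(0.85, NA, NA)), flags)
  expect_equal(t5$missing_reason, "low_confidence")
  t6 <- callTest(repRows(c(0L, NA, NA), c(0.85, NA, NA)), flagsOn)
  expect_equal(t6$genotype, 0L)

  # below the mid band nothing rescues the call
  t7 <- callTest(repRows(c(0L, NA, NA), c(0.75, NA, NA)), flagsOn)
  expect_equal(t7$missing_reason, "low_confidence")

  # two agreeing calls with one failure: both must pass the gate
  t8 <- callTest(repRows(c(2L, 2L, NA), c(0.99, 0.97, NA)), flags)
  expect_equal(t8$genotype, 2L)
  expect_equal(t8$n_replicates_used, 2L)
  t9 <- callTest(repRows(c(2L, 2L, NA), c(0.99, 0.85, NA)), flags)
  expect_equal(t9$missing_reason, "low_confidence")
})

test_that("more than three replicates is an input error", {
  expect_error(callTest(repRows(c(0L, 0L, 0L, 0L), rep(0.99, 4))),
               "more than 3")
  expect_error(callValidation(repRows(c(0L, 0L, 0L, 0L), rep(0.99, 4)),
                              refOf(0L)), "more than 3")
})

test_that("calling is invariant to replicate order", {
  set.seed(33)
  for (i in 1:50) {
    g <- sample(c(0:2, NA), 3, replace = TRUE)
    cf <- ifelse(is.na(g), NA, runif(3, 0.6, 1))
    perm <- sample(3)
    a <- callTest(repRows(g, cf))
    b <- callTest(repRows(g[perm], cf[perm]))
    expect_identical(a$genotype, b$genotype)
    expect_identical(a$missing_reason, b$missing_reason)
    va <- callValidation(repRows(g, cf), refOf(1L))
    vb <- callValidation(repRows(g[perm], cf[perm]), refOf(1L))
    expect_identical(va$outcome, vb$outcome)
  }
})

test_that("summaries on an all-successful toy give unit rates", {
  out <- data.frame(sample_id = paste0("s", 1:6),
                    assay_id = rep(c("a1", "a2"), each = 3),
                    reference_genotype = 0L,
                    outcome = "validated", detail = "x")
  sv <- summarizeValidation(out)
  expect_equal(sv$overall$validation_rate, 1)
  expect_equal(sv$overall$mean_genotyping_success, 1)
  calls <- data.frame(sample_id = paste0("s", 1:6),
                      assay_id = rep(c("a1", "a2"), each = 3),
                      genotype = 1L, missing_reason = NA_character_,
                      n_replicates_used = 3L)
  st <- summarizeTest(calls)
  expect_equal(st$overall$call_rate, 1)
  expect_equal(st$overall$n_sub3, 0)
})

test_that("excluded assays drop out of every summary", {
  out <- rbind(
    data.frame(sample_id = "s1", assay_id = "good",
               reference_genotype = 0L, outcome = "validated", detail = "x"),
    data.frame(sample_id = "s1", assay_id = "bad",
               reference_genotype = 0L, outcome = "failed_validation",
               detail = "x"))
  sv <- summarizeValidation(out, excludeAssays = "bad")
  expect_equal(sv$overall$total, 1)
  expect_equal(sv$overall$validation_rate, 1)
  expect_false("bad" %in% sv$perAssay$assay_id)
})

test_that("positive controls and NTCs are scored correctly", {
  calls <- rbind(repRows(c(0L, 0L, 0L), c(0.99, 0.99, 0.99),
                         sample = "posref"),
                 repRows(c(2L, NA, 2L), c(0.99, NA, 0.97),
                         sample = "posalt"),
                 repRows(c(NA, NA, 0L), c(NA, NA, 0.99), sample = "ntc1"),
                 repRows(rep(NA_integer_, 3), rep(NA_real_, 3),
                         sample = "ntc2"))
  controls <- data.frame(sample_id = c("posref", "posalt", "ntc1", "ntc2"),
                         type = c("reference", "alternate", "ntc", "ntc"))
  rep <- controlCheck(calls, controls)
  expect_equal(rep$failure_rate[rep$sample_id == "posref"], 0)
  expect_equal(rep$match_rate[rep$sample_id == "posref"], 1)
  expect_equal(rep$failure_rate[rep$sample_id == "posalt"], 1 / 3)
  expect_true(rep$contamination[rep$sample_id == "ntc1"])
  expect_false(rep$contamination[rep$sample_id == "ntc2"])
})

test_that("replicate-call CSVs parse genotype codes and reject unknowns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,assay_id,replicate,genotype,confidence",
               "s1,a1,1,0,0.99", "s1,a1,2,NC,", "s1,a1,3,2,0.85"), tmp)
  d <- readReplicateCalls(tmp)
  expect_identical(d$genotype, c(0L, NA, 2L))
  writeLines(c("sample_id,assay_id,replicate,genotype,confidence",
               "s1,a1,1,AB,0.99"), tmp)
  expect_error(readReplicateCalls(tmp), "AB")
})

test_that("heterozygote-as-homozygote validation failures rise with dropout", {
  rates <- vapply(c(0.05, 0.2, 0.5), function(delta) {
    gm <- simulateSnpDataset(nPops = 1, samplesPerPop = 25, nLoci = 60,
                             Fst = 0, missingRate = 0, seed = 35)
    sim <- simulateReplicates(gm, assayErrorModel(dropout = delta,
                                                  failure = 0.05),
                              seed = 36)
    truth <- sim$truth
    ref <- data.frame(sample_id = rep(rownames(truth), ncol(truth)),
                      assay_id = rep(colnames(truth), each = nrow(truth)),
                      genotype = as.vector(truth))
    v <- callValidation(sim$calls, ref)
    het <- ref$genotype[match(paste(v$sample_id, v$assay_id),
                              paste(ref$sample_id, ref$assay_id))] == 1
    mean(v$outcome[het] == "failed_validation")
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})
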