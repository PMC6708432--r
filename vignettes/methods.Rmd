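---
title: "Methods: population assignment from diagnostic SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population assignment from diagnostic SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpAssign)
```

# The problem

Recurrently invading pests — tephritid fruit flies being the canonical
case — are intercepted one specimen at a time in surveillance trapping
networks. Attribution of an intercepted specimen to a source population
("pathway analysis" in the regulatory sense) needs three ingredients: a
range-wide reference collection genotyped at many loci, a statistical
assignment engine, and a small, cheap, robust genotyping panel that can
be run on degraded trap-collected DNA. `snpAssign` implements that chain
on biallelic SNP dosage data and ships a generative model of such data so
every stage can be validated against known truth.

# Data model and filters

Genotypes are stored as alt-allele dosages 0/1/2 with an explicit `NA`
missing sentinel; every statistic skips missing cells rather than
zero-filling. Coordinates are VCF-style 1-based. Only biallelic SNPs are
supported: multi-allelic or indel records are rejected at import, not
split.

The dataset-assembly filter is two-stage with a fixed order: individuals
with missing fraction strictly greater than 0.5 are dropped first, then
— on the retained individuals — loci with missing fraction strictly
greater than 0.2 or minor allele frequency strictly below 0.01. Equality
retains in every comparison; this boundary convention follows the usual
phrasing of such filters (">50%", "<1%") literally. The filter is
idempotent, and both thresholds are arguments with these defaults.

# Diversity statistics

Per group, `observedHet` is the mean over usable loci of the heterozygote
fraction. `expectedHet` uses the Nei–Chesser small-sample corrected gene
diversity per locus,

$$H_S = \frac{n}{n-1}\left(1 - \hat p^2 - \hat q^2 - \frac{H_O}{2n}\right),$$

with $n$ the non-missing individuals at the locus, chosen to emulate the
statistic reported by GenoDive-style software. `geneDiversity` computes
$1 - \hat Q_{inter}$ exactly from genotype pairs: for dosages
$(g_i, g_j)$ the allele-match probability is
$[g_i g_j + (2-g_i)(2-g_j)]/4$, averaged over ordered pairs of distinct
individuals. These two estimators are algebraically identical for a
biallelic locus (a useful cross-check the test suite exploits via a
brute-force pair-enumeration oracle); they are computed by independent
routes in the package. $G_{IS} = 1 - H_O/H_E$ uses the multi-locus
averages, is negative under heterozygote excess, and is undefined when
$H_E = 0$. Each group's average runs over the loci usable *in that
group*, so the usable-locus set may differ between groups.

# Weir–Cockerham F_ST

Per locus, the 1984 method-of-moments variance components are computed
across $r \ge 2$ groups from per-group sample sizes, alt-allele
frequencies and heterozygote fractions ($\bar n$, $n_c$, $\bar p$, $s^2$,
$\bar h$ as defined by that method):

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]$$
$$b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right], \qquad c = \bar h / 2$$

and $\theta = a/(a+b+c)$. Loci with $a+b+c = 0$ (e.g. monomorphic
everywhere) or with a group lacking any non-missing call are *undefined*,
not zero; negative estimates are reported as computed. The multilocus
estimate is the ratio of sums $\sum a / \sum(a+b+c)$ over defined loci.

Pairwise differentiation is this multilocus statistic on each pair of
groups, with a null distribution from permuting individuals between the
two groups (sizes preserved). For biallelic SNP genotypes this
variance-component statistic is what the AMOVA-based pairwise F_ST of
GenoDive-type software reduces to; it is an emulation of that procedure,
not a bit-level clone, and permutation is at the individual level (the
standard choice for genotypic data — whether the original software
permutes individuals or genes is not documented). The p-value uses the
+1/+1 estimator $p = (1 + \#\{\theta^* \ge \theta\})/(1 + n_{perm})$ so
it can never be zero, with its floor $1/(n_{perm}+1)$; significance
applies a Bonferroni threshold $\alpha/m$ over the $m$ pairs. Default
$n_{perm} = 10{,}000$, $\alpha = 0.05$.

# DAPC

`dapcFit` imputes missing dosages with per-locus training means, centers
(scaling to unit variance is off by default and available by flag — the
conventional choice for dosage data, where centering alone preserves the
allele-frequency signal), retains `nPca` principal components via SVD,
and solves the discriminant eigenproblem of between-group versus pooled
within-group covariance (denominators $r-1$ and $n-r$) by symmetric
whitening. Axes are normalized so the pooled within-group covariance in
discriminant space is the identity, which makes Euclidean distance the
natural metric there. If the within-group covariance is numerically
singular it is shrunk toward its diagonal with ridge constant $10^{-6}$
times the mean diagonal, with a warning.

Two numerical conventions remove indeterminacy: discriminant axes are
sign-fixed by making the largest-magnitude locus loading positive (tests
still compare up to sign), and cross-validation ties break toward fewer
PCs. The fitted model stores centering, scaling, PC loadings,
discriminant coefficients and group centroids — everything needed to
project *supplemental* individuals: their dosages are transformed with
the training centering/scaling (missing cells and absent loci imputed at
training means) and pushed through the stored linear maps. Assignment
posteriors are $\mathrm{softmax}(-d_k^2/2)$ over squared distances to
centroids — equal priors and spherical unit covariance in discriminant
space. This emulates the membership probabilities of the reference DAPC
implementation; exact numerical parity with it is not claimed. An
individual equidistant between two centroids therefore splits its
posterior ~0.5/0.5, the behaviour expected for genetically
indistinguishable candidate sources.

`findClusters` runs K-means (with restarts) on PC scores and scores each
K with $BIC(K) = n\ln(WSS_K/n) + K\ln n$; this formula is stated
explicitly because K-means BIC variants differ. The minimum selects K,
and the whole curve is returned since flat minima are common in weakly
structured data. `dapcXval` does stratified 90/10 splits, default 30
replicates, over a grid of candidate `nPca` up to 200, minimizing the
RMSE of hold-out misassignment — the retained `nPca` is a reported
output, not a constant, since weakly differentiated datasets overfit
visibly at large `nPca`.

# Panel selection

Candidate loci are ranked by per-locus $\theta$ descending, undefined
values excluded, with deterministic (scaffold, position) tie-breaks —
a reproducible stand-in for what is in practice a manual curation step.
`selectPanel` scans the ranking greedily, skipping scaffolds already
represented; for this objective (maximize each selected locus's $\theta$
subject to one-per-scaffold) the greedy scan is exactly optimal, which
the tests verify against exhaustive search. Real panel design also
involves vendor design feasibility and bench performance; that is modeled
as an external mask over candidates (an input, never computed).
`panelConcordance` quantifies what was historically a visual check: the
agreement rate and adjusted Rand index between maximum-posterior
assignments of full-data and panel-only DAPC fits, plus pairwise F_ST on
panel loci (inflated by construction when selection is by $\theta$ —
ascertainment bias that panel users must keep in mind).
`extractFlanks` emits `[ref/alt]`-marked ±100 bp windows, truncated only
at scaffold edges, and errors if the FASTA base disagrees with the
recorded reference allele.

# Replicate consensus calling

Two decision tables, both total over every pattern of up to three
replicates (the tests enumerate all $4^3$ genotype patterns × confidence
strata × separation flag):

*Validation mode* (reference genotype known): all-no-call →
`failed_amplification`; ≥2 matches and no contradiction → `validated`;
2 matches + 1 contradiction → `validated` only if both matches have
confidence > 0.95; exactly 1 match with the others failing →
`validated`; everything else → `failed_validation`. The pattern "1 match
+ 1 contradiction + 1 no-call" is not covered by the narrative rules this
table formalizes; it is resolved conservatively as `failed_validation`
with its own detail code (`single_match_with_contradiction`) so it can be
re-tallied under a different convention.

*Test mode* (genotype unknown): any disagreement among called replicates
→ missing (`conflict`); all failed → missing (`no_amplification`); 3
agreeing calls → genotype; 1–2 agreeing calls with the rest failed →
genotype if every call's confidence > 0.95, or if the assay's separation
flag is set and every call lies in (0.80, 0.95]; otherwise missing
(`low_confidence`). With two agreeing partial calls, both must pass the
gate (distinct detail path). The thresholds 0.95/0.80 are configurable
defaults; comparisons are strict and the mid band is half-open. "Very
distinct cluster separation" is irreducibly qualitative and is a
per-assay boolean input, never computed. Excluded-assay lists for the
summaries are likewise explicit inputs, never auto-detected.

Summaries report per-assay and pooled counts and rates (validation rate,
amplification-adjusted rate, genotyping success, test call rate, calls
made from <3 replicates), with conservation identities
(validated + failed amplification + failed validation = assessable
total; successful + missing-by-reason = sample×assay grid) enforced by
tests. The package ships a per-assay QC count table
(`inst/extdata/assay_qc_counts.csv`, 32 assays, 4 flagged for exclusion)
whose pooled and per-assay rates the acceptance checks recompute through
these summaries.

# The synthetic-data generator

`simulateSnpDataset` draws, per locus, an ancestral frequency
$p \sim U(0.1, 0.9)$ and per-population frequencies from the
Balding–Nichols distribution
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, so the expected
differentiation is approximately the parameter $F$; $F = 0$ degenerates
to exact panmixia. Individuals draw two gene copies, each choosing its
source population from per-individual Dirichlet admixture proportions
(degenerate at the labelled population by default). Defaults — 4
populations × 50 individuals, 2,000 loci, $F$ in the low-to-moderate
0.02–0.10 band, 5% missing data, 500 scaffolds — mirror the shape of a
range-wide insect ddRAD dataset with four regional clusters. The
frequency range (0.1, 0.9) reflects a post-MAF-filter SNP panel; the
scaffold count keeps the one-per-scaffold constraint genuinely active
(≈4 loci per scaffold).

`simulateReplicates` overlays the assay error model: per replicate,
amplification failure with probability `failure` (default 0.1), then
heterozygote dropout to a random homozygote with probability `dropout`
(default 0.05), with confidences from Beta(200, 6) for clean calls
(mean ≈ 0.97) and Beta(8, 2) for dropout-affected calls — the diffuse
component exists precisely to exercise the 0.80/0.95 gates.

What the generator deliberately does *not* emulate: missingness is MCAR,
whereas real ddRAD missingness is structured by depth and batch; there is
no linkage (appropriate for one-SNP-per-locus data), no selection, no
demographic history, and no spatially continuous intergradation — the
admixture knob only coarsely imitates clinal mixture. Passing tests
therefore demonstrate correctness of the estimators and decision rules
under the stated generative model, not robustness to every pathology of
real data.

# Validation strategy and problem sizes

Every estimator is checked against an independent oracle: per-locus
$\theta$ against a scalar transcription of the 1984 equations, gene
diversity against brute-force pair enumeration, DAPC coordinates against
a dense PCA+LDA transcription (agreement to 1e-8 up to axis sign), panel
selection against exhaustive search, and the calling tables against
exhaustive pattern enumeration. Recovery checks use 4 populations × 50
individuals × 2,000 loci with 10 seeds per $F \in \{0.02, 0.05, 0.10\}$
(multilocus $\hat\theta$ within ±0.02 of $F$); the end-to-end panel
check holds out 20% of individuals, selects 28 top-$\theta$ loci one per
scaffold, and requires ≥85% correct supplemental assignment and strict
superiority over a random 28-locus panel; permutation calibration uses
100 label-shuffled panmictic replicates at 1,000 permutations each
(fraction of $p \le 0.05$ bounded by 0.08). These sizes were chosen to
make the statistical properties sharp while keeping the full suite in
the low minutes on a single core.

# Known limitations

- Posteriors are assignment probabilities under equal priors, not
  admixture fractions; intergraded individuals split posteriors rather
  than revealing mixed ancestry.
- The permutation F_ST is an emulation of AMOVA-based pairwise F_ST, and
  the DAPC posterior an emulation of the reference implementation's
  membership probabilities; neither claims bit-level parity with any
  external program.
- Panel F_ST is ascertainment-inflated by construction; genomewide and
  panel estimates must not be compared as if exchangeable.
- Validation "success" rates are bounded by the accuracy of the
  sequencing-derived reference genotypes themselves, which the model
  treats as truth.
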