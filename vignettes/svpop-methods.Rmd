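---
title: "Models and methods behind svpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`svpop` implements the statistical chain of a population-scale
structural-variant (SV) study in a species with a recent whole-genome
duplication: reliability filtering of short-read SV calls, empirical
false-discovery accounting from visual curation, amplicon-based genotype
validation, a permutation test for farmed–wild differentiation, and
enrichment analyses connecting SVs to duplicated (ohnolog) genes and to
functional context. This vignette explains each model, its assumptions,
the tunable parameters, and the design decisions taken where the problem
left genuine choices. Everything asserted here is checked by the test
suite or recomputed by `scripts/acceptance.R`; the vignette states no
empirical result beyond what that code computes.

## Coordinates and data model

All intervals are 0-based half-open internally (`[start, end)`); the only
conversions happen at the file edges — VCF `POS`/`END` are 1-based (a
record with `POS = 101, END = 200` becomes `start = 100, end = 200`, size
100), BED is already 0-based half-open. Abutting intervals share no base:
`[100, 200)` does not overlap `[200, 300)`, but merging coalesces them
into `[100, 300)` because no uncovered base separates them. Genotypes are
bi-allelic (`0/0`, `0/1`, `1/1`, missing); dosage recoding maps them to
0/1/2, imputing missing values with the per-SV mean dosage by default
(required by PCA) or leaving `NA` for pairwise-complete analyses.

## Reliability filtering

Collapsed duplications — common after delayed rediploidization — attract
mismapped reads, producing both excess coverage and spurious SV calls.
A window is a *complex region* when at least `sample_threshold` (default
100) individuals show mean depth at or above `depth_threshold` (default
100×) in it; flagged windows within `merge_gap` (default 100 bp,
inclusive: a gap of exactly 100 merges) are merged. The window size is a
free parameter (default 1000 bp): the depth thresholds are properties of
the cohort, window granularity is a resolution/cost trade-off. SV calls
sharing ≥ 1 bp with an excluded region are removed; no minimum overlap
fraction is required, because a call whose breakpoint evidence touches a
complex region at all is suspect.

Redundant calls of the *same* SV type are collapsed at 90% reciprocal
overlap: the shared span must cover at least 90% of **each** call.
Different types are never merged — a deletion and a duplication over the
same span are distinct alleles. Redundant pairs are grouped by transitive
closure and each group keeps its record with the smallest
`(start, end, sv_id)`; this tie-break is arbitrary but deterministic, so
the operation is idempotent (verified against an all-pairs brute-force
oracle on catalogs of 200 SVs).

## Curation FDR

Visual curation answers "is this variant real?" with *yes*, *no* or
*maybe*; only *yes* calls are kept downstream, so *no* and *maybe*
together are the low-confidence set and the empirical false discovery
rate of a stratum is simply `n_low_confidence / n_total`. This is a
false-call rate from curation, not a multiple-testing quantity. An empty
stratum reports `NA` rather than 0 — absence of calls is not evidence of
perfection. Strata always partition the calls, so stratum totals sum to
the overall total (tested).

## Amplicon validation

A pileup with fewer than `min_cov = 50` reads is a failed PCR. Allele
fractions are computed over allele-assignable reads only; reads matching
neither breakpoint state count toward the coverage gate but not the
fractions (they are informative about amplification, not genotype). The
rules apply in order: coverage gate; `1/1` if the SV-allele fraction
exceeds `hom_frac = 0.9` (strict); `0/0` symmetrically on the reference
fraction (the homozygous-reference rule is the mirror image of the stated
homozygous-alternate rule); `0/1` if both fractions are at least
`het_frac = 0.1` (inclusive). A fraction of exactly 0.9 is therefore
heterozygous. A covered pileup with zero assignable reads fails with its
own reason code. Concordance is reported two ways: presence/absence
(agreement on whether any SV allele is present) and exact genotype; FAIL
classifications are excluded from all denominators, and homozygous-
reference confirmations count as concordant presence calls — the
validation data cannot distinguish a correctly absent SV from an
uninformative locus, so we follow the presence/absence rule throughout.

## Weir–Cockerham theta and the permutation scan

For two groups with sizes $n_i$, alternative-allele frequencies $p_i$ and
heterozygote proportions $h_i$, the among-group ($a$), between-individual
($b$) and within-individual ($c$) variance components are combined as
$\theta = a/(a+b+c)$. Missing genotypes are dropped pairwise per SV, so
$n_i$ varies across SVs. Sites monomorphic across both groups have a zero
denominator and are excluded ("no alternative allele in the compared
groups"), not reported as 0. Negative $\theta$ is legitimate sampling
noise around zero differentiation. A site with one group empty after
missing-data removal is flagged, never an abort.

Per-locus $\theta$ agrees with an independently transcribed
variance-component oracle to $10^{-10}$ on random small genotype columns;
the vectorised matrix path used inside the permutation loop is checked
against the scalar path the same way. For *aggregating* loci,
`wc_fst_global()` uses the ratio of summed components
$\sum a / \sum(a+b+c)$ — the form the variance-component framework
defines for multi-locus estimates. The mean of per-locus ratios is biased
low (Jensen's inequality on the ratio), which matters when checking
parameter recovery against a known simulated divergence.

The permutation null re-splits individuals into two sets of the original
sizes (34 vs 257 in the motivating design) `n_perm = 200` times,
recomputing $\theta$ for every SV each time. The per-SV P value is the
fraction of permuted values **strictly greater** than the observed one
("higher than"); ties count as non-exceedances, and the alternative
$\geq$ rule is available behind the `exceed` flag. Ten exceedances in 200
permutations give $P = 0.05$; P values live on the grid
$\{0, 1/200, \dots, 1\}$, so the smallest achievable level with 200
permutations is 0; $P < 0.01$ means at most one exceedance. The global
cutoff is the $q = 0.997$ quantile of the **pooled** permuted $\theta$
(one scalar across all SVs and permutations) — the pooled reading is the
one that yields a single cutoff value comparable across SVs; an SV is an
outlier only if it passes both the per-SV P threshold and the global
cutoff. The permutation stream is seeded independently of the
synthetic-data streams, so scan results are reproducible regardless of
how the input was produced.

Under exchangeable labels the per-SV P values are approximately uniform
on the achievable grid, and the fraction below 0.01 is
$2/201 \approx 0.00995$. Because all SVs share the same 200 permutations,
the Monte-Carlo fluctuation of that fraction is wider than a naive
binomial bound; the calibration test uses a documented $\pm 0.0075$ band
around 0.01, chosen from the spread observed across independent seeds at
the test's problem size (2000 SVs, 291 individuals).

## Dosage PCA

Principal components of the centred samples × SVs dosage matrix
(`stats::prcomp`, no scaling — dosages share a scale). Constant SVs are
dropped with a warning; scores are deterministic up to sign. Strongly
diverged lineages separate on PC1, which is also how a scan cohort should
be chosen: comparing farmed fish against wild fish of their own lineage
keeps lineage and cline structure out of the farmed–wild contrast.

## Ohnolog enrichment and expression

The contingency unit is the **gene**, not the SV: each gene is flagged if
any SV (optionally of one type) overlaps it by ≥ 1 bp, and the
{ohnolog, singleton} × {overlapped, not} table is tested with Fisher's
exact test (two-sided, conditional odds ratio). Gene-level flags keep the
margins well-defined — SV-level counting would double-count SVs spanning
several genes. A zero margin leaves the odds ratio undefined and flagged,
not coerced to a number.

Expression correlation of an ohnolog pair is Spearman's rank correlation
across tissues (average ranks on ties), requiring at least three tissues.
The observed statistic is the median over pairs with an SV-overlapped
member; the null is the median of 1000 random same-size pair sets, and
the empirical P is the proportion of resampled medians **strictly lower**
than the observed one — small P means disrupted pairs are unusually
weakly correlated. Pairs with constant expression in a member are dropped
with a warning. Expression-level tests use each gene's summed
$\log_{10}$ abundance across tissues with a pseudocount of $10^{-3}$
(zeros are real in TPM tables; the pseudocount choice only compresses the
extreme low end). Wilcoxon rank-sum P values are exact by enumeration
when both groups have ≤ 10 untied observations and use the normal
approximation otherwise.

## Functional context

The tissue-specificity index is the per-tissue share of a gene's total
abundance, $CPM(g,t)/\sum_t CPM(g,t)$, bounded in $[0,1]$ and summing to
1 across tissues; genes with total CPM below 1.0 are filtered before any
index is computed, so an all-zero gene never divides by zero. (The
bounded, normalized form is the only reading compatible with a
"specificity ≥ 0.5" threshold; the reciprocal is unbounded.) Enrichment
of tissue-specific genes in a subset is an upper-tail hypergeometric test
$P(X \geq k)$, checked against exhaustive subset enumeration for small
populations; the level comparison is a Welch two-sample t-test of the
subset against the retained transcriptome. ATAC peaks are assigned to
genes within ±3000 bp of the gene span; SV–peak overlap is tested with a
2×2 Fisher test that is symmetric under class-label swap (P unchanged,
odds ratio inverted). SV–gene linkage uses a ±5000 bp window around the
gene span, recording gap distance (0 for body overlap); gene span is the
min-start/max-end interval, a longest-transcript proxy.

## The synthetic-data generator

The generator's job is to produce inputs with the statistical structure
the analyses assume, with every parameter recoverable downstream.

**Cohort.** Allele frequencies follow a hierarchical Balding–Nichols
model: ancestral frequency uniform on (0.05, 0.95); lineage frequencies
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with
$F = \texttt{divergence\_F["lineage"]}$ (default 0.10); population
frequencies a second Balding–Nichols draw (default $F = 0.02$) plus a
logit-scale latitudinal cline (0.03 per degree, a mild cline that
separates along PC2-like axes without swamping lineage structure). The
farmed group derives from the southernmost wild population — mirroring
aquaculture strains founded from southern wild stocks — with its own
drift ($F = 0.02$) and a directional frequency shift
(`outlier_freq_shift`, default 0.3) at `n_planted_outliers` (default 50)
randomly chosen SVs with source frequency in [0.15, 0.6], so planted
outliers are segregating and the shift has room. Genotypes are
Hardy–Weinberg draws; 1% missingness exercises imputation. The
closed-form link $E(\theta) \approx F$ is what makes the generator
testable: the multi-locus Weir–Cockerham estimate recovers the configured
$F$ within ±0.02 at 2000 SVs and 100 + 100 samples.

**Cohort defaults** (257 wild in six populations over two lineages along
a 58–70° cline, 34 farmed, 2000 SVs split ~90/8/2% DEL/DUP/INV) mirror
the motivating study's design at desk scale; the SV type proportions and
the farmed/wild sizes are the study's, the SV count is scaled down three
orders of magnitude to keep a full permutation scan under a few seconds.

**SV catalog.** Sizes are log-normal with per-type parameters set so the
body means match a curated short-read catalog (deletions ≈ 1.5 kb,
duplications ≈ 8 kb, inversions ≈ 120 kb; minimum 100 bp — the defining
SV size floor). A fraction of deletions (default 0.0075, the observed
share of the real catalog) is drawn uniformly in 1432–1436 bp,
reproducing the transposon-excision spike. Draws longer than the longest
chromosome are resampled with a logged warning; placement is uniform over
valid starts.

**Coverage, curation, amplicons.** Depths are Poisson around
`depth_mean = 8` with planted complex regions at `depth_high = 150` in
`n_high_samples = 120` samples — comfortably separated from the
background so the detector's thresholds, not the generator, decide the
outcome (the Poisson tail above 100 at mean 8 is negligible, so a clean
profile yields no regions). Curation labels are false with probability
`fdr_complex = 0.992` inside complex regions and `fdr_normal = 0.85`
outside — the two empirical rates a curated salmon call set shows — with
false calls split evenly between *no* and *maybe*. Amplicon pileups are
Poisson-coverage binomial-allele counts with a per-read error rate
(default 0.02), a 5% failed-PCR rate, and 5% unassignable reads.

**Expression.** Pair abundances are a Gaussian copula on the log2 scale:
per-tissue deviations are bivariate normal with Pearson correlation
$2\sin(\pi\rho_s/6)$, the inverse of the Gaussian rank-correlation map,
so the *population Spearman* equals `expr_rho` (default 0.6) by
construction rather than by tuning. SV-overlapped copies are reduced by
the multiplicative factor `expr_sv_effect` (default 0.5) and perturbed by
independent per-tissue log2 noise (`expr_sv_noise = 0.5`), mean-corrected
so the expected abundance ratio to the partner stays `expr_sv_effect`
while the within-pair correlation is attenuated — a disrupted copy is
both lower and less coordinated, which is what gives the
correlation-resampling test something to detect. A pure multiplicative
effect would leave rank correlations untouched.

**Determinism.** One master seed is expanded into independent named
substreams (`catalog`, `cohort`, `coverage`, `curation`, `amplicon`,
`ohnolog`, `expression`, …) via a string-hash; adding a stage never
perturbs another, and identical configurations give bit-identical
outputs.

**What the generator does not emulate.** Read-level sequence data,
alignment artefacts, SV-caller-specific error modes, linkage
disequilibrium between SVs (sites are independent given population
frequencies), overlapping/nested SV alleles, multi-allelic loci, and the
correlation between SV size and callability. Passing tests therefore
demonstrate that the *estimators and decision rules* behave as specified
under the assumed generative structure — not that the pipeline is robust
to every artefact of real short-read data.

## Pipeline

`run_pipeline()` executes the stages in dependency order from one YAML or
list configuration, validating the configuration (unknown stages, missing
seed) before anything runs. Every output lands in `out_dir` and is listed
in `manifest.json` with md5 digests, parameters and the seed; rerunning
an identical configuration reproduces byte-identical tables. The package
is deliberately library-first — the exported functions, the pipeline
runner and `scripts/acceptance.R` are the interface; there is no separate
shell binary to version alongside the API.

## Problem sizes and test budget

The test suite and acceptance script run everything at desk scale, chosen
so the full suite completes in a couple of minutes on one CPU: 2000-SV
cohorts with 291 individuals and 200 permutations for calibration and
recovery; 2000 ohnolog pairs for correlation recovery; 10,000 calls per
stratum for FDR recovery; 200-SV catalogs for brute-force interval
oracles; exhaustive enumeration for exact tests up to margins of 12.
Data-dependent headline numbers of any real cohort (total SV counts,
outlier counts, a specific θ cutoff such as 0.103, specific Fisher P
values) are properties of that cohort's data and are *not* reproduction
targets at this scale; the seeded simulations cover them qualitatively
(direction, magnitude, calibration).

## Known limitations

- The scan supports exactly two groups; multi-population scans and
  admixture-aware contrasts are out of scope.
- Fisher's conditional odds ratio is reported, which differs from the
  sample odds ratio in small tables (and is `Inf`/0 on zero cells).
- Monomorphic-SV exclusion happens per comparison; a SV monomorphic in
  the compared groups but polymorphic elsewhere in the cohort is still
  excluded, matching the scan's definition.
- The curation-FDR model treats labels as independent Bernoulli draws;
  real curators are correlated raters.
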