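---
title: "Methods: burden gating, signature refitting, consensus-NMF subtyping, immunoediting and the mScore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden gating, signature refitting, consensus-NMF subtyping, immunoediting and the mScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcprofiler)
```

This vignette explains what each stage of the pipeline computes, the
assumptions behind it, the tunable parameters and their defaults, what the
synthetic-cohort generator does and does not emulate, and the numerical and
design choices made where more than one reading was defensible.

## Burden and the hypermutation gate

A somatic variant enters any downstream analysis only after the hard
filters: VAF ≥ 0.08, depth ≥ 8, supporting reads ≥ 2, all boundaries
inclusive (`apply_variant_filters()`). TMB is the count of mutations in
eight functional classes — Frame_Shift_Del/Ins, In_Frame_Del/Ins,
Missense_Mutation, Nonsense_Mutation, Nonstop_Mutation, Splice_Site, matched
case-sensitively — after excluding variants with 1000 Genomes or ExAC allele
frequency strictly above 0.05, divided by the interrogated panel size in Mb.
Missing population frequencies count as zero: absence from a population
database is evidence of rarity, so such variants are kept.

The panel size is a genuine free parameter (`panel_size_mb`, default 35 Mb, a
typical whole-exome footprint): assays differ, and the TMB scale shifts
inversely with it. The hypermutation gate is TMB ≥ 10 muts/Mb, inclusive. A
fixed panel denominator is used rather than per-sample covered bases; if your
pipeline tracks per-sample callable territory, pass it per cohort via the
config.

Percentages in stratified summary tables are rounded to the printed precision
by the largest-remainder method, so each variable's levels sum to exactly
100.0 — plain half-up rounding cannot guarantee that for more than two
levels, and the printed-table convention this mirrors reports closed
percentages.

## Signature refitting

Catalogs are tabulated over the standard 96 substitution classes
(pyrimidine-centered; purine-reference records are counted on the reverse
complement). Only known signatures are refit — no de novo extraction. For
each sample with at least 20 SNVs, the 96-bin fraction profile is regressed
on the reference matrix by non-negative, intercept-free LASSO (`glmnet`),
with the penalty chosen per sample by 5-fold cross-validation over the
log-spaced default grid and the one-standard-error rule. Folds are assigned
deterministically by context index, so refitting is reproducible without
touching the RNG. Fitted activities are rescaled to mutation counts, and
anything below 1e-6 of the catalog total is set to exactly zero — the
cohort-prevalence rule ("active in strictly more than 1% of fitted samples")
needs a crisp notion of zero, and "present" is defined as nonzero after this
floor.

The "exome2genome" adjustment multiplies each bin by a genome/exome
abundance ratio for its flanking trinucleotide. Computing real ratios
requires a reference genome, which this package deliberately does not
bundle; the default is the identity ratio, a synthetic example table ships
in `inst/extdata/synthetic_trinuc_ratio.tsv` (synthetic, for exercising the
code path), and real ratios can be supplied via `read_trinuc_ratio()`. The
bundled signature reference (`synthetic_signature_reference()`) is likewise
synthetic — deterministic, well-separated, documented as such — because a
real COSMIC-format catalog is licensed data the user should supply through
`read_signature_reference()`.

## Consensus-NMF subtyping

Hypermutated samples are set aside first (they would otherwise dominate any
factorization through sheer burden) and are labelled HM unconditionally. The
remaining samples are clustered on a concatenation of two blocks:

- signature exposures, converted to per-sample fractions and then min-max
  scaled per column. Fractions, not raw activity counts: the subtype signal
  is the *relative* signature composition, while absolute activity tracks
  total burden — which the HM gate has already handled. With raw counts the
  within-subtype burden spread dominates the factorization and cluster
  recovery collapses (adjusted Rand ~0.3 versus ~0.99 with fractions on the
  same simulated cohorts).
- binary lesion indicators, passed through unscaled.

Blocks are concatenated without weighting (an optional weight is not needed
for the default feature sets; zero-variance columns are dropped either way).

Each K in 2..6 gets 10 NMF runs (Frobenius loss, multiplicative updates,
2000 iterations maximum, 1e-6 relative tolerance, random uniform
initializations seeded deterministically from the master seed).
A run labels each sample by its dominant basis component; samples with
byte-identical feature rows are forced to share a label via the mean basis
row of their profile, since a degenerate factorization otherwise breaks ties
arbitrarily. The consensus matrix is the co-clustering frequency across
runs; final labels come from average-linkage hierarchical clustering of
1 − consensus cut at K, and the cophenetic correlation of that dendrogram
against 1 − consensus measures stability. `select_k()` takes the cophenetic
argmax with ties to the smaller K, and accepts an override — the published
subtyping fixed K = 3 after inspecting the consensus structure, and the
pipeline treats that as a configuration choice, not a recomputation.

Cluster naming is deliberately unsupervised: GS is the cluster with the
lowest mean feature-row sum (alteration load); of the remaining two, the one
with the higher 10q11.21-amplification fraction is CIN-HR. Survival is *not*
used for naming, although the published subgroups were named partly by
prognosis — naming by outcome would leak the endpoint into the label and
invalidate downstream survival comparisons. Equal amplification fractions
fall back to the higher-load cluster; the case is degenerate and essentially
only arises in toy data. External cohorts with coarse GS/CIN/HM labels map
through the same rule: CIN splits on 10q11.21 amplification ("at least one
gene in the cytoband amplified"), GS and HM pass through.

## Immunoediting, HLA LOH, and the IR composite

Per-context rates are pooled over samples with at least 10 non-silent
mutations: B̄ₛ is the fraction of non-silent mutations in context *s* that
are immunogenic (≥ 1 predicted neoantigen — mutations are counted, not
peptides, because the score divides mutation counts), and N̄ₛ is the ratio of
non-silent to silent mutations in *s*. Contexts with zero silent mutations
get add-one smoothing on the silent count. "Context" here means the full
96-class (substitution plus flanks): silent and non-silent SNVs both carry
one, and the per-sample sums run over the silent mutations' classes:
N_pred = Σ N̄ₛ₍ₘ₎, B_pred = Σ N̄ₛ₍ₘ₎ B̄ₛ₍ₘ₎.

The immunoediting score I = (B_obs/N_obs)/(B_pred/N_pred) is undefined — and
the sample flagged not assessable — when the sample has no silent mutations
(no prediction basis), no observed non-silent mutations, or B_pred = 0.
Z-scores standardize I over the *assessable* samples (not the full cohort;
mixing in undefined scores has no meaningful interpretation), and the
immunoedited gate is z < −1.645, strict: one-sided 5% depletion.

HLA LOH is a decision rule over supplied allele-level calls, not an
estimator: a sample is assessable only with complete HLA-A/B/C output;
allelic imbalance means p < 0.01; LOH adds copy number < 0.5 with the CI
upper bound strictly below 0.7. The IR composite is the OR of
antigen-presenting-gene mutation, HLA LOH and immunoedited status, with
not-assessable components contributing `FALSE` — a patient is never called
immunogenicity-reduced on missing evidence, which mirrors reporting LOH on
the assessable subset while tabulating IR on the full cohort. The TNB
high/low cut in the four-way TNB × IR grouping defaults to the cohort
median since no published cut exists; it is a config knob.

## mScore

R = (purity·ploidy + (1−purity)·2)/2 is the average genome copies per cell
in the admixture relative to diploid: R = 1 for any purity at ploidy 2, and
R → 1 as purity → 0. The mScore m = (r_m/r_n)·R is invariant to uniform
read-count scaling. Whether read counts are raw or deduplicated is a
pipeline-upstream choice; the score only assumes both samples were processed
identically.

MT somatic variants are filtered against rCRS positions {310, 523, 524,
3107} (three historical-numbering "N" positions plus the 310 homopolymer
common variant); the filter is idempotent and removes nothing else.

The risk split defaults to the top 10% *by rank* with ties broken by sample
id — a value-based density cut has no deterministic tie rule. The published
split is the top decile; the named "best-cutoff strategy" is available
explicitly as `strategy = "scan"`, a log-rank maximization over decile
candidates constrained to leave each group ≥ 10% of the cohort. qPCR
quantification uses 2^−ΔΔCt with the calibrator defaulting to the median-ΔCt
sample (no calibrator is named in the protocol this follows; the median is
reproducible and scale-central), and the WES cutoff transfers to the qPCR
scale through an OLS fit of qPCR values on WES mScores.

## Survival and associations

Kaplan-Meier, log-rank, and Cox (Efron ties) all go through the `survival`
package; `cox_adjusted()` exposes the adjusted analysis (exposure plus TMB,
stage, grade) with stage and grade entering as indicator-coded categories —
the coding is not specified in the source analyses, and indicators are the
assumption-light choice. The association matrix fixes the test-selection
rules: categorical pairs use chi-square (Yates for 2×2) unless any expected
cell is below 5, then Fisher; continuous-vs-binary uses a two-sided t-test,
continuous-vs-multilevel one-way ANOVA, continuous pairs Pearson;
Benjamini-Hochberg adjusted p-values are reported alongside raw ones.

## The synthetic-cohort generator

`simulate_cohort()` draws, per sample: a subtype (default proportions 7.09%
HM, with the non-HM remainder split 25/35/40 across CIN-HR/CIN-LR/GS); a
total mutation count from a subtype-specific log-normal, truncated so the HM
and non-HM burden regimes are disjoint (HM is *defined* by the burden gate,
so the generator keeps a margin around 10 muts/Mb — HM counts are floored at
560 total mutations, non-HM capped at 320, which after the ~71% qualifying
rate brackets the 350-mutation gate equivalent comfortably); 96-class
contexts from the subtype's signature mixture applied to the reference;
silent status at 1:3 odds (a typical exome coding ratio — only relative
rates enter the immunoediting expectations); VAF/depth/alt-reads with small
planted failure rates so the hard filters have work to do; 2% common
population variants; per-mutation neoantigen flags at rate 0.15; Bernoulli
lesions with 10q11.21 amplification at 60% in CIN-HR versus ≤ 10% elsewhere;
purity ~ Beta(8,4), ploidy mostly 2-3; log-normal true mScores converted to
consistent MT/nuclear read counts; HLA calls with LOH planted at 17.4% of
the ~41% assessable samples; MT variants at Poisson rate 1.3 with 15%
blacklisted positions (≈ 67% of samples retain a variant after filtering);
and exponential survival with log-hazard = subtype effect + 0.25 per stage
level + 0.3 per log-mScore SD, independently censored at a ~30% target rate
plus a 120-month administrative cap. Exponential baseline (not Weibull)
keeps closed-form sanity checks available.

Randomness is hierarchical: each sample consumes its own substream derived
from the master seed, so enlarging a cohort never perturbs existing samples
— fixtures stay stable as tests grow.

What the generator does **not** emulate: linkage disequilibrium or
co-occurrence structure between lesions, gene-level mutation hotspots,
subclonality and VAF clustering, indels (catalogs are SNV-only; TMB's indel
classes are exercised through hand-built tables in tests), batch effects,
and any correlation between immune flags and subtype beyond what the shared
seed induces. Passing recovery tests on this generator therefore
demonstrates that the estimators are correct under their own assumptions —
well-separated mixtures, independent lesions, exponential hazards — not that
they are robust to the messiness of real cohorts.

`fixture_from_counts()` is the deterministic complement: it reconstructs
cohorts whose flag marginals equal printed counts exactly (e.g. 72
hypermutated of 1015; 46 MSI-H, 25 POLE, 10 both within 72), for worked
examples where the quantity of interest is pure set arithmetic.

## Problem sizes and runtime choices

The test suite and the acceptance script run their recovery checks at sizes
chosen to make the statistical assertions stable: 300 samples for subtype
recovery (ARI threshold 0.8 with planted separation), 2000 mutations per
catalog and 50 replicates for signature recovery (±10 percentage points),
n = 1000 for the Cox point estimate and 500 replicates at n = 120 for null
CI coverage, 10,000 scores for the Z-gate rate, and 1000 random tuples for
the closed-form mScore oracle. These sizes are the package's own choices;
they keep the whole suite under a minute while leaving each assertion's
Monte-Carlo error well inside its tolerance.

## Known limitations

- The signature reference and trinucleotide ratios bundled for offline use
  are synthetic; scientific use requires supplying a real catalog and real
  abundance ratios.
- The prevalence rule counts "nonzero after the activity floor"; a
  minimum-mutation-contribution reading would be stricter and is not
  implemented.
- `select_k()`'s cophenetic criterion can legitimately prefer K = 2 on small
  cohorts where two of the planted groups are close; the override exists
  because fixed-K subtyping is a reproducibility decision, not a model fit.
- The LASSO penalty path is per sample; no information is shared across
  samples (no multi-task penalty), matching the refitting approach this
  follows.
- Cox covariates are complete-case; no imputation.
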