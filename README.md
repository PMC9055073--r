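# crcprofiler

Cohort-scale somatic genomic profiling for colorectal cancer (CRC), built for
analysts who receive pre-called, pre-annotated variant tables (MAF-dialect
TSV), GISTIC-style lesion matrices, allele-level HLA copy-number calls and
mitochondrial/nuclear read counts, and need the downstream decision machinery:
burden gating, signature refitting, genomic subtyping, immune-escape calls and
a mitochondrial copy-number biomarker. Because patient-level CRC genomic data
is typically restricted-access, the package also ships a synthetic-cohort
generator with known ground truth, so every stage is testable and
demonstrable offline.

## What it computes

**Tumor mutational burden and hypermutation.** Variants pass hard filters
(VAF ≥ 8%, depth ≥ 8, supporting reads ≥ 2); TMB counts the eight qualifying
functional classes (Frame_Shift_Del/Ins, In_Frame_Del/Ins, Missense, Nonsense,
Nonstop, Splice_Site) minus common population variants (1000G or ExAC
AF > 0.05), divided by the panel size in Mb. Hypermutated (HM) means
TMB ≥ 10 muts/Mb; HM tumors are partitioned into MSI-H-only, POLE-only, both,
and unexplained.

**Mutational signatures.** Per-sample 96-context catalogs (pyrimidine-centered
convention) are refit against a reference signature matrix by non-negative,
intercept-free LASSO with cross-validated penalty ("exome2genome"
trinucleotide-abundance normalization supported). Samples need ≥ 20 SNVs;
signatures are retained when active in > 1% of fitted samples.

**Genomic subtypes.** Non-HM samples are clustered by consensus NMF (K = 2..6,
10 runs per K) on concatenated signature-exposure and lesion-indicator
features. Clusters are named by statistics, not indices: lowest alteration
load → GS (genomic stable); of the two CIN clusters, higher 10q11.21
amplification fraction → CIN-HR, the other CIN-LR. External cohorts with
coarse GS/CIN/HM labels map through the same 10q11.21 rule.

**Immunoediting and immunogenicity reduction.** From cohort-wide per-context
rates (B̄ₛ = immunogenic mutations per non-silent mutation, N̄ₛ = non-silent per
silent), each sample's silent mutations predict N_pred = Σ N̄ₛ₍ₘ₎ and
B_pred = Σ N̄ₛ₍ₘ₎ B̄ₛ₍ₘ₎; the immunoediting score is
I = (B_obs/N_obs) / (B_pred/N_pred), and samples with cohort Z-score < −1.645
are immunoedited. HLA LOH follows the published thresholds (allelic-imbalance
p < 0.01, allele copy number < 0.5, CI upper bound < 0.7, complete HLA-A/B/C
calls required). IR (immunogenicity-reduced) = antigen-presenting-gene
mutation OR HLA LOH OR immunoedited.

**mScore.** Purity/ploidy corrective factor R = (purity·ploidy +
(1−purity)·2)/2 and mScore m = (r_m/r_n)·R, with the rCRS blacklist
{310, 523, 524, 3107} for MT somatic variants, a top-10% risk split (or a
log-rank cutoff scan), qPCR 2^−ΔΔCt quantification and regression-based
cutoff transfer from the WES scale to the qPCR scale.

Survival machinery (Kaplan-Meier/log-rank, Cox adjusted for TMB, stage and
grade with Efron ties), pathway oncogenic/VUS/Wt rollup, ≥2-tool driver-gene
consensus and the pairwise clinical-molecular association matrix round out
the pipeline.

## Worked example

```r
library(crcprofiler)
cfg <- cohort_sim_config(n_samples = 120, seed = 42)
cohort <- simulate_cohort(cfg)

filtered <- apply_variant_filters(cohort$mutations)
tmb <- classify_hypermutated(compute_tmb(filtered, panel_size_mb = 35))
cat(sprintf("hypermutated: %d/%d (%.2f%%)\n",
            sum(tmb$hypermutated), nrow(tmb), 100 * mean(tmb$hypermutated)))
#> hypermutated: 8/120 (6.67%)

catalogs <- tabulate_contexts(cohort$mutations)
fit <- fit_exposures_lasso(catalogs, cfg$reference)
hm <- setNames(tmb$hypermutated, tmb$sample_id)
fm <- build_feature_matrix(fit$exposures, cohort$lesions, hm)
cn <- consensus_nmf(fm, k_range = 2:6, n_runs = 10, seed = 42)
k <- select_k(cn, override = 3)   # fixed K = 3, as in the published subtyping
cat("K = 3 cophenetic:", round(cn[["3"]]$cophenetic, 3), "\n")
#> K = 3 cophenetic: 0.983
sub <- assign_subtypes(cn[[as.character(k)]]$labels, hm, cohort$lesions, fm)
table(sub$subtype)
#> CIN-HR CIN-LR     GS     HM
#>     33     29     50      8

prof <- mito_profiles(cohort$mt_counts)
split <- split_by_mscore(setNames(prof$mscore, prof$sample_id))
cat(sprintf("mScore-high: %d samples, cutoff %.4f\n",
            sum(split$group == "high"), split$cutoff))
#> mScore-high: 12 samples, cutoff 0.0181
km <- km_logrank(cohort$clinical$os_months, cohort$clinical$os_event,
                 split$group)
cat(sprintf("log-rank chisq %.2f, p = %.3f\n", km$chisq, km$p))
#> log-rank chisq 2.79, p = 0.095
```

The 6.67% hypermutation rate is the gate applied to this particular simulated
draw (the generator's default prevalence is 7.09%); the cophenetic coefficient
near 1 says the three non-HM clusters are stable across NMF restarts; the
subtype counts reflect the generator's planted proportions; the top-decile
mScore split of 120 samples holds 12, and at this cohort size the survival
contrast is suggestive but not significant.

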