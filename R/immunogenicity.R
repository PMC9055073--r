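#' @title Neoantigen immunoediting and immunogenicity reduction
#' @description Estimates per-context immunogenic-mutation rates from the
#'   cohort, predicts each sample's expected non-silent and immunogenic
#'   mutation counts from its silent mutations, scores immunoediting as the
#'   observed/expected ratio of immunogenic mutations per non-silent
#'   mutation, applies the HLA loss-of-heterozygosity decision thresholds to
#'   supplied allele-level calls, and combines antigen-presenting-gene
#'   mutation, HLA LOH and immunoediting into the immunogenicity-reduced (IR)
#'   composite.
#' @name immunogenicity
NULL

# restrict a mutation table to SNVs with a resolvable 96-class and a silent
# flag; returns columns sample_id, class, is_silent, n_neoantigens
.immuno_snvs <- function(tab) {
  require_columns(tab, c("sample_id", "ref", "alt", "trinuc_context",
                         "is_silent", "n_neoantigens"), "immunoediting input")
  cls <- sbs_class_of(tab$ref, tab$alt, tab$trinuc_context)
  keep <- !is.na(cls) & !is.na(tab$is_silent)
  data.frame(sample_id = tab$sample_id[keep], class = cls[keep],
             is_silent = tab$is_silent[keep],
             n_neoantigens = ifelse(is.na(tab$n_neoantigens[keep]), 0L,
                                    tab$n_neoantigens[keep]),
             stringsAsFactors = FALSE)
}

#' Estimate per-context immunogenicity rates from a cohort
#'
#' Pooling over samples with at least `min_nonsilent` non-silent mutations,
#' derives for each of the 96 substitution contexts: `b_bar`, the average
#' number of immunogenic mutations per non-silent mutation (a non-silent
#' mutation is immunogenic when it yields at least one predicted neoantigen),
#' and `n_bar`, the expected number of non-silent mutations per silent
#' mutation. Contexts with zero silent mutations get `n_bar` by add-one
#' smoothing of the silent count.
#'
#' @param tab Cohort `mutation_table` with `is_silent` and `n_neoantigens`.
#' @param min_nonsilent Minimum non-silent mutations for a sample to inform
#'   the rates (default 10).
#' @param immunogenic_min Neoantigen count making a non-silent mutation
#'   immunogenic (default 1).
#' @return data.frame with one row per context: `context`, `n_nonsilent`,
#'   `n_silent`, `n_immunogenic`, `b_bar`, `n_bar`.
#' @export
estimate_context_rates <- function(tab, min_nonsilent = 10,
                                   immunogenic_min = 1) {
  snvs <- .immuno_snvs(tab)
  per_sample <- tapply(!snvs$is_silent, snvs$sample_id, sum)
  eligible <- names(per_sample)[per_sample >= min_nonsilent]
  if (!length(eligible)) {
    stop_fmt("estimate_context_rates: no sample has >= %d non-silent mutations",
             min_nonsilent)
  }
  pool <- snvs[snvs$sample_id %in% eligible, , drop = FALSE]
  ctx <- factor(pool$class, levels = sbs_classes())
  n_nonsilent <- as.integer(tapply(!pool$is_silent, ctx, sum, default = 0L))
  n_silent <- as.integer(tapply(pool$is_silent, ctx, sum, default = 0L))
  immunogenic <- !pool$is_silent & pool$n_neoantigens >= immunogenic_min
  n_immuno <- as.integer(tapply(immunogenic, ctx, sum, default = 0L))
  b_bar <- ifelse(n_nonsilent > 0, n_immuno / n_nonsilent, 0)
  n_bar <- n_nonsilent / ifelse(n_silent > 0, n_silent, n_silent + 1L)
  data.frame(context = sbs_classes(), n_nonsilent = n_nonsilent,
             n_silent = n_silent, n_immunogenic = n_immuno,
             b_bar = b_bar, n_bar = n_bar, stringsAsFactors = FALSE)
}

#' Expected non-silent and immunogenic counts for one sample
#'
#' Sums the per-context rates over the sample's silent mutations:
#' `N_pred = sum(n_bar[s(m)])` and `B_pred = sum(n_bar[s(m)] * b_bar[s(m)])`.
#' A sample with no silent mutations has no prediction basis and is flagged
#' not assessable.
#'
#' @param silent_classes Character vector of 96-class labels of the sample's
#'   silent mutations (possibly empty).
#' @param rates Output of [estimate_context_rates()].
#' @return List `n_pred`, `b_pred`, `assessable`.
#' @export
expected_counts <- function(silent_classes, rates) {
  if (!length(silent_classes)) {
    return(list(n_pred = NA_real_, b_pred = NA_real_, assessable = FALSE))
  }
  i <- match(silent_classes, rates$context)
  if (anyNA(i)) stop_fmt("expected_counts: unknown context class")
  list(n_pred = sum(rates$n_bar[i]),
       b_pred = sum(rates$n_bar[i] * rates$b_bar[i]),
       assessable = TRUE)
}

#' Per-sample immunoediting profiles
#'
#' Computes, for every sample in the table, the observed non-silent count
#' `n_obs`, observed immunogenic count `b_obs`, expected counts from the
#' sample's silent mutations, the immunoediting score
#' `I = (B_obs/N_obs) / (B_pred/N_pred)`, the cohort Z-score of I (over
#' assessable samples), and the immunoedited flag (`z < z_cut`, strict; a
#' score 1.645 standard deviations below the cohort mean marks significant
#' neoantigen depletion at one-sided 5%).
#'
#' @param tab Cohort `mutation_table`.
#' @param rates Optional precomputed [estimate_context_rates()] output.
#' @param z_cut Z threshold (default -1.645).
#' @param immunogenic_min See [estimate_context_rates()].
#' @param min_nonsilent See [estimate_context_rates()].
#' @return data.frame per sample: `sample_id`, `n_obs`, `b_obs`, `n_pred`,
#'   `b_pred`, `i_score`, `z`, `assessable`, `immunoedited`.
#' @export
immunoediting_profiles <- function(tab, rates = NULL, z_cut = -1.645,
                                   immunogenic_min = 1, min_nonsilent = 10) {
  snvs <- .immuno_snvs(tab)
  if (is.null(rates)) {
    rates <- estimate_context_rates(tab, min_nonsilent = min_nonsilent,
                                    immunogenic_min = immunogenic_min)
  }
  samples <- sort(unique(tab$sample_id))
  prof <- data.frame(sample_id = samples, n_obs = 0L, b_obs = 0L,
                     n_pred = NA_real_, b_pred = NA_real_,
                     stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    s <- snvs[snvs$sample_id == samples[j], , drop = FALSE]
    prof$n_obs[j] <- sum(!s$is_silent)
    prof$b_obs[j] <- sum(!s$is_silent & s$n_neoantigens >= immunogenic_min)
    ec <- expected_counts(s$class[s$is_silent], rates)
    prof$n_pred[j] <- ec$n_pred
    prof$b_pred[j] <- ec$b_pred
  }
  immunoediting_score(prof, z_cut = z_cut)
}

#' Immunoediting score, Z-conversion and the immunoedited gate
#'
#' `I = (b_obs/n_obs) / (b_pred/n_pred)`; samples with `n_obs = 0`,
#' `b_pred = 0` or missing predictions are not assessable. Z-scores are
#' computed over the assessable samples, and `immunoedited` is `z < z_cut`
#' (strict).
#'
#' @param prof data.frame with `b_obs`, `n_obs`, `b_pred`, `n_pred`.
#' @param z_cut Z threshold (default -1.645).
#' @return `prof` with `i_score`, `z`, `assessable`, `immunoedited` added.
#' @export
immunoediting_score <- function(prof, z_cut = -1.645) {
  require_columns(prof, c("b_obs", "n_obs", "b_pred", "n_pred"),
                  "immunoediting score input")
  assessable <- !is.na(prof$n_pred) & !is.na(prof$b_pred) &
    prof$n_obs > 0 & prof$b_pred > 0 & prof$n_pred > 0
  i_score <- rep(NA_real_, nrow(prof))
  i_score[assessable] <- (prof$b_obs[assessable] / prof$n_obs[assessable]) /
    (prof$b_pred[assessable] / prof$n_pred[assessable])
  z <- rep(NA_real_, nrow(prof))
  mu <- mean(i_score[assessable])
  sdv <- stats::sd(i_score[assessable])
  z[assessable] <- (i_score[assessable] - mu) / sdv
  prof$i_score <- i_score
  prof$z <- z
  prof$assessable <- assessable
  prof$immunoedited <- !is.na(z) & z < z_cut
  prof
}

#' HLA loss-of-heterozygosity decision rule
#'
#' A sample is assessable only when allele calls are present for all of
#' HLA-A, HLA-B and HLA-C. Per allele: allelic imbalance (AI) iff
#' `ai_pvalue < p_cut`; LOH iff AI and `cn_estimate < cn_cut` and
#' `ci_upper < ci_cut` (all strict). A sample has HLA LOH iff any assessed
#' allele is LOH. The rule is monotone: lowering p, copy number, or the CI
#' upper bound never removes a call.
#'
#' @param calls data.frame with `sample_id`, `locus` (`A`/`B`/`C`),
#'   `ai_pvalue`, `cn_estimate`, `ci_upper` (one row per allele).
#' @param p_cut,cn_cut,ci_cut Decision thresholds (defaults 0.01, 0.5, 0.7).
#' @return data.frame per sample: `sample_id`, `assessable`, `any_ai`,
#'   `hla_loh`, `status` in `{LOH, AI, neither, not-assessable}`.
#' @export
classify_hla_loh <- function(calls, p_cut = 0.01, cn_cut = 0.5, ci_cut = 0.7) {
  require_columns(calls, c("sample_id", "locus", "ai_pvalue", "cn_estimate",
                           "ci_upper"), "HLA calls")
  samples <- sort(unique(calls$sample_id))
  out <- data.frame(sample_id = samples, assessable = FALSE, any_ai = NA,
                    hla_loh = NA, status = "not-assessable",
                    stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    sub <- calls[calls$sample_id == samples[j], , drop = FALSE]
    if (!all(c("A", "B", "C") %in% sub$locus)) next
    ai <- sub$ai_pvalue < p_cut
    loh <- ai & sub$cn_estimate < cn_cut & sub$ci_upper < ci_cut
    out$assessable[j] <- TRUE
    out$any_ai[j] <- any(ai, na.rm = TRUE)
    out$hla_loh[j] <- any(loh, na.rm = TRUE)
    out$status[j] <- if (out$hla_loh[j]) "LOH"
                     else if (out$any_ai[j]) "AI" else "neither"
  }
  out
}

#' Immunogenicity-reduced (IR) composite
#'
#' IR iff at least one of: antigen-presenting-gene mutation, HLA LOH, or
#' immunoedited status; nIR iff none. Not-assessable components (NA) count as
#' `FALSE`, so a patient is never called IR on missing evidence.
#'
#' @param npg_mutated,hla_loh,immunoedited Logical vectors (NA allowed).
#' @return Character vector `"IR"`/`"nIR"`.
#' @export
classify_immunogenicity_reduction <- function(npg_mutated, hla_loh,
                                              immunoedited) {
  f <- function(x) !is.na(x) & x
  ifelse(f(npg_mutated) | f(hla_loh) | f(immunoedited), "IR", "nIR")
}

#' Cross-classify samples by neoantigen burden and IR status
#'
#' Four disjoint, exhaustive groups: TNB-high/low (burden strictly above the
#' cut versus at-or-below; default cut = cohort median) crossed with IR/nIR.
#'
#' @param tnb Numeric tumor neoantigen burden per sample.
#' @param ir_status Character `"IR"`/`"nIR"` per sample.
#' @param tnb_cut Cut point (default `median(tnb)`).
#' @return Factor with levels `TNB-high/IR`, `TNB-high/nIR`, `TNB-low/IR`,
#'   `TNB-low/nIR`; the cut used is in `attr(, "tnb_cut")`.
#' @export
group_by_tnb_ir <- function(tnb, ir_status, tnb_cut = NULL) {
  stopifnot(length(tnb) == length(ir_status))
  tnb_cut <- tnb_cut %||% stats::median(tnb, na.rm = TRUE)
  hi <- ifelse(tnb > tnb_cut, "TNB-high", "TNB-low")
  g <- factor(paste0(hi, "/", ir_status),
              levels = c("TNB-high/IR", "TNB-high/nIR",
                         "TNB-low/IR", "TNB-low/nIR"))
  attr(g, "tnb_cut") <- tnb_cut
  g
}
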