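#' @title Tumor mutational burden and hypermutation gating
#' @description Variant hard filters, TMB per sample, the hypermutation gate
#'   (TMB >= 10 muts/Mb) and its attribution to MSI-H / POLE.
#' @name burden
NULL

# the eight functional classes that count toward TMB; exact, case-sensitive
tmb_classes <- c("Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                 "In_Frame_Ins", "Missense_Mutation", "Nonsense_Mutation",
                 "Nonstop_Mutation", "Splice_Site")

#' Apply the somatic-variant hard filters
#'
#' Keeps a record iff VAF >= `vaf_min` AND depth >= `depth_min` AND supporting
#' reads >= `altreads_min`; all three boundaries inclusive. Row order is
#' preserved and the filter is idempotent.
#'
#' @param tab A `mutation_table`.
#' @param vaf_min Minimum variant allele frequency (default 0.08).
#' @param depth_min Minimum sequencing depth (default 8).
#' @param altreads_min Minimum reads supporting the variant (default 2).
#' @return The filtered table.
#' @export
apply_variant_filters <- function(tab, vaf_min = 0.08, depth_min = 8,
                                  altreads_min = 2) {
  require_columns(tab, c("vaf", "depth", "alt_reads"), "variant filter input")
  keep <- tab$vaf >= vaf_min & tab$depth >= depth_min &
    tab$alt_reads >= altreads_min
  keep[is.na(keep)] <- FALSE
  tab[keep, , drop = FALSE]
}

#' Compute tumor mutational burden per sample
#'
#' Counts, per sample, mutations whose functional class is one of the eight
#' qualifying classes (Frame_Shift_Del/Ins, In_Frame_Del/Ins,
#' Missense_Mutation, Nonsense_Mutation, Nonstop_Mutation, Splice_Site),
#' excluding common population variants (1000 Genomes or ExAC allele frequency
#' strictly greater than `pop_af_max`; missing frequencies count as 0, i.e.
#' the variant is kept). TMB = qualifying count / `panel_size_mb`.
#'
#' @param tab A filtered `mutation_table`.
#' @param panel_size_mb Interrogated exome size in megabases.
#' @param pop_af_max Population-frequency exclusion threshold (strict `>`).
#' @param samples Optional character vector fixing the sample universe, so
#'   samples with zero qualifying mutations still get a row.
#' @return data.frame with `sample_id`, `n_qualifying`, `tmb`.
#' @export
compute_tmb <- function(tab, panel_size_mb = 35, pop_af_max = 0.05,
                        samples = NULL) {
  if (panel_size_mb <= 0) stop_fmt("compute_tmb: panel_size_mb must be > 0")
  require_columns(tab, c("sample_id", "func_class"), "TMB input")
  af1 <- if ("pop_af_1000g" %in% names(tab)) tab$pop_af_1000g else NA_real_
  af2 <- if ("pop_af_exac" %in% names(tab)) tab$pop_af_exac else NA_real_
  af1[is.na(af1)] <- 0
  af2[is.na(af2)] <- 0
  qual <- tab$func_class %in% tmb_classes & af1 <= pop_af_max & af2 <= pop_af_max
  samples <- samples %||% sort(unique(tab$sample_id))
  counts <- table(factor(tab$sample_id[qual], levels = samples))
  data.frame(
    sample_id = samples,
    n_qualifying = as.integer(counts),
    tmb = as.numeric(counts) / panel_size_mb,
    stringsAsFactors = FALSE
  )
}

#' Flag hypermutated samples
#'
#' Hypermutated iff TMB >= `threshold` (inclusive; default 10 muts/Mb).
#'
#' @param tmb_results Output of [compute_tmb()].
#' @param threshold Hypermutation threshold in mutations/Mb.
#' @return The input with a logical `hypermutated` column added.
#' @export
classify_hypermutated <- function(tmb_results, threshold = 10) {
  require_columns(tmb_results, c("sample_id", "tmb"), "TMB results")
  tmb_results$hypermutated <- tmb_results$tmb >= threshold
  tmb_results
}

#' Partition hypermutated samples by MSI-H / POLE status
#'
#' Splits the hypermutated samples into four disjoint groups: MSI-H only,
#' POLE only, both, and unexplained (neither). The four counts always sum to
#' the number of hypermutated samples.
#'
#' @param hm_flags,msi_flags,pole_flags Logical vectors aligned on the same
#'   samples.
#' @return Named list `msi_only`, `pole_only`, `both`, `unexplained`, `n_hm`.
#' @export
explain_hypermutation <- function(hm_flags, msi_flags, pole_flags) {
  stopifnot(length(hm_flags) == length(msi_flags),
            length(hm_flags) == length(pole_flags))
  hm <- which(as.logical(hm_flags))
  msi <- as.logical(msi_flags)[hm]
  pole <- as.logical(pole_flags)[hm]
  msi[is.na(msi)] <- FALSE
  pole[is.na(pole)] <- FALSE
  list(
    msi_only = sum(msi & !pole),
    pole_only = sum(!msi & pole),
    both = sum(msi & pole),
    unexplained = sum(!msi & !pole),
    n_hm = length(hm)
  )
}

#' Stratified categorical summary of a cohort
#'
#' For each stratum (e.g. hypermutated vs not), tabulates the count and
#' percentage of every level of every categorical variable. Percentages are
#' rounded to `digits` decimals by the largest-remainder method, so the
#' levels of each variable sum to exactly 100 at the printed precision (the
#' convention of printed clinical characteristics tables).
#'
#' @param clinical Clinical data.frame.
#' @param strata Vector (aligned with `clinical`) defining the strata.
#' @param vars Character vector of categorical columns to summarize
#'   (default: stage, grade, site).
#' @param digits Decimals for the percentage (default 1).
#' @return data.frame with `stratum`, `variable`, `level`, `n`, `pct`.
#' @export
summarize_cohort <- function(clinical, strata,
                             vars = c("stage", "grade", "site"),
                             digits = 1) {
  stopifnot(length(strata) == nrow(clinical))
  out <- list()
  for (s in unique(strata)) {
    sub <- clinical[strata == s, , drop = FALSE]
    for (v in vars) {
      tab <- table(sub[[v]], useNA = "no")
      if (!sum(tab)) next
      out[[length(out) + 1L]] <- data.frame(
        stratum = as.character(s),
        variable = v,
        level = names(tab),
        n = as.integer(tab),
        pct = round_largest_remainder(100 * as.integer(tab) / sum(tab),
                                      digits),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
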