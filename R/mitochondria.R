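#' @title Mitochondrial copy-number score (mScore)
#' @description Purity/ploidy-corrected mitochondrial-to-nuclear read ratio
#'   as a proxy for mtDNA copy number, the rCRS position blacklist for MT
#'   somatic variants, the top-decile risk-group split, and the qPCR
#'   delta-delta-Ct path with cutoff transfer by linear regression.
#' @name mitochondria
NULL

#' Purity/ploidy corrective factor
#'
#' `R = (purity * ploidy + (1 - purity) * 2) / 2`: the average genome copies
#' per cell in the sequenced admixture (tumor fraction at tumor ploidy,
#' normal fraction diploid) relative to a diploid genome. `R = 1` whenever
#' ploidy is 2, for any purity, and tends to 1 as purity tends to 0.
#'
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Tumor ploidy, > 0.
#' @return Numeric corrective factor(s).
#' @export
purity_ploidy_factor <- function(purity, ploidy) {
  if (any(!is.finite(purity)) || any(purity <= 0 | purity > 1)) {
    stop_fmt("purity_ploidy_factor: purity must lie in (0, 1]")
  }
  if (any(!is.finite(ploidy)) || any(ploidy <= 0)) {
    stop_fmt("purity_ploidy_factor: ploidy must be positive")
  }
  (purity * ploidy + (1 - purity) * 2) / 2
}

#' Normalized mitochondrial copy score
#'
#' `m = (r_m / r_n) * R`, where `r_m` and `r_n` are reads mapped to the
#' mitochondrial and nuclear genomes and `R` the purity/ploidy factor.
#' Invariant to uniform read-count scaling; strictly increasing in `r_m`.
#'
#' @param r_m Mitochondrial-mapped read count (>= 0).
#' @param r_n Nuclear-mapped read count (> 0).
#' @param R Corrective factor from [purity_ploidy_factor()].
#' @return Numeric mScore(s).
#' @export
compute_mscore <- function(r_m, r_n, R = 1) {
  if (any(r_n <= 0)) stop_fmt("compute_mscore: r_n must be > 0")
  if (any(r_m < 0)) stop_fmt("compute_mscore: r_m must be >= 0")
  (r_m / r_n) * R
}

#' Filter mitochondrial somatic variants against the rCRS blacklist
#'
#' Removes variants at positions 310 (homopolymer-adjacent common variant)
#' and 523, 524, 3107 (encoded `N` in the rCRS to preserve historical
#' numbering); every other position is kept. Idempotent.
#'
#' @param variants data.frame with a `pos` column on rCRS numbering
#'   (1..16569).
#' @param blacklist Positions to remove (default `c(310, 523, 524, 3107)`).
#' @return The filtered data.frame.
#' @export
filter_mt_blacklist <- function(variants,
                                blacklist = c(310L, 523L, 524L, 3107L)) {
  require_columns(variants, "pos", "MT variant table")
  if (nrow(variants) &&
      (any(variants$pos < 1) || any(variants$pos > 16569))) {
    stop_fmt("filter_mt_blacklist: positions must lie in 1..16569 (rCRS)")
  }
  variants[!variants$pos %in% blacklist, , drop = FALSE]
}

#' Split the cohort into mScore-high and mScore-low groups
#'
#' Default strategy `"top_fraction"`: the `top_fraction` of samples with the
#' highest mScores (by rank; `floor(n * top_fraction)` samples, ties broken
#' by sample id for determinism) form the high group. Strategy `"scan"`
#' chooses, among decile cutoffs leaving each group at least 10% of the
#' cohort, the one maximizing the log-rank statistic for overall survival.
#'
#' @param mscores Named numeric vector of mScores (names = sample ids).
#' @param survival_df Optional data.frame `sample_id`, `os_months`,
#'   `os_event`; required for `strategy = "scan"`.
#' @param top_fraction Fraction of samples in the high group (default 0.10).
#' @param strategy `"top_fraction"` or `"scan"`.
#' @return List `group` (named character `"high"`/`"low"`), `cutoff`
#'   (smallest mScore in the high group, or `NA` when degenerate) and
#'   `strategy`.
#' @export
split_by_mscore <- function(mscores, survival_df = NULL, top_fraction = 0.10,
                            strategy = c("top_fraction", "scan")) {
  strategy <- match.arg(strategy)
  n <- length(mscores)
  if (n < 20) stop_fmt("split_by_mscore: need >= 20 samples, got %d", n)
  ids <- names(mscores) %||% as.character(seq_len(n))
  if (length(unique(mscores)) == 1L) {
    warning("split_by_mscore: all mScores equal; no split performed")
    return(list(group = stats::setNames(rep("low", n), ids), cutoff = NA_real_,
                strategy = strategy))
  }
  if (strategy == "top_fraction") {
    ord <- order(-mscores, ids)
    n_high <- floor(n * top_fraction)
    high_ids <- ids[ord[seq_len(n_high)]]
    group <- stats::setNames(ifelse(ids %in% high_ids, "high", "low"), ids)
    cutoff <- min(mscores[high_ids])
  } else {
    if (is.null(survival_df)) stop_fmt("split_by_mscore: scan needs survival data")
    require_columns(survival_df, c("sample_id", "os_months", "os_event"),
                    "survival table")
    os <- survival_df[match(ids, survival_df$sample_id), , drop = FALSE]
    cands <- stats::quantile(mscores, probs = seq(0.1, 0.9, by = 0.1),
                             names = FALSE, type = 7)
    best <- NULL
    for (cut in unique(cands)) {
      grp <- mscores > cut
      if (mean(grp) < 0.10 || mean(!grp) < 0.10) next
      sd <- survival::survdiff(
        survival::Surv(os$os_months, os$os_event) ~ grp)
      if (is.null(best) || sd$chisq > best$chisq) {
        best <- list(chisq = sd$chisq, cut = cut)
      }
    }
    if (is.null(best)) stop_fmt("split_by_mscore: no admissible scan cutoff")
    group <- stats::setNames(ifelse(mscores > best$cut, "high", "low"), ids)
    cutoff <- best$cut
  }
  list(group = group, cutoff = cutoff, strategy = strategy)
}

#' Relative mtDNA copies from qPCR by the 2^-ddCt method
#'
#' Per sample, `dCt = ct_dloop - ct_control`; `ddCt = dCt - dCt(reference)`;
#' relative copies `= 2^-ddCt`. The reference (calibrator) defaults to the
#' sample with the median dCt (lower of the middle pair for even n).
#'
#' @param ct data.frame with `sample_id`, `ct_control`, `ct_dloop`.
#' @param reference Sample id of the calibrator, or `NULL` for the median-dCt
#'   sample.
#' @return data.frame `sample_id`, `dct`, `ddct`, `relative_copies`.
#' @export
qpcr_relative_copies <- function(ct, reference = NULL) {
  require_columns(ct, c("sample_id", "ct_control", "ct_dloop"), "Ct table")
  if (any(!is.finite(ct$ct_control)) || any(!is.finite(ct$ct_dloop))) {
    stop_fmt("qpcr_relative_copies: Cts must be finite")
  }
  dct <- ct$ct_dloop - ct$ct_control
  if (is.null(reference)) {
    ord <- order(dct, ct$sample_id)
    reference <- ct$sample_id[ord[ceiling(length(dct) / 2)]]
  }
  i <- match(reference, ct$sample_id)
  if (is.na(i)) stop_fmt("qpcr_relative_copies: reference sample %s not found",
                         reference)
  ddct <- dct - dct[i]
  data.frame(sample_id = ct$sample_id, dct = dct, ddct = ddct,
             relative_copies = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Transfer the WES mScore cutoff to the qPCR scale
#'
#' Ordinary least squares of the qPCR relative-copy value on the WES mScore
#' over paired samples; the qPCR-scale cutoff is the fitted value at the WES
#' cutoff.
#'
#' @param wes_mscores,qpcr_values Paired numeric vectors (>= 10 pairs).
#' @param wes_cutoff WES-scale cutoff to transfer.
#' @return List `cutoff_qpcr`, `slope`, `intercept`, `pearson_r`, `n`.
#' @export
transfer_cutoff <- function(wes_mscores, qpcr_values, wes_cutoff) {
  stopifnot(length(wes_mscores) == length(qpcr_values))
  ok <- is.finite(wes_mscores) & is.finite(qpcr_values)
  x <- wes_mscores[ok]; y <- qpcr_values[ok]
  if (length(x) < 10) stop_fmt("transfer_cutoff: need >= 10 paired samples")
  if (stats::sd(x) == 0) stop_fmt("transfer_cutoff: WES mScores have zero variance")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(cutoff_qpcr = unname(co[1] + co[2] * wes_cutoff),
       slope = unname(co[2]), intercept = unname(co[1]),
       pearson_r = stats::cor(x, y), n = length(x))
}

#' Assemble per-sample mitochondrial profiles
#'
#' Convenience wrapper: computes `R` and the mScore from a read-count table.
#'
#' @param counts data.frame `sample_id`, `r_m`, `r_n`, `purity`, `ploidy`.
#' @return The input with `R` and `mscore` columns added.
#' @export
mito_profiles <- function(counts) {
  require_columns(counts, c("sample_id", "r_m", "r_n", "purity", "ploidy"),
                  "MT read-count table")
  counts$R <- purity_ploidy_factor(counts$purity, counts$ploidy)
  counts$mscore <- compute_mscore(counts$r_m, counts$r_n, counts$R)
  counts
}
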