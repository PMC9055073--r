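#' @title Mutational-signature refitting
#' @description Tabulation of per-sample 96-context catalogs, exome-to-genome
#'   abundance normalization, and LASSO-penalized non-negative refitting of
#'   each catalog against a reference signature matrix (COSMIC-v2 style).
#'   New signatures are never extracted; activities of known signatures are
#'   estimated.
#' @name signatures
NULL

# functional classes eligible for signature tabulation (SNVs only in practice)
signature_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                       "Nonstop_Mutation", "RNA", "Silent", "Splice_Site",
                       "Translation_Start_Site")

#' Tabulate per-sample 96-context catalogs
#'
#' Each eligible SNV increments exactly one of the 96 substitution classes;
#' purine-centered records are counted on the reverse-complement strand.
#' Records whose context contains an `N` (or is otherwise unresolvable) are
#' skipped and counted in `attr(, "n_skipped")`, with a warning when any are
#' skipped.
#'
#' @param tab A `mutation_table`.
#' @param classes Functional classes to include (default
#'   [signature_classes]); pass `NULL` to include every SNV.
#' @param samples Optional fixed sample universe.
#' @return Integer matrix samples x 96 (columns [sbs_classes()]).
#' @export
tabulate_contexts <- function(tab, classes = signature_classes,
                              samples = NULL) {
  require_columns(tab, c("sample_id", "ref", "alt", "trinuc_context"),
                  "context tabulation input")
  if (!is.null(classes)) {
    tab <- tab[tab$func_class %in% classes, , drop = FALSE]
  }
  is_snv <- !is.na(tab$ref) & !is.na(tab$alt) &
    nchar(tab$ref) == 1L & nchar(tab$alt) == 1L &
    tab$ref %in% c("A", "C", "G", "T") & tab$alt %in% c("A", "C", "G", "T")
  snvs <- tab[is_snv, , drop = FALSE]
  cls <- sbs_class_of(snvs$ref, snvs$alt, snvs$trinuc_context)
  n_skipped <- sum(is.na(cls))
  if (n_skipped > 0) {
    warning(sprintf("tabulate_contexts: skipped %d SNV(s) with unresolvable context",
                    n_skipped))
  }
  keep <- !is.na(cls)
  samples <- samples %||% sort(unique(tab$sample_id))
  m <- table(factor(snvs$sample_id[keep], levels = samples),
             factor(cls[keep], levels = sbs_classes()))
  m <- matrix(as.integer(m), nrow = length(samples),
              dimnames = list(samples, sbs_classes()))
  attr(m, "n_skipped") <- n_skipped
  m
}

#' Identity genome/exome trinucleotide abundance ratios
#'
#' A named 32-vector of ones over [pyrimidine_trinucs()], the neutral default
#' for [normalize_exome2genome()]. Supply your own ratios (genome abundance /
#' exome abundance per flanking trinucleotide) to correct exome catalogs to
#' genome scale; a synthetic example ships in
#' `inst/extdata/synthetic_trinuc_ratio.tsv`.
#'
#' @return Named numeric vector of length 32.
#' @export
identity_trinuc_ratio <- function() {
  stats::setNames(rep(1, 32), pyrimidine_trinucs())
}

#' Read a trinucleotide abundance ratio table
#' @param path TSV with columns `trinuc` and `ratio` covering the 32
#'   pyrimidine-centered trinucleotides.
#' @return Named numeric vector of length 32.
#' @export
read_trinuc_ratio <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("trinuc", "ratio"), "trinucleotide ratio table")
  if (!setequal(df$trinuc, pyrimidine_trinucs())) {
    stop_fmt("trinucleotide ratio table must cover the 32 pyrimidine-centered trinucleotides")
  }
  r <- stats::setNames(df$ratio, df$trinuc)[pyrimidine_trinucs()]
  r
}

#' Rescale a context catalog from exome to genome trinucleotide abundance
#'
#' Multiplies each of the 96 bins by the genome/exome abundance ratio of its
#' flanking trinucleotide ("exome2genome" normalization). Applying the
#' element-wise inverse ratio undoes the adjustment exactly.
#'
#' @param catalog Numeric vector of length 96, or a samples x 96 matrix.
#' @param ratio Named 32-vector over [pyrimidine_trinucs()]; entries must be
#'   strictly positive.
#' @return Adjusted catalog, same shape as the input.
#' @export
normalize_exome2genome <- function(catalog, ratio = identity_trinuc_ratio()) {
  if (is.null(names(ratio)) || !setequal(names(ratio), pyrimidine_trinucs())) {
    stop_fmt("normalize_exome2genome: ratio must be named over the 32 trinucleotides")
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop_fmt("normalize_exome2genome: ratios must be positive and finite")
  }
  per_class <- unname(ratio[trinuc_of_class(sbs_classes())])
  if (is.matrix(catalog)) {
    stopifnot(ncol(catalog) == 96L)
    sweep(catalog, 2, per_class, "*")
  } else {
    stopifnot(length(catalog) == 96L)
    catalog * per_class
  }
}

#' LASSO refitting of signature activities
#'
#' For each sample with at least `min_snvs` mutations in its catalog, solves a
#' non-negative, intercept-free LASSO regression of the (optionally
#' exome2genome-normalized) 96-bin mutation fraction profile on the reference
#' signature matrix. The penalty is chosen per sample by `nfolds`-fold
#' cross-validation over glmnet's log-spaced grid with the one-standard-error
#' rule (folds assigned deterministically by context index). Fitted
#' activities are rescaled to mutation counts and values below
#' `floor_frac * total` are set to exactly 0 so downstream prevalence rules
#' have a crisp notion of "present". Samples below `min_snvs` (or with empty
#' catalogs) are excluded from fitting and flagged, not fitted with zeros
#' silently.
#'
#' @param catalogs samples x 96 count matrix from [tabulate_contexts()].
#' @param reference 96 x K signature matrix, columns summing to 1.
#' @param min_snvs Minimum catalog size to fit (default 20).
#' @param ratio Optional trinucleotide abundance ratio applied before fitting.
#' @param nfolds Cross-validation folds (default 5).
#' @param floor_frac Activity floor as a fraction of the catalog total.
#' @return List with `exposures` (samples x K matrix of mutation counts,
#'   excluded samples as `NA` rows), `fitted` (logical per sample), and
#'   `n_snvs` (catalog totals).
#' @export
fit_exposures_lasso <- function(catalogs, reference, min_snvs = 20,
                                ratio = NULL, nfolds = 5, floor_frac = 1e-6) {
  stopifnot(is.matrix(catalogs), ncol(catalogs) == 96L,
            is.matrix(reference), nrow(reference) == 96L)
  if (max(abs(colSums(reference) - 1)) > 1e-6) {
    stop_fmt("fit_exposures_lasso: reference columns must sum to 1")
  }
  if (!is.null(ratio)) catalogs <- normalize_exome2genome(catalogs, ratio)
  n <- nrow(catalogs)
  K <- ncol(reference)
  exposures <- matrix(NA_real_, n, K,
                      dimnames = list(rownames(catalogs), colnames(reference)))
  totals <- rowSums(catalogs)
  fitted <- totals >= min_snvs
  foldid <- rep_len(seq_len(nfolds), 96L)  # deterministic fold assignment
  for (i in which(fitted)) {
    y <- catalogs[i, ] / totals[i]
    cv <- glmnet::cv.glmnet(reference, y, lower.limits = 0, intercept = FALSE,
                            standardize = FALSE, foldid = foldid)
    w <- as.numeric(stats::coef(cv, s = "lambda.1se"))[-1]  # drop intercept slot
    w[w < 0] <- 0
    expo <- w * totals[i]
    expo[expo < floor_frac * totals[i]] <- 0
    exposures[i, ] <- expo
  }
  list(exposures = exposures, fitted = fitted, n_snvs = totals)
}

#' Retain signatures by cohort prevalence
#'
#' Keeps signatures whose activity is nonzero in strictly more than
#' `min_prevalence` of the fitted samples.
#'
#' @param fit Result of [fit_exposures_lasso()], or a samples x K exposure
#'   matrix (NA rows treated as unfitted).
#' @param min_prevalence Prevalence threshold (strict `>`, default 0.01).
#' @return Character vector of retained signature names; prevalences in
#'   `attr(, "prevalence")`.
#' @export
filter_signature_prevalence <- function(fit, min_prevalence = 0.01) {
  exposures <- if (is.list(fit)) fit$exposures else fit
  fitted_rows <- stats::complete.cases(exposures)
  sub <- exposures[fitted_rows, , drop = FALSE]
  if (!nrow(sub)) stop_fmt("filter_signature_prevalence: no fitted samples")
  prevalence <- colMeans(sub > 0)
  kept <- colnames(sub)[prevalence > min_prevalence]
  attr(kept, "prevalence") <- prevalence
  kept
}

#' Deterministic synthetic signature reference
#'
#' Generates a synthetic 96 x K reference matrix of well-separated mutational
#' signatures (each concentrated on a handful of context classes over a weak
#' uniform background). This is a stand-in for a real reference catalog such
#' as COSMIC v2 — it is synthetic and carries no biological meaning — and
#' exists so that the refitting and simulation machinery can be exercised and
#' tested offline. For real analyses read an actual reference with
#' [read_signature_reference()].
#'
#' @param n_signatures Number of signatures (default 10).
#' @param n_peaks Contexts carrying concentrated mass per signature.
#' @param seed RNG seed; the default yields the reference used throughout the
#'   package's examples and simulator defaults.
#' @return 96 x K matrix, columns `SigSyn1..K` summing to 1.
#' @export
synthetic_signature_reference <- function(n_signatures = 10, n_peaks = 6,
                                          seed = 760123) {
  with_preserved_seed(seed, {
    ref <- matrix(0, 96, n_signatures,
                  dimnames = list(sbs_classes(),
                                  paste0("SigSyn", seq_len(n_signatures))))
    for (j in seq_len(n_signatures)) {
      w <- stats::runif(96) * 0.15
      peaks <- sample.int(96, n_peaks)
      w[peaks] <- w[peaks] + stats::rgamma(n_peaks, shape = 3, rate = 0.5)
      ref[, j] <- w / sum(w)
    }
    ref
  })
}

# run expr under a temporary seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
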