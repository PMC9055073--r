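#' @title Consensus-NMF genomic subtyping
#' @description Clusters non-hypermutated samples on concatenated signature
#'   exposures (min-max scaled) and binary lesion indicators by consensus
#'   non-negative matrix factorization, then names clusters HM / CIN-HR /
#'   CIN-LR / GS using alteration load and 10q11.21 amplification enrichment.
#' @name subtyping
NULL

#' Convert lesion calls to a binary sample-by-lesion matrix
#'
#' @param calls Lesion call data.frame ([read_lesion_matrix()]).
#' @param samples Sample universe (rows of the output).
#' @return Logical-as-integer matrix samples x lesion labels
#'   (`amp_<id>` / `del_<id>`).
#' @export
lesion_indicator_matrix <- function(calls, samples) {
  labels <- sort(unique(paste0(calls$direction, "_", calls$lesion_id)))
  m <- matrix(0L, length(samples), length(labels),
              dimnames = list(samples, labels))
  if (nrow(calls)) {
    lab <- paste0(calls$direction, "_", calls$lesion_id)
    keep <- calls$sample_id %in% samples
    m[cbind(match(calls$sample_id[keep], samples),
            match(lab[keep], labels))] <- 1L
  }
  m
}

#' Build the clustering feature matrix
#'
#' Concatenates per-sample signature exposures (continuous block) and lesion
#' indicators (binary block). Exposures are first converted to per-sample
#' fractions (`as_fractions = TRUE`, the default) so the clustering sees
#' relative signature composition rather than total burden — burden is
#' already handled by the hypermutation gate — then min-max scaled to
#' \[0,1\] per column. Hypermutated samples are excluded before clustering
#' so the dominant TMB axis cannot swamp the factorization; samples missing
#' either block (e.g. unfitted exposures) are dropped and reported via
#' `attr(, "dropped")`. Zero-variance columns are removed.
#'
#' @param exposures samples x signatures matrix (NA rows = unfitted).
#' @param lesions Lesion call data.frame.
#' @param hm_flags Named logical vector of hypermutation status per sample.
#' @param min_samples Minimum samples that must remain (default 6, the top of
#'   the default K range).
#' @param as_fractions Normalize each exposure row to sum to 1 before
#'   scaling (default `TRUE`).
#' @return Numeric matrix (entries in \[0,1\]) with attributes `dropped`
#'   (sample ids removed for missing data) and `n_continuous` (columns in the
#'   exposure block).
#' @export
build_feature_matrix <- function(exposures, lesions, hm_flags,
                                 min_samples = 6, as_fractions = TRUE) {
  samples_all <- names(hm_flags)
  if (is.null(samples_all)) stop_fmt("hm_flags must be named by sample id")
  non_hm <- samples_all[!hm_flags]
  have_expo <- rownames(exposures)[stats::complete.cases(exposures)]
  keep <- intersect(non_hm, have_expo)
  dropped <- setdiff(non_hm, keep)
  if (length(keep) < min_samples) {
    stop_fmt("build_feature_matrix: only %d usable samples (need >= %d)",
             length(keep), min_samples)
  }
  cont <- exposures[keep, , drop = FALSE]
  if (as_fractions) {
    tot <- rowSums(cont)
    cont <- cont / ifelse(tot > 0, tot, 1)
  }
  rng <- apply(cont, 2, function(x) diff(range(x)))
  cont <- cont[, rng > 0, drop = FALSE]
  cont <- apply(cont, 2, function(x) (x - min(x)) / diff(range(x)))
  lm <- lesion_indicator_matrix(lesions, keep)
  lm <- lm[, apply(lm, 2, function(x) diff(range(x))) > 0, drop = FALSE]
  out <- cbind(cont, lm)
  attr(out, "dropped") <- dropped
  attr(out, "n_continuous") <- ncol(cont)
  out
}

# single NMF fit: V (n x p) ~ W (n x k) H (k x p), Frobenius loss,
# multiplicative updates from random uniform init
nmf_fit <- function(V, k, max_iter = 2000, tol = 1e-6) {
  n <- nrow(V); p <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(n * k), n, k)
  H <- matrix(stats::runif(k * p), k, p)
  err_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_old) && abs(err_old - err) <= tol * max(err_old, eps)) {
        converged <- TRUE
        break
      }
      err_old <- err
    }
  }
  list(W = W, H = H, converged = converged)
}

#' Consensus non-negative matrix factorization
#'
#' For each K in `k_range`, runs `n_runs` NMF factorizations (Frobenius loss,
#' multiplicative updates, random non-negative initializations seeded
#' deterministically from `seed`). Each run assigns every sample to its
#' dominant basis component; the consensus matrix holds the fraction of runs
#' in which each sample pair co-clustered. Final labels come from
#' average-linkage hierarchical clustering of 1 - consensus cut at K; the
#' cophenetic correlation of that dendrogram against 1 - consensus measures
#' cluster stability. Non-convergent runs are counted but still used.
#'
#' @param features Non-negative samples x features matrix
#'   ([build_feature_matrix()]).
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param n_runs Factorizations per K (default 10).
#' @param seed Integer seed driving all runs.
#' @param max_iter,tol NMF stopping rule.
#' @return A list of class `consensus_nmf`, one entry per K, each with
#'   `consensus`, `labels`, `cophenetic`, `connectivity` (mean within-cluster
#'   consensus) and `n_nonconverged`.
#' @export
consensus_nmf <- function(features, k_range = 2:6, n_runs = 10, seed = 1,
                          max_iter = 2000, tol = 1e-6) {
  if (any(features < 0)) stop_fmt("consensus_nmf: matrix must be non-negative")
  n <- nrow(features)
  if (n < max(k_range)) {
    stop_fmt("consensus_nmf: %d samples cannot support K = %d", n, max(k_range))
  }
  # samples with byte-identical feature rows must always co-cluster: labels
  # are taken from the mean basis row of each distinct profile
  row_key <- apply(features, 1, paste, collapse = "\r")
  key_idx <- match(row_key, unique(row_key))
  out <- list()
  for (k in k_range) {
    C <- matrix(0, n, n, dimnames = list(rownames(features), rownames(features)))
    n_bad <- 0L
    for (r in seq_len(n_runs)) {
      run_seed <- (as.integer(seed) %% 100000L) * 10000L + k * 1000L + r
      fit <- with_preserved_seed(run_seed,
                                 nmf_fit(features, k, max_iter, tol))
      if (!fit$converged) n_bad <- n_bad + 1L
      W_grp <- apply(fit$W, 2, function(col) tapply(col, key_idx, mean))
      if (is.null(dim(W_grp))) W_grp <- matrix(W_grp, nrow = 1)
      grp_lab <- apply(W_grp, 1, which.max)
      lab <- grp_lab[key_idx]
      C <- C + outer(lab, lab, "==")
    }
    C <- C / n_runs
    diag(C) <- 1
    hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
    labels <- stats::cutree(hc, k = k)
    coph <- suppressWarnings(
      stats::cor(stats::cophenetic(hc), stats::as.dist(1 - C)))
    if (is.na(coph)) coph <- 1  # degenerate: all distances equal
    same <- outer(labels, labels, "==")
    connectivity <- mean(C[same & upper.tri(C)])
    out[[as.character(k)]] <- list(
      k = k, consensus = C, labels = labels, cophenetic = coph,
      connectivity = connectivity, n_nonconverged = n_bad
    )
  }
  structure(out, class = "consensus_nmf")
}

#' Choose the number of clusters
#'
#' Returns the K maximizing the cophenetic coefficient; ties go to the
#' smaller K. An explicit `override` (e.g. the published K = 3) wins
#' regardless of the metric.
#'
#' @param results A `consensus_nmf` object.
#' @param override Optional fixed K.
#' @return Integer K.
#' @export
select_k <- function(results, override = NULL) {
  ks <- vapply(results, `[[`, numeric(1), "k")
  if (!is.null(override)) {
    if (!override %in% ks) stop_fmt("select_k: override K=%d was not run", override)
    return(as.integer(override))
  }
  if (length(results) < 2) stop_fmt("select_k: need results for >= 2 values of K")
  coph <- vapply(results, `[[`, numeric(1), "cophenetic")
  as.integer(ks[which.max(coph)])  # ks ascending, so ties go to smaller K
}

#' Name clusters as genomic subtypes
#'
#' Hypermutated samples are labelled `HM` regardless of clustering input.
#' Among the three non-HM clusters, the one with the lowest alteration load
#' (mean feature-matrix row sum) is `GS`; of the remaining two CIN clusters,
#' the one with the higher fraction of 10q11.21 amplification is `CIN-HR`,
#' the other `CIN-LR` (equal fractions fall back to the higher-load cluster
#' as CIN-HR). Naming depends only on these statistics, never on cluster
#' indices or sample order.
#'
#' @param labels Named integer cluster labels for the non-HM samples (3
#'   clusters).
#' @param hm_flags Named logical hypermutation flags for all samples.
#' @param lesions Lesion call data.frame (source of amplification flags).
#' @param features Feature matrix used for clustering (load statistic).
#' @param lesion_of_interest Cytoband whose amplification separates the CIN
#'   clusters (default `"10q11.21"`).
#' @return data.frame `sample_id`, `subtype` covering every sample in
#'   `hm_flags`.
#' @export
assign_subtypes <- function(labels, hm_flags, lesions, features,
                            lesion_of_interest = "10q11.21") {
  cl <- sort(unique(labels))
  if (length(cl) != 3) {
    stop_fmt("assign_subtypes: expected 3 non-HM clusters, found %d", length(cl))
  }
  load <- vapply(cl, function(g) {
    mean(rowSums(features[names(labels)[labels == g], , drop = FALSE]))
  }, numeric(1))
  amp_samples <- unique(lesions$sample_id[lesions$direction == "amp" &
                                          lesions$lesion_id == lesion_of_interest])
  amp_frac <- vapply(cl, function(g) {
    mean(names(labels)[labels == g] %in% amp_samples)
  }, numeric(1))
  gs <- cl[which.min(load)]
  cin <- setdiff(cl, gs)
  if (amp_frac[match(cin[1], cl)] == amp_frac[match(cin[2], cl)]) {
    hr <- cin[which.max(load[match(cin, cl)])]
  } else {
    hr <- cin[which.max(amp_frac[match(cin, cl)])]
  }
  lr <- setdiff(cin, hr)
  name_of <- stats::setNames(c("GS", "CIN-HR", "CIN-LR"),
                             as.character(c(gs, hr, lr)))
  samples <- names(hm_flags)
  subtype <- ifelse(hm_flags, "HM",
                    unname(name_of[as.character(labels[samples])]))
  data.frame(sample_id = samples, subtype = unname(subtype),
             stringsAsFactors = FALSE)
}

#' Map an externally-subtyped cohort onto the four subtypes
#'
#' Given coarse per-sample labels `GS` / `CIN` / `HM` (e.g. from a published
#' classification of an external cohort) and a 10q11.21 amplification flag,
#' splits `CIN` into `CIN-HR` (amplified: at least one gene in the cytoband
#' amplified) and `CIN-LR` (not); `GS` and `HM` pass through.
#'
#' @param labels Character vector in `{GS, CIN, HM}`.
#' @param amp_10q11_21 Logical vector aligned with `labels`.
#' @return Character vector over `{HM, CIN-HR, CIN-LR, GS}`.
#' @export
map_external_cohort <- function(labels, amp_10q11_21) {
  stopifnot(length(labels) == length(amp_10q11_21))
  bad <- setdiff(unique(labels), c("GS", "CIN", "HM"))
  if (length(bad)) {
    stop_fmt("map_external_cohort: unknown label(s): %s", paste(bad, collapse = ", "))
  }
  ifelse(labels == "CIN",
         ifelse(amp_10q11_21, "CIN-HR", "CIN-LR"),
         labels)
}
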