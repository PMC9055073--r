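#' @title Pathway rollup, driver consensus and clinical associations
#' @description Rolls per-gene alterations up to pathway oncogenic/VUS/Wt
#'   status, aggregates multi-tool driver-gene lists into a high-confidence
#'   consensus set, runs Kaplan-Meier/log-rank and covariate-adjusted Cox
#'   survival analyses, and builds the pairwise clinical-molecular
#'   association matrix with Benjamini-Hochberg correction.
#' @name clinical_assoc
NULL

#' Read pathway definitions from YAML
#'
#' Document shape: `pathway_name: {genes: {GENE: role, ...}}` or
#' `pathway_name: [GENE, ...]` (roles default `unknown`).
#'
#' @param path YAML file path.
#' @return Named list of data.frames with `gene` and `role`.
#' @export
read_pathways <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(p) {
    if (is.list(p) && !is.null(p$genes)) {
      g <- p$genes
      if (is.list(g)) {
        data.frame(gene = names(g), role = unlist(g, use.names = FALSE),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(gene = g, role = "unknown", stringsAsFactors = FALSE)
      }
    } else {
      data.frame(gene = unlist(p), role = "unknown", stringsAsFactors = FALSE)
    }
  })
}

#' Roll alterations up to pathway oncogenic/VUS/Wt status
#'
#' For each sample and pathway: `oncogenic` if any member-gene alteration
#' (mutation or copy-number event) is annotated oncogenic; otherwise `vus`
#' if any member-gene alteration exists (annotated VUS or unknown);
#' otherwise `wt`. Precedence oncogenic > vus > wt, so adding an oncogenic
#' alteration can never downgrade a status. Genes absent from every pathway
#' are ignored.
#'
#' @param mutations `mutation_table` with `gene` and `oncogenicity`.
#' @param pathways Named list of data.frames with `gene` (see
#'   [read_pathways()]).
#' @param cnv_calls Optional data.frame `sample_id`, `gene`, `oncogenicity`
#'   for copy-number events.
#' @param samples Optional sample universe (default: all seen).
#' @return data.frame `sample_id`, `pathway`, `status`.
#' @export
rollup_pathway_status <- function(mutations, pathways, cnv_calls = NULL,
                                  samples = NULL) {
  require_columns(mutations, c("sample_id", "gene", "oncogenicity"),
                  "pathway rollup input")
  alt <- data.frame(sample_id = mutations$sample_id, gene = mutations$gene,
                    oncogenicity = mutations$oncogenicity,
                    stringsAsFactors = FALSE)
  if (!is.null(cnv_calls)) {
    require_columns(cnv_calls, c("sample_id", "gene", "oncogenicity"),
                    "CNV calls")
    alt <- rbind(alt, cnv_calls[, c("sample_id", "gene", "oncogenicity")])
  }
  samples <- samples %||% sort(unique(alt$sample_id))
  out <- list()
  for (pw in names(pathways)) {
    members <- pathways[[pw]]$gene
    sub <- alt[alt$gene %in% members, , drop = FALSE]
    onc <- unique(sub$sample_id[sub$oncogenicity == "oncogenic"])
    any_alt <- unique(sub$sample_id)
    status <- ifelse(samples %in% onc, "oncogenic",
              ifelse(samples %in% any_alt, "vus", "wt"))
    out[[pw]] <- data.frame(sample_id = samples, pathway = pw,
                            status = status, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' High-confidence significantly-mutated-gene consensus
#'
#' Keeps genes reported by at least `min_tools` of the supplied per-tool
#' gene lists. Duplicates within a list and list order do not matter.
#'
#' @param tool_lists Named list of character vectors (one per tool).
#' @param min_tools Minimum supporting tools (default 2).
#' @return data.frame `gene`, `n_tools`, `tools` (comma-separated), sorted by
#'   support then name; only genes meeting the threshold.
#' @export
smg_consensus <- function(tool_lists, min_tools = 2) {
  if (length(tool_lists) < 2) stop_fmt("smg_consensus: need >= 2 tool lists")
  if (is.null(names(tool_lists))) {
    names(tool_lists) <- paste0("tool", seq_along(tool_lists))
  }
  tool_lists <- lapply(tool_lists, unique)
  genes <- sort(unique(unlist(tool_lists)))
  support <- vapply(genes, function(g) {
    sum(vapply(tool_lists, function(l) g %in% l, logical(1)))
  }, integer(1))
  which_tools <- vapply(genes, function(g) {
    paste(names(tool_lists)[vapply(tool_lists, function(l) g %in% l,
                                   logical(1))], collapse = ",")
  }, character(1))
  keep <- support >= min_tools
  out <- data.frame(gene = genes[keep], n_tools = support[keep],
                    tools = which_tools[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$n_tools, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimates and log-rank comparison
#'
#' Product-limit survival per group and the log-rank test across groups.
#' Groups in which every subject is censored get `NA` median survival and are
#' flagged.
#'
#' @param times Follow-up times (e.g. months).
#' @param events Logical/0-1 event indicators.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List of class `km_result`: `table` (per group: n, events, median),
#'   `chisq`, `df`, `p`, `all_censored` (group names), plus the `survfit`
#'   object in `fit`.
#' @export
km_logrank <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2) {
    stop_fmt("km_logrank: need >= 2 non-empty groups, got %d", nlevels(groups))
  }
  s <- survival::Surv(times, as.integer(events))
  fit <- survival::survfit(s ~ groups)
  sd <- survival::survdiff(s ~ groups)
  p <- stats::pchisq(sd$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  smry <- summary(fit)$table
  if (is.null(dim(smry))) smry <- t(smry)
  tab <- data.frame(
    group = sub("^groups=", "", rownames(smry)),
    n = smry[, "records"], events = smry[, "events"],
    median = smry[, "median"], stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  all_cens <- tab$group[tab$events == 0]
  structure(list(table = tab, chisq = unname(sd$chisq),
                 df = nlevels(groups) - 1, p = p,
                 all_censored = all_cens, fit = fit),
            class = "km_result")
}

#' Covariate-adjusted Cox proportional-hazards model
#'
#' Fits `Surv(times, events) ~ exposure + covariates` by partial likelihood
#' with Efron handling of ties. Character/factor covariates (e.g. stage,
#' grade) enter as indicator terms. Rows with missing values are dropped and
#' counted. A constant exposure (no contrast to estimate) is an error.
#'
#' @param times,events Survival outcome vectors.
#' @param exposure Vector of the exposure of interest (numeric or 2-level).
#' @param covariates data.frame of adjustment covariates (may be NULL).
#' @return List of class `cox_result`: `table` (term, hr, ci_lower, ci_upper,
#'   p), `n_used`, `n_dropped`, and the `coxph` fit.
#' @export
cox_adjusted <- function(times, events, exposure, covariates = NULL) {
  df <- data.frame(.time = times, .event = as.integer(events),
                   exposure = exposure)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (length(unique(df$exposure)) < 2) {
    stop_fmt("cox_adjusted: exposure is constant; hazard ratio undefined")
  }
  rhs <- paste(setdiff(names(df), c(".time", ".event")), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(!is.finite(stats::coef(fit)))) {
    stop_fmt("cox_adjusted: fit did not converge (non-finite coefficients)")
  }
  sm <- summary(fit)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    hr = sm$conf.int[, "exp(coef)"],
    ci_lower = sm$conf.int[, "lower .95"],
    ci_upper = sm$conf.int[, "upper .95"],
    p = sm$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, n_used = nrow(df), n_dropped = n_dropped,
                 fit = fit),
            class = "cox_result")
}

#' Pairwise clinical-molecular association matrix
#'
#' Tests every pair of supplied variables: categorical x categorical by
#' chi-square (Yates-corrected for 2x2) or Fisher's exact test when any
#' expected cell count is below 5; continuous x binary by two-sided t-test;
#' continuous x continuous by Pearson correlation test. Constant variables
#' are skipped and flagged. Benjamini-Hochberg adjusted p-values are reported
#' alongside the raw p and `-log10(p)`.
#'
#' @param data data.frame of variables (factors/characters/logicals treated
#'   as categorical, numerics as continuous).
#' @return data.frame per tested pair: `var1`, `var2`, `test`, `statistic`,
#'   `p`, `neglog10_p`, `p_adj`, `skipped`.
#' @export
association_network <- function(data) {
  vars <- names(data)
  is_cat <- vapply(data, function(x) !is.numeric(x), logical(1))
  res <- list()
  for (i in seq_along(vars)) {
    for (j in seq_len(i - 1L)) {
      x <- data[[vars[i]]]; y <- data[[vars[j]]]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      row <- data.frame(var1 = vars[j], var2 = vars[i], test = NA_character_,
                        statistic = NA_real_, p = NA_real_, skipped = FALSE,
                        stringsAsFactors = FALSE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) {
        row$skipped <- TRUE
        res[[length(res) + 1L]] <- row
        next
      }
      if (is_cat[i] && is_cat[j]) {
        tab <- table(x, y)
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          ft <- stats::fisher.test(tab, simulate.p.value = nrow(tab) > 2 &&
                                     ncol(tab) > 2, B = 10000)
          row$test <- "fisher"
          row$p <- ft$p.value
        } else {
          ct <- stats::chisq.test(tab,
                                  correct = nrow(tab) == 2 && ncol(tab) == 2)
          row$test <- "chisq"
          row$statistic <- unname(ct$statistic)
          row$p <- ct$p.value
        }
      } else if (!is_cat[i] && !is_cat[j]) {
        tt <- stats::cor.test(x, y)
        row$test <- "pearson"
        row$statistic <- unname(tt$statistic)
        row$p <- tt$p.value
      } else {
        num <- if (is_cat[i]) y else x
        cat_ <- as.factor(if (is_cat[i]) x else y)
        if (nlevels(cat_) != 2) {
          # collapse by one-way ANOVA when the categorical has > 2 levels
          row$test <- "anova"
          fit <- stats::aov(num ~ cat_)
          an <- summary(fit)[[1]]
          row$statistic <- an[["F value"]][1]
          row$p <- an[["Pr(>F)"]][1]
        } else {
          tt <- stats::t.test(num ~ cat_)
          row$test <- "t"
          row$statistic <- unname(tt$statistic)
          row$p <- tt$p.value
        }
      }
      res[[length(res) + 1L]] <- row
    }
  }
  out <- do.call(rbind, res)
  out$neglog10_p <- -log10(out$p)
  out$p_adj <- NA_real_
  tested <- !out$skipped
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out
}
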