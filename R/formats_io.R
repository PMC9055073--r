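#' @title Tabular input/output for the profiling pipeline
#' @description Readers and writers for the MAF-dialect mutation table, the
#'   GISTIC-style lesion-by-sample matrix, the clinical table, the 96-context
#'   signature reference, and the analysis configuration. Coordinates are
#'   1-based and fully closed throughout, matching the MAF convention.
#' @name formats_io
NULL

.mutation_required <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                        "func_class", "vaf", "depth", "alt_reads",
                        "trinuc_context")
.mutation_optional <- c("pop_af_1000g", "pop_af_exac", "oncogenicity",
                        "n_neoantigens", "is_silent")

#' Read a MAF-dialect somatic mutation table
#'
#' Reads a tab-delimited per-variant table. Column names may be remapped via
#' `dialect`, a named character vector `c(canonical = "file_column")`.
#' Trinucleotide contexts are normalized to the pyrimidine-centered convention
#' on read: when the reference allele of an SNV is a purine, ref, alt and
#' context are all reverse-complemented (the 96-class assignment is invariant
#' to this). Unknown functional class strings are kept verbatim. Missing
#' population allele frequencies are kept as `NA` and treated as 0 (variant
#' retained) by downstream filters: absence from a population database is
#' itself evidence of rarity.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return A `data.frame` with one row per variant (class
#'   `c("mutation_table", "data.frame")`).
#' @export
read_mutation_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_fmt("mutation table not found: %s", path)
  # read everything as character so allele columns like "T" are never
  # coerced to logicals; numeric columns are converted explicitly below
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  require_columns(raw, .mutation_required, "mutation table")
  for (col in .mutation_optional) {
    if (!col %in% names(raw)) {
      raw[[col]] <- if (col == "oncogenicity") "unknown"
                    else if (col == "is_silent") NA
                    else NA_real_
    }
  }
  vaf_num <- suppressWarnings(as.numeric(raw$vaf))
  bad <- which(!is.na(raw$vaf) & is.na(vaf_num))
  if (length(bad)) {
    stop_fmt("mutation table: non-numeric VAF at line %d (header is line 1)",
             bad[1] + 1L)
  }
  raw$vaf <- vaf_num
  raw$pos <- as.integer(raw$pos)
  raw$depth <- as.integer(raw$depth)
  raw$alt_reads <- as.integer(raw$alt_reads)
  for (col in c("pop_af_1000g", "pop_af_exac")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  raw$n_neoantigens <- suppressWarnings(as.integer(raw$n_neoantigens))
  raw$is_silent <- as.logical(raw$is_silent)
  as_mutation_table(raw)
}

#' Construct/validate a mutation table
#'
#' Validates field-level invariants (1-based positions, VAF in \[0,1\],
#' alt reads bounded by depth) and normalizes SNV records to the
#' pyrimidine-centered context convention.
#'
#' @param df A data.frame carrying the per-variant columns.
#' @return The validated table, classed `mutation_table`.
#' @export
as_mutation_table <- function(df) {
  require_columns(df, .mutation_required, "mutation table")
  if (any(df$pos < 1, na.rm = TRUE)) stop_fmt("mutation table: pos must be >= 1")
  if (any(df$vaf < 0 | df$vaf > 1, na.rm = TRUE)) {
    stop_fmt("mutation table: vaf must lie in [0, 1]")
  }
  if (any(df$alt_reads > df$depth, na.rm = TRUE)) {
    stop_fmt("mutation table: alt_reads exceeds depth")
  }
  is_snv <- !is.na(df$ref) & !is.na(df$alt) &
    nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
  flip <- is_snv & df$ref %in% c("A", "G") &
    !is.na(df$trinuc_context) & nchar(df$trinuc_context) == 3L
  if (any(flip)) {
    df$trinuc_context[flip] <- revcomp(df$trinuc_context[flip])
    newref <- revcomp(df$ref[flip])
    newalt <- revcomp(df$alt[flip])
    df$ref[flip] <- newref
    df$alt[flip] <- newalt
  }
  class(df) <- unique(c("mutation_table", class(df)))
  df
}

#' Write a mutation table as tab-delimited text
#'
#' @param tab A `mutation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(tab, path) {
  cols <- c(.mutation_required, .mutation_optional)
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GISTIC-style lesion-by-sample matrix
#'
#' Rows are lesions labelled `"Amp_<cytoband>"` or `"Del_<cytoband>"`, columns
#' are samples, cells are GISTIC threshold codes (0 = not called, 1/2 = called)
#' or logicals. Nonzero cells become calls; direction is parsed from the label
#' prefix.
#'
#' @param path Path to a tab-delimited matrix with lesion labels in the first
#'   column and sample ids as the remaining column names.
#' @return A `data.frame` of calls with columns `sample_id`, `lesion_id`,
#'   `direction` (`"amp"`/`"del"`) and `called` (all `TRUE`); the full sample
#'   set is kept in `attr(, "samples")`.
#' @export
read_lesion_matrix <- function(path) {
  if (!file.exists(path)) stop_fmt("lesion matrix not found: %s", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         row.names = 1)
  lesion_calls_from_matrix(as.matrix(m))
}

#' Convert a lesion matrix into lesion calls
#'
#' @param m Numeric or logical matrix, lesions in rows (labelled
#'   `Amp_`/`Del_`), samples in columns.
#' @return Call `data.frame`; see [read_lesion_matrix()].
#' @export
lesion_calls_from_matrix <- function(m) {
  labels <- rownames(m)
  dir <- ifelse(grepl("^amp[_.]", labels, ignore.case = TRUE), "amp",
         ifelse(grepl("^del[_.]", labels, ignore.case = TRUE), "del", NA))
  if (anyNA(dir)) {
    stop_fmt("lesion matrix: ambiguous direction label(s): %s",
             paste(labels[is.na(dir)], collapse = ", "))
  }
  lesion_id <- sub("^(amp|del)[_.]", "", labels, ignore.case = TRUE)
  idx <- which(m != 0, arr.ind = TRUE)
  calls <- data.frame(
    sample_id = colnames(m)[idx[, 2]],
    lesion_id = lesion_id[idx[, 1]],
    direction = dir[idx[, 1]],
    called = rep(TRUE, nrow(idx)),
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$sample_id, calls$lesion_id, calls$direction), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "samples") <- colnames(m)
  attr(calls, "lesions") <- labels
  calls
}

#' Write lesion calls back to a lesion-by-sample matrix
#'
#' @param calls Lesion call data.frame as returned by [read_lesion_matrix()].
#' @param path Output path.
#' @param samples,lesions Optional full sample/lesion-label sets; default to
#'   the attributes stored on `calls`.
#' @return `path`, invisibly.
#' @export
write_lesion_matrix <- function(calls, path, samples = NULL, lesions = NULL) {
  samples <- samples %||% attr(calls, "samples") %||% sort(unique(calls$sample_id))
  lesions <- lesions %||% attr(calls, "lesions") %||%
    sort(unique(paste0(ifelse(calls$direction == "amp", "Amp_", "Del_"),
                       calls$lesion_id)))
  m <- matrix(0L, nrow = length(lesions), ncol = length(samples),
              dimnames = list(lesions, samples))
  if (nrow(calls)) {
    lab <- paste0(ifelse(calls$direction == "amp", "Amp_", "Del_"),
                  calls$lesion_id)
    # match against the stored labels case-insensitively on the prefix
    li <- match(tolower(lab), tolower(lesions))
    si <- match(calls$sample_id, samples)
    m[cbind(li, si)] <- 1L
  }
  out <- data.frame(lesion = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.clinical_cols <- c("sample_id", "stage", "grade", "site", "msi_high",
                    "pole_mutant", "os_months", "os_event")

#' Read the clinical table
#'
#' Comma-separated table with columns `sample_id`, `stage` (I-IV/unknown),
#' `grade`, `site`, `msi_high`, `pole_mutant`, `os_months`, `os_event`.
#'
#' @param path Path to a CSV file.
#' @return A validated clinical `data.frame`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop_fmt("clinical table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, .clinical_cols, "clinical table")
  df$msi_high <- as.logical(df$msi_high)
  df$pole_mutant <- as.logical(df$pole_mutant)
  df$os_event <- as.logical(df$os_event)
  if (any(df$os_months < 0, na.rm = TRUE)) {
    stop_fmt("clinical table: os_months must be non-negative")
  }
  df
}

#' Write the clinical table
#' @param df Clinical data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(df, path) {
  utils::write.csv(df[, .clinical_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 96-context signature reference matrix
#'
#' Tab-delimited COSMIC-v2-style table: first column the 96 substitution class
#' labels (`"A[C>A]A"` format, any order), remaining columns one signature
#' each. Each signature column must sum to 1 within `tol`; columns are
#' renormalized to sum exactly 1 and rows reordered to [sbs_classes()].
#'
#' @param path Path to the TSV.
#' @param tol Tolerance on input column sums (default 0.05).
#' @return Numeric 96 x K matrix, rownames the class labels, colnames the
#'   signature names.
#' @export
read_signature_reference <- function(path, tol = 0.05) {
  if (!file.exists(path)) stop_fmt("signature reference not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 96L) {
    stop_fmt("signature reference: expected 96 context rows, found %d", nrow(df))
  }
  ctx <- df[[1]]
  if (!setequal(ctx, sbs_classes())) {
    stop_fmt("signature reference: first column must hold the 96 class labels")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ctx
  m <- m[sbs_classes(), , drop = FALSE]
  sums <- colSums(m)
  off <- which(abs(sums - 1) > tol)
  if (length(off)) {
    stop_fmt("signature reference: column(s) %s do not sum to 1 (tol %.3g)",
             paste(colnames(m)[off], collapse = ", "), tol)
  }
  sweep(m, 2, sums, "/")
}

#' Write a signature reference matrix
#' @param ref 96 x K matrix with class-label rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature_reference <- function(ref, path) {
  out <- data.frame(context = rownames(ref), ref, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' Returns the pipeline configuration with the published decision thresholds
#' baked in: variant hard filters (VAF >= 8%, depth >= 8, alt reads >= 2),
#' population-frequency cutoff (> 0.05 excluded), hypermutation gate
#' (TMB >= 10 muts/Mb), signature refitting rules (>= 20 SNVs per sample,
#' > 1% cohort prevalence), consensus-NMF settings (K = 2..6, 10 runs),
#' immunoediting Z gate (< -1.645), HLA-LOH rule (p < 0.01, allele CN < 0.5,
#' CI upper < 0.7), mitochondrial position blacklist {310, 523, 524, 3107}
#' and the top-10% mScore split. Every value can be overridden by name.
#'
#' The exome panel size behind the TMB denominator is exposed as
#' `panel_size_mb` (default 35 Mb, a typical whole-exome footprint) because
#' panels differ; set it to the interrogated size of your assay.
#'
#' @param ... Named overrides of any config entry.
#' @return A named list of class `analysis_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    panel_size_mb = 35,
    tmb_threshold = 10,
    vaf_min = 0.08,
    depth_min = 8L,
    altreads_min = 2L,
    pop_af_max = 0.05,
    mt_blacklist = c(310L, 523L, 524L, 3107L),
    nmf_k_range = 2:6,
    nmf_runs = 10L,
    random_seed = 1L,
    signature_min_snvs = 20L,
    signature_prevalence_min = 0.01,
    immunoedit_z_cut = -1.645,
    hla_p_cut = 0.01,
    hla_cn_cut = 0.5,
    hla_ci_cut = 0.7,
    mscore_top_fraction = 0.10
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_fmt("unknown config entries: %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

#' Validate an analysis configuration
#' @param cfg Named list of config entries.
#' @return `cfg` classed `analysis_config`; errors on invalid values.
#' @export
validate_config <- function(cfg) {
  num <- c("panel_size_mb", "tmb_threshold", "vaf_min", "pop_af_max",
           "signature_prevalence_min", "immunoedit_z_cut", "hla_p_cut",
           "hla_cn_cut", "hla_ci_cut", "mscore_top_fraction")
  for (nm in num) {
    if (!is.finite(cfg[[nm]])) stop_fmt("config: %s must be finite", nm)
  }
  if (cfg$panel_size_mb <= 0) stop_fmt("config: panel_size_mb must be positive")
  if (cfg$tmb_threshold <= 0) stop_fmt("config: tmb_threshold must be positive")
  kr <- cfg$nmf_k_range
  if (min(kr) < 2 || max(kr) > 10) {
    stop_fmt("config: nmf_k_range must lie within [2, 10]")
  }
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML or JSON
#'
#' Entries present in the file override the defaults from [default_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` document.
#' @return An `analysis_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config not found: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(default_config, vals)
}

#' Write a results bundle
#'
#' Writes each per-sample result table in `bundle` (a named list of
#' data.frames) as `<name>.tsv` in `out_dir`, plus a `manifest.json` recording
#' the configuration, seed and the files written. Output is deterministic:
#' tables are written in name order with their stored column order, and the
#' manifest carries no timestamps, so writing the same bundle twice yields
#' byte-identical files.
#'
#' @param bundle Named list of data.frames (may be empty).
#' @param out_dir Output directory (created if needed).
#' @param config An `analysis_config`; defaults to [default_config()].
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(bundle, out_dir, config = default_config()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    stop_fmt("write_results: cannot write to directory %s", out_dir)
  }
  written <- character(0)
  for (nm in sort(names(bundle))) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(bundle[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
  }
  manifest <- list(
    config = unclass(config),
    seed = config$random_seed,
    tables = sort(names(bundle))
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(written, mf))
}
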