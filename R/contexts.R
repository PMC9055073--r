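#' The 96 single-base-substitution context classes
#'
#' Returns the standard 96 trinucleotide substitution classes used for
#' mutational-signature analysis, in the conventional order: the six
#' pyrimidine-centered substitutions (C>A, C>G, C>T, T>A, T>C, T>G), each
#' crossed with the 16 combinations of 5' and 3' flanking bases, flanks in
#' alphabetical order. Labels look like `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_classes())
sbs_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    for (f5 in bases) {
      for (f3 in bases) {
        out <- c(out, paste0(f5, "[", s, "]", f3))
      }
    }
  }
  out
}

#' The 32 pyrimidine-centered trinucleotides
#'
#' Flanking-context classes (middle base C or T) used to key genome/exome
#' trinucleotide abundance ratios.
#'
#' @return Character vector of length 32 (e.g. `"ACA"`, `"ACC"`, ...).
#' @export
pyrimidine_trinucs <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (mid in c("C", "T")) {
    for (f5 in bases) {
      for (f3 in bases) {
        out <- c(out, paste0(f5, mid, f3))
      }
    }
  }
  out
}

#' Reverse complement of a DNA string vector
#'
#' @param x Character vector of DNA strings over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' Map SNV records to their 96-class label
#'
#' Combines the reference allele, alternate allele and trinucleotide context of
#' a single-nucleotide variant into its substitution class. Purine-centered
#' inputs (ref A or G) are reverse-complemented to the pyrimidine convention.
#' Returns `NA` for non-SNVs or contexts containing `N`.
#'
#' @param ref,alt Single-character reference/alternate alleles.
#' @param trinuc 3-letter trinucleotide context around the variant, on the same
#'   strand as `ref`.
#' @return Character vector of class labels (`"A[C>T]G"` style) or `NA`.
#' @export
#' @examples
#' sbs_class_of("C", "T", "ACG")
#' sbs_class_of("G", "A", "CGT")  # same class, opposite strand
sbs_class_of <- function(ref, alt, trinuc) {
  ref <- toupper(ref); alt <- toupper(alt); trinuc <- toupper(trinuc)
  n <- length(ref)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(ref[i]) || is.na(alt[i]) || is.na(trinuc[i])) next
    if (nchar(ref[i]) != 1L || nchar(alt[i]) != 1L || nchar(trinuc[i]) != 3L) next
    if (grepl("N", trinuc[i]) || !ref[i] %in% c("A", "C", "G", "T") ||
        !alt[i] %in% c("A", "C", "G", "T") || ref[i] == alt[i]) next
    r <- ref[i]; a <- alt[i]; ctx <- trinuc[i]
    if (substr(ctx, 2, 2) != r) next  # context inconsistent with ref
    if (r %in% c("A", "G")) {
      ctx <- revcomp(ctx)
      r <- revcomp(r)
      a <- revcomp(a)
    }
    out[i] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  }
  out
}

# flanking trinucleotide (pyrimidine-centered) of a 96-class label
trinuc_of_class <- function(cls) {
  paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7))
}

# round half away from zero at `digits` decimals (presentation convention for
# percentage tables; base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# largest-remainder rounding of percentages to `digits` decimals: preserves
# the exact total (100) while matching plain rounding almost everywhere
round_largest_remainder <- function(pct, digits = 1) {
  p <- 10^digits
  units <- pct * p
  fl <- floor(units + 1e-9)
  short <- as.integer(round(sum(units)) - sum(fl))
  if (short > 0) {
    rem <- units - fl
    bump <- order(-rem, seq_along(rem))[seq_len(short)]
    fl[bump] <- fl[bump] + 1
  }
  fl / p
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_fmt("%s: missing required column(s): %s", what,
             paste(missing, collapse = ", "))
  }
  invisible(df)
}
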