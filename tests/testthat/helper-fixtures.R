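# shared test helpers: tiny table builders and an independent ARI

make_mutations <- function(n = 3, sample_id = "S1", func_class = "Missense_Mutation",
                           vaf = 0.3, depth = 100L, alt_reads = 30L,
                           ref = "C", alt = "T", trinuc = "ACG",
                           pop_af_1000g = 0, pop_af_exac = 0,
                           oncogenicity = "unknown", n_neo = 0L,
                           is_silent = FALSE, gene = "GENE1") {
  as_mutation_table(data.frame(
    sample_id = rep_len(sample_id, n), gene = rep_len(gene, n),
    chrom = "1", pos = seq_len(n) * 100L,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    func_class = rep_len(func_class, n),
    vaf = rep_len(vaf, n), depth = rep_len(depth, n),
    alt_reads = rep_len(alt_reads, n),
    trinuc_context = rep_len(trinuc, n),
    pop_af_1000g = rep_len(pop_af_1000g, n),
    pop_af_exac = rep_len(pop_af_exac, n),
    oncogenicity = rep_len(oncogenicity, n),
    n_neoantigens = rep_len(n_neo, n),
    is_silent = rep_len(is_silent, n),
    stringsAsFactors = FALSE
  ))
}

# adjusted Rand index, written independently of any clustering code under test
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (si - expected) / ((sa + sb) / 2 - expected)
}

# draw a catalog of n mutations from a mixture of reference signature columns
draw_catalog <- function(reference, weights, n) {
  p <- as.numeric(reference %*% weights)
  counts <- tabulate(sample.int(96, n, replace = TRUE, prob = p), nbins = 96)
  stats::setNames(counts, rownames(reference))
}
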