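test_that("hard filters respect inclusive boundaries", {
  tab <- make_mutations(6,
    vaf = c(0.08, 0.079, 0.30, 0.30, 0.30, 0.50),
    depth = c(8L, 100L, 7L, 100L, 100L, 200L),
    alt_reads = c(2L, 50L, 2L, 1L, 30L, 100L))
  kept <- apply_variant_filters(tab)
  # record 1 sits exactly on all three boundaries and survives
  expect_equal(kept$pos, tab$pos[c(1, 5, 6)])
  # brute-force check per record
  manual <- tab$vaf >= 0.08 & tab$depth >= 8 & tab$alt_reads >= 2
  expect_equal(nrow(kept), sum(manual))
})

test_that("filtering is idempotent and order-preserving", {
  coh <- simulate_cohort(cohort_sim_config(n_samples = 10, seed = 2))
  once <- apply_variant_filters(coh$mutations)
  twice <- apply_variant_filters(once)
  expect_identical(once, twice)
  expect_true(!is.unsorted(match(once$sample_id, unique(coh$mutations$sample_id))))
})

test_that("TMB counts only the eight qualifying classes", {
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
               "Nonstop_Mutation", "Splice_Site", "Silent", "3'UTR")
  tab <- make_mutations(10, func_class = classes)
  res <- compute_tmb(tab, panel_size_mb = 35)
  expect_equal(res$n_qualifying, 8L)   # Silent and 3'UTR contribute 0
  expect_equal(res$tmb, 8 / 35)

  tab35 <- make_mutations(35)
  expect_equal(compute_tmb(tab35, panel_size_mb = 35)$tmb, 1.0)
  expect_error(compute_tmb(tab35, panel_size_mb = 0), "panel_size_mb")
})

test_that("population-frequency exclusion is strictly greater than 0.05", {
  tab <- make_mutations(3, pop_af_1000g = c(0.06, 0.05, NA))
  res <- compute_tmb(tab, panel_size_mb = 1)
  expect_equal(res$n_qualifying, 2L)  # 0.05 kept, 0.06 dropped, NA kept
  tab2 <- make_mutations(2, pop_af_exac = c(0.2, 0))
  expect_equal(compute_tmb(tab2, panel_size_mb = 1)$n_qualifying, 1L)
})

test_that("TMB is additive over disjoint subsets of a sample's mutations", {
  coh <- simulate_cohort(cohort_sim_config(n_samples = 6, seed = 4))
  tab <- apply_variant_filters(coh$mutations)
  whole <- compute_tmb(tab, panel_size_mb = 35)
  odd <- compute_tmb(tab[seq(1, nrow(tab), 2), ], panel_size_mb = 35,
                     samples = whole$sample_id)
  even <- compute_tmb(tab[seq(2, nrow(tab), 2), ], panel_size_mb = 35,
                      samples = whole$sample_id)
  expect_equal(odd$tmb + even$tmb, whole$tmb, tolerance = 1e-12)
})

test_that("hypermutation gate is inclusive at the threshold", {
  res <- data.frame(sample_id = c("A", "B", "C"), tmb = c(10.0, 9.99, 21))
  out <- classify_hypermutated(res, threshold = 10)
  expect_equal(out$hypermutated, c(TRUE, FALSE, TRUE))
})

test_that("hypermutation attribution partitions the HM set", {
  # printed worked example: 72 HM with 46 MSI-H, 25 POLE, 10 both
  fx <- fixture_from_counts(list(n = 72, msi = 46, pole = 25, both = 10))
  part <- explain_hypermutation(fx$flags$hypermutated, fx$flags$msi_high,
                                fx$flags$pole_mutant)
  expect_equal(part$unexplained, 11)
  expect_equal(part$msi_only + part$pole_only + part$both + part$unexplained,
               part$n_hm)

  none <- explain_hypermutation(rep(FALSE, 5), rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(unlist(none), c(msi_only = 0, pole_only = 0, both = 0,
                               unexplained = 0, n_hm = 0))

  # random flags vs exhaustive per-sample enumeration
  set.seed(31)
  hm <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  msi <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  pole <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  part2 <- explain_hypermutation(hm, msi, pole)
  brute <- table(factor(paste(msi[hm], pole[hm]),
                        levels = c("TRUE FALSE", "FALSE TRUE", "TRUE TRUE",
                                   "FALSE FALSE")))
  expect_equal(unname(unlist(part2[1:4])), as.integer(brute))
})

test_that("cohort summary reproduces printed stratified percentages", {
  fx <- fixture_from_counts(list(n = 72, right_sided = 57))
  # collapse site to right/left-sided as in printed tables
  cl <- fx$clinical
  cl$side <- ifelse(cl$site %in% c("ascending", "transverse"), "right", "left")
  sm <- summarize_cohort(cl, strata = fx$flags$hypermutated, vars = "side")
  right <- sm[sm$level == "right", ]
  expect_equal(right$n, 57L)
  expect_equal(right$pct, 79.2)

  one <- summarize_cohort(data.frame(stage = "II"), strata = "all",
                          vars = "stage")
  expect_equal(one$pct, 100.0)

  # percentages within each stratum x variable sum to 100
  coh <- simulate_cohort(cohort_sim_config(n_samples = 50, seed = 8))
  sm2 <- summarize_cohort(coh$clinical, strata = coh$clinical$msi_high)
  sums <- tapply(sm2$pct, paste(sm2$stratum, sm2$variable), sum)
  expect_true(all(abs(sums - 100) <= 0.1))
})
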