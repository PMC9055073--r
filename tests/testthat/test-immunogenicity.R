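test_that("context rates match direct ratios on a toy table", {
  # one sample, 10 non-silent to clear the eligibility floor; in context
  # A[C>T]G: 4 non-silent carrying 2 immunogenic mutations, plus 2 silent
  tab <- make_mutations(12,
    trinuc = c(rep("ACG", 6), rep("ACA", 6)),
    alt = "T",
    is_silent = c(rep(FALSE, 4), TRUE, TRUE, rep(FALSE, 6)),
    n_neo = c(1, 1, 0, 0, 0, 0, rep(0, 6)))
  rates <- estimate_context_rates(tab, min_nonsilent = 10)
  r <- rates[rates$context == "A[C>T]G", ]
  expect_equal(r$b_bar, 0.5)
  expect_equal(r$n_bar, 2)
  # context with zero silent mutations: add-one smoothing on the denominator
  r2 <- rates[rates$context == "A[C>T]A", ]
  expect_equal(r2$n_bar, 6 / 1)
})

test_that("samples under 10 non-silent mutations do not inform the rates", {
  big <- make_mutations(10, sample_id = "big", trinuc = "ACG", alt = "T",
                        n_neo = 1L)
  small <- make_mutations(9, sample_id = "small", trinuc = "ACA", alt = "T",
                          n_neo = 1L)
  rates <- estimate_context_rates(rbind(big, small))
  expect_equal(rates$n_nonsilent[rates$context == "A[C>T]A"], 0L)
  expect_gt(rates$n_nonsilent[rates$context == "A[C>T]G"], 0L)
  expect_error(estimate_context_rates(small), "no sample")
})

test_that("rates equal an independent brute-force tally on a random table", {
  set.seed(55)
  n <- 50
  ctxs <- sample(c("ACG", "TCG", "ATA", "GCG"), n, replace = TRUE)
  alts <- ifelse(substr(ctxs, 2, 2) == "C", "T", "G")
  tab <- make_mutations(n, sample_id = "S1",
                        ref = substr(ctxs, 2, 2), alt = alts, trinuc = ctxs,
                        is_silent = sample(c(TRUE, FALSE), n, replace = TRUE,
                                           prob = c(0.3, 0.7)),
                        n_neo = sample(0:2, n, replace = TRUE))
  rates <- estimate_context_rates(tab, min_nonsilent = 10)
  cls <- sbs_class_of(tab$ref, tab$alt, tab$trinuc_context)
  for (cc in unique(cls)) {
    ns <- sum(cls == cc & !tab$is_silent)
    sil <- sum(cls == cc & tab$is_silent)
    imm <- sum(cls == cc & !tab$is_silent & tab$n_neoantigens >= 1)
    r <- rates[rates$context == cc, ]
    expect_equal(r$b_bar, if (ns > 0) imm / ns else 0, info = cc)
    expect_equal(r$n_bar, ns / max(sil, 1), info = cc)
  }
})

test_that("expected counts sum term-by-term over silent mutations", {
  rates <- data.frame(context = sbs_classes(),
                      b_bar = seq(0, 0.95, length.out = 96),
                      n_bar = seq(1, 3, length.out = 96))
  one <- expected_counts("A[C>A]A", rates)
  expect_equal(one$n_pred, rates$n_bar[1])
  expect_equal(one$b_pred, rates$n_bar[1] * rates$b_bar[1])

  picks <- c("A[C>A]A", "T[T>G]T", "C[C>T]G")
  multi <- expected_counts(picks, rates)
  i <- match(picks, rates$context)
  expect_equal(multi$n_pred, sum(rates$n_bar[i]))
  expect_equal(multi$b_pred, sum(rates$n_bar[i] * rates$b_bar[i]))

  none <- expected_counts(character(0), rates)
  expect_false(none$assessable)
})

test_that("the immunoediting score is the observed/expected ratio", {
  prof <- data.frame(
    b_obs = c(5, 0, 5, 5),
    n_obs = c(50, 50, 0, 50),
    b_pred = c(2, 2, 2, 0),
    n_pred = c(20, 20, 20, 20))
  out <- immunoediting_score(prof)
  expect_equal(out$i_score[1], 1)        # observed rate equals expected rate
  expect_equal(out$i_score[2], 0)        # no observed immunogenic mutations
  expect_false(out$assessable[3])        # N_obs = 0
  expect_false(out$assessable[4])        # B_pred = 0
})

test_that("z-scores standardize the assessable population", {
  set.seed(77)
  prof <- data.frame(b_obs = stats::rpois(200, 10) + 1, n_obs = 100,
                     b_pred = 10, n_pred = 100)
  out <- immunoediting_score(prof)
  expect_equal(mean(out$z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(out$z), 1, tolerance = 1e-9)
})

test_that("pipeline profiles equal a brute-force per-mutation tally", {
  coh <- simulate_cohort(cohort_sim_config(n_samples = 8, seed = 44))
  tab <- coh$mutations
  prof <- immunoediting_profiles(tab)
  rates <- estimate_context_rates(tab)
  cls <- sbs_class_of(tab$ref, tab$alt, tab$trinuc_context)
  for (s in prof$sample_id[1:4]) {
    rows <- tab$sample_id == s & !is.na(cls)
    expect_equal(prof$n_obs[prof$sample_id == s],
                 sum(rows & !tab$is_silent))
    expect_equal(prof$b_obs[prof$sample_id == s],
                 sum(rows & !tab$is_silent & tab$n_neoantigens >= 1))
    sil <- cls[rows & tab$is_silent]
    i <- match(sil, rates$context)
    expect_equal(prof$n_pred[prof$sample_id == s], sum(rates$n_bar[i]))
    expect_equal(prof$b_pred[prof$sample_id == s],
                 sum(rates$n_bar[i] * rates$b_bar[i]))
  }
})

test_that("HLA LOH rule applies the published thresholds per locus", {
  calls <- data.frame(
    sample_id = rep(c("loh", "ai", "neither", "partial"), each = 3)[1:11],
    locus = c(rep(c("A", "B", "C"), 3), "A", "B"),
    ai_pvalue = c(0.005, 0.5, 0.5,   0.005, 0.5, 0.5,  0.02, 0.5, 0.5,
                  0.001, 0.001),
    cn_estimate = c(0.3, 1, 1,  0.6, 1, 1,  0.1, 1, 1,  0.1, 0.1),
    ci_upper = c(0.6, 1.2, 1.2,  0.65, 1.2, 1.2,  0.2, 1.2, 1.2, 0.2, 0.2))
  out <- classify_hla_loh(calls)
  expect_equal(out$status[out$sample_id == "loh"], "LOH")
  expect_equal(out$status[out$sample_id == "ai"], "AI")       # cn fails
  expect_equal(out$status[out$sample_id == "neither"], "neither")  # p fails
  expect_equal(out$status[out$sample_id == "partial"], "not-assessable")
  expect_false(out$assessable[out$sample_id == "partial"])
})

test_that("the LOH rule is monotone in p, copy number and CI bound", {
  base <- data.frame(sample_id = "s", locus = c("A", "B", "C"),
                     ai_pvalue = c(0.009, 0.5, 0.5),
                     cn_estimate = c(0.49, 1, 1),
                     ci_upper = c(0.69, 1.2, 1.2))
  expect_equal(classify_hla_loh(base)$status, "LOH")
  for (col in c("ai_pvalue", "cn_estimate", "ci_upper")) {
    dec <- base
    dec[[col]][1] <- dec[[col]][1] / 2
    expect_equal(classify_hla_loh(dec)$status, "LOH", info = col)
  }
})

test_that("IR status is the OR of its three components", {
  grid <- expand.grid(npg = c(TRUE, FALSE), loh = c(TRUE, FALSE),
                      edited = c(TRUE, FALSE))
  got <- classify_immunogenicity_reduction(grid$npg, grid$loh, grid$edited)
  expect_equal(got, ifelse(grid$npg | grid$loh | grid$edited, "IR", "nIR"))
  # not-assessable components count as absent, never as evidence
  expect_equal(classify_immunogenicity_reduction(NA, NA, NA), "nIR")
  expect_equal(classify_immunogenicity_reduction(NA, TRUE, NA), "IR")
})

test_that("TNB x IR grouping partitions the cohort", {
  set.seed(91)
  tnb <- stats::rpois(60, 20)
  ir <- sample(c("IR", "nIR"), 60, replace = TRUE)
  g <- group_by_tnb_ir(tnb, ir)
  expect_equal(length(g), 60L)
  expect_false(anyNA(g))
  cut <- attr(g, "tnb_cut")
  manual <- table(paste0(ifelse(tnb > cut, "TNB-high", "TNB-low"), "/", ir))
  expect_equal(as.integer(table(g)[names(manual)]), as.integer(manual))

  low <- group_by_tnb_ir(c(1, 2, 3), c("IR", "nIR", "IR"), tnb_cut = 10)
  expect_equal(sum(table(low)[c("TNB-high/IR", "TNB-high/nIR")]), 0L)
})
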