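test_that("pathway rollup applies oncogenic > vus > wt precedence", {
  pathways <- list(cell_cycle = data.frame(gene = c("RB1", "CCND1", "CCNE1"),
                                           role = "unknown"))
  tab <- make_mutations(5, sample_id = c("onc", "onc", "vus", "vus", "other"),
                        gene = c("RB1", "CCND1", "RB1", "CCNE1", "TP53"),
                        oncogenicity = c("oncogenic", "vus", "vus", "unknown",
                                         "oncogenic"))
  st <- rollup_pathway_status(tab, pathways,
                              samples = c("onc", "vus", "other"))
  expect_equal(st$status[st$sample_id == "onc"], "oncogenic")
  expect_equal(st$status[st$sample_id == "vus"], "vus")
  expect_equal(st$status[st$sample_id == "other"], "wt")  # TP53 not a member
})

test_that("rollup is monotone: adding an oncogenic event never downgrades", {
  pathways <- list(p = data.frame(gene = c("G1", "G2"), role = "unknown"))
  base <- make_mutations(1, sample_id = "s", gene = "G1",
                         oncogenicity = "vus")
  more <- rbind(base, make_mutations(1, sample_id = "s", gene = "G2",
                                     oncogenicity = "oncogenic"))
  rank <- c(wt = 0, vus = 1, oncogenic = 2)
  s1 <- rollup_pathway_status(base, pathways)$status
  s2 <- rollup_pathway_status(more, pathways)$status
  expect_gte(rank[s2], rank[s1])
})

test_that("CNV events roll up alongside mutations", {
  pathways <- list(p = data.frame(gene = "SMAD4", role = "unknown"))
  tab <- make_mutations(1, sample_id = "s", gene = "OTHER")
  cnv <- data.frame(sample_id = "s", gene = "SMAD4",
                    oncogenicity = "oncogenic")
  st <- rollup_pathway_status(tab, pathways, cnv_calls = cnv)
  expect_equal(st$status, "oncogenic")
})

test_that("driver consensus keeps genes found by two or more tools", {
  lists <- list(t1 = c("APC", "TP53", "KRAS"),
                t2 = c("APC", "TP53"),
                t3 = c("APC", "BRAF"),
                t4 = character(0),
                t5 = c("KRAS", "KRAS"))   # duplicates must not double-count
  out <- smg_consensus(lists)
  expect_setequal(out$gene, c("APC", "TP53", "KRAS"))
  expect_equal(out$n_tools[out$gene == "APC"], 3L)
  expect_false("BRAF" %in% out$gene)   # single-tool gene dropped
  # order invariance
  out2 <- smg_consensus(rev(lists))
  expect_setequal(out2$gene, out$gene)
  # brute-force multiset intersection on random lists
  set.seed(15)
  rl <- replicate(4, sample(LETTERS, 10), simplify = FALSE)
  got <- smg_consensus(rl)
  brute <- table(unlist(lapply(rl, unique)))
  expect_setequal(got$gene, names(brute)[brute >= 2])
  expect_error(smg_consensus(lists[1]), ">= 2")
})

test_that("log-rank statistic matches an independent hand tally", {
  # small two-group cohort, all events, distinct times
  times <- c(1, 3, 5, 7, 9, 11, 2, 4, 6, 8, 10, 12)
  group <- rep(c("a", "b"), each = 6)
  events <- rep(TRUE, 12)
  res <- km_logrank(times, events, group)
  # brute-force log-rank: sum over event times of observed minus expected
  # deaths in group a, with hypergeometric variance
  o_minus_e <- 0; v <- 0
  for (t in sort(times)) {
    at_risk <- times >= t
    d <- sum(times == t)
    n <- sum(at_risk)
    n_a <- sum(at_risk & group == "a")
    d_a <- sum(times == t & group == "a")
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  expect_equal(res$chisq, o_minus_e^2 / v, tolerance = 1e-9)
  expect_error(km_logrank(times, events, rep("a", 12)), "2 non-empty")
})

test_that("KM output flags all-censored groups and starts at 1", {
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  groups <- rep(c("died", "censored"), each = 3)
  res <- km_logrank(times, events, groups)
  expect_true("censored" %in% res$all_censored)
  expect_true(is.na(res$table$median[res$table$group == "censored"]))
  s <- summary(res$fit)
  expect_true(all(s$surv <= 1))
  expect_true(all(diff(s$surv[s$strata == s$strata[1]]) <= 0))
})

test_that("Cox recovers a planted hazard ratio and rejects degeneracy", {
  set.seed(70)
  n <- 1000
  x <- stats::rbinom(n, 1, 0.5)
  t_event <- stats::rexp(n, 0.02 * exp(log(2) * x))
  t_cens <- stats::rexp(n, 0.008)
  res <- cox_adjusted(pmin(t_event, t_cens), t_event <= t_cens, x)
  hr <- res$table$hr[res$table$term == "exposure"]
  expect_gte(hr, 1.7)
  expect_lte(hr, 2.3)
  expect_true(res$table$ci_lower[1] < hr && hr < res$table$ci_upper[1])
  expect_error(cox_adjusted(1:10, rep(TRUE, 10), rep(1, 10)), "constant")
})

test_that("Cox adjusts for categorical stage and grade and drops NAs", {
  coh <- simulate_cohort(cohort_sim_config(n_samples = 200, seed = 33))
  cl <- coh$clinical
  cl$stage[1:3] <- NA
  expo <- coh$truth$per_sample$subtype == "CIN-HR"
  res <- cox_adjusted(cl$os_months, cl$os_event, expo,
                      covariates = cl[, c("stage", "grade")])
  expect_equal(res$n_dropped, 3L)
  expect_true(any(grepl("stage", res$table$term)))
  expect_true(all(res$table$hr > 0))
})

test_that("association matrix picks the prescribed test branches", {
  set.seed(88)
  x <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  df <- data.frame(a = x, b = x,                       # perfectly associated
                   num = stats::rnorm(100),
                   const = rep("k", 100))
  out <- association_network(df)
  ab <- out[out$var1 == "a" & out$var2 == "b", ]
  expect_lt(ab$p, 1e-10)
  expect_true(all(out$skipped[out$var1 == "const" | out$var2 == "const"]))
  tnum <- out[(out$var1 == "a" & out$var2 == "num") |
              (out$var1 == "num" & out$var2 == "b"), ]
  expect_true(all(tnum$test == "t"))

  # a 2x2 with a small expected cell goes through Fisher's exact test
  small <- data.frame(u = c(rep("x", 4), rep("y", 46)),
                      v = c(rep("p", 2), rep("q", 48)))
  out2 <- association_network(small)
  expect_equal(out2$test, "fisher")

  # adjusted p-values are BH over the tested pairs
  tested <- out[!out$skipped, ]
  expect_equal(tested$p_adj, stats::p.adjust(tested$p, "BH"))
})

test_that("the bundled pathway YAML parses into gene/role tables", {
  f <- system.file("extdata", "default_pathways.yaml", package = "crcprofiler")
  pw <- read_pathways(f)
  expect_true(all(c("cell_cycle", "tgf_beta") %in% names(pw)))
  expect_true(all(c("SMAD4", "SMAD2") %in% pw$tgf_beta$gene))
  expect_equal(pw$cell_cycle$role[pw$cell_cycle$gene == "RB1"],
               "tumor_suppressor")
})
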