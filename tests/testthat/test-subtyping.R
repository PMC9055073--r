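test_that("feature matrix excludes HM samples, scales and drops constants", {
  expo <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80,
                   5, 5, 5, 5, 5, 5, 5, 5), ncol = 2,
                 dimnames = list(paste0("S", 1:8), c("varies", "constant")))
  hm <- stats::setNames(c(rep(FALSE, 7), TRUE), paste0("S", 1:8))
  lesions <- data.frame(sample_id = c("S1", "S2"), lesion_id = "10q11.21",
                        direction = "amp", called = TRUE)
  fm <- build_feature_matrix(expo, lesions, hm, min_samples = 4,
                             as_fractions = FALSE)
  expect_false("S8" %in% rownames(fm))   # HM sample excluded
  expect_false("constant" %in% colnames(fm))
  expect_equal(min(fm[, "varies"]), 0)
  expect_equal(max(fm[, "varies"]), 1)
  expect_true(all(fm >= 0 & fm <= 1))
  expect_error(build_feature_matrix(expo, lesions, hm, min_samples = 100),
               "usable samples")
})

test_that("identical rows give an all-ones consensus at every K", {
  m <- matrix(rep(c(0.2, 0.8, 0.5), each = 12), nrow = 12,
              dimnames = list(paste0("S", 1:12), NULL))
  res <- consensus_nmf(m, k_range = 2:3, n_runs = 5, seed = 1)
  for (k in c("2", "3")) {
    expect_true(all(res[[k]]$consensus == 1), info = paste("K =", k))
  }
})

test_that("consensus NMF is deterministic under a fixed seed", {
  set.seed(77)
  m <- matrix(stats::runif(40 * 6), 40, 6,
              dimnames = list(paste0("S", 1:40), NULL))
  a <- consensus_nmf(m, k_range = 2:3, n_runs = 5, seed = 9)
  b <- consensus_nmf(m, k_range = 2:3, n_runs = 5, seed = 9)
  expect_identical(a[["2"]]$labels, b[["2"]]$labels)
  expect_identical(a[["3"]]$consensus, b[["3"]]$consensus)
})

test_that("consensus entries are rationals with denominator n_runs", {
  set.seed(5)
  m <- matrix(stats::runif(30 * 5), 30, 5,
              dimnames = list(paste0("S", 1:30), NULL))
  res <- consensus_nmf(m, k_range = 2, n_runs = 10, seed = 2)
  C <- res[["2"]]$consensus
  expect_true(all(abs(C * 10 - round(C * 10)) < 1e-9))
  expect_true(isSymmetric(C))
  expect_true(all(diag(C) == 1))
})

test_that("three planted blocks are recovered with high agreement", {
  set.seed(19)
  blocks <- rep(1:3, each = 20)
  centers <- matrix(c(1, 0, 0, 0, 0.9, 0, 0, 0, 0.8), 3, 3, byrow = TRUE)
  m <- centers[blocks, ] + matrix(abs(stats::rnorm(60 * 3, 0, 0.05)), 60, 3)
  rownames(m) <- paste0("S", 1:60)
  res <- consensus_nmf(m, k_range = 3, n_runs = 10, seed = 4)
  expect_gte(adjusted_rand(res[["3"]]$labels, blocks), 0.9)
})

test_that("K selection follows the cophenetic coefficient with override", {
  fake <- structure(list(`2` = list(k = 2, cophenetic = 0.95),
                         `3` = list(k = 3, cophenetic = 0.99)),
                    class = "consensus_nmf")
  expect_equal(select_k(fake), 3L)
  expect_equal(select_k(fake, override = 2), 2L)
  tie <- structure(list(`2` = list(k = 2, cophenetic = 0.9),
                        `3` = list(k = 3, cophenetic = 0.9)),
                   class = "consensus_nmf")
  expect_equal(select_k(tie), 2L)  # ties go to the smaller K

  # a clean two-block structure selects K = 2 by the metric
  set.seed(3)
  m <- rbind(matrix(c(1, 0), 15, 2, byrow = TRUE),
             matrix(c(0, 1), 15, 2, byrow = TRUE)) +
    matrix(abs(stats::rnorm(60, 0, 0.03)), 30, 2)
  rownames(m) <- paste0("S", 1:30)
  res <- consensus_nmf(m, k_range = 2:4, n_runs = 10, seed = 8)
  expect_equal(select_k(res), 2L)
})

test_that("subtype naming follows load and 10q11.21 enrichment, not indices", {
  # construct three clusters: A high-lesion high-amp, B high-lesion no-amp,
  # C low everything; plus one HM sample
  samples <- c(paste0("A", 1:10), paste0("B", 1:10), paste0("C", 1:10), "H1")
  hm <- stats::setNames(samples == "H1", samples)
  labels <- stats::setNames(rep(c(2L, 3L, 1L), each = 10), samples[1:30])
  features <- rbind(
    matrix(0.9, 10, 4), matrix(0.8, 10, 4), matrix(0.05, 10, 4))
  rownames(features) <- samples[1:30]
  lesions <- data.frame(
    sample_id = c(paste0("A", 1:6), "B1", "C1"),
    lesion_id = "10q11.21", direction = "amp", called = TRUE)
  sub <- assign_subtypes(labels, hm, lesions, features)
  expect_equal(sub$subtype[sub$sample_id == "H1"], "HM")
  expect_true(all(sub$subtype[grep("^A", sub$sample_id)] == "CIN-HR"))
  expect_true(all(sub$subtype[grep("^B", sub$sample_id)] == "CIN-LR"))
  expect_true(all(sub$subtype[grep("^C", sub$sample_id)] == "GS"))
  # partition: exactly one label per input sample
  expect_setequal(sub$sample_id, samples)
  expect_equal(anyDuplicated(sub$sample_id), 0L)

  # naming is invariant to permuting cluster indices
  perm <- stats::setNames(c(3L, 1L, 2L)[labels], names(labels))
  sub2 <- assign_subtypes(perm, hm, lesions, features)
  expect_equal(sub2$subtype, sub$subtype)
})

test_that("external cohorts map through the 10q11.21 rule", {
  labels <- c("CIN", "CIN", "GS", "HM")
  amp <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(map_external_cohort(labels, amp),
               c("CIN-HR", "CIN-LR", "GS", "HM"))
  expect_error(map_external_cohort("MSI", TRUE), "unknown")
})
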