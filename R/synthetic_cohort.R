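#' @title Synthetic-cohort generation
#' @description Generates cohorts with the statistical structure the
#'   downstream analyses assume — subtype-dependent mutation catalogs drawn
#'   from signature mixtures, cluster-structured lesion matrices, purity and
#'   ploidy, mitochondrial read counts, HLA allele calls, neoantigen flags
#'   and subtype-dependent exponential survival — so that every pipeline
#'   stage is testable without access to restricted patient-level data. All
#'   output is synthetic; it emulates structure, not any real cohort.
#' @name synthetic_cohort
NULL

.subtype_levels <- c("HM", "CIN-HR", "CIN-LR", "GS")

#' Cohort simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: a hypermutation
#' prevalence of 7.09%, three non-hypermutated subtypes with distinct
#' signature mixtures and lesion profiles, 10q11.21 amplification enriched in
#' CIN-HR, an HLA-LOH rate of 17.4% among the ~41% of samples with complete
#' HLA calls, antigen-presenting-gene mutations in 6.7% of samples, and
#' exponential survival with a hazard penalty on CIN-HR. Mutation-count
#' distributions are log-normal per subtype and truncated so the
#' hypermutated and non-hypermutated burden regimes stay disjoint (the
#' hypermutation gate is definitional for the HM subtype).
#'
#' @param n_samples Cohort size (>= 4).
#' @param hm_prevalence Fraction of hypermutated samples; replaces the HM
#'   component of `subtype_proportions` (non-HM components rescaled).
#' @param subtype_proportions Named 4-vector over HM, CIN-HR, CIN-LR, GS,
#'   summing to 1.
#' @param reference Signature reference matrix (96 x K); defaults to the
#'   synthetic reference.
#' @param signature_mixtures 4 x K matrix of per-subtype signature weights
#'   (rows sum to 1).
#' @param mutations_per_sample data.frame with per-subtype `median` and
#'   `sigma` of the log-normal total mutation count, plus truncation bounds
#'   `min`/`max`.
#' @param lesion_amp_probs Named list: `target` = per-subtype probability of
#'   10q11.21 amplification; `background` = lesion x subtype probability
#'   matrix for background lesions.
#' @param purity_dist,ploidy_dist Beta parameters `c(shape1, shape2)` for
#'   purity; named weights over ploidies 1.5..6 for ploidy.
#' @param mt_reads_model List: `r_n_meanlog`, `r_n_sdlog`,
#'   `mscore_meanlog`, `mscore_sdlog`, `blacklist_frac` (fraction of MT
#'   variants at blacklisted positions), `variant_rate` (Poisson mean of raw
#'   MT variants per sample).
#' @param hla_assessable_frac Fraction of samples with complete HLA-A/B/C
#'   calls.
#' @param hla_loh_prob LOH probability among assessable samples.
#' @param npg_mut_prob Probability of an antigen-presenting-gene mutation.
#' @param neoantigen_rate_per_nonsilent Per-mutation immunogenicity rate.
#' @param silent_odds Probability a simulated SNV is silent (default 0.25,
#'   i.e. 1:3 silent:non-silent odds, a typical exome coding ratio).
#' @param survival_log_hazards List: `baseline_rate` (events/month),
#'   `subtype` (named log-hazards), `stage_per_level`, `mscore` (log-hazard
#'   per unit of log-mScore z-score).
#' @param censor_rate Target fraction censored by the independent censoring
#'   process.
#' @param seed Integer master seed.
#' @return Named list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_samples = 300,
    hm_prevalence = 0.0709,
    subtype_proportions = NULL,
    reference = synthetic_signature_reference(),
    signature_mixtures = NULL,
    mutations_per_sample = NULL,
    lesion_amp_probs = NULL,
    purity_dist = c(8, 4),
    ploidy_dist = c(`1.5` = 0.02, `2` = 0.50, `2.5` = 0.10, `3` = 0.20,
                    `3.5` = 0.08, `4` = 0.06, `4.5` = 0.02, `5` = 0.01,
                    `5.5` = 0.005, `6` = 0.005),
    mt_reads_model = list(r_n_meanlog = log(8e7), r_n_sdlog = 0.10,
                          mscore_meanlog = log(0.01), mscore_sdlog = 0.5,
                          blacklist_frac = 0.15, variant_rate = 1.3),
    hla_assessable_frac = 0.41,
    hla_loh_prob = 0.174,
    npg_mut_prob = 0.067,
    neoantigen_rate_per_nonsilent = 0.15,
    silent_odds = 0.25,
    survival_log_hazards = list(baseline_rate = 0.012,
                                subtype = c(HM = -0.5, `CIN-HR` = 0.7,
                                            `CIN-LR` = 0, GS = 0),
                                stage_per_level = 0.25, mscore = 0.3),
    censor_rate = 0.3,
    seed = 1L) {
  if (n_samples < 4) stop_fmt("cohort_sim_config: n_samples must be >= 4")
  if (is.null(subtype_proportions)) {
    subtype_proportions <- c(HM = NA, `CIN-HR` = 0.25, `CIN-LR` = 0.35,
                             GS = 0.40)
    subtype_proportions["HM"] <- 0
    rest <- subtype_proportions[-1] / sum(subtype_proportions[-1])
    subtype_proportions <- c(HM = hm_prevalence, (1 - hm_prevalence) * rest)
  } else {
    stopifnot(setequal(names(subtype_proportions), .subtype_levels))
    subtype_proportions <- subtype_proportions[.subtype_levels]
    if (!missing(hm_prevalence)) {
      rest <- subtype_proportions[-1] / sum(subtype_proportions[-1])
      subtype_proportions <- c(HM = hm_prevalence,
                               (1 - hm_prevalence) * rest)
    }
  }
  if (abs(sum(subtype_proportions) - 1) > 1e-9) {
    stop_fmt("cohort_sim_config: subtype proportions must sum to 1")
  }
  if (any(subtype_proportions < 0 | subtype_proportions > 1)) {
    stop_fmt("cohort_sim_config: proportions must lie in [0, 1]")
  }
  K <- ncol(reference)
  if (is.null(signature_mixtures)) {
    if (K < 8) stop_fmt("default mixtures need a reference with >= 8 signatures")
    signature_mixtures <- matrix(0, 4, K,
                                 dimnames = list(.subtype_levels,
                                                 colnames(reference)))
    signature_mixtures["HM", 1:2] <- c(0.6, 0.4)
    signature_mixtures["CIN-HR", 3:4] <- c(0.7, 0.3)
    signature_mixtures["CIN-LR", 5:6] <- c(0.7, 0.3)
    signature_mixtures["GS", 7:8] <- c(0.7, 0.3)
  }
  if (max(abs(rowSums(signature_mixtures) - 1)) > 1e-9) {
    stop_fmt("cohort_sim_config: mixture rows must sum to 1")
  }
  if (is.null(mutations_per_sample)) {
    mutations_per_sample <- data.frame(
      subtype = .subtype_levels,
      median = c(800, 120, 100, 60),
      sigma = c(0.3, 0.5, 0.5, 0.5),
      min = c(560, 25, 25, 25),
      max = c(30000, 320, 320, 320),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(lesion_amp_probs)) {
    bg <- c("Amp_8q24.21", "Del_8p23.1", "Amp_13q12.2", "Del_17p12",
            "Amp_20q13.12", "Del_18q21.2", "Amp_6p21.1", "Del_4q22.1")
    background <- matrix(0, length(bg), 4, dimnames = list(bg, .subtype_levels))
    background[, "HM"] <- 0.15
    background[, "CIN-HR"] <- c(0.55, 0.50, 0.10, 0.45, 0.50, 0.10, 0.45, 0.10)
    background[, "CIN-LR"] <- c(0.10, 0.10, 0.50, 0.10, 0.10, 0.50, 0.10, 0.45)
    background[, "GS"] <- 0.04
    lesion_amp_probs <- list(
      target = c(HM = 0.10, `CIN-HR` = 0.60, `CIN-LR` = 0.05, GS = 0.05),
      background = background
    )
  }
  cfg <- list(n_samples = as.integer(n_samples),
              hm_prevalence = unname(subtype_proportions["HM"]),
              subtype_proportions = subtype_proportions,
              reference = reference,
              signature_mixtures = signature_mixtures,
              mutations_per_sample = mutations_per_sample,
              lesion_amp_probs = lesion_amp_probs,
              purity_dist = purity_dist, ploidy_dist = ploidy_dist,
              mt_reads_model = mt_reads_model,
              hla_assessable_frac = hla_assessable_frac,
              hla_loh_prob = hla_loh_prob, npg_mut_prob = npg_mut_prob,
              neoantigen_rate_per_nonsilent = neoantigen_rate_per_nonsilent,
              silent_odds = silent_odds,
              survival_log_hazards = survival_log_hazards,
              censor_rate = censor_rate, seed = as.integer(seed))
  class(cfg) <- "cohort_sim_config"
  cfg
}

# deterministic per-sample substream seed: adding samples never perturbs
# earlier samples
.sample_seed <- function(master, i) {
  (as.integer(master) %% 1000003L) * 2011L + i * 7919L
}

.sim_gene_pool <- function() {
  drivers <- c("APC", "TP53", "KRAS", "PIK3CA", "SMAD4", "SMAD2", "BRAF",
               "FBXW7", "RB1", "CCND1", "CCNE1", "ACVR2A", "ERBB2", "POLE",
               "POLD1", "B2M", "TAP1", "RET", "NOTCH4", "PTEN")
  filler <- sprintf("GENE%03d", 1:180)
  list(genes = c(drivers, filler),
       w = c(rep(8, length(drivers)), rep(1, length(filler))))
}

# simulate one sample's mutation table rows
.sim_mutations <- function(sid, n_mut, p96, cfg, pool) {
  cls_idx <- sample.int(96, n_mut, replace = TRUE, prob = p96)
  cls <- sbs_classes()[cls_idx]
  ref <- substr(cls, 3, 3)
  alt <- substr(cls, 5, 5)
  trinuc <- trinuc_of_class(cls)
  silent <- stats::runif(n_mut) < cfg$silent_odds
  func <- ifelse(silent, "Silent",
                 sample(c("Missense_Mutation", "Nonsense_Mutation",
                          "Splice_Site"), n_mut, replace = TRUE,
                        prob = c(0.85, 0.10, 0.05)))
  true_vaf <- stats::rbeta(n_mut, 2.5, 5)
  depth <- stats::rpois(n_mut, 150) + 20L
  alt_reads <- stats::rbinom(n_mut, depth, true_vaf)
  vaf <- alt_reads / depth
  common <- stats::runif(n_mut) < 0.02
  af <- ifelse(common, stats::runif(n_mut, 0.06, 0.4), 0)
  n_neo <- ifelse(silent, 0L,
                  stats::rbinom(n_mut, 2,
                                cfg$neoantigen_rate_per_nonsilent))
  data.frame(
    sample_id = sid,
    gene = sample(pool$genes, n_mut, replace = TRUE, prob = pool$w),
    chrom = as.character(sample.int(22, n_mut, replace = TRUE)),
    pos = sample.int(2.4e8, n_mut, replace = TRUE),
    ref = ref, alt = alt, func_class = func, vaf = vaf, depth = depth,
    alt_reads = alt_reads, trinuc_context = trinuc,
    pop_af_1000g = af, pop_af_exac = af,
    oncogenicity = sample(c("oncogenic", "vus", "unknown"), n_mut,
                          replace = TRUE, prob = c(0.08, 0.32, 0.60)),
    n_neoantigens = n_neo, is_silent = silent,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic cohort
#'
#' Per sample (each driven by its own deterministic substream of the master
#' seed): a subtype is drawn from the configured proportions; a total
#' mutation count from the subtype's truncated log-normal; each mutation's
#' 96-class from the subtype's signature mixture applied to the reference;
#' silent status, functional class, VAF/depth/alt reads, population
#' frequencies, oncogenicity and per-mutation neoantigen flags; lesion calls
#' (Bernoulli per lesion, 10q11.21 amplification enriched in CIN-HR);
#' purity, ploidy and mitochondrial read counts consistent with a log-normal
#' true mScore; HLA allele-level calls with planted LOH; MT somatic variants
#' including blacklisted positions; and exponential survival with log-hazard
#' = subtype effect + stage effect + mScore effect, independently censored.
#'
#' @param config A [cohort_sim_config()].
#' @return List of class `simulated_cohort`: `mutations` (mutation_table),
#'   `lesions` (call data.frame), `clinical`, `hla`, `mt_counts`,
#'   `mt_variants`, `immune_flags` (`npg_mutated` per sample), and `truth`
#'   (true subtype, mixtures, planted counts, mScore, linear predictor).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  pool <- .sim_gene_pool()
  mixtures <- config$signature_mixtures
  ref <- config$reference
  mps <- config$mutations_per_sample
  stages <- c("I", "II", "III", "IV")
  mut_list <- vector("list", n)
  lesion_list <- vector("list", n)
  hla_list <- vector("list", n)
  mtvar_list <- vector("list", n)
  clinical <- data.frame(sample_id = ids, stage = NA_character_,
                         grade = NA_character_, site = NA_character_,
                         msi_high = NA, pole_mutant = NA,
                         os_months = NA_real_, os_event = NA,
                         stringsAsFactors = FALSE)
  mt_counts <- data.frame(sample_id = ids, r_m = NA_real_, r_n = NA_real_,
                          purity = NA_real_, ploidy = NA_real_,
                          stringsAsFactors = FALSE)
  immune_flags <- data.frame(sample_id = ids, npg_mutated = NA,
                             stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, subtype = NA_character_,
                      n_mut_planted = NA_integer_, mscore_true = NA_real_,
                      linear_predictor = NA_real_, hla_loh_true = NA,
                      stringsAsFactors = FALSE)
  surv <- config$survival_log_hazards
  mtm <- config$mt_reads_model
  lesion_labels <- rownames(config$lesion_amp_probs$background)
  for (i in seq_len(n)) {
    with_preserved_seed(.sample_seed(config$seed, i), {
      st <- sample(.subtype_levels, 1, prob = config$subtype_proportions)
      row <- mps[mps$subtype == st, ]
      n_mut <- round(stats::rlnorm(1, log(row$median), row$sigma))
      n_mut <- as.integer(min(max(n_mut, row$min), row$max))
      p96 <- as.numeric(ref %*% mixtures[st, ])
      mut_list[[i]] <- .sim_mutations(ids[i], n_mut, p96, config, pool)
      # lesions
      amp_t <- stats::runif(1) < config$lesion_amp_probs$target[st]
      bg <- stats::runif(length(lesion_labels)) <
        config$lesion_amp_probs$background[, st]
      labs <- c(if (amp_t) "Amp_10q11.21", lesion_labels[bg])
      if (length(labs)) {
        lesion_list[[i]] <- data.frame(
          sample_id = ids[i],
          lesion_id = sub("^(Amp|Del)_", "", labs),
          direction = ifelse(grepl("^Amp_", labs), "amp", "del"),
          called = TRUE, stringsAsFactors = FALSE)
      }
      # clinical covariates
      stage <- sample(stages, 1, prob = c(0.2, 0.3, 0.3, 0.2))
      grade <- sample(c("high", "moderately", "low", "mucinous"), 1,
                      prob = c(0.2, 0.6, 0.15, 0.05))
      site <- if (st == "HM") {
        sample(c("ascending", "transverse", "descending", "rectum"), 1,
               prob = c(0.6, 0.2, 0.1, 0.1))
      } else {
        sample(c("ascending", "transverse", "descending", "rectum"), 1,
               prob = c(0.25, 0.15, 0.2, 0.4))
      }
      msi <- stats::runif(1) < if (st == "HM") 0.64 else 0.02
      pole <- stats::runif(1) < if (st == "HM") 0.35 else 0.01
      # purity / ploidy / MT reads
      purity <- stats::rbeta(1, config$purity_dist[1], config$purity_dist[2])
      purity <- min(max(purity, 0.05), 1)
      ploidy <- as.numeric(sample(names(config$ploidy_dist), 1,
                                  prob = config$ploidy_dist))
      r_n <- stats::rlnorm(1, mtm$r_n_meanlog, mtm$r_n_sdlog)
      mscore_true <- stats::rlnorm(1, mtm$mscore_meanlog, mtm$mscore_sdlog)
      R <- purity_ploidy_factor(purity, ploidy)
      r_m <- round(mscore_true * r_n / R)
      # MT somatic variants (blacklisted positions included on purpose)
      n_v <- stats::rpois(1, mtm$variant_rate)
      if (n_v > 0) {
        bl <- stats::runif(n_v) < mtm$blacklist_frac
        posv <- ifelse(bl, sample(c(310L, 523L, 524L, 3107L), n_v,
                                  replace = TRUE),
                       sample(setdiff(1:16569, c(310L, 523L, 524L, 3107L)),
                              n_v, replace = TRUE))
        mtvar_list[[i]] <- data.frame(
          sample_id = ids[i], pos = posv,
          ref = sample(c("A", "C", "G", "T"), n_v, replace = TRUE),
          alt = sample(c("A", "C", "G", "T"), n_v, replace = TRUE),
          stringsAsFactors = FALSE)
      }
      # HLA allele calls
      assessable <- stats::runif(1) < config$hla_assessable_frac
      loh_true <- FALSE
      loci <- if (assessable) c("A", "B", "C") else c("A", "B")
      h <- data.frame(sample_id = ids[i], locus = loci,
                      allele = paste0("hla_", tolower(loci), "_01_01"),
                      ai_pvalue = stats::runif(length(loci), 0.2, 1),
                      cn_estimate = stats::runif(length(loci), 0.8, 1.2),
                      stringsAsFactors = FALSE)
      h$ci_upper <- h$cn_estimate + 0.2
      if (assessable && stats::runif(1) < config$hla_loh_prob) {
        loh_true <- TRUE
        j <- sample(3, 1)
        h$ai_pvalue[j] <- stats::runif(1, 1e-4, 0.009)
        h$cn_estimate[j] <- stats::runif(1, 0.05, 0.45)
        h$ci_upper[j] <- stats::runif(1, h$cn_estimate[j], 0.65)
      }
      hla_list[[i]] <- h
      npg <- stats::runif(1) < config$npg_mut_prob
      # survival
      lp <- surv$subtype[st] +
        surv$stage_per_level * (match(stage, stages) - 1) +
        surv$mscore * (log(mscore_true) - mtm$mscore_meanlog) /
          mtm$mscore_sdlog
      t_event <- stats::rexp(1, surv$baseline_rate * exp(lp))
      cens_rate <- surv$baseline_rate * config$censor_rate /
        (1 - config$censor_rate)
      t_cens <- min(stats::rexp(1, cens_rate), 120)
      clinical[i, c("stage", "grade", "site")] <- c(stage, grade, site)
      clinical$msi_high[i] <- msi
      clinical$pole_mutant[i] <- pole
      clinical$os_months[i] <- min(t_event, t_cens)
      clinical$os_event[i] <- t_event <= t_cens
      mt_counts[i, c("r_m", "r_n", "purity", "ploidy")] <-
        c(r_m, r_n, purity, ploidy)
      immune_flags$npg_mutated[i] <- npg
      truth[i, "subtype"] <- st
      truth$n_mut_planted[i] <- n_mut
      truth$mscore_true[i] <- mscore_true
      truth$linear_predictor[i] <- lp
      truth$hla_loh_true[i] <- loh_true
    })
  }
  lesions <- do.call(rbind, lesion_list[!vapply(lesion_list, is.null,
                                                logical(1))])
  if (is.null(lesions)) {
    lesions <- data.frame(sample_id = character(0), lesion_id = character(0),
                          direction = character(0), called = logical(0))
  }
  attr(lesions, "samples") <- ids
  out <- list(
    mutations = as_mutation_table(do.call(rbind, mut_list)),
    lesions = lesions,
    clinical = clinical,
    hla = do.call(rbind, hla_list),
    mt_counts = mt_counts,
    mt_variants = do.call(rbind, mtvar_list[!vapply(mtvar_list, is.null,
                                                    logical(1))]) %||%
      data.frame(sample_id = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
    immune_flags = immune_flags,
    truth = list(per_sample = truth, mixtures = mixtures,
                 config = config)
  )
  class(out) <- "simulated_cohort"
  out
}

#' Deterministic minimal cohort from printed counts
#'
#' Builds a cohort whose boolean flag marginals match the supplied counts
#' exactly (not in expectation): hypermutation, MSI-H, POLE, MSI-H-and-POLE
#' overlap, right-sided location, and MT-variant carriage. When `hm` is
#' given, the MSI/POLE/right-sided counts are assigned within the
#' hypermutated block (the usual reading of printed hypermutation tables);
#' otherwise within the whole cohort. Numeric fields are filled
#' deterministically consistent with the flags: TMB is spread uniformly over
#' \[10, 50\] for hypermutated samples and over \[0, 9.9\] otherwise;
#' MT-variant carriers get one non-blacklisted variant while non-carriers
#' get a variant at blacklisted position 310 (removed by the filter).
#'
#' @param group_spec Named list of non-negative counts: `n` (required) and
#'   optionally `hm`, `msi`, `pole`, `both`, `right_sided`, `mt_variant`.
#' @return List of class `fixture_cohort`: `clinical`, `tmb` (with
#'   `hypermutated`), `mt_variants`, `flags`.
#' @export
fixture_from_counts <- function(group_spec) {
  n <- group_spec$n
  if (is.null(n)) stop_fmt("fixture_from_counts: 'n' is required")
  if (n == 0) {
    empty <- data.frame(sample_id = character(0))
    return(structure(list(clinical = empty, tmb = empty,
                          mt_variants = data.frame(sample_id = character(0),
                                                   pos = integer(0)),
                          flags = empty),
                     class = "fixture_cohort"))
  }
  g <- function(k) group_spec[[k]] %||% 0L
  hm <- if (is.null(group_spec$hm)) n else group_spec$hm
  msi <- g("msi"); pole <- g("pole"); both <- g("both")
  right <- g("right_sided"); mtv <- g("mt_variant")
  if (any(c(hm, msi, pole, both, right, mtv) < 0)) {
    stop_fmt("fixture_from_counts: counts must be non-negative")
  }
  block <- hm  # flags are assigned within the hypermutated block
  if (both > min(msi, pole) || (msi + pole - both) > block ||
      right > block || hm > n || mtv > n) {
    stop_fmt("fixture_from_counts: overlapping counts exceed group size")
  }
  ids <- sprintf("F%04d", seq_len(n))
  is_hm <- seq_len(n) <= hm
  # within the block: samples 1..both get both flags, then msi-only, pole-only
  msi_flag <- seq_len(n) <= msi & is_hm
  pole_flag <- (seq_len(n) <= both |
                (seq_len(n) > msi & seq_len(n) <= msi + pole - both)) & is_hm
  right_flag <- seq_len(n) <= right & is_hm
  tmb_val <- numeric(n)
  tmb_val[is_hm] <- if (hm > 1) seq(10, 50, length.out = hm) else 10
  n_lo <- n - hm
  tmb_val[!is_hm] <- if (n_lo > 1) seq(0, 9.9, length.out = n_lo)
                     else if (n_lo == 1) 5 else numeric(0)
  clinical <- data.frame(
    sample_id = ids,
    stage = rep(c("I", "II", "III", "IV"), length.out = n),
    grade = "moderately",
    site = ifelse(right_flag, "ascending", "descending"),
    msi_high = msi_flag, pole_mutant = pole_flag,
    os_months = 12 + seq_len(n) %% 60,
    os_event = seq_len(n) %% 2 == 1,
    stringsAsFactors = FALSE
  )
  tmb <- data.frame(sample_id = ids,
                    n_qualifying = as.integer(round(tmb_val * 35)),
                    tmb = tmb_val, hypermutated = is_hm,
                    stringsAsFactors = FALSE)
  mt_variants <- data.frame(
    sample_id = ids,
    pos = ifelse(seq_len(n) <= mtv, 1000L + seq_len(n), 310L),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  structure(list(clinical = clinical, tmb = tmb, mt_variants = mt_variants,
                 flags = data.frame(sample_id = ids, hypermutated = is_hm,
                                    msi_high = msi_flag,
                                    pole_mutant = pole_flag,
                                    right_sided = right_flag,
                                    mt_variant = seq_len(n) <= mtv,
                                    stringsAsFactors = FALSE)),
            class = "fixture_cohort")
}

#' Simulate a qPCR Ct table from mitochondrial profiles
#'
#' The D-loop Ct tracks the mScore on the log2 scale:
#' `dCt = -log2(mscore * scale) + noise`, with the endogenous-control Ct
#' fixed, so at zero noise the 2^-ddCt method recovers relative mScores
#' exactly and doubling the mScore lowers the D-loop Ct by one cycle.
#'
#' @param profiles data.frame with `sample_id` and `mscore` (all positive).
#' @param noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param scale Multiplicative scale mapping mScore to relative copies.
#' @param ct_control Fixed endogenous-control Ct (default 20).
#' @param seed Seed for the noise draw.
#' @return data.frame `sample_id`, `ct_control`, `ct_dloop`.
#' @export
simulate_qpcr <- function(profiles, noise_sd = 0.2, scale = 100,
                          ct_control = 20, seed = 1L) {
  require_columns(profiles, c("sample_id", "mscore"), "mito profiles")
  if (any(profiles$mscore <= 0)) {
    stop_fmt("simulate_qpcr: mScores must be positive")
  }
  with_preserved_seed(seed, {
    dct <- -log2(profiles$mscore * scale)
    noise <- if (noise_sd > 0) stats::rnorm(nrow(profiles), 0, noise_sd) else 0
    data.frame(sample_id = profiles$sample_id,
               ct_control = ct_control,
               ct_dloop = ct_control + dct + noise,
               stringsAsFactors = FALSE)
  })
}
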