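# Synthetic data generators with planted ground truth.
#
# Every input the pipeline consumes can be generated here: two-condition
# Infinium-style intensity matrices with planted hyper/hypomethylated CpGs,
# a matched expression matrix with planted repression, GMT gene-set
# collections with causal (plant-enriched) sets, and a patient cohort whose
# survival hazard depends on a planted latent score. A fixed seed gives
# byte-identical outputs; each generator runs on its own sub-stream so the
# four datasets can be regenerated independently.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study design the pipeline targets: a 3-replicate
#' control arm versus a 6-replicate knockdown arm on an 850K-style array,
#' a dominant hypermethylation response concentrated in regulatory regions
#' of designated repressed (tumor-suppressor-like) genes, correlated
#' down-expression of those genes, oncogenic-signature-style gene sets, and
#' a cohort whose hazard rises with the planted stress score.
#'
#' @param n_probes number of CpG probes.
#' @param n_genes size of the gene universe.
#' @param n_ctrl_samples,n_case_samples replicates per condition (3 vs 6).
#' @param frac_hyper_probes,frac_hypo_probes fractions of probes planted as
#'   hyper/hypomethylated in the case condition; must sum to at most 1.
#' @param planted_delta_beta planted methylation shift in beta units.
#' @param beta_noise_conc concentration of the Beta-distributed replicate
#'   noise around each probe's target beta; 1000 gives a replicate SD of
#'   roughly 0.01-0.016, typical of Infinium arrays.
#' @param frac_type2_probes fraction of probes using the type II chemistry.
#' @param region_mix named fractions over region classes
#'   (promoter, enhancer, body, intergenic, mixed); must sum to 1.
#' @param n_repressed_genes number of genes planted as epigenetically
#'   repressed; each is guaranteed one planted hyper probe in its promoter
#'   or enhancer.
#' @param expr_log2fc planted log2 fold-change (down in cases) for
#'   repressed genes.
#' @param n_gene_sets,set_size_range number of gene sets and (min, max) size.
#' @param n_patients cohort size.
#' @param hazard_coef log-hazard increase per unit of the latent score.
#' @param censor_rate expected fraction of censored patients.
#' @param seed master seed; fans out to per-generator sub-streams.
#' @param type2_compression slope of the type II distortion
#'   beta' = 0.5 + s (beta - 0.5).
#' @param det_fail_frac fraction of probes failing detection in one sample.
#' @param frac_cross_reactive,frac_snp,frac_sex_chrom fractions of flagged /
#'   sex-chromosome probes (exercise the filtering step).
#' @param n_causal_sets number of gene sets enriched in repressed genes.
#' @param causal_enrichment fraction of each causal set drawn from the
#'   repressed genes (0 = indistinguishable from decoys).
#' @param cohort_loading magnitude of the negative loading of signature-gene
#'   expression on the latent patient score.
#' @param expr_noise_sd replicate SD of log2 expression.
#' @param hyper_concentration probability that a non-anchor planted hyper
#'   probe in a regulatory region is rewired to a repressed gene, producing
#'   DMR-like clusters of planted CpGs per gene.
#' @param base_event_rate baseline event rate per month (1/60: mean survival
#'   of 60 months at score 0).
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of the
#'   total intensity U + M.
#' @param channel_noise_sd multiplicative log-scale noise per channel.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_probes = 10000, n_genes = 2000,
                         n_ctrl_samples = 3, n_case_samples = 6,
                         frac_hyper_probes = 0.08, frac_hypo_probes = 0.012,
                         planted_delta_beta = 0.3,
                         beta_noise_conc = 1000, frac_type2_probes = 0.7,
                         region_mix = c(promoter = 0.25, enhancer = 0.15,
                                        body = 0.30, intergenic = 0.20,
                                        mixed = 0.10),
                         n_repressed_genes = 100, expr_log2fc = 1,
                         n_gene_sets = 30, set_size_range = c(80, 150),
                         n_patients = 200, hazard_coef = 0.8,
                         censor_rate = 0.3, seed = 1,
                         type2_compression = 0.8, det_fail_frac = 0.002,
                         frac_cross_reactive = 0.01, frac_snp = 0.01,
                         frac_sex_chrom = 0.02,
                         n_causal_sets = 3, causal_enrichment = 0.6,
                         cohort_loading = 0.6, expr_noise_sd = 0.1,
                         hyper_concentration = 0.7,
                         base_event_rate = 1 / 60,
                         intensity_meanlog = log(5000),
                         intensity_sdlog = 0.3,
                         channel_noise_sd = 0.03) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fr <- c("frac_hyper_probes", "frac_hypo_probes", "frac_type2_probes",
          "censor_rate", "det_fail_frac", "frac_cross_reactive", "frac_snp",
          "frac_sex_chrom", "causal_enrichment")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a fraction in [0, 1]", f))
  }
  if (cfg$frac_hyper_probes + cfg$frac_hypo_probes > 1)
    stop("frac_hyper_probes + frac_hypo_probes must be <= 1")
  cnt <- c("n_probes", "n_genes", "n_ctrl_samples", "n_case_samples",
           "n_gene_sets", "n_patients")
  for (f in cnt) {
    if (cfg[[f]] < 1) stop(sprintf("'%s' must be a positive count", f))
  }
  if (cfg$n_repressed_genes < 0) stop("n_repressed_genes must be >= 0")
  need <- c("promoter", "enhancer", "body", "intergenic", "mixed")
  if (!all(need %in% names(cfg$region_mix)))
    stop("region_mix must name all of: ", paste(need, collapse = ", "))
  if (abs(sum(cfg$region_mix) - 1) > 1e-8)
    stop("region_mix fractions must sum to 1")
  if (cfg$planted_delta_beta < 0 || cfg$planted_delta_beta > 1)
    stop("planted_delta_beta must be in [0, 1]")
  if (length(cfg$set_size_range) != 2 ||
      cfg$set_size_range[1] > cfg$set_size_range[2] ||
      cfg$set_size_range[1] < 1)
    stop("set_size_range must be (min, max) with 1 <= min <= max")
  invisible(cfg)
}

# Beta draw with a given mode and concentration (mode-parameterized so the
# planted target is the distribution's peak, not its mean).
rbeta_mode <- function(n, mode, conc) {
  stats::rbeta(n, 1 + mode * conc, 1 + (1 - mode) * conc)
}

#' Generate a two-condition Infinium-style methylation dataset
#'
#' Draws a bimodal baseline beta per probe (unmethylated mode near 0.1,
#' methylated near 0.9), plants hyper/hypomethylated probes with a case-arm
#' shift of `planted_delta_beta`, compresses type II probes towards 0.5,
#' and emits methylated/unmethylated intensity matrices such that
#' M / (U + M) equals the intended beta up to small multiplicative channel
#' noise. Every planted repressed gene carries at least one planted hyper
#' probe in its promoter or enhancer, which is what makes the downstream
#' repressed-gene list recoverable.
#'
#' @param cfg a [synth_config()].
#' @return list with intensity matrices `M` and `U`, `detection_p`,
#'   `annotation` (probe_id, design_type, chrom, gene_id, region_class,
#'   cross_reactive, snp_overlap), `condition` factor, and `truth`
#'   (hyper/hypo probe ids, repressed gene ids).
#' @export
make_methylation_dataset <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(sub_seed(cfg$seed, 1))
  n <- cfg$n_probes
  ns <- cfg$n_ctrl_samples + cfg$n_case_samples
  probe_id <- sprintf("cg%08d", seq_len(n))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  samples <- c(sprintf("ctrl_%d", seq_len(cfg$n_ctrl_samples)),
               sprintf("case_%d", seq_len(cfg$n_case_samples)))
  condition <- factor(rep(c("control", "case"),
                          c(cfg$n_ctrl_samples, cfg$n_case_samples)),
                      levels = c("control", "case"))

  region <- sample(names(cfg$region_mix), n, replace = TRUE,
                   prob = cfg$region_mix)
  gene_id <- ifelse(region == "intergenic", NA_character_,
                    sample(genes, n, replace = TRUE))
  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
  n_sex <- round(cfg$frac_sex_chrom * n)
  if (n_sex > 0) {
    sex_idx <- sample.int(n, n_sex)
    chrom[sex_idx] <- sample(c("chrX", "chrY"), n_sex, replace = TRUE)
  }
  cross_reactive <- stats::runif(n) < cfg$frac_cross_reactive
  snp_overlap <- stats::runif(n) < cfg$frac_snp

  # bimodal baseline: modes ~0.1 and ~0.9, equal weight, concentration 30
  low_comp <- stats::runif(n) < 0.5
  baseline <- ifelse(low_comp, rbeta_mode(n, 0.10, 30), rbeta_mode(n, 0.90, 30))

  eligible <- !cross_reactive & !snp_overlap & !(chrom %in% c("chrX", "chrY"))
  n_hyper <- round(cfg$frac_hyper_probes * n)
  n_hypo <- round(cfg$frac_hypo_probes * n)
  n_rep <- if (n_hyper > 0) min(cfg$n_repressed_genes, n_hyper) else 0

  hyper_idx <- integer(0); hypo_idx <- integer(0)
  repressed_genes <- character(0)
  if (n_rep > 0) {
    reg_pool <- which(eligible & region %in% c("promoter", "enhancer"))
    if (length(reg_pool) < n_rep)
      stop("not enough eligible promoter/enhancer probes to anchor ",
           n_rep, " repressed genes")
    reserved <- sample(reg_pool, n_rep)
    repressed_genes <- sample(genes, n_rep)
    gene_id[reserved] <- repressed_genes
    hyper_idx <- reserved
  }
  free <- setdiff(which(eligible), hyper_idx)
  if (n_hyper > length(hyper_idx)) {
    extra <- sample(free, n_hyper - length(hyper_idx))
    # hypermethylation concentrates in regulatory regions of the repressed
    # genes (DMR-like clusters of planted CpGs per gene)
    if (length(repressed_genes) > 0) {
      reg_extra <- extra[region[extra] %in% c("promoter", "enhancer", "mixed")]
      rewire <- reg_extra[stats::runif(length(reg_extra)) <
                            cfg$hyper_concentration]
      if (length(rewire) > 0)
        gene_id[rewire] <- sample(repressed_genes, length(rewire),
                                  replace = TRUE)
    }
    hyper_idx <- c(hyper_idx, extra)
    free <- setdiff(free, extra)
  }
  if (n_hypo > 0) hypo_idx <- sample(free, n_hypo)

  # planted probes start from the matching baseline mode so the shift fits
  baseline[hyper_idx] <- rbeta_mode(length(hyper_idx), 0.10, 30)
  baseline[hypo_idx] <- rbeta_mode(length(hypo_idx), 0.90, 30)

  case_target <- baseline
  case_target[hyper_idx] <- baseline[hyper_idx] + cfg$planted_delta_beta
  case_target[hypo_idx] <- baseline[hypo_idx] - cfg$planted_delta_beta
  planted <- c(hyper_idx, hypo_idx)
  if (length(planted) > 0) {
    out_of_range <- mean(case_target[planted] < 0 | case_target[planted] > 1)
    if (out_of_range > 0.5)
      stop(sprintf(paste0(
        "planted_delta_beta = %.2f pushes beta outside [0, 1] for %.0f%% ",
        "of planted probes; reduce the effect size"),
        cfg$planted_delta_beta, 100 * out_of_range))
  }
  baseline <- clip(baseline, 0.005, 0.995)
  case_target <- clip(case_target, 0.005, 0.995)

  conc <- cfg$beta_noise_conc
  true_beta <- matrix(NA_real_, n, ns, dimnames = list(probe_id, samples))
  for (j in seq_len(ns)) {
    tgt <- if (condition[j] == "control") baseline else case_target
    true_beta[, j] <- stats::rbeta(n, tgt * conc, (1 - tgt) * conc)
  }

  design_type <- ifelse(stats::runif(n) < cfg$frac_type2_probes, "II", "I")
  obs_beta <- true_beta
  t2 <- design_type == "II"
  obs_beta[t2, ] <- 0.5 + cfg$type2_compression * (true_beta[t2, ] - 0.5)

  total <- matrix(stats::rlnorm(n * ns, cfg$intensity_meanlog,
                                cfg$intensity_sdlog), n, ns)
  M <- obs_beta * total *
    exp(matrix(stats::rnorm(n * ns, 0, cfg$channel_noise_sd), n, ns))
  U <- (1 - obs_beta) * total *
    exp(matrix(stats::rnorm(n * ns, 0, cfg$channel_noise_sd), n, ns))
  dimnames(M) <- dimnames(U) <- list(probe_id, samples)

  detection_p <- matrix(stats::runif(n * ns, 0, 0.01), n, ns,
                        dimnames = list(probe_id, samples))
  n_fail <- round(cfg$det_fail_frac * n)
  if (n_fail > 0) {
    fail_pool <- setdiff(seq_len(n), planted)
    fail_idx <- sample(fail_pool, min(n_fail, length(fail_pool)))
    for (i in fail_idx)
      detection_p[i, sample.int(ns, 1)] <- stats::runif(1, 0.06, 0.5)
  }

  annotation <- data.frame(
    probe_id = probe_id, design_type = design_type, chrom = chrom,
    gene_id = gene_id, region_class = region,
    cross_reactive = cross_reactive, snp_overlap = snp_overlap,
    stringsAsFactors = FALSE)

  truth <- list(hyper_probe_ids = probe_id[hyper_idx],
                hypo_probe_ids = probe_id[hypo_idx],
                repressed_gene_ids = repressed_genes,
                causal_set_names = character(0),
                true_patient_score = NULL)

  list(M = M, U = U, detection_p = detection_p, annotation = annotation,
       condition = condition, truth = truth)
}

#' Generate a matched TPM-like expression dataset
#'
#' Log-normal baseline expression per gene; genes in
#' `truth$repressed_gene_ids` are down-shifted by `expr_log2fc` in the case
#' samples. Repressed genes are given a well-expressed baseline (so their
#' repression is a transcriptional signal, not a detection-limit artifact).
#'
#' @param cfg a [synth_config()].
#' @param truth ground truth from [make_methylation_dataset()].
#' @return list with `tpm` (genes x samples), `condition`, and `truth`.
#' @export
make_expression_dataset <- function(cfg, truth) {
  validate_synth_config(cfg)
  set.seed(sub_seed(cfg$seed, 2))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  ns <- cfg$n_ctrl_samples + cfg$n_case_samples
  samples <- c(sprintf("ctrl_%d", seq_len(cfg$n_ctrl_samples)),
               sprintf("case_%d", seq_len(cfg$n_case_samples)))
  condition <- factor(rep(c("control", "case"),
                          c(cfg$n_ctrl_samples, cfg$n_case_samples)),
                      levels = c("control", "case"))
  base_log2 <- log2(stats::rlnorm(cfg$n_genes, log(20), 1.2))
  rep_idx <- match(truth$repressed_gene_ids, genes)
  rep_idx <- rep_idx[!is.na(rep_idx)]
  base_log2[rep_idx] <- log2(stats::rlnorm(length(rep_idx), log(60), 0.4))
  tpm <- matrix(NA_real_, cfg$n_genes, ns, dimnames = list(genes, samples))
  for (j in seq_len(ns)) {
    mu <- base_log2
    if (condition[j] == "case") mu[rep_idx] <- mu[rep_idx] - cfg$expr_log2fc
    tpm[, j] <- 2^(mu + stats::rnorm(cfg$n_genes, 0, cfg$expr_noise_sd))
  }
  list(tpm = tpm, condition = condition, truth = truth)
}

#' Generate a gene-set collection with causal (plant-enriched) sets
#'
#' `n_causal_sets` sets draw a fraction `causal_enrichment` of their members
#' from the repressed genes (labelled TSG-A: tumor-suppressor activation);
#' the remaining decoy sets are uniform draws from the gene universe with
#' TSG-A/OG-I labels assigned at random.
#'
#' @param cfg a [synth_config()].
#' @param truth ground truth carrying `repressed_gene_ids`.
#' @return list with `sets` (a `gene_set_collection`, see [parse_gmt()]) and
#'   updated `truth` (`causal_set_names` filled in).
#' @export
make_gene_sets <- function(cfg, truth) {
  validate_synth_config(cfg)
  set.seed(sub_seed(cfg$seed, 3))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  if (cfg$set_size_range[2] > cfg$n_genes)
    stop("set_size_range exceeds the gene universe")
  n_causal <- min(cfg$n_causal_sets, cfg$n_gene_sets)
  if (length(truth$repressed_gene_ids) == 0) n_causal <- 0
  sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                  cfg$n_gene_sets, replace = TRUE)
  sets <- vector("list", cfg$n_gene_sets)
  cls <- character(cfg$n_gene_sets)
  nms <- character(cfg$n_gene_sets)
  rep_genes <- truth$repressed_gene_ids
  for (k in seq_len(cfg$n_gene_sets)) {
    if (k <= n_causal) {
      n_in <- min(round(cfg$causal_enrichment * sizes[k]), length(rep_genes))
      members <- c(sample(rep_genes, n_in),
                   sample(setdiff(genes, rep_genes), sizes[k] - n_in))
      nms[k] <- sprintf("CAUSAL_TSGA_%d", k)
      cls[k] <- "TSG-A"
    } else {
      members <- sample(genes, sizes[k])
      nms[k] <- sprintf("DECOY_SET_%d", k - n_causal)
      cls[k] <- sample(c("TSG-A", "OG-I"), 1)
    }
    sets[[k]] <- members
  }
  names(sets) <- nms
  names(cls) <- nms
  collection <- gene_set_collection(sets, cls)
  truth$causal_set_names <- nms[seq_len(n_causal)]
  list(sets = collection, truth = truth)
}

#' Generate a patient cohort with a planted signature-driven hazard
#'
#' Each patient carries a latent standard-normal stress score; signature
#' genes load negatively on it (high score, low expression, matching the
#' repressed-gene convention), and survival times are exponential with
#' log-hazard `hazard_coef` x score. Censoring is independent with expected
#' fraction `censor_rate`.
#'
#' @param cfg a [synth_config()].
#' @param signature_genes character vector of genes loaded on the score.
#' @return list with `expr` (genes x patients, log-scale), `clinical`
#'   (patient_id, time_months, event) and `true_score`.
#' @export
make_cohort <- function(cfg, signature_genes) {
  validate_synth_config(cfg)
  if (length(signature_genes) == 0) stop("signature_genes must be nonempty")
  if (cfg$n_patients < 10)
    stop("n_patients must be >= 10: survival estimation is degenerate below that")
  set.seed(sub_seed(cfg$seed, 4))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  patients <- sprintf("pt_%04d", seq_len(cfg$n_patients))
  z <- stats::rnorm(cfg$n_patients)
  expr <- matrix(stats::rnorm(cfg$n_genes * cfg$n_patients),
                 cfg$n_genes, cfg$n_patients,
                 dimnames = list(genes, patients))
  expr <- expr + stats::rnorm(cfg$n_genes, 9, 2)  # gene-level baseline offsets
  sig_idx <- match(intersect(signature_genes, genes), genes)
  if (length(sig_idx) > 0)
    expr[sig_idx, ] <- expr[sig_idx, ] -
      cfg$cohort_loading * matrix(z, length(sig_idx), cfg$n_patients,
                                  byrow = TRUE)
  rate <- cfg$base_event_rate * exp(cfg$hazard_coef * z)
  t_event <- stats::rexp(cfg$n_patients, rate)
  if (cfg$censor_rate > 0) {
    rate_c <- cfg$base_event_rate * cfg$censor_rate / (1 - cfg$censor_rate)
    t_cens <- stats::rexp(cfg$n_patients, rate_c)
  } else {
    t_cens <- rep(Inf, cfg$n_patients)
  }
  clinical <- data.frame(
    patient_id = patients,
    time_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE)
  list(expr = expr, clinical = clinical, true_score = stats::setNames(z, patients))
}
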