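# End-to-end pipeline: methylome -> stand-in DE -> preranked GSEA on both
# sides -> meta-integration -> signature refinement on the cohort ->
# scoring, stratification and survival. One configuration, one run
# directory, a provenance record, and deterministic outputs under a fixed
# seed.

#' Pipeline configuration
#'
#' Holds the input file paths and every threshold the pipeline applies.
#' Defaults are the published cutoffs: delta-beta > 0.2 with adjusted
#' p < 0.05 for DMCs, FDR < 0.05 on both DE tests, p and FDR q < 0.05 for
#' GSEA, R > 0.25 with p < 0.05 for refinement, and a control-mean TPM
#' cutoff of 1.
#'
#' @param input_dir directory holding the inputs (as written by
#'   [generate_synthetic_inputs()], or equivalent real data).
#' @param delta_beta DMC delta-beta threshold (0, 1).
#' @param p_adj DMC adjusted-p threshold.
#' @param de_fdr DE FDR threshold (both tests).
#' @param gsea_fdr GSEA significance threshold (p and q).
#' @param refine_r,refine_p refinement correlation and p thresholds.
#' @param tpm_min low-expression TPM cutoff.
#' @param weight_p GSEA score weighting exponent.
#' @param n_perm GSEA permutations.
#' @param seed seed for the GSEA permutations.
#' @param aggregation gene-level delta-beta rule ("max_abs" or "mean").
#' @param stratification "tertiles" or "median".
#' @param intensity_offset offset in the beta formula denominator.
#' @param signature_mode "union" or "intersection" of pathway members.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, delta_beta = 0.2, p_adj = 0.05,
                            de_fdr = 0.05, gsea_fdr = 0.05,
                            refine_r = 0.25, refine_p = 0.05, tpm_min = 1,
                            weight_p = 1, n_perm = 1000, seed = 1,
                            aggregation = "max_abs",
                            stratification = "tertiles",
                            intensity_offset = 0,
                            signature_mode = "union") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  in01 <- c("delta_beta", "p_adj", "de_fdr", "gsea_fdr", "refine_r",
            "refine_p")
  for (f in in01) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(sprintf("'%s' must lie strictly within (0, 1), got %s", f, v))
  }
  if (cfg$tpm_min < 0) stop("tpm_min must be nonnegative")
  if (cfg$n_perm < 100) stop("n_perm must be >= 100")
  if (!cfg$aggregation %in% c("max_abs", "mean"))
    stop("aggregation must be 'max_abs' or 'mean'")
  if (!cfg$stratification %in% c("tertiles", "median"))
    stop("stratification must be 'tertiles' or 'median'")
  if (!dir.exists(cfg$input_dir))
    stop("input_dir does not exist: ", cfg$input_dir)
  invisible(cfg)
}

read_manifest_inputs <- function(input_dir) {
  manifest_path <- file.path(input_dir, "manifest.yaml")
  if (!file.exists(manifest_path))
    stop("no manifest.yaml in ", input_dir)
  manifest <- yaml::read_yaml(manifest_path)
  p <- function(key) {
    f <- file.path(input_dir, manifest$files[[key]])
    if (!file.exists(f)) stop("missing input file: ", f)
    f
  }
  list(
    M = read_matrix_tsv(p("intensity_methylated")),
    U = read_matrix_tsv(p("intensity_unmethylated")),
    detection_p = read_matrix_tsv(p("detection_p")),
    annotation = utils::read.delim(p("probe_annotation"),
                                   stringsAsFactors = FALSE),
    tpm = read_matrix_tsv(p("expression_tpm")),
    sets = parse_gmt(p("gene_sets")),
    cohort_expr = read_matrix_tsv(p("cohort_expression")),
    cohort_clinical = utils::read.delim(p("cohort_clinical"),
                                        stringsAsFactors = FALSE),
    condition = factor(unlist(manifest$condition),
                       levels = c("control", "case")),
    manifest = manifest)
}

#' Run the full pipeline
#'
#' Executes, in order: beta computation, probe filtering, peak-based
#' correction, differential methylation; stand-in differential expression;
#' preranked GSEA on gene-level delta-beta and on the DE fold-change proxy;
#' meta-integration into the repressed-gene list, repressed pathways and
#' the derived signature; correlation-based refinement on the cohort; MG
#' scoring, tertile stratification, Kaplan-Meier curves and the low-vs-high
#' log-rank test. Every stage's artifact is written to `out_dir` as TSV,
#' together with a provenance JSON and a plain-text summary.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return (invisibly) a list with every stage result: `dmc`,
#'   `dmc_summary`, `deg`, `deg_summary`, `meth_gsea`, `expr_gsea`,
#'   `integration`, `refinement`, `mg_score`, `cohort`, `km`, `logrank`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_manifest_inputs(cfg$input_dir)

  # methylome
  beta <- compute_beta(inp$M, inp$U, condition = inp$condition,
                       offset = cfg$intensity_offset)
  beta <- filter_probes(beta, inp$annotation, inp$detection_p)
  beta <- peak_correct(beta, inp$annotation)
  dmc <- diff_methylation(beta, ann = inp$annotation,
                          delta_beta_min = cfg$delta_beta,
                          p_adj_max = cfg$p_adj)
  dmc_summary <- summarize_dmc(dmc)
  write_table_tsv(dmc, file.path(out_dir, "dmc_table.tsv"))

  # transcriptome
  deg <- standin_de(inp$tpm, inp$condition, fdr = cfg$de_fdr,
                    tpm_min = cfg$tpm_min)
  deg_summary <- summarize_deg(deg)
  write_table_tsv(deg, file.path(out_dir, "deg_table.tsv"))

  # preranked GSEA, methylation and expression sides
  meth_rank <- make_rank_file(gene_level_scores(dmc, rule = cfg$aggregation))
  expr_rank <- make_rank_file(stats::setNames(deg$beta_fc, deg$gene))
  write_rnk(meth_rank, file.path(out_dir, "methylation.rnk"))
  write_rnk(expr_rank, file.path(out_dir, "expression.rnk"))
  meth_gsea <- permutation_stats(meth_rank, inp$sets, n_perm = cfg$n_perm,
                                 weight_p = cfg$weight_p, seed = cfg$seed)
  expr_gsea <- permutation_stats(expr_rank, inp$sets, n_perm = cfg$n_perm,
                                 weight_p = cfg$weight_p,
                                 seed = cfg$seed + 1)
  write_table_tsv(meth_gsea, file.path(out_dir, "gsea_methylation.tsv"))
  write_table_tsv(expr_gsea, file.path(out_dir, "gsea_expression.tsv"))

  # meta-integration
  flags <- gene_methylation_status(dmc)
  integration <- build_lists(flags, deg)
  integration$repressed_pathways <-
    epigenetically_repressed_pathways(meth_gsea, expr_gsea)
  integration$signature_genes <- derive_signature(
    integration$list2_down_hyper, integration$repressed_pathways,
    inp$sets, mode = cfg$signature_mode)
  for (nm in c("list1_up_hypo", "list2_down_hyper", "body_up_hyper",
               "body_down_hypo", "signature_genes")) {
    write_table_tsv(data.frame(gene = integration[[nm]]),
                    file.path(out_dir, paste0(nm, ".tsv")))
  }

  # refinement on the cohort
  membership <- do.call(rbind, lapply(integration$repressed_pathways,
    function(p) {
      g <- intersect(inp$sets$sets[[p]], integration$signature_genes)
      if (length(g) == 0) return(NULL)
      data.frame(gene = g, pathway = p, stringsAsFactors = FALSE)
    }))
  if (is.null(membership) || nrow(membership) == 0) {
    warning("no signature gene belongs to a repressed pathway; ",
            "skipping refinement, scoring the unrefined signature")
    refinement <- list(genes = integration$signature_genes,
                       report = NULL)
  } else {
    refinement <- refine_signature(inp$cohort_expr, membership, inp$sets,
                                   r_min = cfg$refine_r,
                                   p_max = cfg$refine_p)
    write_table_tsv(refinement$report,
                    file.path(out_dir, "refinement_report.tsv"))
  }
  final_signature <- if (length(refinement$genes) > 0) refinement$genes
  else integration$signature_genes
  if (length(final_signature) == 0)
    stop("pipeline stage 'signature': empty signature, cannot score cohort")

  # scoring, stratification, survival
  mg_score <- signature_score(inp$cohort_expr, final_signature)
  write_table_tsv(data.frame(patient_id = names(mg_score$score),
                             score = unname(mg_score$score)),
                  file.path(out_dir, "mg_score.tsv"))
  cohort <- stratify(mg_score, inp$cohort_clinical,
                     scheme = cfg$stratification)
  write_table_tsv(cohort, file.path(out_dir, "cohort_groups.tsv"))
  km <- lapply(split(cohort, cohort$group), function(d)
    if (nrow(d) > 0) km_estimate(d$time_months, d$event) else NULL)
  for (g in names(km)) if (!is.null(km[[g]]))
    write_table_tsv(km[[g]], file.path(out_dir, paste0("km_", g, ".tsv")))
  lr <- logrank(cohort[cohort$group == "low", ],
                cohort[cohort$group == "high", ])

  provenance <- list(
    config = unclass(cfg), seed = cfg$seed,
    n_probes_tested = nrow(dmc), n_genes_tested = nrow(deg),
    final_signature = final_signature,
    package_version = as.character(utils::packageVersion("mgstress")),
    r_version = R.version.string)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(chi2 = lr$chi2, p = lr$p,
                            n = as.list(stats::setNames(as.integer(lr$n),
                                                        names(lr$n)))),
                       file.path(out_dir, "logrank.json"),
                       auto_unbox = TRUE, digits = NA)

  summary_lines <- c(
    sprintf("DMCs: %d (%s%% hyper, %s%% hypo)", dmc_summary$n_dmc,
            dmc_summary$pct_hyper, dmc_summary$pct_hypo),
    sprintf("DEGs: %d (%d down, %d up)", deg_summary$n_total,
            deg_summary$n_down, deg_summary$n_up),
    sprintf("Repressed genes (list 2): %d",
            length(integration$list2_down_hyper)),
    sprintf("Repressed pathways: %d (%s)",
            length(integration$repressed_pathways),
            paste(integration$repressed_pathways, collapse = ", ")),
    sprintf("Derived signature: %d genes; refined: %d genes",
            length(integration$signature_genes), length(final_signature)),
    sprintf("Log-rank low vs high: chi2 = %.2f, p = %.3g", lr$chi2, lr$p))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(dmc = dmc, dmc_summary = dmc_summary, deg = deg,
                 deg_summary = deg_summary, meth_gsea = meth_gsea,
                 expr_gsea = expr_gsea, integration = integration,
                 refinement = refinement, final_signature = final_signature,
                 mg_score = mg_score, cohort = cohort, km = km,
                 logrank = lr))
}
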