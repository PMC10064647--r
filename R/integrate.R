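# Meta-integration of differential methylation, differential expression and
# pathway enrichment: regulatory-region methylation flags per gene, the two
# inverse-relation gene lists, the epigenetically repressed pathways, and
# the stress gene signature.

#' Region-wise methylation flags per gene
#'
#' A gene is `hyper_regulatory` when it carries at least one hypermethylated
#' CpG assigned to its promoter, enhancer or mixed (promoter-or-enhancer)
#' region; `hypo_regulatory` analogously. Gene-body flags are computed
#' separately — body methylation never contributes to the regulatory flags.
#'
#' @param dmc annotated `dmc_table` (gene_id, region_class, status).
#' @return data.frame: gene_id, hyper_regulatory, hypo_regulatory,
#'   body_hyper, body_hypo. Genes with no DMC carry all-FALSE flags.
#' @export
gene_methylation_status <- function(dmc) {
  if (is.null(dmc$gene_id) || is.null(dmc$region_class))
    stop("dmc table must carry gene_id and region_class")
  d <- dmc[!is.na(dmc$gene_id), ]
  regulatory <- d$region_class %in% c("promoter", "enhancer", "mixed")
  body <- d$region_class == "body"
  genes <- sort(unique(d$gene_id))
  any_by_gene <- function(mask) {
    hits <- unique(d$gene_id[mask])
    genes %in% hits
  }
  data.frame(
    gene_id = genes,
    hyper_regulatory = any_by_gene(d$status == "hyper" & regulatory),
    hypo_regulatory = any_by_gene(d$status == "hypo" & regulatory),
    body_hyper = any_by_gene(d$status == "hyper" & body),
    body_hypo = any_by_gene(d$status == "hypo" & body),
    stringsAsFactors = FALSE)
}

#' Build the inverse-relation gene lists
#'
#' List 2 (the epigenetically repressed genes) is the intersection of
#' down-regulated genes with regulatory hypermethylation; list 1 is
#' up-regulated with regulatory hypomethylation. Body lists pair
#' up-regulation with body hypermethylation and down-regulation with body
#' hypomethylation. Genes that are both hyper- and hypomethylated in
#' regulatory regions are conflicting and excluded from lists 1 and 2.
#'
#' @param flags output of [gene_methylation_status()].
#' @param deg a `deg_table`.
#' @return an `integration_result` list: list1_up_hypo, list2_down_hyper,
#'   body_up_hyper, body_down_hypo, conflicted, repressed_pathways (empty
#'   here), signature_genes (empty here).
#' @export
build_lists <- function(flags, deg) {
  down <- deg$gene[deg$status == "down"]
  up <- deg$gene[deg$status == "up"]
  conflicted <- flags$gene_id[flags$hyper_regulatory & flags$hypo_regulatory]
  hyper_reg <- setdiff(flags$gene_id[flags$hyper_regulatory], conflicted)
  hypo_reg <- setdiff(flags$gene_id[flags$hypo_regulatory], conflicted)
  res <- list(
    list1_up_hypo = sort(intersect(up, hypo_reg)),
    list2_down_hyper = sort(intersect(down, hyper_reg)),
    body_up_hyper = sort(intersect(up, flags$gene_id[flags$body_hyper])),
    body_down_hypo = sort(intersect(down, flags$gene_id[flags$body_hypo])),
    conflicted = sort(conflicted),
    repressed_pathways = character(0),
    signature_genes = character(0))
  if (length(res$list1_up_hypo) == 0 && length(res$list2_down_hyper) == 0)
    warning("no gene shows an inverse methylation-expression relation")
  if (length(conflicted) > 0)
    message(length(conflicted),
            " gene(s) hyper- and hypomethylated in regulatory regions; excluded")
  class(res) <- "integration_result"
  res
}

#' Epigenetically repressed pathways
#'
#' Pathways significant with positive NES in the methylation GSEA and
#' significant with negative NES in the expression GSEA — hypermethylated
#' and underexpressed.
#'
#' @param meth_gsea,expr_gsea `gsea_result` tables computed on the same
#'   collection.
#' @return character vector of pathway names.
#' @export
epigenetically_repressed_pathways <- function(meth_gsea, expr_gsea) {
  if (length(intersect(meth_gsea$set, expr_gsea$set)) == 0)
    stop("the two GSEA results share no gene sets; same collection required")
  intersect(select_pathways(meth_gsea, "positive"),
            select_pathways(expr_gsea, "negative"))
}

#' Derive the stress gene signature
#'
#' The genes composing the repressed pathways collectively (union of their
#' members; a strict per-pathway intersection is available via `mode`)
#' intersected with the epigenetically repressed genes (list 2).
#'
#' @param list2 character vector of epigenetically repressed genes.
#' @param repressed_pathways pathway names from
#'   [epigenetically_repressed_pathways()].
#' @param sets the `gene_set_collection` the pathways come from.
#' @param mode "union" (default) or "intersection" of pathway members.
#' @return character vector of signature genes (possibly empty, with a
#'   warning).
#' @export
derive_signature <- function(list2, repressed_pathways, sets,
                             mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  members <- sets$sets[repressed_pathways]
  pathway_genes <- if (length(members) == 0) character(0)
  else if (mode == "union") Reduce(union, members)
  else Reduce(intersect, members)
  sig <- sort(intersect(pathway_genes, list2))
  if (length(sig) == 0) warning("empty signature")
  sig
}
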