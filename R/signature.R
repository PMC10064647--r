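# Signature scoring and correlation-based refinement. The score follows the
# stress-signature convention: each gene's expression is z-scored across
# patients, the per-patient mean over signature genes is taken, and the
# result is negated so that a high score means strong repression of the
# signature genes (high stress).

#' Per-patient signature score
#'
#' Restricts to the signature genes present in the matrix, z-scores each
#' gene across patients (sample SD by default), averages per patient over
#' genes, and multiplies by -1. Zero-variance genes are excluded from the
#' mean (counted in `n_excluded`).
#'
#' @param expr genes x patients expression matrix (any monotone expression
#'   scale; the score is invariant to per-gene positive affine maps).
#' @param genes signature gene ids.
#' @param sd_type "sample" (n - 1 denominator, default) or "population".
#' @return a `score_vector`: list with `score` (named per-patient numeric),
#'   `signature_genes_used`, `n_excluded`.
#' @export
signature_score <- function(expr, genes, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (ncol(expr) < 2) stop("need at least 2 patients to z-score")
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) stop("no signature gene present in the matrix")
  x <- expr[present, , drop = FALSE]
  mu <- rowMeans(x)
  denom <- if (sd_type == "sample") ncol(x) - 1 else ncol(x)
  sdv <- sqrt(rowSums((x - mu)^2) / denom)
  keep <- sdv > 0
  n_excluded <- sum(!keep)
  if (!any(keep)) stop("all signature genes have zero variance")
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  score <- -colMeans(z)
  structure(list(score = score,
                 signature_genes_used = present[keep],
                 n_excluded = n_excluded),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector: %d patients, %d genes used (%d excluded)\n",
              length(x$score), length(x$signature_genes_used), x$n_excluded))
  print(summary(unname(x$score)))
  invisible(x)
}

#' Per-pathway module scores
#'
#' [signature_score()] applied to each pathway's member genes. Pathways
#' with no member in the matrix are skipped with a warning.
#'
#' @param expr genes x patients matrix.
#' @param pathway_names pathways to score.
#' @param sets the `gene_set_collection`.
#' @param sd_type passed to [signature_score()].
#' @return named list of `score_vector`s.
#' @export
pathway_module_scores <- function(expr, pathway_names, sets,
                                  sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  out <- list()
  for (p in pathway_names) {
    members <- sets$sets[[p]]
    if (is.null(members)) stop("unknown pathway: ", p)
    if (length(intersect(members, rownames(expr))) == 0) {
      warning("pathway '", p, "' has no gene in the matrix; skipped")
      next
    }
    out[[p]] <- signature_score(expr, members, sd_type)
  }
  out
}

#' Correlation-based signature refinement
#'
#' For each candidate gene, its expression across patients is correlated
#' (Pearson) with the module expression profile of each of its repressed
#' pathways — the mean z-scored expression of the pathway's members, i.e.
#' the negated module score, so that a repressed gene tracking its
#' co-repressed pathway correlates positively. The gene is kept when
#' R > `r_min` and p < `p_max` (strict) for at least one of its pathways.
#' Constant genes are dropped with a message.
#'
#' @param expr genes x patients matrix (the refinement cohort).
#' @param membership data.frame with columns `gene` and `pathway` (one row
#'   per candidate-pathway assignment; every candidate needs >= 1 row).
#' @param sets the `gene_set_collection` defining pathway members.
#' @param r_min correlation threshold, default 0.25.
#' @param p_max p-value threshold (raw, uncorrected), default 0.05.
#' @param sd_type passed to the module scoring.
#' @return list with `genes` (the refined signature) and `report`
#'   (data.frame gene, pathway, r, p, kept).
#' @export
refine_signature <- function(expr, membership, sets, r_min = 0.25,
                             p_max = 0.05,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("gene", "pathway") %in% names(membership)))
  pathways <- unique(membership$pathway)
  modules <- pathway_module_scores(expr, pathways, sets, sd_type)
  rows <- list()
  for (i in seq_len(nrow(membership))) {
    g <- membership$gene[i]; p <- membership$pathway[i]
    if (!(g %in% rownames(expr)) || is.null(modules[[p]])) next
    x <- expr[g, ]
    if (stats::sd(x) == 0) {
      message("constant gene '", g, "' dropped from refinement")
      next
    }
    profile <- -modules[[p]]$score  # module expression profile
    ct <- stats::cor.test(x, profile, method = "pearson")
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, pathway = p, r = unname(ct$estimate), p = ct$p.value,
      kept = unname(ct$estimate) > r_min && ct$p.value < p_max,
      stringsAsFactors = FALSE)
  }
  report <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(gene = character(0), pathway = character(0),
                  r = numeric(0), p = numeric(0), kept = logical(0))
  list(genes = sort(unique(report$gene[report$kept])), report = report)
}
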