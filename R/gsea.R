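# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment score, gene-tag permutation null, NES normalization by the
# same-sign null mean, and the positive/negative-pool FDR procedure.

#' Build a ranked gene list
#'
#' Sorts per-gene scores in descending order; ties are broken
#' lexicographically by gene id for reproducibility.
#'
#' @param scores named numeric vector of per-gene scores (names = gene ids,
#'   unique, finite).
#' @return a `ranked_list` data.frame with columns `gene` and `score`.
#' @export
make_rank_file <- function(scores) {
  if (length(scores) == 0) stop("empty score vector")
  if (is.null(names(scores)) || any(names(scores) == ""))
    stop("scores must be named by gene id")
  if (anyDuplicated(names(scores))) stop("duplicate gene ids in scores")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(-scores, names(scores), method = "radix")
  out <- data.frame(gene = names(scores)[ord], score = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Aggregate CpG-level delta-beta to gene-level scores
#'
#' For each gene, the CpG with the largest |delta-beta| among its
#' regulatory assignments (promoter, enhancer, mixed by default) gives the
#' gene's score, keeping its sign — the most-affected regulatory CpG is
#' taken to drive silencing. A `mean` rule is available.
#'
#' @param dmc annotated `dmc_table` (needs gene_id and region_class).
#' @param rule "max_abs" (default) or "mean".
#' @param regions region classes counted as regulatory.
#' @return named numeric vector of gene-level delta-beta scores.
#' @export
gene_level_scores <- function(dmc, rule = c("max_abs", "mean"),
                              regions = c("promoter", "enhancer", "mixed")) {
  rule <- match.arg(rule)
  if (is.null(dmc$gene_id) || is.null(dmc$region_class))
    stop("dmc table must carry gene_id and region_class")
  sel <- !is.na(dmc$gene_id) & dmc$region_class %in% regions
  d <- dmc[sel, c("gene_id", "delta_beta")]
  if (nrow(d) == 0) stop("no CpGs with regulatory assignments")
  agg <- if (rule == "max_abs") {
    function(x) x[which.max(abs(x))]
  } else {
    mean
  }
  vapply(split(d$delta_beta, d$gene_id), agg, numeric(1))
}

#' Weighted running-sum enrichment score
#'
#' The classic preranked statistic: walking down the ranked list, the
#' running sum increments by |score|^`weight_p` / sum over the set's hits
#' at each member and decrements by 1 / (N - Nh) at each non-member; the
#' enrichment score is the extremum (largest absolute deviation). The
#' leading edge contains the members up to the extremum (positive ES) or
#' after it (negative ES).
#'
#' @param ranked a `ranked_list` from [make_rank_file()].
#' @param set_members character vector; members absent from the list are
#'   ignored (error if none is present).
#' @param weight_p score weighting exponent, default 1 (0 = unweighted KS).
#' @return list with `es`, `running` (length-N running sum), and
#'   `leading_edge`.
#' @export
enrichment_score <- function(ranked, set_members, weight_p = 1) {
  genes <- ranked$gene
  n <- length(genes)
  hit <- genes %in% set_members
  nh <- sum(hit)
  if (nh == 0) stop("no set member present in the ranked list")
  if (nh == n) {
    warning("set covers the entire ranked list; ES degenerate at 1")
    return(list(es = 1, running = cumsum(abs(ranked$score)^weight_p) /
                  sum(abs(ranked$score)^weight_p),
                leading_edge = genes))
  }
  w <- abs(ranked$score)^weight_p
  wh <- w * hit
  tot <- sum(wh)
  inc <- if (tot > 0) wh / tot else hit / nh
  running <- cumsum(inc - (!hit) / (n - nh))
  # extremum = largest |running sum|; near-ties (within 1e-9, e.g. the
  # symmetric +/- extreme of an unweighted walk) resolve to the earliest
  a <- abs(running)
  at <- which(a > max(a) - 1e-9)[1]
  es <- running[at]
  leading_edge <- if (es >= 0) genes[hit & seq_len(n) <= at]
  else genes[hit & seq_len(n) > at]
  list(es = es, running = running, leading_edge = leading_edge)
}

# ES for a random member index set, given precomputed weights. Mirrors
# enrichment_score() but takes positions, for the permutation null.
es_for_positions <- function(w, pos, n) {
  hit <- logical(n)
  hit[pos] <- TRUE
  nh <- length(pos)
  tot <- sum(w[pos])
  inc <- if (tot > 0) (w * hit) / tot else hit / nh
  running <- cumsum(inc - (!hit) / (n - nh))
  a <- abs(running)
  running[which(a > max(a) - 1e-9)[1]]
}

#' Permutation statistics for a gene-set collection
#'
#' Gene-tag permutation (the preranked convention): for each set, `n_perm`
#' random member sets of the same size are drawn from the ranked list and
#' scored. NES is ES divided by the mean |null ES| of the same sign; the
#' nominal p is one-sided against the same-sign null (with a
#' 1 / (n_perm + 1) floor when that pool is empty); the FDR q compares the
#' observed NES against the pooled normalized null NES of the same sign,
#' following the positive/negative-pool procedure. Deterministic under a
#' fixed seed.
#'
#' @param ranked a `ranked_list`.
#' @param sets a `gene_set_collection` (see [gene_set_collection()]).
#' @param n_perm number of permutations, >= 100; default 1000.
#' @param weight_p score weighting exponent, default 1.
#' @param seed RNG seed, default 1.
#' @return a `gsea_result` data.frame: set, class, size, es, nes,
#'   p_nominal, fdr_q, significant, leading_edge (comma-joined).
#' @export
permutation_stats <- function(ranked, sets, n_perm = 1000, weight_p = 1,
                              seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  n <- nrow(ranked)
  w <- abs(ranked$score)^weight_p
  set_names <- names(sets$sets)
  obs <- vector("list", length(set_names))
  null_nes_all <- list()
  nes <- es <- p_nom <- numeric(length(set_names))
  sizes <- integer(length(set_names))
  le <- character(length(set_names))
  for (k in seq_along(set_names)) {
    members <- sets$sets[[k]]
    present <- intersect(members, ranked$gene)
    if (length(members) > n)
      stop(sprintf("set '%s' is larger than the ranked list", set_names[k]))
    e <- enrichment_score(ranked, present, weight_p)
    es[k] <- e$es
    sizes[k] <- length(present)
    le[k] <- paste(e$leading_edge, collapse = ",")
    null_es <- vapply(seq_len(n_perm), function(b)
      es_for_positions(w, sample.int(n, length(present)), n), numeric(1))
    pos_mean <- mean(null_es[null_es >= 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    null_nes <- ifelse(null_es >= 0,
                       null_es / pos_mean, null_es / neg_mean)
    null_nes_all[[k]] <- null_nes[is.finite(null_nes)]
    if (es[k] >= 0) {
      pool <- null_es[null_es >= 0]
      nes[k] <- if (length(pool) > 0) es[k] / mean(pool) else NA_real_
      p_nom[k] <- if (length(pool) > 0)
        (sum(pool >= es[k]) + 1) / (length(pool) + 1)
      else 1 / (n_perm + 1)
    } else {
      pool <- null_es[null_es < 0]
      nes[k] <- if (length(pool) > 0) -es[k] / mean(pool) else NA_real_
      p_nom[k] <- if (length(pool) > 0)
        (sum(pool <= es[k]) + 1) / (length(pool) + 1)
      else 1 / (n_perm + 1)
    }
    if (is.na(nes[k])) nes[k] <- sign(es[k]) * abs(es[k])
  }
  all_null_nes <- unlist(null_nes_all)
  fdr_q <- vapply(seq_along(set_names), function(k) {
    if (nes[k] >= 0) {
      num_pool <- all_null_nes[all_null_nes >= 0]
      num <- if (length(num_pool) > 0) mean(num_pool >= nes[k]) else 0
      den <- mean(nes[nes >= 0] >= nes[k])
    } else {
      num_pool <- all_null_nes[all_null_nes < 0]
      num <- if (length(num_pool) > 0) mean(num_pool <= nes[k]) else 0
      den <- mean(nes[nes < 0] <= nes[k])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  out <- data.frame(set = set_names,
                    class = unname(sets$class[set_names]),
                    size = sizes, es = es, nes = nes,
                    p_nominal = p_nom, fdr_q = fdr_q,
                    significant = p_nom < 0.05 & fdr_q < 0.05,
                    leading_edge = le,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Select significant pathways by NES direction
#'
#' @param results a `gsea_result`.
#' @param direction "positive" or "negative".
#' @return character vector of set names with `significant = TRUE` and the
#'   matching NES sign.
#' @export
select_pathways <- function(results, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (nrow(results) == 0) return(character(0))
  keep <- results$significant &
    if (direction == "positive") results$nes > 0 else results$nes < 0
  results$set[keep]
}
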