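# Differential-expression side of the integration: parse external DE
# tables carrying two FDR-corrected tests (likelihood-ratio and Wald, as
# produced by a Kallisto/Sleuth-style workflow), or compute a documented
# stand-in DE directly on an expression matrix.

# Recompute the status column from the two q-values and the fold-change
# proxy. A gene is differential only when it passes BOTH tests at `fdr`.
deg_status <- function(beta_fc, q_lrt, q_wald, fdr = 0.05) {
  sig <- q_lrt < fdr & q_wald < fdr
  status <- rep("unchanged", length(beta_fc))
  status[sig & beta_fc < 0] <- "down"
  status[sig & beta_fc > 0] <- "up"
  factor(status, levels = c("down", "up", "unchanged"))
}

as_deg_table <- function(df, fdr = 0.05, tpm_min = 1) {
  df$status <- deg_status(df$beta_fc, df$q_lrt, df$q_wald, fdr)
  if (!is.null(df$mean_tpm_ctrl))
    df$low_expressed <- df$mean_tpm_ctrl < tpm_min
  class(df) <- c("deg_table", "data.frame")
  df
}

#' Load a differential-expression results table
#'
#' TSV with columns `gene`, `beta_fc` (fold-change proxy, case vs control),
#' `q_lrt`, `q_wald` and optionally `mean_tpm_ctrl`. The status column is
#' always recomputed from the q-values and fold change: a gene is down/up
#' only when it passes both tests at `fdr` (and its fold change is strictly
#' negative/positive); a status column present in the file is ignored.
#'
#' @param path TSV path.
#' @param fdr FDR cutoff applied to both q-values, default 0.05.
#' @param tpm_min low-expression TPM threshold, default 1.
#' @return a `deg_table` data.frame.
#' @export
load_deg_table <- function(path, fdr = 0.05, tpm_min = 1) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "beta_fc", "q_lrt", "q_wald")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("beta_fc", "q_lrt", "q_wald")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("non-numeric '%s' at row(s): %s", col,
                   paste(utils::head(bad, 10), collapse = ", ")))
    df[[col]] <- v
  }
  dup <- which(duplicated(df$gene))
  if (length(dup) > 0)
    stop("duplicate gene at row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  as_deg_table(df[c(need, intersect("mean_tpm_ctrl", names(df)))],
               fdr = fdr, tpm_min = tpm_min)
}

#' Stand-in differential expression on an expression matrix
#'
#' A per-gene pooled-variance t-test on log2(TPM + 1) (the two conditions
#' share one noise model, so the pooled test keeps its 7 residual degrees
#' of freedom at 3 vs 6 replicates); the BH-corrected q-value fills
#' both q slots so that the two-test AND-rule of [load_deg_table()] is
#' preserved structurally and a real two-test table drops in unchanged.
#' `beta_fc` is the case-minus-control mean log2 difference. Genes whose
#' control mean TPM falls below `tpm_min` are flagged `low_expressed`;
#' all-zero genes are retained with p = 1.
#'
#' @param tpm nonnegative genes x samples matrix.
#' @param condition per-sample labels (control/case), >= 2 per condition.
#' @param fdr FDR cutoff, default 0.05.
#' @param tpm_min low-expression threshold on the control mean, default 1.
#' @return a `deg_table` data.frame.
#' @export
standin_de <- function(tpm, condition, fdr = 0.05, tpm_min = 1) {
  condition <- factor(condition, levels = c("control", "case"))
  idx_ctrl <- which(condition == "control")
  idx_case <- which(condition == "case")
  if (length(idx_ctrl) < 2 || length(idx_case) < 2)
    stop("need at least 2 samples per condition")
  lx <- log2(tpm + 1)
  tt <- row_pooled_t(lx, idx_ctrl, idx_case)
  q <- stats::p.adjust(tt$p, method = "BH")
  df <- data.frame(gene = rownames(tpm), beta_fc = tt$diff,
                   q_lrt = q, q_wald = q,
                   mean_tpm_ctrl = rowMeans(tpm[, idx_ctrl, drop = FALSE]),
                   row.names = NULL, stringsAsFactors = FALSE)
  if (any(tt$degenerate))
    message(sum(tt$degenerate),
            " gene(s) with zero variance in both groups retained with p = 1")
  as_deg_table(df, fdr = fdr, tpm_min = tpm_min)
}

#' Summarize a differential-expression table
#'
#' Counts of down- and up-regulated genes and their total. Can also be
#' applied directly to printed counts via `n_down` / `n_up`.
#'
#' @param deg a `deg_table` (or NULL when raw counts are supplied).
#' @param n_down,n_up raw counts, used when `deg` is NULL.
#' @return list with `n_down`, `n_up` and `n_total` (= down + up).
#' @export
summarize_deg <- function(deg = NULL, n_down = NULL, n_up = NULL) {
  if (!is.null(deg)) {
    n_down <- sum(deg$status == "down")
    n_up <- sum(deg$status == "up")
  }
  if (is.null(n_down) || is.null(n_up))
    stop("supply either a deg table or both n_down and n_up")
  list(n_down = n_down, n_up = n_up, n_total = n_down + n_up)
}
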