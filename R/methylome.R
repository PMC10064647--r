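# Methylation array processing: beta computation, probe filtering,
# peak-based type I/II correction, and per-CpG differential methylation.

#' Construct a beta matrix
#'
#' Container for probes x samples methylation fractions with the per-sample
#' condition labels and a flag recording whether probe-type correction has
#' been applied.
#'
#' @param values numeric matrix in \[0, 1\] (NAs allowed), rownames = probes.
#' @param condition factor/character of length ncol with levels
#'   control/case.
#' @param corrected logical; has peak-based correction been applied.
#' @return a `beta_matrix` object.
#' @export
beta_matrix <- function(values, condition = NULL, corrected = FALSE) {
  stopifnot(is.matrix(values))
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("beta-values must lie in [0, 1]")
  if (!is.null(condition)) {
    condition <- factor(condition, levels = c("control", "case"))
    if (length(condition) != ncol(values))
      stop("condition must have one label per sample")
  }
  structure(list(values = values, condition = condition,
                 corrected = corrected),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$corrected) "peak-corrected" else "uncorrected"))
  if (!is.null(x$condition))
    cat("  conditions:", paste(sprintf("%s=%d", levels(x$condition),
                                       table(x$condition)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Compute beta-values from raw intensities
#'
#' beta = M / (U + M), where M and U are the methylated and unmethylated
#' channel intensities. Cells with U + M = 0 are undefined and returned as
#' NA. No intensity offset is used by default; a nonzero `offset` switches
#' to the common stabilized form M / (U + M + offset).
#'
#' @param M,U nonnegative intensity matrices of identical shape.
#' @param condition optional per-sample condition labels (control/case).
#' @param offset intensity offset added to the denominator (default 0).
#' @return a [beta_matrix()] (uncorrected).
#' @export
compute_beta <- function(M, U, condition = NULL, offset = 0) {
  if (!all(dim(M) == dim(U))) stop("M and U must have the same shape")
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")
  denom <- M + U + offset
  b <- M / denom
  b[denom == 0] <- NA_real_
  dimnames(b) <- dimnames(M)
  beta_matrix(b, condition = condition, corrected = FALSE)
}

#' Filter low-quality, flagged and sex-chromosome probes
#'
#' Removes probes that (i) fail detection (p > `detection_p_max`) in any
#' sample, (ii) are flagged cross-reactive, (iii) overlap a SNP, or
#' (iv) target chrX/chrY. The removal log records every reason that applied
#' to each dropped probe.
#'
#' @param beta a [beta_matrix()].
#' @param ann probe annotation data.frame with columns probe_id, chrom,
#'   cross_reactive, snp_overlap.
#' @param detection_p detection p-value matrix aligned with `beta`.
#' @param detection_p_max detection threshold, default 0.05.
#' @return filtered `beta_matrix` with attribute `removal_log`, a
#'   data.frame (probe_id, reason).
#' @export
filter_probes <- function(beta, ann, detection_p, detection_p_max = 0.05) {
  probes <- rownames(beta$values)
  missing <- setdiff(probes, ann$probe_id)
  if (length(missing) > 0)
    stop("probes missing from annotation: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" ... (%d total)", length(missing)))
  ann <- ann[match(probes, ann$probe_id), ]
  det_fail <- apply(detection_p[probes, , drop = FALSE] > detection_p_max,
                    1, any)
  reasons <- list(
    detection = det_fail,
    cross_reactive = as.logical(ann$cross_reactive),
    snp_overlap = as.logical(ann$snp_overlap),
    sex_chromosome = ann$chrom %in% c("chrX", "chrY"))
  log <- do.call(rbind, lapply(names(reasons), function(r) {
    idx <- which(reasons[[r]])
    if (length(idx) == 0) return(NULL)
    data.frame(probe_id = probes[idx], reason = r, stringsAsFactors = FALSE)
  }))
  if (is.null(log))
    log <- data.frame(probe_id = character(0), reason = character(0))
  drop <- Reduce(`|`, reasons)
  out <- beta_matrix(beta$values[!drop, , drop = FALSE],
                     condition = beta$condition, corrected = beta$corrected)
  attr(out, "removal_log") <- log
  out
}

# Locate the unmethylated (M < 0) and methylated (M > 0) density peaks of a
# set of M-values: Gaussian KDE, Silverman bandwidth, highest local maximum
# on each side of zero. Returns c(neg, pos) or NULL when a side has no peak.
find_m_peaks <- function(m) {
  d <- stats::density(m, bw = "nrd0")
  y <- d$y
  loc <- which(diff(sign(diff(y))) == -2) + 1
  if (length(loc) == 0) return(NULL)
  px <- d$x[loc]; py <- y[loc]
  neg <- px[px < 0]; negy <- py[px < 0]
  pos <- px[px > 0]; posy <- py[px > 0]
  if (length(neg) == 0 || length(pos) == 0) return(NULL)
  c(neg = neg[which.max(negy)], pos = pos[which.max(posy)])
}

#' Peak-based correction of type II probe bias
#'
#' Type II probes read compressed beta-values at the extremes. Per sample,
#' the M-value densities of type I and type II probes are estimated
#' separately; the unmethylated and methylated peaks of each design are
#' located, and type II M-values are rescaled linearly on each side of zero
#' so that their peaks align with the type I peaks. Type I values are
#' untouched. Requires at least `min_probes` probes of each design (else a
#' warning and pass-through); a sample whose peaks cannot be located (e.g.
#' unimodal distribution) is passed through with a warning.
#'
#' @param beta a [beta_matrix()].
#' @param ann annotation with columns probe_id and design_type ("I"/"II").
#' @param min_probes minimum probes per design type, default 50.
#' @return corrected [beta_matrix()] with attribute `peak_table`
#'   (per-sample type I / type II peak positions before correction).
#' @export
peak_correct <- function(beta, ann, min_probes = 50) {
  probes <- rownames(beta$values)
  design <- ann$design_type[match(probes, ann$probe_id)]
  i1 <- which(design == "I"); i2 <- which(design == "II")
  if (length(i1) < min_probes || length(i2) < min_probes) {
    warning("fewer than ", min_probes,
            " probes of one design type; returning input uncorrected")
    return(beta)
  }
  vals <- beta$values
  peak_rows <- list()
  for (j in seq_len(ncol(vals))) {
    m <- beta_to_m(vals[, j])
    p1 <- find_m_peaks(m[i1]); p2 <- find_m_peaks(m[i2])
    if (is.null(p1) || is.null(p2)) {
      warning("peak finding failed for sample ", colnames(vals)[j],
              "; sample passed through uncorrected")
      next
    }
    m2 <- m[i2]
    scaled <- m2
    scaled[m2 < 0] <- m2[m2 < 0] * (p1["neg"] / p2["neg"])
    scaled[m2 > 0] <- m2[m2 > 0] * (p1["pos"] / p2["pos"])
    vals[i2, j] <- m_to_beta(scaled)
    peak_rows[[colnames(vals)[j]]] <-
      data.frame(sample = colnames(vals)[j],
                 type1_neg = p1["neg"], type1_pos = p1["pos"],
                 type2_neg = p2["neg"], type2_pos = p2["pos"],
                 row.names = NULL)
  }
  out <- beta_matrix(vals, condition = beta$condition, corrected = TRUE)
  attr(out, "peak_table") <- do.call(rbind, peak_rows)
  out
}

#' Per-CpG differential methylation
#'
#' For every probe: delta-beta is the difference of the per-condition
#' medians of beta (case minus control); significance is a Welch t-test on
#' M-values (log2 beta / (1 - beta), beta clipped to `[1e-6, 1 - 1e-6]`),
#' with Benjamini-Hochberg correction across all tested probes. A probe is
#' called hyper when delta-beta > `delta_beta_min` and adjusted p <
#' `p_adj_max` (strict inequalities), hypo for delta-beta <
#' `-delta_beta_min`. Probes with zero variance in both groups get p = 1.
#'
#' @param beta a [beta_matrix()] with condition labels; a warning is issued
#'   when probe-type correction has not been applied.
#' @param ann optional annotation; when given, gene_id and region_class are
#'   carried into the output.
#' @param delta_beta_min delta-beta threshold, default 0.2.
#' @param p_adj_max adjusted-p threshold, default 0.05.
#' @return a `dmc_table` data.frame: probe_id, delta_beta, p_value, p_adj,
#'   status (hyper/hypo/unchanged), plus gene_id/region_class if annotated.
#' @export
diff_methylation <- function(beta, ann = NULL, delta_beta_min = 0.2,
                             p_adj_max = 0.05) {
  if (is.null(beta$condition)) stop("beta matrix carries no condition labels")
  idx_ctrl <- which(beta$condition == "control")
  idx_case <- which(beta$condition == "case")
  if (length(idx_ctrl) < 2 || length(idx_case) < 2)
    stop("need at least 2 samples per condition")
  if (!beta$corrected)
    warning("differential methylation on uncorrected beta-values")
  vals <- beta$values
  mvals <- beta_to_m(vals)
  tt <- row_welch(mvals, idx_ctrl, idx_case)
  delta <- apply(vals[, idx_case, drop = FALSE], 1, stats::median) -
    apply(vals[, idx_ctrl, drop = FALSE], 1, stats::median)
  p_adj <- stats::p.adjust(tt$p, method = "BH")
  status <- rep("unchanged", nrow(vals))
  status[delta > delta_beta_min & p_adj < p_adj_max] <- "hyper"
  status[delta < -delta_beta_min & p_adj < p_adj_max] <- "hypo"
  out <- data.frame(probe_id = rownames(vals), delta_beta = delta,
                    p_value = tt$p, p_adj = p_adj,
                    status = factor(status,
                                    levels = c("hyper", "hypo", "unchanged")),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(tt$degenerate))
    message(sum(tt$degenerate), " probe(s) had zero variance in both groups; p set to 1")
  if (!is.null(ann)) {
    m <- match(out$probe_id, ann$probe_id)
    out$gene_id <- ann$gene_id[m]
    out$region_class <- ann$region_class[m]
  }
  class(out) <- c("dmc_table", "data.frame")
  out
}

#' Summarize differentially methylated CpGs
#'
#' Counts and percentages (one decimal) of hyper- and hypomethylated CpGs
#' among all DMCs, plus the per-region-class distribution when region
#' assignments are present. Can also be applied directly to printed counts
#' via `n_hyper` / `n_hypo`.
#'
#' @param dmc a `dmc_table` from [diff_methylation()] (or NULL when raw
#'   counts are supplied).
#' @param n_hyper,n_hypo raw DMC counts, used when `dmc` is NULL.
#' @return list with n_dmc, n_hyper, n_hypo, pct_hyper, pct_hypo (percent,
#'   rounded to one decimal; NA when there are no DMCs) and, for annotated
#'   tables, `region_distribution` (counts by status x region_class).
#' @export
summarize_dmc <- function(dmc = NULL, n_hyper = NULL, n_hypo = NULL) {
  region_distribution <- NULL
  if (!is.null(dmc)) {
    n_hyper <- sum(dmc$status == "hyper")
    n_hypo <- sum(dmc$status == "hypo")
    if (!is.null(dmc$region_class)) {
      sel <- dmc$status != "unchanged"
      region_distribution <- table(status = droplevels(dmc$status[sel]),
                                   region_class = dmc$region_class[sel])
    }
  }
  if (is.null(n_hyper) || is.null(n_hypo))
    stop("supply either a dmc table or both n_hyper and n_hypo")
  n_dmc <- n_hyper + n_hypo
  pct <- function(x) if (n_dmc == 0) NA_real_ else round(100 * x / n_dmc, 1)
  list(n_dmc = n_dmc, n_hyper = n_hyper, n_hypo = n_hypo,
       pct_hyper = pct(n_hyper), pct_hypo = pct(n_hypo),
       region_distribution = region_distribution)
}
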