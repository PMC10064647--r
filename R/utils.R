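# Shared numeric helpers.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert beta-values to M-values
#'
#' M = log2(beta / (1 - beta)). Beta-values are clipped to
#' `[eps, 1 - eps]` first so boundary values stay finite.
#'
#' @param beta numeric vector or matrix of methylation fractions in \[0, 1\].
#' @param eps clipping margin, default 1e-6.
#' @return object of the same shape on the M scale.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- clip(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector or matrix of M-values.
#' @return beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  e <- 2^m
  e / (1 + e)
}

# Derive a reproducible sub-stream seed from a master seed. Keeps the result
# strictly below 2^31 so it is a valid R integer seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 59999) * 35317 + k * 101 + 7) %% 2147483629L
}

# Row-wise pooled-variance (Student) two-sample t-test. Same contract as
# row_welch() below.
row_pooled_t <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  stopifnot(n1 >= 2, n2 >= 2)
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  sp2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / (n1 + n2 - 2)
  se2 <- sp2 * (1 / n1 + 1 / n2)
  tstat <- (m2 - m1) / sqrt(se2)
  df <- rep(n1 + n2 - 2, length(tstat))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  data.frame(diff = m2 - m1, t = tstat, df = df, p = p,
             degenerate = degenerate)
}

# Row-wise Welch two-sample t-test on a matrix. idx1/idx2 are column indices
# of the two groups. Rows where both groups have zero variance get p = 1
# (flagged in the `degenerate` column).
row_welch <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  stopifnot(n1 >= 2, n2 >= 2)
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- 1
  tstat[degenerate] <- 0
  df[degenerate] <- NA_real_
  data.frame(diff = m2 - m1, t = tstat, df = df, p = p,
             degenerate = degenerate)
}
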