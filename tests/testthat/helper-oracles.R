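# Independent oracles and small fixture builders used across the suite.

# Brute-force running-sum enrichment score: sequential accumulation, no
# vectorization, independent of the package's implementation path.
es_brute_force <- function(genes, scores, members, weight_p = 1) {
  n <- length(genes)
  hit <- genes %in% members
  nh <- sum(hit)
  stopifnot(nh > 0, nh < n)
  w <- abs(scores)^weight_p
  tot <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (tot > 0) w[i] / tot else 1 / nh
    } else {
      run <- run - 1 / (n - nh)
    }
    # earliest extremum wins near-ties, matching the stated tie rule
    if (abs(run) > abs(best) + 1e-9) best <- run
  }
  best
}

# Hand product-limit estimator: loop over distinct event times.
km_brute_force <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Hand log-rank: observed vs expected events with hypergeometric variance,
# summed over distinct event times.
logrank_brute_force <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (tk in ts) {
    n_at <- sum(time >= tk)
    n1_at <- sum(time >= tk & grp == 1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & grp == 1)
    e <- d * n1_at / n_at
    o_minus_e <- o_minus_e + d1 - e
    if (n_at > 1)
      v <- v + d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) / (n_at - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# A small beta_matrix with prescribed per-condition probe means and tight
# Beta noise, for differential-methylation fixtures.
toy_beta_matrix <- function(ctrl_means, case_means, n_ctrl = 3, n_case = 6,
                            conc = 5000, seed = 42) {
  set.seed(seed)
  n <- length(ctrl_means)
  draw <- function(mu) stats::rbeta(n, mu * conc, (1 - mu) * conc)
  vals <- cbind(
    vapply(seq_len(n_ctrl), function(i) draw(ctrl_means), numeric(n)),
    vapply(seq_len(n_case), function(i) draw(case_means), numeric(n)))
  rownames(vals) <- sprintf("cg%03d", seq_len(n))
  colnames(vals) <- c(sprintf("c%d", seq_len(n_ctrl)),
                      sprintf("k%d", seq_len(n_case)))
  beta_matrix(vals,
              condition = rep(c("control", "case"), c(n_ctrl, n_case)),
              corrected = TRUE)
}

# Small synthetic configuration for fast module tests; overrides win.
small_cfg <- function(...) {
  args <- list(n_probes = 2000, n_genes = 500, n_repressed_genes = 30,
               n_gene_sets = 12, set_size_range = c(30, 60),
               n_causal_sets = 2, n_patients = 60)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}
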