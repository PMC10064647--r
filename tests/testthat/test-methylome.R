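test_that("beta computation follows M / (U + M) with missing-safe division", {
  M <- matrix(c(100, 0, 300, 0), 2, 2)
  U <- matrix(c(100, 500, 100, 0), 2, 2)
  b <- compute_beta(M, U)
  expect_equal(b$values[1, 1], 0.5)
  expect_equal(b$values[2, 1], 0.0)
  expect_equal(b$values[1, 2], 0.75)
  expect_true(is.na(b$values[2, 2]))  # U + M = 0 undefined
  expect_false(b$corrected)
  expect_error(compute_beta(-M, U), "negative")
  expect_error(compute_beta(M, U[, 1, drop = FALSE]), "same shape")
})

test_that("beta/M transform round-trips and is monotone", {
  b <- c(1e-5, 0.1, 0.25, 0.5, 0.77, 1 - 1e-5)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
  expect_true(all(diff(beta_to_m(b)) > 0))
})

test_that("probe filtering removes each class of bad probe with its reason", {
  n <- 10
  vals <- matrix(0.5, n, 3, dimnames = list(sprintf("p%02d", 1:n),
                                            c("a", "b", "c")))
  det <- matrix(0.01, n, 3, dimnames = dimnames(vals))
  det[4, 2] <- 0.2  # fails detection in one sample -> dropped (any-sample)
  ann <- data.frame(probe_id = rownames(vals), design_type = "II",
                    chrom = c(rep("chr1", 8), "chrY", "chrX"),
                    gene_id = "g1", region_class = "promoter",
                    cross_reactive = c(TRUE, TRUE, rep(FALSE, 8)),
                    snp_overlap = c(rep(FALSE, 2), TRUE, rep(FALSE, 7)))
  b <- beta_matrix(vals, condition = c("control", "control", "case"))
  # chrX probe with perfect detection is still removed as sex_chromosome
  f <- filter_probes(b, ann, det)
  log <- attr(f, "removal_log")
  expect_equal(log$reason[log$probe_id == "p10"], "sex_chromosome")
  expect_equal(nrow(f$values), 4)  # 2 cross-reactive + 1 snp + 1 det + 2 sex
  expect_setequal(rownames(f$values), sprintf("p%02d", 5:8))
  expect_error(filter_probes(b, ann[-1, ], det), "missing from annotation")
})

test_that("peak correction is the identity when the type distributions match", {
  set.seed(1)
  n <- 400
  x <- c(rbeta(n / 2, 4, 28), rbeta(n / 2, 28, 4))
  vals <- cbind(s1 = c(x, x), s2 = c(rev(x), rev(x)))
  rownames(vals) <- sprintf("p%04d", seq_len(2 * n))
  ann <- data.frame(probe_id = rownames(vals),
                    design_type = rep(c("I", "II"), each = n))
  b <- beta_matrix(vals)
  corr <- peak_correct(b, ann)
  expect_true(corr$corrected)
  expect_equal(corr$values, vals, tolerance = 1e-6)
})

test_that("peak correction realigns compressed type II peaks", {
  cfg <- small_cfg(n_probes = 6000, seed = 21)
  d <- make_methylation_dataset(cfg)
  b <- filter_probes(compute_beta(d$M, d$U, condition = d$condition),
                     d$annotation, d$detection_p)
  corr <- peak_correct(b, d$annotation)
  design <- d$annotation$design_type[match(rownames(corr$values),
                                           d$annotation$probe_id)]
  for (j in seq_len(ncol(corr$values))) {
    m <- beta_to_m(corr$values[, j])
    p1 <- mgstress:::find_m_peaks(m[design == "I"])
    p2 <- mgstress:::find_m_peaks(m[design == "II"])
    expect_lt(max(abs(p1 - p2)), 0.05)
  }
  # pre-correction misalignment was substantial, so the check has teeth
  m_raw <- beta_to_m(b$values[, 1])
  design_raw <- d$annotation$design_type[match(rownames(b$values),
                                               d$annotation$probe_id)]
  p1r <- mgstress:::find_m_peaks(m_raw[design_raw == "I"])
  p2r <- mgstress:::find_m_peaks(m_raw[design_raw == "II"])
  expect_gt(max(abs(p1r - p2r)), 0.3)
})

test_that("linear rescale preserves within-sample rank order of type II probes", {
  cfg <- small_cfg(n_probes = 3000, seed = 22)
  d <- make_methylation_dataset(cfg)
  b <- compute_beta(d$M, d$U, condition = d$condition)
  corr <- peak_correct(b, d$annotation)
  t2 <- d$annotation$probe_id[d$annotation$design_type == "II"]
  t2 <- intersect(t2, rownames(b$values))
  before <- b$values[t2, 1]
  after <- corr$values[t2, 1]
  for (side in list(before < 0.5, before >= 0.5))
    expect_equal(order(before[side]), order(after[side]))
})

test_that("too few probes of one design passes through with a warning", {
  vals <- matrix(runif(40), 20, 2,
                 dimnames = list(sprintf("p%02d", 1:20), c("a", "b")))
  ann <- data.frame(probe_id = rownames(vals),
                    design_type = c("I", rep("II", 19)))
  expect_warning(out <- peak_correct(beta_matrix(vals), ann),
                 "fewer than")
  expect_identical(out$values, vals)
  expect_false(out$corrected)
})

test_that("differential methylation applies the delta-beta and p thresholds", {
  # probe 1: planted shift 0.30 -> hyper; probe 2: shift 0.25 -> hyper;
  # probe 3: no shift; probe 4: shift -0.3 -> hypo;
  # probe 5: large shift but we will check the exact boundary separately
  ctrl <- c(0.30, 0.30, 0.50, 0.80, 0.20)
  case <- c(0.60, 0.55, 0.50, 0.50, 0.45)
  b <- toy_beta_matrix(ctrl, case)
  dmc <- diff_methylation(b)
  expect_s3_class(dmc, "dmc_table")
  expect_equal(as.character(dmc$status[1:4]),
               c("hyper", "hyper", "unchanged", "hypo"))
  expect_equal(dmc$delta_beta[3], 0, tolerance = 0.02)
  expect_true(all(dmc$p_adj >= dmc$p_value))
  # delta beta is the difference of condition medians
  med_diff <- apply(b$values[, 4:9], 1, median) -
    apply(b$values[, 1:3], 1, median)
  expect_equal(dmc$delta_beta, unname(med_diff))
})

test_that("delta-beta exactly at the threshold stays unchanged (strict rule)", {
  # medians exactly 0.30 (control) and 0.50 (case), nonzero within-group
  # variance: delta-beta is exactly 0.2
  d <- 1e-3
  row <- c(0.30 - d, 0.30, 0.30 + d,
           0.50 - d, 0.50 - d, 0.50, 0.50, 0.50 + d, 0.50 + d)
  vals <- rbind(a = row, b = row, c = row)
  b <- beta_matrix(vals, condition = rep(c("control", "case"), c(3, 6)),
                   corrected = TRUE)
  dmc <- diff_methylation(b)
  expect_equal(dmc$delta_beta, rep(0.2, 3))
  expect_lt(max(dmc$p_adj), 0.05)
  expect_equal(as.character(dmc$status), rep("unchanged", 3))
})

test_that("welch machinery matches stats::t.test row by row", {
  set.seed(33)
  x <- matrix(rnorm(50 * 9), 50, 9)
  tt <- mgstress:::row_welch(x, 1:3, 4:9)
  ref <- apply(x, 1, function(r) t.test(r[4:9], r[1:3])$p.value)
  expect_equal(tt$p, unname(ref), tolerance = 1e-12)
  tp <- mgstress:::row_pooled_t(x, 1:3, 4:9)
  refp <- apply(x, 1, function(r)
    t.test(r[4:9], r[1:3], var.equal = TRUE)$p.value)
  expect_equal(tp$p, unname(refp), tolerance = 1e-12)
})

test_that("zero-variance probes get p = 1 instead of NaN", {
  vals <- rbind(rep(0.4, 9), c(rep(0.2, 3), rep(0.6, 6)))
  vals[2, ] <- vals[2, ] + rep(c(-1e-3, 0, 1e-3), 3)
  rownames(vals) <- c("flat", "shifted")
  b <- beta_matrix(vals, condition = rep(c("control", "case"), c(3, 6)),
                   corrected = TRUE)
  expect_message(dmc <- diff_methylation(b), "zero variance")
  expect_equal(dmc$p_value[1], 1)
  expect_equal(as.character(dmc$status[1]), "unchanged")
})

test_that("BH adjustment is monotone in the p ranks", {
  set.seed(44)
  b <- toy_beta_matrix(runif(80, 0.2, 0.8), runif(80, 0.2, 0.8))
  dmc <- diff_methylation(b)
  ord <- order(dmc$p_value)
  expect_true(all(diff(cummin(rev(dmc$p_adj[ord]))) <= 0))
  expect_true(all(dmc$p_adj >= dmc$p_value))
  expect_equal(dmc$p_adj, p.adjust(dmc$p_value, "BH"))
})

test_that("DMC summary reproduces printed-percentage arithmetic", {
  expect_equal(summarize_dmc(n_hyper = 41431, n_hypo = 47578 - 41431),
               list(n_dmc = 47578, n_hyper = 41431, n_hypo = 6147,
                    pct_hyper = 87.1, pct_hypo = 12.9,
                    region_distribution = NULL))
  s <- summarize_dmc(n_hyper = 79419, n_hypo = 90441 - 79419)
  expect_equal(s$pct_hyper, 87.8)
  empty <- data.frame(probe_id = character(0), delta_beta = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      status = factor(character(0),
                                      levels = c("hyper", "hypo",
                                                 "unchanged")))
  s0 <- summarize_dmc(empty)
  expect_equal(s0$n_dmc, 0)
  expect_true(is.na(s0$pct_hyper))
})
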