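test_that("symmetric two-gene example cancels to zero scores", {
  expr <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1))
  colnames(expr) <- paste0("p", 1:3)
  sc <- signature_score(expr, c("g1", "g2"))
  expect_equal(unname(sc$score), c(0, 0, 0))
  expect_equal(sc$n_excluded, 0)
})

test_that("single-gene score is the negated z, highest score = lowest expression", {
  expr <- matrix(c(10, 20, 30), 1, dimnames = list("g1", paste0("p", 1:3)))
  sc_pop <- signature_score(expr, "g1", sd_type = "population")
  expect_equal(unname(sc_pop$score),
               -c(-1, 0, 1) * (10 / sqrt(200 / 3)), tolerance = 1e-12)
  # under the default sample SD the z-scores are exactly (-1, 0, 1)
  sc <- signature_score(expr, "g1")
  expect_equal(unname(sc$score), c(1, 0, -1))
  expect_equal(unname(which.max(sc$score)), 1L)  # lowest-expression patient
})

test_that("zero-variance genes are excluded from the mean", {
  expr <- rbind(flat = rep(5, 4), g = c(1, 2, 3, 4))
  colnames(expr) <- paste0("p", 1:4)
  sc <- signature_score(expr, c("flat", "g"))
  expect_equal(sc$n_excluded, 1)
  expect_equal(sc$signature_genes_used, "g")
  expect_equal(unname(sc$score),
               unname(signature_score(expr, "g")$score))
  expect_error(signature_score(expr["flat", , drop = FALSE], "flat"),
               "zero variance")
  expect_error(signature_score(expr[, 1, drop = FALSE], "g"), "2 patients")
  expect_error(signature_score(expr, "missing"), "no signature gene")
})

test_that("scores are mean-zero, affine-invariant and permutation-equivariant", {
  set.seed(21)
  for (i in 1:10) {
    expr <- matrix(rnorm(20 * 50), 20, 50,
                   dimnames = list(paste0("g", 1:20), paste0("p", 1:50)))
    genes <- sample(rownames(expr), 8)
    sc <- signature_score(expr, genes)
    expect_lt(abs(mean(sc$score)), 1e-9)
    # positive affine rescaling of any gene row changes nothing
    expr2 <- expr
    expr2[genes[1], ] <- 3.7 * expr2[genes[1], ] + 11
    expect_equal(signature_score(expr2, genes)$score, sc$score,
                 tolerance = 1e-9)
    # permuting patients permutes scores identically
    perm <- sample(ncol(expr))
    expect_equal(unname(signature_score(expr[, perm], genes)$score),
                 unname(sc$score[perm]), tolerance = 1e-12)
  }
})

test_that("raising one patient's expression of a signature gene lowers their score", {
  set.seed(22)
  expr <- matrix(rnorm(10 * 30), 10, 30,
                 dimnames = list(paste0("g", 1:10), paste0("p", 1:30)))
  genes <- paste0("g", 1:4)
  base <- signature_score(expr, genes)$score
  expr["g1", "p5"] <- expr["g1", "p5"] + 2
  bumped <- signature_score(expr, genes)$score
  expect_lt(bumped["p5"], base["p5"])
})

test_that("pathway module scores reduce to signature scores per pathway", {
  set.seed(23)
  expr <- matrix(rnorm(12 * 20), 12, 20,
                 dimnames = list(paste0("g", 1:12), paste0("p", 1:20)))
  sets <- gene_set_collection(list(one = "g1", two = c("g2", "g3"),
                                   absent = "nope"))
  expect_warning(ms <- pathway_module_scores(expr, names(sets$sets), sets),
                 "no gene in the matrix")
  expect_named(ms, c("one", "two"))
  # single-gene pathway: module score is the negated z of that gene
  z <- (expr["g1", ] - mean(expr["g1", ])) / sd(expr["g1", ])
  expect_equal(ms$one$score, -z, tolerance = 1e-12)
  expect_equal(ms$two$score, signature_score(expr, c("g2", "g3"))$score)
})

test_that("module scores on disjoint null blocks are uncorrelated", {
  set.seed(24)
  expr <- matrix(rnorm(40 * 200), 40, 200,
                 dimnames = list(paste0("g", 1:40), paste0("p", 1:200)))
  sets <- gene_set_collection(list(A = paste0("g", 1:20),
                                   B = paste0("g", 21:40)))
  ms <- pathway_module_scores(expr, c("A", "B"), sets)
  expect_lt(abs(cor(ms$A$score, ms$B$score)), 0.2)
})

test_that("refinement keeps tracking genes and applies strict thresholds", {
  set.seed(25)
  n <- 100
  latent <- rnorm(n)
  # members of pathway P co-repressed on the latent factor
  expr <- rbind(
    t(sapply(1:6, function(i) -0.8 * latent + rnorm(n, sd = 0.5))),
    tracker = -0.9 * latent + rnorm(n, sd = 0.3),
    decoy = rnorm(n))
  rownames(expr)[1:6] <- paste0("m", 1:6)
  colnames(expr) <- paste0("p", 1:n)
  sets <- gene_set_collection(list(P = c(paste0("m", 1:6), "tracker",
                                         "decoy")))
  membership <- data.frame(gene = c("tracker", "decoy"), pathway = "P")
  ref <- refine_signature(expr, membership, sets)
  expect_true("tracker" %in% ref$genes)
  expect_false("decoy" %in% ref$genes)
  expect_true(all(c("gene", "pathway", "r", "p", "kept") %in%
                    names(ref$report)))
})

test_that("correlation exactly at the threshold is dropped (strict rule)", {
  # construct gene with known correlation to a fixed profile
  profile <- c(-1.5, -0.5, 0.5, 1.5, 0, 2, -2, 1, -1, 0.3)
  n <- length(profile)
  sets <- gene_set_collection(list(P = "anchor"))
  # anchor defines the module: module profile is z(anchor)
  expr <- rbind(anchor = profile, gene = profile)
  colnames(expr) <- paste0("p", 1:n)
  membership <- data.frame(gene = "gene", pathway = "P")
  ref <- refine_signature(expr, membership, sets)
  expect_equal(ref$report$r, 1, tolerance = 1e-12)
  expect_true(ref$report$kept)
  # R below/at 0.25 is rejected even with tiny p: use r_min just above r
  ref2 <- refine_signature(expr, membership, sets, r_min = 1)
  expect_false(ref2$report$kept)  # r = 1 is not > 1: strict inequality
})

test_that("constant candidate genes are dropped with a message", {
  expr <- rbind(anchor = c(1, 2, 3, 4, 5), flat = rep(2, 5))
  colnames(expr) <- paste0("p", 1:5)
  sets <- gene_set_collection(list(P = "anchor"))
  expect_message(
    ref <- refine_signature(expr,
                            data.frame(gene = "flat", pathway = "P"), sets),
    "constant")
  expect_length(ref$genes, 0)
})

test_that("cohort-scale refinement separates loaded genes from decoys", {
  cfg <- small_cfg(n_patients = 200, seed = 71)
  d <- make_methylation_dataset(cfg)
  gs <- make_gene_sets(cfg, d$truth)
  co <- make_cohort(cfg, d$truth$repressed_gene_ids)
  causal <- gs$truth$causal_set_names
  loaded <- intersect(unlist(gs$sets$sets[causal]),
                      d$truth$repressed_gene_ids)
  decoys <- setdiff(sample(rownames(co$expr), 60),
                    d$truth$repressed_gene_ids)
  membership <- rbind(
    do.call(rbind, lapply(causal, function(p) data.frame(
      gene = intersect(gs$sets$sets[[p]], loaded), pathway = p))),
    data.frame(gene = decoys, pathway = causal[1]))
  ref <- refine_signature(co$expr, membership, gs$sets)
  expect_gte(mean(loaded %in% ref$genes), 0.9)
  expect_lte(mean(decoys %in% ref$genes), 0.1)
})
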