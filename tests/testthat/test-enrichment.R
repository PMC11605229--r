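test_that("signal-to-noise ranking matches the direct formula", {
  set.seed(12)
  expr <- matrix(rnorm(5 * 8, 5, 1), 5, 8,
                 dimnames = list(c("GA", "GB", "GC", "GD", "GE"),
                                 sprintf("S%d", 1:8)))
  ph <- factor(rep(c("control", "case"), each = 4),
               levels = c("control", "case"))
  rk <- rank_genes(expr, ph)
  case <- ph == "case"
  for (g in rownames(expr)) {
    expect_equal(rk$metric[rk$gene == g],
                 s2n_oracle(expr[g, case], expr[g, !case]),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(rk$metric) <= 0))

  # scale invariance: multiplying all values by c > 0 changes nothing
  rk2 <- rank_genes(expr * 3.7, ph)
  expect_equal(rk2$metric, rk$metric, tolerance = 1e-12)

  # a gene with identical group distributions scores 0
  expr0 <- rbind(expr, GZ = rep(c(2, 3, 4, 5), 2))
  rk0 <- rank_genes(expr0, ph)
  expect_equal(rk0$metric[rk0$gene == "GZ"], 0)

  expect_error(rank_genes(expr[, 1:5], factor(c("a", "a", "a", "a", "b"))),
               ">= 3 samples")
})

test_that("enrichment scores hit the weighted running-sum oracle", {
  # unweighted extremes: single top-ranked hit gives ES = 1,
  # single bottom-ranked hit gives ES = -1
  rk <- data.frame(gene = sprintf("G%02d", 1:10),
                   metric = seq(2, -2, length.out = 10))
  expect_equal(enrichment_score(rk, "G01", weight_p = 0)$es, 1)
  expect_equal(enrichment_score(rk, "G10", weight_p = 0)$es, -1)

  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    rk <- data.frame(gene = sprintf("G%03d", 1:n),
                     metric = sort(rnorm(n), decreasing = TRUE))
    gs <- sample(rk$gene, sample(3:(n - 2), 1))
    es <- enrichment_score(rk, gs, weight_p = 1)$es
    expect_equal(es, es_bruteforce(rk$metric, rk$gene %in% gs, 1),
                 tolerance = 1e-12)
    expect_gte(es, -1)
    expect_lte(es, 1)
  }

  expect_error(enrichment_score(rk, "NOT_THERE"), "empty intersection")
  expect_error(enrichment_score(rk, rk$gene), "universe")
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  for (i in 1:10) {
    n <- 100
    rk <- data.frame(gene = sprintf("G%03d", 1:n),
                     metric = sort(rnorm(n), decreasing = TRUE))
    gs <- sample(rk$gene, 15)
    mine <- enrichment_score(rk, gs, weight_p = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(rk$metric, rk$gene),
                               selectedStats = which(rk$gene %in% gs),
                               gseaParam = 1)
    expect_equal(mine, unname(ref), tolerance = 1e-10)
  }
})

test_that("nominal p equals the exhaustive permutation oracle on 3 vs 3", {
  set.seed(23)
  expr <- matrix(rnorm(40 * 6), 40, 6,
                 dimnames = list(sprintf("G%03d", 1:40), sprintf("S%d", 1:6)))
  ph <- factor(rep(c("control", "case"), each = 3),
               levels = c("control", "case"))
  sets <- list(S1 = rownames(expr)[1:12],
               S2 = rownames(expr)[c(5, 9, 14:20)],
               S3 = sample(rownames(expr), 10))
  res <- suppressWarnings(gsea(expr, ph, sets, n_perm = 1000, seed = 1,
                               min_size = 5))
  for (s in names(sets)) {
    p_oracle <- exhaustive_gsea_p_oracle(expr, ph == "case", sets[[s]])
    expect_equal(res$p[res$set == s], p_oracle, tolerance = 1e-12)
  }
})

test_that("gsea results are deterministic, order-invariant and sign-symmetric", {
  cfg <- expression_sim_config(n_genes = 200, n_controls = 8, n_cases = 8,
                               planted_sets = list(UP = list(size = 20,
                                                             delta = 1)),
                               noise_sd = 1, seed = 6)
  ex <- simulate_expression(cfg)
  set.seed(99)
  sets <- c(ex$sets, list(RAND = sample(rownames(ex$expr)[30:200], 20)))
  r1 <- gsea(ex$expr, ex$phenotype, sets, n_perm = 200, seed = 7)
  r2 <- gsea(ex$expr, ex$phenotype, sets, n_perm = 200, seed = 7)
  expect_identical(r1, r2)

  shuffle <- sample(nrow(ex$expr))
  r3 <- gsea(ex$expr[shuffle, ], ex$phenotype, sets, n_perm = 200, seed = 7)
  expect_identical(r1, r3)

  # flipping the phenotype orientation negates every ES
  r4 <- gsea(ex$expr, ex$phenotype, sets, n_perm = 200, seed = 7,
             positive_class = "control")
  expect_equal(r4$es[match(r1$set, r4$set)], -r1$es, tolerance = 1e-12)

  expect_true(all(r1$p >= 1 / 201 & r1$p <= 1))
  expect_true(all(r1$es >= -1 & r1$es <= 1))
  expect_true(all(r1$q >= 0 & r1$q <= 1))
})

test_that("a strongly planted set dominates and reaches significance", {
  cfg <- expression_sim_config(n_genes = 300, n_controls = 10, n_cases = 10,
                               planted_sets = list(PLANTED = list(size = 20,
                                                                  delta = 2)),
                               noise_sd = 0.5, seed = 31)
  ex <- simulate_expression(cfg)
  other <- setdiff(rownames(ex$expr), ex$sets$PLANTED)
  set.seed(31)
  null_sets <- lapply(stats::setNames(1:15, sprintf("NULL%02d", 1:15)),
                      function(i) sample(other, 20))
  res <- gsea(ex$expr, ex$phenotype, c(ex$sets, null_sets),
              n_perm = 500, seed = 2)
  top <- res$set[which.max(abs(res$nes))]
  expect_identical(top, "PLANTED")
  expect_lt(res$q[res$set == "PLANTED"], 0.05)
  expect_identical(res$enriched_in[res$set == "PLANTED"], "case")
})

test_that("preranked mode with a gene-permutation null flags a loaded top set", {
  set.seed(41)
  n <- 200
  rk <- data.frame(gene = sprintf("G%03d", 1:n),
                   metric = sort(rnorm(n, 0, 1), decreasing = TRUE))
  sets <- list(TOP = rk$gene[1:20],
               RAND = sample(rk$gene, 20))
  res <- gsea_preranked(rk, sets, n_perm = 500, seed = 3)
  expect_lt(res$p[res$set == "TOP"], 0.01)
  expect_gt(res$es[res$set == "TOP"], 0)
})
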