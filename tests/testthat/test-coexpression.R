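test_that("topological overlap matches the triple-loop oracle", {
  set.seed(14)
  for (i in 1:20) {
    a <- random_adjacency(8)
    expect_equal(tom_similarity(a), tom_bruteforce(a), tolerance = 1e-12)
  }

  # empty graph: all off-diagonal TOM = 0
  z <- matrix(0, 5, 5)
  tz <- tom_similarity(z)
  expect_true(all(tz[upper.tri(tz)] == 0))
  expect_true(all(diag(tz) == 1))

  # complete graph: TOM = 1 everywhere
  ones <- matrix(1, 6, 6)
  diag(ones) <- 0
  expect_equal(tom_similarity(ones), matrix(1, 6, 6), tolerance = 1e-12)

  # star graphs have no two-paths between leaves, handled by the same
  # oracle; TOM stays within [0, 1] and symmetric
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 0.7
  ts <- tom_similarity(star)
  expect_equal(ts, tom_bruteforce(star), tolerance = 1e-12)
  expect_equal(ts, t(ts))
  expect_true(all(ts >= 0 & ts <= 1))

  bad <- random_adjacency(5)
  bad[1, 2] <- bad[1, 2] + 0.2
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("soft-threshold adjacency decreases with power and selection works", {
  set.seed(15)
  expr <- matrix(rnorm(40 * 20), 40, 20)
  a3 <- adjacency_matrix(expr, 3)
  a5 <- adjacency_matrix(expr, 5)
  off <- upper.tri(a3)
  strict <- a3[off] > 0 & a3[off] < 1
  expect_true(all(a5[off][strict] < a3[off][strict]))

  # saturated network (|r| = 1 everywhere): adjacency is all-ones for
  # every power, the fit is degenerate and the smallest power returns
  perfect <- outer(rnorm(35, 0, 1), rnorm(12)) +
    matrix(rnorm(35 * 12, 0, 1e-9), 35, 12)
  expect_warning(sel <- pick_soft_power(perfect), "degenerate")
  expect_equal(sel$power, 1L)

  # latent-factor modules: selected power is moderate with a good fit
  cfg <- expression_sim_config(n_genes = 450, n_controls = 50, n_cases = 50,
                               modules = list(sizes = c(150, 100, 50),
                                              loading_mean = 1,
                                              loading_sd = 0.8),
                               noise_sd = 0.5, seed = 1)
  ex <- simulate_expression(cfg)
  sp <- pick_soft_power(ex$expr)
  expect_true(sp$power >= 3 && sp$power <= 12)
  expect_gte(sp$fit$r2_signed[sp$fit$power == sp$power], 0.8)
})

test_that("modules are recovered from planted structure and noise stays out", {
  # two rank-one modules, zero noise: perfect recovery
  cfg <- expression_sim_config(n_genes = 60, n_controls = 10, n_cases = 10,
                               modules = list(sizes = c(30, 30),
                                              loading_mean = 1,
                                              loading_sd = 0.2),
                               noise_sd = 0, seed = 5)
  ex <- simulate_expression(cfg)
  tom <- tom_similarity(adjacency_matrix(ex$expr, 6))
  lab <- detect_modules(tom)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(lab, ex$module_truth), 1)

  # pure-noise genes stay unassigned at default settings
  set.seed(6)
  noise <- matrix(rnorm(100 * 40), 100, 40,
                  dimnames = list(sprintf("G%03d", 1:100), NULL))
  tom_n <- tom_similarity(adjacency_matrix(noise, 6))
  lab_n <- suppressWarnings(detect_modules(tom_n))
  expect_gte(mean(lab_n == 0), 0.9)
})

test_that("eigengenes orient consistently and find trait associations", {
  # module of identical genes: eigengene correlates 1 with each member
  cfg <- expression_sim_config(n_genes = 25, n_controls = 10, n_cases = 10,
                               modules = list(sizes = 25, loading_mean = 1,
                                              loading_sd = 0),
                               noise_sd = 0, seed = 7)
  ex <- simulate_expression(cfg)
  lab <- rep(1L, 25)
  mt <- module_trait(ex$expr, lab, rnorm(20))
  expect_equal(unname(cor(mt$eigengenes[, 1], ex$expr[1, ])), 1,
               tolerance = 1e-10)
  expect_equal(unname(sd(mt$eigengenes[, 1])), 1, tolerance = 1e-12)

  # planted module with factor shifted -1 in cases: negative trait r
  cfg2 <- expression_sim_config(n_genes = 120, n_controls = 30, n_cases = 30,
                                modules = list(sizes = c(60, 40),
                                               loading_mean = 1,
                                               loading_sd = 0.2,
                                               case_shift = c(-1, 0)),
                                noise_sd = 0.5, seed = 8)
  ex2 <- simulate_expression(cfg2)
  trait <- as.numeric(ex2$phenotype == "case")
  mt2 <- module_trait(ex2$expr, ex2$module_truth, trait)
  r1 <- mt2$trait_cor[mt2$trait_cor$module == 1, ]
  expect_lt(r1$r, 0)
  expect_lt(r1$p, 0.01)

  # gene order must not matter, and flipping every member's sign must
  # not change the module-trait correlation magnitude or direction
  shuffle <- sample(nrow(ex2$expr))
  mt3 <- module_trait(ex2$expr[shuffle, ], ex2$module_truth[shuffle], trait)
  expect_equal(mt3$trait_cor$r, mt2$trait_cor$r, tolerance = 1e-10)
  flipped <- ex2$expr
  flipped[ex2$module_truth == 1, ] <- -flipped[ex2$module_truth == 1, ]
  mt4 <- module_trait(flipped, ex2$module_truth, trait)
  expect_equal(abs(mt4$trait_cor$r[1]), abs(r1$r), tolerance = 1e-10)
})
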