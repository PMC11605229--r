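test_that("simulated BioID tables are deterministic with forced class counts", {
  cfg <- bioid_sim_config(n_proteins = 1000,
                          class_fractions = c(interactor = 0.1,
                                              biotin_background = 0.2,
                                              oe_responsive = 0.2,
                                              null = 0.5),
                          seed = 1)
  a <- simulate_bioid(cfg)
  b <- simulate_bioid(cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$truth, b$truth)

  counts <- table(a$truth$class)
  expect_equal(counts[["interactor"]], 100)
  expect_equal(counts[["biotin_background"]], 200)
  expect_equal(counts[["oe_responsive"]], 200)
  expect_equal(counts[["null"]], 500)

  # exactly one class per protein; null proteins carry no effects
  expect_equal(nrow(a$truth), 1000)
  nulls <- a$truth[a$truth$class == "null", ]
  expect_true(all(nulls$t == 0 & nulls$b == 0 & nulls$o == 0))

  expect_identical(sort(unique(a$design$condition)), sort(BIOID_CONDITIONS))
  expect_equal(table(a$design$condition)[["BAG3_Biotin"]], 3)
  expect_false(anyDuplicated(a$design$sample) > 0)
  expect_false(anyDuplicated(rownames(a$intensities)) > 0)

  expect_error(bioid_sim_config(class_fractions = c(interactor = 0.5,
                                                    biotin_background = 0.5,
                                                    oe_responsive = 0.5,
                                                    null = -0.5)),
               "sum to 1")
})

test_that("zero effects and zero noise produce identical sample columns", {
  cfg <- bioid_sim_config(n_proteins = 50,
                          effect_means_log2 = c(mu_t = 0, mu_b = 0, mu_o = 0),
                          effect_sd_log2 = 0, noise_sd = 0,
                          lod_steepness = 0, seed = 9)
  sim <- simulate_bioid(cfg)
  expect_true(all(apply(sim$intensities, 1, function(r) length(unique(r))) == 1))

  # downstream corrected effect is exactly 0 for every protein
  res <- run_bioid_chain(sim)
  expect_true(all(res$calls$corrected == 0))
  expect_true(all(!res$calls$called))
})

test_that("lowering the detection threshold never adds missing cells", {
  base <- bioid_sim_config(n_proteins = 300, seed = 11)
  miss_at <- function(lod) {
    cfg <- base
    cfg$lod_threshold <- lod
    sum(is.na(simulate_bioid(cfg)$intensities))
  }
  n_miss <- vapply(c(20, 18, 16, 14, 10), miss_at, 0)
  expect_true(all(diff(n_miss) <= 0))
})

test_that("expression simulator plants rank-one modules and case shifts", {
  # identical loadings, zero noise: within-module correlation is 1
  cfg <- expression_sim_config(n_genes = 30, n_controls = 5, n_cases = 5,
                               modules = list(sizes = 10, loading_mean = 1,
                                              loading_sd = 0),
                               noise_sd = 0, seed = 2)
  ex <- simulate_expression(cfg)
  cc <- cor(t(ex$expr[1:10, ]))
  expect_equal(max(abs(cc - 1)), 0, tolerance = 1e-12)
  expect_identical(unname(ex$module_truth[1:10]), rep(1L, 10))
  expect_identical(unname(ex$module_truth[11:30]), rep(0L, 20))

  # planted set mean shift appears in cases only
  cfg2 <- expression_sim_config(n_genes = 40, n_controls = 20, n_cases = 20,
                                planted_sets = list(UP = list(size = 15,
                                                              delta = 2)),
                                noise_sd = 0, seed = 3)
  ex2 <- simulate_expression(cfg2)
  in_set <- rownames(ex2$expr) %in% ex2$sets$UP
  case <- ex2$phenotype == "case"
  expect_equal(unname(rowMeans(ex2$expr[in_set, case]) -
                        rowMeans(ex2$expr[in_set, !case])),
               rep(2, sum(in_set)))
  expect_true(all(ex2$expr[!in_set, ] == 0))

  # overlapping module definitions are rejected
  expect_error(expression_sim_config(n_genes = 30,
                                     modules = list(genes = list(1:10, 5:15))),
               "overlapping")
  a <- simulate_expression(cfg2)
  expect_identical(a$expr, ex2$expr)
})
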