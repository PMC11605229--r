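test_that("corrected effect is the exact triple-contrast difference", {
  expect_equal(corrected_effect(0, 0, 0), 0)
  expect_equal(corrected_effect(5, 1, 2), 2)
  expect_equal(corrected_effect(c(1, 2), c(0.5, 0), c(0, 1)), c(0.5, 1))
  expect_error(corrected_effect(NA, 0, 0), "fc_main")
  expect_error(corrected_effect(1, Inf, 0), "fc_biotin")
})

test_that("the caller gates on main-contrast significance and positivity", {
  mk <- function(id, fc, q, testable = TRUE) {
    data.frame(feature = id, log2fc = fc, t = 1, df = 4, p = q, q = q,
               n_a = 3L, n_b = 3L, testable = testable,
               stringsAsFactors = FALSE)
  }
  ids <- c("P1", "P2", "P3", "P4")
  # P1: significant, corrected positive -> called
  # P2: significant but corrected = 2 - 0 - 3 = -1 -> not called
  # P3: not significant -> not called
  # P4: untestable in main -> never called
  main <- mk(ids, fc = c(3, 2, 3, 5), q = c(0.01, 0.01, 0.5, 0.01),
             testable = c(TRUE, TRUE, TRUE, FALSE))
  biotin <- mk(ids, fc = c(0.5, 0, 0, 0), q = 0.5)
  oe <- mk(ids, fc = c(0.5, 3, 0, 0), q = 0.5)
  res <- call_interactors(main, biotin, oe)
  expect_identical(res$called[match(ids, res$protein)],
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$corrected[res$protein == "P2"], -1)
  expect_true(is.na(res$corrected[res$protein == "P4"]))

  # all q above alpha: zero calls
  none <- call_interactors(mk(ids, fc = 3, q = 0.2), biotin, oe)
  expect_equal(sum(none$called), 0)

  # untestable correction contrast degrades to 0 with a flag
  biotin_miss <- mk(ids, fc = c(NA, 0, 0, 0), q = 0.5,
                    testable = c(FALSE, TRUE, TRUE, TRUE))
  expect_warning(res2 <- call_interactors(main, biotin_miss, oe),
                 "correction contrast")
  expect_equal(res2$fc_biotin[res2$protein == "P1"], 0)
  expect_true(res2$correction_imputed[res2$protein == "P1"])
  expect_equal(res2$corrected[res2$protein == "P1"], 3 - 0 - 0.5)

  # alternative positivity reading gates on the raw main fold change
  res3 <- call_interactors(main, biotin, oe, positive = "main")
  expect_true(res3$called[res3$protein == "P2"])

  # output sorted by corrected effect descending, ties by protein id
  expect_true(all(diff(xtfrm(res$corrected[!is.na(res$corrected)])) <= 0))

  expect_error(call_interactors(main, mk("ZZ", 1, 0.5), oe), "no protein ids")
})

test_that("near-zero noise recovers the planted interactor set exactly", {
  cfg <- bioid_sim_config(n_proteins = 1000,
                          class_fractions = c(interactor = 0.1,
                                              biotin_background = 0.2,
                                              oe_responsive = 0.2,
                                              null = 0.5),
                          effect_means_log2 = c(mu_t = 3, mu_b = 1.5,
                                                mu_o = 1),
                          noise_sd = 0.01, lod_steepness = 0, seed = 1)
  sim <- simulate_bioid(cfg)
  res <- run_bioid_chain(sim, normalize = TRUE)
  called <- res$calls$protein[res$calls$called]
  truth <- sim$truth$protein[sim$truth$class == "interactor"]
  expect_setequal(called, truth)
})

test_that("corrected effects recover the planted proximity effect per class", {
  # additive model: E[corrected] = t for every class, so interactors
  # average mu_t and artifact classes average 0
  per_class <- sapply(1:5, function(seed) {
    cfg <- bioid_sim_config(n_proteins = 400,
                            class_fractions = c(interactor = 0.25,
                                                biotin_background = 0.25,
                                                oe_responsive = 0.25,
                                                null = 0.25),
                            noise_sd = 0.5, seed = seed)
    sim <- simulate_bioid(cfg)
    res <- run_bioid_chain(sim)
    m <- merge(res$calls, sim$truth, by = "protein")
    m <- m[!is.na(m$corrected), ]
    tapply(m$corrected - m$t, m$class, mean)
  })
  bias <- rowMeans(per_class)
  se <- apply(per_class, 1, sd) / sqrt(ncol(per_class))
  expect_true(all(abs(bias) < 3 * se + 1e-8))
})
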