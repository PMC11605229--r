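# Independent oracles used to validate the package implementations.
# These deliberately use naive, direct formulations (loops, explicit
# formulas) and never call the package functions they check.

# BH step-up, evaluated directly from the definition:
# q_(i) = min_{j >= i} min(1, p_(j) * m / j) at sorted rank i.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Pooled-variance two-sample t from first principles.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, df = na + nb - 2,
       p = 2 * stats::pt(-abs(tstat), na + nb - 2))
}

# Weighted KS enrichment score by explicit position-by-position walk.
es_bruteforce <- function(metric_sorted, hits, p = 1) {
  n <- length(metric_sorted)
  nh <- sum(hits)
  wsum <- sum(abs(metric_sorted[hits])^p)
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      cur <- cur + abs(metric_sorted[i])^p / wsum
    } else {
      cur <- cur - 1 / (n - nh)
    }
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# Signal-to-noise metric, one gene at a time, straight from the formula.
s2n_oracle <- function(x_case, x_ctrl) {
  m1 <- mean(x_case); m0 <- mean(x_ctrl)
  s1 <- max(sd(x_case), 0.2 * abs(m1), 1e-8)
  s0 <- max(sd(x_ctrl), 0.2 * abs(m0), 1e-8)
  (m1 - m0) / (s1 + s0)
}

# Exhaustive phenotype-permutation nominal p for one gene set on a tiny
# study: enumerate every distinct case/control split, recompute the
# ranking and ES each time, and apply the sign-matched p formula.
exhaustive_gsea_p_oracle <- function(expr, case, gene_set, weight_p = 1) {
  n <- length(case)
  n_case <- sum(case)
  splits <- utils::combn(n, n_case)
  es_for <- function(case_idx) {
    cs <- logical(n); cs[case_idx] <- TRUE
    metric <- vapply(seq_len(nrow(expr)), function(g) {
      s2n_oracle(expr[g, cs], expr[g, !cs])
    }, 0)
    o <- order(-metric, rownames(expr))
    es_bruteforce(metric[o], rownames(expr)[o] %in% gene_set, weight_p)
  }
  es_obs <- es_for(which(case))
  es_all <- apply(splits, 2, es_for)
  if (es_obs > 0) {
    pos <- es_all[es_all > 0]
    (1 + sum(pos >= es_obs)) / (1 + length(pos))
  } else {
    neg <- es_all[es_all < 0]
    (1 + sum(neg <= es_obs)) / (1 + length(neg))
  }
}

# Topological overlap by triple loop.
tom_bruteforce <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l_ij <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l_ij <- l_ij + a[i, u] * a[u, j]
      }
      k_i <- sum(a[i, ]); k_j <- sum(a[j, ])
      out[i, j] <- (l_ij + a[i, j]) / (min(k_i, k_j) + 1 - a[i, j])
    }
  }
  out
}

# Symmetric random adjacency with zero diagonal, entries in [0, 1].
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# Run the three design contrasts and the interactor caller on one
# simulated BioID data set. normalize = TRUE mirrors the full pipeline
# (equalize-medians first); FALSE tests the estimator on the simulator's
# common scale directly.
run_bioid_chain <- function(sim, alpha = 0.05, normalize = FALSE) {
  mat <- if (normalize) normalize_median(sim$intensities) else sim$intensities
  cm <- contrast_groups(mat, sim$design, "BAG3_Biotin", "BioID")
  cb <- contrast_groups(mat, sim$design, "AC16_Biotin", "AC16")
  co <- contrast_groups(mat, sim$design, "BAG3", "BioID")
  list(main = cm, biotin = cb, oe = co,
       calls = suppressWarnings(call_interactors(cm, cb, co, alpha = alpha)))
}
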