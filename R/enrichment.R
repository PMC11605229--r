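# Weighted Kolmogorov-Smirnov gene-set enrichment with a phenotype
# permutation null: signal-to-noise ranking, weighted running-sum ES,
# sign-matched NES, and the ratio-method FDR q.

# Signal-to-noise metric for a fixed case/control split; x is the
# gene x sample matrix, case a logical per sample. Each group sd is
# floored at max(sd, 0.2 * |group mean|, 1e-8), the usual guard against
# near-constant genes blowing up the ratio.
s2n_metric <- function(x, case) {
  xa <- x[, case, drop = FALSE]
  xb <- x[, !case, drop = FALSE]
  m_a <- rowMeans(xa)
  m_b <- rowMeans(xb)
  sd_a <- sqrt(rowSums((xa - m_a)^2) / (ncol(xa) - 1))
  sd_b <- sqrt(rowSums((xb - m_b)^2) / (ncol(xb) - 1))
  sd_a <- pmax(sd_a, 0.2 * abs(m_a), 1e-8)
  sd_b <- pmax(sd_b, 0.2 * abs(m_b), 1e-8)
  (m_a - m_b) / (sd_a + sd_b)
}

#' Rank genes by a two-group differential metric
#'
#' Computes the signal-to-noise ratio
#' \code{(mean_case - mean_control) / (sd_case + sd_control)} per gene,
#' with each group standard deviation floored at
#' \code{max(sd, 0.2 * |group mean|, 1e-8)}, and returns genes sorted by
#' the metric in decreasing order. Ties are broken by gene id
#' (lexicographic), so the ranking is reproducible and independent of
#' input row order.
#'
#' @param expr Gene x sample numeric matrix with gene row names.
#' @param phenotype Factor (or coercible) with exactly two levels over
#'   the samples; each level needs >= 3 samples.
#' @param positive_class The phenotype level treated as "case" (metric
#'   numerator mean); defaults to the second factor level.
#' @return Data frame \code{gene}, \code{metric}, sorted descending.
#' @export
rank_genes <- function(expr, phenotype,
                       positive_class = levels(as.factor(phenotype))[2L]) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  phenotype <- as.factor(phenotype)
  if (nlevels(phenotype) != 2L) stop("phenotype must have exactly two levels")
  case <- phenotype == positive_class
  if (sum(case) < 3L || sum(!case) < 3L) {
    stop("each phenotype group needs >= 3 samples (permutation would be ",
         "degenerate)")
  }
  metric <- s2n_metric(expr, case)
  o <- order(-metric, rownames(expr))
  data.frame(gene = rownames(expr)[o], metric = metric[o],
             row.names = NULL, stringsAsFactors = FALSE)
}

# ES of one set given hit indicator and weights, both already in rank
# order. Returns the signed deviation of maximal absolute value; the
# full running sum is optionally attached.
es_core <- function(hits, w, keep_running = FALSE) {
  n <- length(hits)
  n_h <- sum(hits)
  hw <- w * hits
  tot <- sum(hw)
  if (tot == 0) hw[hits] <- 1 / n_h else hw <- hw / tot
  p_hit <- cumsum(hw)
  if (tot == 0) p_hit <- pmin(p_hit, 1)
  p_miss <- cumsum(!hits) / (n - n_h)
  dev <- p_hit - p_miss
  es <- dev[which.max(abs(dev))]
  if (keep_running) attr(es, "running") <- dev
  es
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating \code{|metric|^weight_p} for set
#' members (normalized to total 1) against a uniform miss penalty
#' \code{1/(N - N_hit)}, and returns the signed deviation of maximal
#' absolute value. \code{weight_p = 0} reduces to the classical
#' Kolmogorov-Smirnov statistic; \code{weight_p = 1} is the standard
#' weighted form.
#'
#' @param ranked Data frame from \code{\link{rank_genes}} (or any data
#'   frame with \code{gene} and \code{metric} sorted by decreasing
#'   metric).
#' @param gene_set Character vector of member symbols.
#' @param weight_p Weighting exponent on \code{|metric|}.
#' @return List with \code{es} and \code{running} (the deviation at
#'   every rank position).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(is.data.frame(ranked), all(c("gene", "metric") %in% names(ranked)))
  hits <- ranked$gene %in% gene_set
  if (!any(hits)) stop("gene set has empty intersection with the ranked list")
  if (all(hits)) stop("gene set equals the whole universe (miss penalty ",
                      "denominator is degenerate)")
  w <- abs(ranked$metric)^weight_p
  es <- es_core(hits, w, keep_running = TRUE)
  list(es = as.numeric(es), running = attr(es, "running"))
}

# All distinct case/control label assignments as a logical matrix
# (samples x assignments); used when the exhaustive null is smaller
# than the requested number of permutations.
all_label_splits <- function(n, n_case) {
  combos <- utils::combn(n, n_case)
  m <- matrix(FALSE, n, ncol(combos))
  for (j in seq_len(ncol(combos))) m[combos[, j], j] <- TRUE
  m
}

#' Gene-set enrichment analysis with phenotype permutation
#'
#' For each gene set: the weighted running-sum enrichment score on the
#' observed signal-to-noise ranking; a nominal p from sign-matched
#' phenotype-label permutations,
#' \code{p = (1 + #\{|ES_perm| >= |ES|, same sign\}) / (1 + #same-sign perms)};
#' \code{NES = ES / mean(|same-sign permuted ES|)}; and a ratio-method
#' FDR q — for \code{NES* > 0},
#' \code{q = P(permuted NES >= NES*) / P(observed NES >= NES*)} pooled
#' over all sets, clipped to \[0, 1\] and made monotone in \code{|NES|}
#' (symmetric for negative scores). When the number of distinct label
#' splits does not exceed \code{n_perm} the null is enumerated
#' exhaustively instead of sampled.
#'
#' Zero-variance genes are dropped from the universe first; sets are
#' restricted to the universe and those outside \code{[min_size,
#' max_size]} are dropped with a message.
#'
#' @param expr Gene x sample matrix.
#' @param phenotype Two-level factor over samples.
#' @param sets Named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param n_perm Number of phenotype permutations.
#' @param seed RNG seed for the permutation draw.
#' @param weight_p ES weighting exponent.
#' @param min_size,max_size Set-size bounds after universe restriction.
#' @param positive_class Phenotype level ranked at the top
#'   (positive metric); defaults to the second factor level.
#' @return Data frame, one row per retained set: \code{set},
#'   \code{size}, \code{es}, \code{nes}, \code{p}, \code{q},
#'   \code{enriched_in} (phenotype level at the leading edge), sorted by
#'   decreasing \code{nes}.
#' @export
gsea <- function(expr, phenotype, sets, n_perm = 1000, seed = 1L,
                 weight_p = 1, min_size = 15L, max_size = 500L,
                 positive_class = levels(as.factor(phenotype))[2L]) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), length(sets) >= 1)
  if (n_perm < 100) warning("n_perm < 100: permutation p-values will be coarse",
                            call. = FALSE)
  phenotype <- as.factor(phenotype)
  if (nlevels(phenotype) != 2L) stop("phenotype must have exactly two levels")
  case <- phenotype == positive_class
  if (sum(case) < 3L || sum(!case) < 3L) {
    stop("each phenotype group needs >= 3 samples")
  }

  gene_var <- apply(expr, 1, stats::var)
  if (any(gene_var == 0)) {
    message("gsea: dropping ", sum(gene_var == 0), " zero-variance gene(s)")
    expr <- expr[gene_var > 0, , drop = FALSE]
  }
  universe <- rownames(expr)

  members <- lapply(sets, function(s) intersect(toupper(s), universe))
  sizes <- vapply(members, length, 1L)
  keep <- sizes >= min_size & sizes <= max_size & sizes < length(universe)
  if (any(!keep)) {
    message("gsea: dropping ", sum(!keep), " set(s) outside size bounds [",
            min_size, ", ", max_size, "] after universe restriction")
  }
  members <- members[keep]
  if (!length(members)) stop("no gene sets left after size filtering")
  n_sets <- length(members)
  hit_mat <- vapply(members, function(m) universe %in% m,
                    logical(length(universe)))

  es_all_sets <- function(case_labels) {
    metric <- s2n_metric(expr, case_labels)
    o <- order(-metric, universe)
    w <- abs(metric[o])^weight_p
    vapply(seq_len(n_sets), function(s) {
      as.numeric(es_core(hit_mat[o, s], w))
    }, 0)
  }

  es_obs <- es_all_sets(case)

  n_samp <- length(case)
  n_case <- sum(case)
  n_distinct <- choose(n_samp, n_case)
  set.seed(seed)
  if (n_distinct <= n_perm) {
    perm_labels <- all_label_splits(n_samp, n_case)
  } else {
    perm_labels <- vapply(seq_len(n_perm), function(i) sample(case),
                          logical(n_samp))
  }
  es_perm <- apply(perm_labels, 2, es_all_sets)
  if (is.null(dim(es_perm))) es_perm <- matrix(es_perm, nrow = n_sets)

  p <- nes <- numeric(n_sets)
  nes_perm <- matrix(NA_real_, n_sets, ncol(es_perm))
  for (s in seq_len(n_sets)) {
    ep <- es_perm[s, ]
    pos <- ep[ep > 0]
    neg <- ep[ep < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    nes_perm[s, ep > 0] <- ep[ep > 0] / mean_pos
    nes_perm[s, ep < 0] <- ep[ep < 0] / mean_neg
    nes_perm[s, ep == 0] <- 0
    if (es_obs[s] > 0) {
      p[s] <- (1 + sum(pos >= es_obs[s])) / (1 + length(pos))
      nes[s] <- if (is.na(mean_pos)) 0 else es_obs[s] / mean_pos
    } else if (es_obs[s] < 0) {
      p[s] <- (1 + sum(neg <= es_obs[s])) / (1 + length(neg))
      nes[s] <- if (is.na(mean_neg)) 0 else -abs(es_obs[s]) / mean_neg
    } else {
      p[s] <- 1
      nes[s] <- 0
    }
  }

  q <- fdr_ratio_q(nes, nes_perm)

  other_class <- setdiff(levels(phenotype), positive_class)
  out <- data.frame(set = names(members),
                    size = vapply(members, length, 1L),
                    es = es_obs, nes = nes, p = p, q = q,
                    enriched_in = ifelse(es_obs >= 0, positive_class,
                                         other_class),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$nes, out$set), , drop = FALSE]
}

# Ratio-method FDR over the pooled permutation NES distribution:
# q(NES*) = P(perm NES beyond NES*) / P(observed NES beyond NES*),
# per sign, clipped to [0, 1] and made monotone non-decreasing as |NES|
# shrinks (suffix minimum from the most extreme score inward).
fdr_ratio_q <- function(nes, nes_perm) {
  all_perm <- nes_perm[is.finite(nes_perm)]
  n_sets <- length(nes)
  q <- rep(NA_real_, n_sets)
  for (s in seq_len(n_sets)) {
    if (nes[s] > 0) {
      num <- mean(all_perm >= nes[s])
      den <- mean(nes >= nes[s])
    } else if (nes[s] < 0) {
      num <- mean(all_perm <= nes[s])
      den <- mean(nes <= nes[s])
    } else {
      q[s] <- 1
      next
    }
    q[s] <- min(1, max(0, num / den))
  }
  for (sgn in c(1, -1)) {
    idx <- which(sign(nes) == sgn)
    if (!length(idx)) next
    ord <- idx[order(-abs(nes[idx]))]
    # suffix minimum: a more extreme |NES| can never have a larger q
    q[ord] <- rev(cummin(rev(q[ord])))
  }
  q
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' Companion mode for externally ranked lists: the null redraws random
#' gene sets of matching size from the ranked universe instead of
#' permuting phenotype labels.
#'
#' @param ranked Data frame from \code{\link{rank_genes}} or any ranked
#'   \code{gene}/\code{metric} table sorted descending.
#' @param sets Named list of member vectors.
#' @inheritParams gsea
#' @return Same shape as \code{\link{gsea}}, with \code{enriched_in}
#'   reported as \code{"positive"}/\code{"negative"}.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1L,
                           weight_p = 1, min_size = 15L, max_size = 500L) {
  stopifnot(is.data.frame(ranked), all(c("gene", "metric") %in% names(ranked)))
  universe <- ranked$gene
  w <- abs(ranked$metric)^weight_p
  members <- lapply(sets, function(s) intersect(toupper(s), universe))
  sizes <- vapply(members, length, 1L)
  keep <- sizes >= min_size & sizes <= max_size & sizes < length(universe)
  if (any(!keep)) {
    message("gsea_preranked: dropping ", sum(!keep),
            " set(s) outside size bounds")
  }
  members <- members[keep]
  if (!length(members)) stop("no gene sets left after size filtering")
  n <- length(universe)
  n_sets <- length(members)

  es_obs <- vapply(members, function(m) {
    as.numeric(es_core(universe %in% m, w))
  }, 0)

  set.seed(seed)
  uniq_sizes <- sort(unique(vapply(members, length, 1L)))
  es_perm_by_size <- lapply(uniq_sizes, function(k) {
    vapply(seq_len(n_perm), function(i) {
      hits <- logical(n)
      hits[sample.int(n, k)] <- TRUE
      as.numeric(es_core(hits, w))
    }, 0)
  })
  names(es_perm_by_size) <- as.character(uniq_sizes)
  es_perm <- t(vapply(members, function(m) {
    es_perm_by_size[[as.character(length(m))]]
  }, numeric(n_perm)))

  p <- nes <- numeric(n_sets)
  nes_perm <- matrix(NA_real_, n_sets, n_perm)
  for (s in seq_len(n_sets)) {
    ep <- es_perm[s, ]
    pos <- ep[ep > 0]
    neg <- ep[ep < 0]
    nes_perm[s, ep > 0] <- ep[ep > 0] / mean(pos)
    nes_perm[s, ep < 0] <- ep[ep < 0] / mean(abs(neg))
    nes_perm[s, ep == 0] <- 0
    if (es_obs[s] > 0) {
      p[s] <- (1 + sum(pos >= es_obs[s])) / (1 + length(pos))
      nes[s] <- es_obs[s] / mean(pos)
    } else if (es_obs[s] < 0) {
      p[s] <- (1 + sum(neg <= es_obs[s])) / (1 + length(neg))
      nes[s] <- -abs(es_obs[s]) / mean(abs(neg))
    } else {
      p[s] <- 1
      nes[s] <- 0
    }
  }
  q <- fdr_ratio_q(nes, nes_perm)
  out <- data.frame(set = names(members),
                    size = vapply(members, length, 1L),
                    es = es_obs, nes = nes, p = p, q = q,
                    enriched_in = ifelse(es_obs >= 0, "positive", "negative"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$nes, out$set), , drop = FALSE]
}
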