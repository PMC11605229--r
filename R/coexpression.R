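# Minimal weighted co-expression network analysis: soft-threshold
# adjacency, topological overlap, average-linkage module detection with
# a static cut, and eigengene-trait correlation.

#' Choose a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, builds the unsigned adjacency
#' \code{a_ij = |cor(x_i, x_j)|^beta}, computes connectivities
#' \code{k_i = sum_j a_ij}, bins \code{k} into equal-width bins and
#' regresses the log10 bin frequency \code{log10 p(k)} on the log10
#' mean connectivity per bin (the standard scale-free fit). The signed fit
#' index is R-squared with the sign of the slope flipped (a scale-free
#' network has a negative slope). Returns the smallest power whose
#' signed fit reaches \code{r2_target}; if none does, the power with the
#' maximal signed fit.
#'
#' @param expr Gene x sample matrix (>= 30 genes after dropping
#'   constant rows, which are removed with a warning).
#' @param powers Candidate integer powers.
#' @param r2_target Signed scale-free fit threshold.
#' @param n_bins Connectivity bins for the fit.
#' @return List: \code{power} (the chosen beta), \code{fit} (data frame
#'   \code{power}, \code{r2_signed}, \code{slope}, \code{mean_k}).
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_target = 0.8,
                            n_bins = 10L) {
  stopifnot(is.matrix(expr))
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " constant gene row(s)", call. = FALSE)
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 30) stop("need >= 30 usable genes to assess topology")
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0

  fit <- data.frame(power = powers, r2_signed = NA_real_, slope = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- ac^powers[i]
    k <- rowSums(a)
    fit$mean_k[i] <- mean(k)
    if (diff(range(k)) < .Machine$double.eps^0.5) next  # all k equal
    bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
    pk <- tabulate(bin, nbins = nlevels(bin)) / length(k)
    km <- as.numeric(tapply(k, bin, mean))
    use <- !is.na(km) & pk > 0 & km > 0
    if (sum(use) < 2) next
    lk <- log10(km[use])
    lp <- log10(pk[use])
    lm_fit <- stats::lm(lp ~ lk)
    slope <- stats::coef(lm_fit)[2]
    r2 <- summary(lm_fit)$r.squared
    fit$slope[i] <- slope
    fit$r2_signed[i] <- -sign(slope) * r2
  }
  if (all(is.na(fit$r2_signed))) {
    # saturated/degenerate network: adjacency (and hence connectivity)
    # is flat for every power, so the choice of power is immaterial
    warning("scale-free fit undefined for every power (degenerate ",
            "connectivity); returning the smallest candidate power",
            call. = FALSE)
    return(list(power = powers[1L], fit = fit))
  }
  ok <- which(!is.na(fit$r2_signed) & fit$r2_signed >= r2_target)
  power <- if (length(ok)) powers[ok[1L]] else
    powers[which.max(fit$r2_signed)]
  list(power = power, fit = fit)
}

#' Unsigned soft-threshold adjacency
#' @param expr Gene x sample matrix.
#' @param power Soft-thresholding exponent beta.
#' @return Symmetric adjacency matrix \code{|cor|^beta} with zero
#'   diagonal.
#' @export
adjacency_matrix <- function(expr, power) {
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \code{L_ij = sum_{u != i,j} a_iu a_uj} and \code{k_i = sum_j
#' a_ij}; the diagonal is 1. Nodes sharing many neighbours score high
#' even when their direct adjacency is modest.
#'
#' @param adjacency Symmetric matrix, zero diagonal, entries in \[0, 1\].
#' @return TOM similarity matrix (same dimension, unit diagonal).
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-12))) {
    stop("adjacency must be symmetric")
  }
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  l_mat <- a %*% a  # (a %*% a)_ij = sum_u a_iu a_uj; u = i,j terms vanish
  kmin <- outer(k, k, pmin)
  tom <- (l_mat + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' \code{1 - TOM}; the tree is cut at \code{cut_height} (the
#' conventional static-cut region just below the top of a TOM
#' dendrogram, where unrelated genes join near height 1), clusters
#' smaller than \code{min_size} are relabeled 0 (unassigned), and the
#' surviving modules are renumbered by decreasing size (ties by the
#' order of first appearance).
#'
#' @param tom TOM similarity matrix from \code{\link{tom_similarity}}.
#' @param cut_height Static cut height on \code{1 - TOM}.
#' @param min_size Minimum module size.
#' @return Integer vector of module labels (named by gene when the TOM
#'   carries dimnames); 0 = unassigned.
#' @export
detect_modules <- function(tom, cut_height = 0.95, min_size = 20L) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- integer(length(raw))
  if (!length(keep)) {
    warning("no cluster reaches min_size = ", min_size,
            "; all genes unassigned", call. = FALSE)
  } else {
    keep_sorted <- keep[order(-sizes[keep], as.integer(keep))]
    for (m in seq_along(keep_sorted)) {
      labels[raw == as.integer(keep_sorted[m])] <- m
    }
  }
  names(labels) <- rownames(tom)
  labels
}

#' Module eigengenes and module-trait correlation
#'
#' The eigengene of a module is the first principal component of its
#' standardized member-gene submatrix, scaled to unit variance and
#' sign-oriented so its mean correlation with member genes is
#' non-negative. Each eigengene is then correlated (Pearson) with the
#' sample trait; p comes from the usual t transform with n - 2 degrees
#' of freedom.
#'
#' @param expr Gene x sample matrix.
#' @param labels Integer module labels per gene (0 = unassigned), as
#'   from \code{\link{detect_modules}}.
#' @param trait Numeric vector, one value per sample.
#' @return List: \code{eigengenes} (sample x module matrix, columns
#'   \code{ME1}, ...), \code{trait_cor} (data frame \code{module},
#'   \code{size}, \code{r}, \code{p}).
#' @export
module_trait <- function(expr, labels, trait) {
  stopifnot(is.matrix(expr), length(labels) == nrow(expr),
            length(trait) == ncol(expr))
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no assigned modules")
  n <- ncol(expr)
  eig <- matrix(NA_real_, n, length(mods),
                dimnames = list(colnames(expr), paste0("ME", mods)))
  res <- data.frame(module = mods, size = NA_integer_, r = NA_real_,
                    p = NA_real_)
  for (i in seq_along(mods)) {
    sub <- expr[labels == mods[i], , drop = FALSE]
    res$size[i] <- nrow(sub)
    z <- t(scale(t(sub)))  # standardize each gene across samples
    if (nrow(z) == 1L) {
      e <- as.numeric(z)
    } else {
      sv <- svd(z, nu = 0, nv = 1)
      e <- sv$v[, 1]
    }
    e <- as.numeric(scale(e))  # unit variance
    if (mean(stats::cor(e, t(sub))) < 0) e <- -e
    eig[, i] <- e
    r <- stats::cor(e, trait)
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    res$r[i] <- r
    res$p[i] <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(eigengenes = eig, trait_cor = res)
}
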