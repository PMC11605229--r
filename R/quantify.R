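#' Equalize-medians normalization
#'
#' Shifts each sample column (log2 scale) so its median over observed
#' values equals the global median of the pre-normalization sample
#' medians. Missing cells are untouched.
#'
#' @param mat Log2 intensity matrix (features x samples), \code{NA} missing.
#' @return Normalized matrix of the same shape.
#' @export
normalize_median <- function(mat) {
  stopifnot(is.matrix(mat))
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs == 0)) {
    stop("sample(s) with zero observed values: ",
         paste(colnames(mat)[n_obs == 0], collapse = ", "))
  }
  med <- apply(mat, 2, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  sweep(mat, 2, med - target, "-")
}

#' Group-vs-group contrast with pooled-variance t tests
#'
#' For each feature with at least \code{min_obs} observed values in each
#' group, computes \code{log2FC = mean(A) - mean(B)}, a two-sample
#' pooled-variance t statistic with \code{df = n_A + n_B - 2}, a
#' two-sided p-value, and a Benjamini-Hochberg adjusted p over the
#' testable features only. Features failing \code{min_obs} in either
#' group get \code{testable = FALSE} and \code{NA} statistics.
#'
#' Degenerate variance cases: both groups constant and equal gives
#' \code{t = 0, p = 1}; both constant but unequal gives the machine
#' minimum positive p with a warning.
#'
#' @param mat Log2 matrix (features x samples).
#' @param design Data frame with \code{sample}, \code{condition};
#'   \code{sample} values must name columns of \code{mat}.
#' @param group_a,group_b Condition labels; log2FC is A minus B.
#' @param min_obs Minimum observed values required per group (>= 2).
#' @return Data frame (one row per feature): \code{feature},
#'   \code{log2fc}, \code{t}, \code{df}, \code{p}, \code{q},
#'   \code{n_a}, \code{n_b}, \code{testable}.
#' @export
contrast_groups <- function(mat, design, group_a, group_b, min_obs = 2L) {
  stopifnot(is.matrix(mat), min_obs >= 2)
  for (g in c(group_a, group_b)) {
    if (!g %in% design$condition) stop("unknown condition label: ", g)
  }
  cols_a <- design$sample[design$condition == group_a]
  cols_b <- design$sample[design$condition == group_b]
  stopifnot(all(c(cols_a, cols_b) %in% colnames(mat)))
  xa <- mat[, cols_a, drop = FALSE]
  xb <- mat[, cols_b, drop = FALSE]

  n_a <- rowSums(!is.na(xa))
  n_b <- rowSums(!is.na(xb))
  testable <- n_a >= min_obs & n_b >= min_obs
  if (!any(testable)) stop("no testable features for ", group_a, " vs ", group_b)

  m_a <- rowMeans(xa, na.rm = TRUE)
  m_b <- rowMeans(xb, na.rm = TRUE)
  ss_a <- rowSums((xa - m_a)^2, na.rm = TRUE)
  ss_b <- rowSums((xb - m_b)^2, na.rm = TRUE)
  df <- n_a + n_b - 2
  sp2 <- (ss_a + ss_b) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  log2fc <- m_a - m_b

  tstat <- log2fc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- testable & se == 0
  if (any(zero_var)) {
    equal <- zero_var & log2fc == 0
    tstat[equal] <- 0
    p[equal] <- 1
    unequal <- zero_var & log2fc != 0
    if (any(unequal)) {
      warning(sum(unequal), " feature(s) with zero within-group variance ",
              "but unequal means; p set to machine minimum", call. = FALSE)
      tstat[unequal] <- sign(log2fc[unequal]) * Inf
      p[unequal] <- .Machine$double.xmin
    }
  }

  log2fc[!testable] <- NA_real_
  tstat[!testable] <- NA_real_
  p[!testable] <- NA_real_
  df[!testable] <- NA_integer_
  q <- rep(NA_real_, nrow(mat))
  q[testable] <- adjust_bh(p[testable])

  data.frame(feature = rownames(mat), log2fc = log2fc, t = tstat,
             df = as.integer(df), p = p, q = q,
             n_a = as.integer(n_a), n_b = as.integer(n_b),
             testable = testable, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: \code{q_(i) = min_{j >= i} min(1, p_(j) * m / j)} at
#' sorted rank i, returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q) in the input order.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
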