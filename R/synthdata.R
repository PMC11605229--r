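#' Configuration for the five-condition BioID simulator
#'
#' The generative model works entirely in log2 intensity space. Each
#' protein gets a baseline abundance and belongs to exactly one class:
#' \describe{
#'   \item{interactor}{true proximity partner of the bait; gains a
#'     proximity effect \code{t} only in the bait+biotin condition.}
#'   \item{biotin_background}{binds biotin/streptavidin machinery; gains
#'     a background effect \code{b} in every biotin-treated condition
#'     (bait+biotin, free ligase, biotin-only).}
#'   \item{oe_responsive}{responds to bait over-expression; gains an
#'     over-expression effect \code{o} in the two bait-transfected
#'     conditions (with and without biotin).}
#'   \item{null}{no effect anywhere.}
#' }
#' Replicate noise is i.i.d. Gaussian, and cells drop out with
#' probability \code{plogis((lod_threshold - value) / lod_steepness)},
#' i.e. low-abundance measurements are missing preferentially, as in
#' label-free MS.
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates Replicates per condition (the study design uses 3).
#' @param class_fractions Named fractions over
#'   \code{c(interactor, biotin_background, oe_responsive, null)};
#'   must be non-negative and sum to 1.
#' @param effect_means_log2 Named means \code{c(mu_t, mu_b, mu_o)} of the
#'   proximity, biotin-background and over-expression effects (log2 units).
#' @param effect_sd_log2 Common standard deviation of the three effects.
#' @param baseline_mean,baseline_sd Log2 baseline abundance distribution.
#' @param noise_sd Replicate noise standard deviation (log2 units).
#' @param lod_threshold,lod_steepness Logistic limit-of-detection
#'   missingness parameters (log2 units); \code{lod_steepness <= 0}
#'   disables missingness.
#' @param seed RNG seed.
#' @return Object of class \code{bioid_sim_config}.
#' @export
bioid_sim_config <- function(n_proteins = 2000,
                             n_replicates = 3,
                             class_fractions = c(interactor = 0.05,
                                                 biotin_background = 0.25,
                                                 oe_responsive = 0.10,
                                                 null = 0.60),
                             effect_means_log2 = c(mu_t = 3, mu_b = 1.5,
                                                   mu_o = 1),
                             effect_sd_log2 = 0.5,
                             baseline_mean = 20, baseline_sd = 2,
                             noise_sd = 0.5,
                             lod_threshold = 16, lod_steepness = 1,
                             seed = 1L) {
  classes <- c("interactor", "biotin_background", "oe_responsive", "null")
  if (is.null(names(class_fractions))) names(class_fractions) <- classes
  if (!setequal(names(class_fractions), classes)) {
    stop("class_fractions must be named over: ", paste(classes, collapse = ", "))
  }
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must be non-negative and sum to 1")
  }
  if (is.null(names(effect_means_log2))) {
    names(effect_means_log2) <- c("mu_t", "mu_b", "mu_o")
  }
  stopifnot(n_proteins >= 1, n_replicates >= 2, noise_sd >= 0,
            effect_sd_log2 >= 0, baseline_sd >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 class_fractions = class_fractions,
                 effect_means_log2 = effect_means_log2,
                 effect_sd_log2 = effect_sd_log2,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd,
                 lod_threshold = lod_threshold,
                 lod_steepness = lod_steepness,
                 seed = as.integer(seed)),
            class = "bioid_sim_config")
}

# Largest-remainder apportionment: integer class counts from fractions,
# summing exactly to n. Ties broken by class order.
class_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Simulate a five-condition BioID intensity table with ground truth
#'
#' Log2 intensity of protein i in sample s:
#' \deqn{y_{is} = baseline_i + b_i [s\ biotin{-}treated]
#'   + o_i [s\ bait{-}transfected] + t_i [s = BAG3\_Biotin] + \epsilon_{is}}
#' where biotin-treated conditions are \code{BAG3_Biotin}, \code{BioID},
#' \code{AC16_Biotin} and bait-transfected conditions are
#' \code{BAG3_Biotin}, \code{BAG3}. Under this model the corrected
#' interaction effect (see \code{\link{corrected_effect}}) has
#' expectation \code{t_i} exactly:
#' \code{(t+o) - b - (o-b) = t}.
#'
#' Cells are then set missing with probability
#' \code{plogis((lod_threshold - y) / lod_steepness)} using a single
#' uniform draw per cell, so lowering the threshold never adds missing
#' cells under a fixed seed (common random numbers).
#'
#' @param config A \code{\link{bioid_sim_config}}.
#' @return List with elements \code{intensities} (protein x sample log2
#'   matrix with \code{NA} for missing), \code{design} (data frame
#'   \code{sample}, \code{condition}), \code{truth} (data frame
#'   \code{protein}, \code{class}, \code{t}, \code{b}, \code{o}), and
#'   \code{config}.
#' @export
simulate_bioid <- function(config = bioid_sim_config()) {
  stopifnot(inherits(config, "bioid_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  counts <- class_counts(config$class_fractions, n)
  cls <- rep(names(counts), counts)
  proteins <- sprintf("PROT%05d", seq_len(n))

  sd_e <- config$effect_sd_log2
  mu <- config$effect_means_log2
  t_i <- ifelse(cls == "interactor", stats::rnorm(n, mu[["mu_t"]], sd_e), 0)
  b_i <- ifelse(cls == "biotin_background",
                stats::rnorm(n, mu[["mu_b"]], sd_e), 0)
  o_i <- ifelse(cls == "oe_responsive", stats::rnorm(n, mu[["mu_o"]], sd_e), 0)
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)

  conditions <- rep(BIOID_CONDITIONS, each = config$n_replicates)
  samples <- paste0(conditions, "_R",
                    rep(seq_len(config$n_replicates),
                        times = length(BIOID_CONDITIONS)))
  biotin_treated <- conditions %in% c("BAG3_Biotin", "BioID", "AC16_Biotin")
  bait_transfected <- conditions %in% c("BAG3_Biotin", "BAG3")
  proximity_on <- conditions == "BAG3_Biotin"

  n_s <- length(samples)
  signal <- outer(baseline, rep(1, n_s)) +
    outer(b_i, as.numeric(biotin_treated)) +
    outer(o_i, as.numeric(bait_transfected)) +
    outer(t_i, as.numeric(proximity_on))
  noise <- matrix(stats::rnorm(n * n_s, 0, config$noise_sd), n, n_s)
  y <- signal + noise
  dimnames(y) <- list(proteins, samples)

  if (config$lod_steepness > 0) {
    u <- matrix(stats::runif(n * n_s), n, n_s)
    p_miss <- stats::plogis((config$lod_threshold - y) / config$lod_steepness)
    y[u < p_miss] <- NA_real_
  }

  list(intensities = y,
       design = data.frame(sample = samples, condition = conditions,
                           stringsAsFactors = FALSE),
       truth = data.frame(protein = proteins, class = cls,
                          t = t_i, b = b_i, o = o_i,
                          stringsAsFactors = FALSE),
       config = config)
}

#' Configuration for the two-group expression simulator
#'
#' Emulates the statistical structure of a case-control myocardial
#' expression study: latent-factor co-expression modules plus planted
#' gene-set mean shifts in cases, over Gaussian noise. Default group
#' sizes follow the 16-control / 86-case design of the idiopathic
#' cardiomyopathy comparison this pipeline targets.
#'
#' @param n_genes Number of genes.
#' @param n_controls,n_cases Group sizes (each >= 3).
#' @param modules List describing co-expression modules:
#'   \code{sizes} (integer vector), \code{loading_mean}, \code{loading_sd},
#'   and optional \code{case_shift} (numeric per module: the latent factor
#'   mean in cases minus controls, in factor units). Modules occupy the
#'   first \code{sum(sizes)} genes in order; overlap is impossible by
#'   construction, and an explicit \code{genes} list may be supplied
#'   instead, in which case overlap is an error.
#' @param planted_sets Named list; each element is
#'   \code{list(size =, delta =)} or \code{list(genes =, delta =)}.
#'   \code{delta} is the log2 mean shift added to case samples. Sets
#'   specified by \code{size} are carved sequentially from the genes
#'   after the module blocks.
#' @param noise_sd Residual noise standard deviation.
#' @param seed RNG seed.
#' @return Object of class \code{expression_sim_config}.
#' @export
expression_sim_config <- function(n_genes = 1000,
                                  n_controls = 16, n_cases = 86,
                                  modules = NULL,
                                  planted_sets = NULL,
                                  noise_sd = 1,
                                  seed = 1L) {
  stopifnot(n_genes >= 1, n_controls >= 3, n_cases >= 3, noise_sd >= 0)
  if (!is.null(modules)) {
    if (is.null(modules$genes)) {
      stopifnot(!is.null(modules$sizes))
      if (sum(modules$sizes) > n_genes) stop("module sizes exceed n_genes")
      offs <- cumsum(c(0, modules$sizes))
      modules$genes <- lapply(seq_along(modules$sizes), function(m) {
        seq(offs[m] + 1L, offs[m + 1L])
      })
    }
    idx <- unlist(modules$genes)
    if (anyDuplicated(idx)) stop("overlapping module gene assignments")
    if (any(idx < 1 | idx > n_genes)) stop("module gene index out of range")
    if (is.null(modules$loading_mean)) modules$loading_mean <- 1
    if (is.null(modules$loading_sd)) modules$loading_sd <- 0.2
    if (is.null(modules$case_shift)) {
      modules$case_shift <- rep(0, length(modules$genes))
    }
    stopifnot(length(modules$case_shift) == length(modules$genes))
  }
  if (!is.null(planted_sets)) {
    stopifnot(is.list(planted_sets), !is.null(names(planted_sets)))
    cursor <- if (is.null(modules)) 0L else max(unlist(modules$genes))
    for (s in names(planted_sets)) {
      ps <- planted_sets[[s]]
      if (is.null(ps$genes)) {
        stopifnot(!is.null(ps$size))
        if (cursor + ps$size > n_genes) stop("planted sets exceed n_genes")
        planted_sets[[s]]$genes <- seq(cursor + 1L, cursor + ps$size)
        cursor <- cursor + ps$size
      }
      if (any(planted_sets[[s]]$genes < 1 | planted_sets[[s]]$genes > n_genes)) {
        stop("planted set gene index out of range")
      }
      if (is.null(planted_sets[[s]]$delta)) planted_sets[[s]]$delta <- 0
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases),
                 modules = modules, planted_sets = planted_sets,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a two-group expression study
#'
#' Gene g, sample j:
#' \code{x_gj = loading_g * factor_{m(g), j} + delta_S * [g in S, j case]
#'   + noise}, with per-module latent factors \code{factor_{m,.} ~ N(shift_m
#'   * case_j, 1)} and loadings \code{~ N(loading_mean, loading_sd)}.
#'
#' @param config An \code{\link{expression_sim_config}}.
#' @return List with \code{expr} (gene x sample matrix), \code{phenotype}
#'   (factor \code{control}/\code{case} per sample), \code{module_truth}
#'   (integer module label per gene, 0 = none), and \code{sets}
#'   (named list of planted-set member symbols, possibly empty).
#' @export
simulate_expression <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genes
  n_s <- config$n_controls + config$n_cases
  genes <- sprintf("GENE%05d", seq_len(n_g))
  samples <- c(sprintf("CTRL%03d", seq_len(config$n_controls)),
               sprintf("CASE%03d", seq_len(config$n_cases)))
  phenotype <- factor(rep(c("control", "case"),
                          c(config$n_controls, config$n_cases)),
                      levels = c("control", "case"))
  case <- phenotype == "case"

  x <- matrix(0, n_g, n_s, dimnames = list(genes, samples))
  module_truth <- integer(n_g)
  if (!is.null(config$modules)) {
    mod <- config$modules
    for (m in seq_along(mod$genes)) {
      g_idx <- mod$genes[[m]]
      module_truth[g_idx] <- m
      fac <- stats::rnorm(n_s, mean = mod$case_shift[m] * as.numeric(case))
      loadings <- stats::rnorm(length(g_idx), mod$loading_mean, mod$loading_sd)
      x[g_idx, ] <- x[g_idx, ] + outer(loadings, fac)
    }
  }
  sets <- list()
  if (!is.null(config$planted_sets)) {
    for (s in names(config$planted_sets)) {
      ps <- config$planted_sets[[s]]
      x[ps$genes, case] <- x[ps$genes, case] + ps$delta
      sets[[s]] <- genes[ps$genes]
    }
  }
  x <- x + matrix(stats::rnorm(n_g * n_s, 0, config$noise_sd), n_g, n_s)

  list(expr = x, phenotype = phenotype,
       module_truth = stats::setNames(module_truth, genes),
       sets = sets, config = config)
}
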