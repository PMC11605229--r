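# End-to-end driver: simulate -> quantify (3 contrasts) -> corrected
# interaction calls -> enrichment -> co-expression modules -> gene-set
# integration, with a run manifest and TSV outputs.

#' Assemble and validate a pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master RNG seed; simulation and permutation seeds derive
#'   from it and it is recorded in every output header.
#' @param alpha Significance threshold on the main contrast's adjusted p.
#' @param q_threshold FDR threshold for gene-set significance.
#' @param min_n Minimum interacting proteins per set for the core-set
#'   filter.
#' @param background_n Background gene count for the overlap test.
#' @param bioid A \code{\link{bioid_sim_config}}, or a list
#'   \code{list(table = , design = )} of file paths.
#' @param expression An \code{\link{expression_sim_config}}, or a list
#'   \code{list(expr = , phenotype = )} of file paths, or \code{NULL} to
#'   skip the expression stages.
#' @param n_perm GSEA permutations.
#' @param n_null_sets,null_set_size Random background gene sets added to
#'   the simulated planted sets for the GSEA stage.
#' @param gsea_min_size,gsea_max_size GSEA set-size bounds.
#' @param cut_height,module_min_size Module detection parameters.
#' @param enrichment_table,core_sets Fixture paths for the integration
#'   stage.
#' @param overlap_reference Named numeric vector
#'   \code{c(k = , size_a = , size_b = )} for the reference list-overlap
#'   computation, defaulting to the published 22-protein overlap between
#'   the 387-protein call set and a 382-protein external interactome.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = tempfile("proxidiff_run_"),
                            seed = 1L,
                            alpha = 0.05, q_threshold = 0.05,
                            min_n = 3L, background_n = 20000,
                            bioid = NULL,
                            expression = NULL,
                            n_perm = 200L,
                            n_null_sets = 10L, null_set_size = 30L,
                            gsea_min_size = 15L, gsea_max_size = 500L,
                            cut_height = 0.25, module_min_size = 20L,
                            enrichment_table = proxidiff_fixture("hallmark_cardiomyopathy.tsv"),
                            core_sets = proxidiff_fixture("bag3_core_sets.tsv"),
                            overlap_reference = c(k = 22, size_a = 387,
                                                  size_b = 382)) {
  if (is.null(bioid)) bioid <- bioid_sim_config(seed = seed)
  for (p in c(enrichment_table, core_sets)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  if (is.list(bioid) && !inherits(bioid, "bioid_sim_config")) {
    for (p in unlist(bioid)) {
      if (!file.exists(p)) stop("configured path does not exist: ", p)
    }
  }
  if (is.list(expression) && !inherits(expression, "expression_sim_config")) {
    for (p in unlist(expression)) {
      if (!file.exists(p)) stop("configured path does not exist: ", p)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
                 q_threshold = q_threshold, min_n = min_n,
                 background_n = background_n, bioid = bioid,
                 expression = expression, n_perm = n_perm,
                 n_null_sets = n_null_sets, null_set_size = null_set_size,
                 gsea_min_size = gsea_min_size, gsea_max_size = gsea_max_size,
                 cut_height = cut_height, module_min_size = module_min_size,
                 enrichment_table = enrichment_table, core_sets = core_sets,
                 overlap_reference = overlap_reference),
            class = "pipeline_config")
}

# Short hash of the scientific configuration (output location excluded)
# for output headers.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

pkg_version <- function() {
  as.character(utils::packageVersion("proxidiff"))
}

write_stage_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: BioID simulation (or file input), median
#' normalization, the three design contrasts, corrected interactor
#' calling, the expression stages (GSEA and co-expression modules) when
#' configured, and the gene-set integration arithmetic over the fixture
#' tables. Writes stage outputs and a run manifest under
#' \code{config$out_dir}; every output starts with a comment header
#' carrying the package version, seed and configuration hash. A stage
#' failure aborts with the stage name in the error.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Report list: \code{calls} (interactor table),
#'   \code{n_called}, \code{enrichment}, \code{modules},
#'   \code{integration} (significant-set counts, Venn counts, core-set
#'   filter, union counts, reference overlap test), \code{manifest},
#'   \code{files}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- paste0("proxidiff ", pkg_version(), " | seed=", config$seed,
                 " | config=", config_hash(config))
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("input", {
    if (inherits(config$bioid, "bioid_sim_config")) {
      simulate_bioid(config$bioid)
    } else {
      list(intensities = read_matrix(config$bioid$table),
           design = read_design(config$bioid$design), truth = NULL)
    }
  })

  norm <- stage("normalize", normalize_median(sim$intensities))

  contrasts <- stage("contrasts", list(
    main = contrast_groups(norm, sim$design, "BAG3_Biotin", "BioID"),
    biotin = contrast_groups(norm, sim$design, "AC16_Biotin", "AC16"),
    oe = contrast_groups(norm, sim$design, "BAG3", "BioID")))

  calls <- stage("score", call_interactors(contrasts$main, contrasts$biotin,
                                           contrasts$oe,
                                           alpha = config$alpha))
  f <- file.path(config$out_dir, "interactor_calls.tsv")
  write_stage_tsv(calls, f, meta)
  files <- c(files, f)

  enr <- NULL
  mods <- NULL
  if (!is.null(config$expression)) {
    ex <- stage("expression", {
      if (inherits(config$expression, "expression_sim_config")) {
        simulate_expression(config$expression)
      } else {
        m <- read_matrix(config$expression$expr)
        ph <- utils::read.delim(config$expression$phenotype,
                                comment.char = "#")
        list(expr = m, phenotype = factor(ph$phenotype),
             module_truth = NULL, sets = list())
      }
    })
    enr <- stage("gsea", {
      sets <- ex$sets
      if (config$n_null_sets > 0) {
        set.seed(config$seed + 1L)
        null_sets <- lapply(seq_len(config$n_null_sets), function(i) {
          sample(rownames(ex$expr), config$null_set_size)
        })
        names(null_sets) <- sprintf("NULL_SET_%02d", seq_along(null_sets))
        sets <- c(sets, null_sets)
      }
      gsea(ex$expr, ex$phenotype, sets, n_perm = config$n_perm,
           seed = config$seed + 2L, min_size = config$gsea_min_size,
           max_size = config$gsea_max_size)
    })
    f <- file.path(config$out_dir, "enrichment.tsv")
    write_stage_tsv(enr, f, meta)
    files <- c(files, f)

    mods <- stage("modules", {
      sp <- pick_soft_power(ex$expr)
      tom <- tom_similarity(adjacency_matrix(ex$expr, sp$power))
      labels <- detect_modules(tom, cut_height = config$cut_height,
                               min_size = config$module_min_size)
      trait <- as.numeric(ex$phenotype == levels(ex$phenotype)[2L])
      mt <- if (any(labels > 0)) module_trait(ex$expr, labels, trait) else NULL
      list(power = sp$power, labels = labels, trait = mt)
    })
    f <- file.path(config$out_dir, "modules.tsv")
    write_stage_tsv(data.frame(gene = names(mods$labels),
                               module = mods$labels), f, meta)
    files <- c(files, f)
    if (!is.null(mods$trait)) {
      f <- file.path(config$out_dir, "module_trait.tsv")
      write_stage_tsv(mods$trait$trait_cor, f, meta)
      files <- c(files, f)
    }
  }

  integ <- stage("integrate", {
    tab <- read_enrichment_table(config$enrichment_table)
    sig_idio <- significant_sets(tab, "idiopathic", config$q_threshold)
    sig_isch <- significant_sets(tab, "ischemic", config$q_threshold)
    venn <- venn_compare(sig_idio$hallmark, sig_isch$hallmark)
    fx <- interactor_sets(tab)
    mapping <- map_interactors(fx$interactors, fx$gmt)
    core <- sets_with_min(mapping,
                          intersect(venn$both, names(mapping$members)),
                          min_n = config$min_n)
    cell_cycle <- intersect(c("MYC_TARGETS_V1", "E2F_TARGETS",
                              "G2M_CHECKPOINT", "P53_PATHWAY"),
                            names(mapping$members))
    ref <- config$overlap_reference
    overlap <- overlap_test_counts(k = ref[["k"]], size_a = ref[["size_a"]],
                                   size_b = ref[["size_b"]],
                                   background_n = config$background_n)
    list(n_significant_idiopathic = nrow(sig_idio),
         n_significant_ischemic = nrow(sig_isch),
         venn_counts = venn$counts,
         core_sets = core,
         n_core_sets = nrow(core),
         n_interactors_mapped = length(fx$interactors),
         cell_cycle_union = union_count(mapping, cell_cycle),
         reference_overlap = overlap)
  })
  f <- file.path(config$out_dir, "integration_summary.tsv")
  write_stage_tsv(data.frame(
    quantity = c("significant_idiopathic", "significant_ischemic",
                 "significant_both", "significant_either",
                 "core_sets_min3", "cell_cycle_union_proteins",
                 "reference_overlap_p"),
    value = c(integ$n_significant_idiopathic, integ$n_significant_ischemic,
              integ$venn_counts[["both"]], integ$venn_counts[["either"]],
              integ$n_core_sets, integ$cell_cycle_union,
              integ$reference_overlap$p)), f, meta)
  files <- c(files, f)

  manifest <- list(package = "proxidiff", version = pkg_version(),
                   seed = config$seed, config_hash = config_hash(config),
                   alpha = config$alpha, q_threshold = config$q_threshold,
                   min_n = config$min_n, background_n = config$background_n,
                   n_perm = config$n_perm,
                   inputs = list(enrichment_table = config$enrichment_table,
                                 core_sets = config$core_sets),
                   outputs = basename(files))
  mf <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  files <- c(files, mf)

  list(calls = calls, n_called = sum(calls$called), enrichment = enr,
       modules = mods, integration = integ, manifest = manifest,
       files = files)
}
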