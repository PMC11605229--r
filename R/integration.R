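# Gene-set integration arithmetic: dual-condition significance Venn
# logic over hallmark enrichment results, mapping called interactors
# into gene sets, minimum-membership filtering, and the exact
# hypergeometric overlap test between two protein lists.

#' Read a two-condition hallmark enrichment table
#'
#' Expects a TSV with columns \code{hallmark}, \code{size},
#' \code{direction_idiopathic}, \code{nes_idiopathic},
#' \code{q_idiopathic}, \code{direction_ischemic}, \code{nes_ischemic},
#' \code{q_ischemic}, \code{proteins} (comma-joined interacting-protein
#' symbols, possibly empty). Directions are \code{up}/\code{down}
#' (up = higher in disease). The packaged fixture
#' \code{hallmark_cardiomyopathy.tsv} transcribes the 50 hallmark sets
#' scored in idiopathic and ischemic cardiomyopathy.
#'
#' @param path File path; defaults to the packaged fixture.
#' @return Data frame with the columns above, \code{proteins} as a list
#'   column of uppercased symbol vectors.
#' @export
read_enrichment_table <- function(path = proxidiff_fixture("hallmark_cardiomyopathy.tsv")) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         comment.char = "#")
  need <- c("hallmark", "size", "direction_idiopathic", "nes_idiopathic",
            "q_idiopathic", "direction_ischemic", "nes_ischemic",
            "q_ischemic", "proteins")
  if (!all(need %in% names(d))) {
    stop("enrichment table missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  if (anyDuplicated(d$hallmark)) stop("duplicate set names in ", path)
  stopifnot(all(d$q_idiopathic >= 0 & d$q_idiopathic <= 1),
            all(d$q_ischemic >= 0 & d$q_ischemic <= 1))
  d$proteins <- lapply(strsplit(ifelse(is.na(d$proteins), "", d$proteins), ","),
                       function(v) toupper(trimws(v[nzchar(trimws(v))])))
  d
}

#' Read the both-condition core gene-set table
#'
#' TSV with columns \code{set}, \code{regulation} (\code{up}/\code{down}
#' in disease) and \code{proteins} (comma-joined interacting-protein
#' symbols). The packaged fixture \code{bag3_core_sets.tsv} lists the
#' hallmark sets enriched in both cardiomyopathy conditions with at
#' least three BAG3-interacting proteins.
#'
#' @param path File path; defaults to the packaged fixture.
#' @return Data frame with \code{proteins} as a list column.
#' @export
read_core_sets <- function(path = proxidiff_fixture("bag3_core_sets.tsv")) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         comment.char = "#")
  stopifnot(all(c("set", "regulation", "proteins") %in% names(d)))
  d$proteins <- lapply(strsplit(d$proteins, ","),
                       function(v) toupper(trimws(v[nzchar(trimws(v))])))
  d
}

#' Interactor list and per-set membership from an enrichment table
#'
#' Convenience accessor: turns the \code{proteins} list column of
#' \code{\link{read_enrichment_table}} into a GMT-style named list (one
#' entry per hallmark set, empty sets dropped) and the pooled unique
#' interactor list across all sets.
#'
#' @param table Data frame from \code{\link{read_enrichment_table}}.
#' @return List: \code{gmt} (named list of member vectors),
#'   \code{interactors} (sorted unique symbols).
#' @export
interactor_sets <- function(table) {
  gmt <- stats::setNames(table$proteins, table$hallmark)
  gmt <- gmt[vapply(gmt, length, 1L) > 0]
  list(gmt = gmt, interactors = sort(unique(unlist(gmt))))
}

#' Path to a packaged fixture file
#' @param file File name under the package's \code{extdata}.
#' @return Absolute path.
#' @export
proxidiff_fixture <- function(file) {
  p <- system.file("extdata", file, package = "proxidiff", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

#' Gene sets significantly enriched in one condition
#'
#' Selects sets with FDR q strictly below the threshold for the given
#' condition, tagged with their direction.
#'
#' @param table Data frame from \code{\link{read_enrichment_table}}.
#' @param condition \code{"idiopathic"} or \code{"ischemic"}.
#' @param q_threshold Strict significance cutoff on q.
#' @return Data frame \code{hallmark}, \code{direction}, \code{nes},
#'   \code{q} for the significant sets.
#' @export
significant_sets <- function(table, condition, q_threshold = 0.05) {
  if (!condition %in% c("idiopathic", "ischemic")) {
    stop("unknown condition: ", condition)
  }
  qcol <- paste0("q_", condition)
  keep <- table[[qcol]] < q_threshold
  data.frame(hallmark = table$hallmark[keep],
             direction = table[[paste0("direction_", condition)]][keep],
             nes = table[[paste0("nes_", condition)]][keep],
             q = table[[qcol]][keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-way Venn comparison of named set collections
#' @param sets_a,sets_b Character vectors of set names.
#' @return List: \code{both}, \code{only_a}, \code{only_b},
#'   \code{either} (sorted character vectors) and \code{counts}
#'   (named integer vector).
#' @export
venn_compare <- function(sets_a, sets_b) {
  both <- sort(intersect(sets_a, sets_b))
  only_a <- sort(setdiff(sets_a, sets_b))
  only_b <- sort(setdiff(sets_b, sets_a))
  either <- sort(union(sets_a, sets_b))
  list(both = both, only_a = only_a, only_b = only_b, either = either,
       counts = c(both = length(both), only_a = length(only_a),
                  only_b = length(only_b), either = length(either)))
}

#' Map interacting proteins into gene sets
#'
#' Intersects an interactor list with each gene set's members
#' (case-insensitive on uppercased symbols). Interactors not found in
#' any set are returned in an \code{unmapped} bucket.
#'
#' @param interactors Character vector of protein/gene symbols.
#' @param gmt Named list of member vectors (e.g. \code{\link{read_gmt}}).
#' @return List: \code{members} (named list of sorted per-set
#'   intersections), \code{counts} (named integer vector),
#'   \code{unmapped} (sorted vector of symbols in no set).
#' @export
map_interactors <- function(interactors, gmt) {
  if (!length(gmt)) stop("empty gene-set collection")
  ints <- unique(toupper(trimws(interactors)))
  members <- lapply(gmt, function(s) sort(intersect(ints, toupper(s))))
  mapped <- unique(unlist(members))
  list(members = members,
       counts = vapply(members, length, 1L),
       unmapped = sort(setdiff(ints, mapped)))
}

#' Gene sets with at least a minimum number of interacting proteins
#'
#' @param mapping Result of \code{\link{map_interactors}}.
#' @param set_filter Set names to consider (must be mapped sets).
#' @param min_n Minimum member count.
#' @return Data frame \code{set}, \code{n}, sorted by \code{n}
#'   descending then set name.
#' @export
sets_with_min <- function(mapping, set_filter = names(mapping$members),
                          min_n = 3L) {
  if (!all(set_filter %in% names(mapping$members))) {
    stop("set_filter contains unmapped set name(s): ",
         paste(setdiff(set_filter, names(mapping$members)), collapse = ", "))
  }
  n <- mapping$counts[set_filter]
  keep <- n >= min_n
  out <- data.frame(set = set_filter[keep], n = as.integer(n[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n, out$set), , drop = FALSE]
}

#' Distinct proteins across a group of gene sets
#' @param mapping Result of \code{\link{map_interactors}}.
#' @param set_names Set names to pool.
#' @return Integer: size of the union of the per-set member lists.
#' @export
union_count <- function(mapping, set_names) {
  if (!all(set_names %in% names(mapping$members))) {
    stop("unknown set name(s): ",
         paste(setdiff(set_names, names(mapping$members)), collapse = ", "))
  }
  length(unique(unlist(mapping$members[set_names])))
}

#' Exact hypergeometric overlap test between two lists
#'
#' Upper-tail probability of observing at least \code{k = |A
#' intersect B|} shared members when lists of sizes \code{K = |A|} and
#' \code{n = |B|} are drawn from a background of \code{background_n}
#' genes. The tail is computed by exact summation of log-scale
#' hypergeometric point masses (log-sum-exp), so extreme p-values keep
#' full precision.
#'
#' @param list_a,list_b Character vectors of symbols (deduplicated,
#'   case-insensitive).
#' @param background_n Background population size (default 20000,
#'   roughly the protein-coding human genome).
#' @return List: \code{background_n}, \code{size_a}, \code{size_b},
#'   \code{overlap}, \code{expected} (\code{size_a * size_b /
#'   background_n}), \code{p} (one-sided upper tail), and
#'   \code{overlap_symbols}.
#' @export
overlap_test <- function(list_a, list_b, background_n = 20000) {
  a <- unique(toupper(trimws(list_a)))
  b <- unique(toupper(trimws(list_b)))
  if (background_n < length(union(a, b))) {
    stop("background_n smaller than the union of the two lists")
  }
  shared <- sort(intersect(a, b))
  p <- hyper_upper_tail(k = length(shared), big_k = length(a),
                        n = length(b), big_n = background_n)
  list(background_n = background_n, size_a = length(a), size_b = length(b),
       overlap = length(shared),
       expected = length(a) * length(b) / background_n,
       p = p, overlap_symbols = shared)
}

#' Hypergeometric overlap test from counts alone
#'
#' Same computation as \code{\link{overlap_test}} when only the list
#' sizes and overlap count are known (e.g. when comparing against a
#' published interactome whose membership is not distributed).
#'
#' @param k Observed overlap.
#' @param size_a,size_b List sizes.
#' @param background_n Background population size.
#' @return List: \code{background_n}, \code{size_a}, \code{size_b},
#'   \code{overlap}, \code{expected}, \code{p}.
#' @export
overlap_test_counts <- function(k, size_a, size_b, background_n = 20000) {
  stopifnot(k >= 0, k <= min(size_a, size_b),
            background_n >= size_a + size_b - k)
  list(background_n = background_n, size_a = size_a, size_b = size_b,
       overlap = k, expected = size_a * size_b / background_n,
       p = hyper_upper_tail(k = k, big_k = size_a, n = size_b,
                            big_n = background_n))
}

# P(X >= k) for X ~ Hypergeometric(N, K, n), by log-space summation of
# point masses over the feasible upper tail.
hyper_upper_tail <- function(k, big_k, n, big_n) {
  if (k <= 0) return(1)
  upper <- min(big_k, n)
  if (k > upper) return(0)
  logs <- stats::dhyper(k:upper, m = big_k, n = big_n - big_k, k = n,
                        log = TRUE)
  m <- max(logs)
  exp(m) * sum(exp(logs - m))
}
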