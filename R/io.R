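#' Read a feature-by-sample matrix from TSV/CSV
#'
#' The first column holds feature (protein/gene) identifiers, the header
#' row holds sample identifiers. Empty cells and the token \code{NA} are
#' read as missing. The delimiter is a tab unless the file name ends in
#' \code{.csv}. Identifiers are uppercased so protein and gene symbols
#' share one namespace.
#'
#' @param path File path.
#' @return Numeric matrix with feature row names and sample column names.
#' @export
read_matrix <- function(path) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncol_expect <- length(fields[[1L]])
  bad <- which(vapply(fields, length, 1L) != ncol_expect)
  if (length(bad)) {
    stop("ragged row(s) at line ", paste(bad, collapse = ", "), " in ", path)
  }
  samples <- fields[[1L]][-1L]
  body <- fields[-1L]
  ids <- toupper(vapply(body, `[[`, "", 1L))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate feature id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  cells <- lapply(body, `[`, -1L)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
                dimnames = list(ids, samples))
  for (i in seq_along(cells)) {
    v <- cells[[i]]
    v[v == "" | v == "NA"] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad_cell <- which(!is.na(v) & is.na(num))
    if (length(bad_cell)) {
      stop("non-numeric cell at line ", i + 1L, ", column ",
           samples[bad_cell[1L]], " in ", path, ": '", v[bad_cell[1L]], "'")
    }
    mat[i, ] <- num
  }
  message("read_matrix: ", nrow(mat), " features x ", ncol(mat),
          " samples from ", path)
  mat
}

#' Write a feature-by-sample matrix as canonical TSV
#'
#' Tab-separated, \code{.} decimal separator, \code{NA} for missing;
#' the first header field names the feature column. Numbers are written
#' with full double precision (17 significant digits) so that
#' parse-write-parse is idempotent.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output file path.
#' @param feature_col Header name for the identifier column.
#' @param header_comment Optional comment line(s) written first, each
#'   prefixed with \code{#}.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(mat, path, feature_col = "feature",
                         header_comment = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                     trim = TRUE, nsmall = 0)
    }, "")
    out
  }
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t")
  }, "")
  header <- paste(c(feature_col, colnames(mat)), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a sample design table
#'
#' Two-column TSV mapping sample identifiers to condition labels.
#'
#' @param path File path.
#' @return Data frame with columns \code{sample} and \code{condition}.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (!all(c("sample", "condition") %in% names(d))) {
    stop("design file must have columns 'sample' and 'condition': ", path)
  }
  if (anyDuplicated(d$sample)) {
    stop("duplicate sample id(s) in design: ",
         paste(unique(d$sample[duplicated(d$sample)]), collapse = ", "))
  }
  d[, c("sample", "condition")]
}

#' Write a sample design table
#' @param design Data frame with \code{sample} and \code{condition}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design[, c("sample", "condition")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard MSigDB GMT: one set per line, tab-separated
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Member symbols
#' are uppercased and deduplicated (with a warning naming the set);
#' duplicate set names are an error.
#'
#' @param path File path.
#' @return Named list of character vectors of member symbols.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields in ",
         path)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(seq_along(fields), function(i) {
    members <- toupper(trimws(fields[[i]][-(1:2)]))
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set ", nm[i], "; deduplicated",
              call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
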