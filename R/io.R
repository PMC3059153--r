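# Tab-delimited interchange: expression matrices (first column feature ID,
# header row of sample IDs), probe annotations, replicate designs.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of feature IDs;
#' the body must be fully numeric. Malformed input (ragged rows, duplicate
#' feature IDs, non-numeric or missing cells) raises an error naming the
#' offending line and column.
#'
#' @param path Path to a tab-delimited file.
#' @return Numeric matrix with feature IDs as row names and sample IDs as
#'   column names.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading cell for the feature-ID column
  n_body <- length(fields[[2L]])
  samples <- if (length(header) == n_body) header[-1L]
             else if (length(header) == n_body - 1L) header
             else stop("header/body field-count mismatch at line 2")
  widths <- lengths(fields[-1L])
  if (any(widths != n_body)) {
    stop("ragged row at line ", which(widths != n_body)[1L] + 1L)
  }
  ids <- vapply(fields[-1L], `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate feature ID: ", ids[duplicated(ids)][1L])
  }
  body <- vapply(fields[-1L], function(f) {
    suppressWarnings(as.numeric(f[-1L]))
  }, numeric(n_body - 1L))
  body <- t(matrix(body, nrow = n_body - 1L))
  if (anyNA(body)) {
    idx <- which(is.na(body), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing value at line ", idx[1L] + 1L,
         ", column ", idx[2L] + 1L, " (sample '", samples[idx[2L]], "')")
  }
  dimnames(body) <- list(ids, samples)
  body
}

#' Write an expression matrix to TSV
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param digits Significant digits; the default \code{NA} writes full
#'   precision (17 digits) so that write-then-read round-trips exactly.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(x, path, digits = NA) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("matrix needs feature and sample names")
  }
  dg <- if (is.na(digits)) 17L else as.integer(digits)
  fmt <- function(v) formatC(v, digits = dg, format = "g")
  lines <- c(
    paste(c("feature_id", colnames(x)), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], fmt(x[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a unified-expression set to TSV files
#'
#' Writes the gene x sample score matrix to \code{path}, the per-gene QC
#' table (loadings, uniquenesses, Heywood/convergence flags, QC flags) to
#' \code{qc_path}, and the skipped-genes report to \code{skipped_path}.
#' Scores are written at full precision by default and round-trip through
#' [read_expression_tsv()] exactly.
#'
#' @param ue A \code{"ue_set"} from [unify_gene_level()] or
#'   [unify_probe_level()]; must contain at least one fitted gene.
#' @param path Output path for the score matrix.
#' @param qc_path,skipped_path Sibling outputs; defaults derive from
#'   \code{path}.
#' @param digits Passed to [write_expression_tsv()].
#' @return \code{path}, invisibly.
#' @export
write_unified_tsv <- function(ue, path,
                              qc_path = sub("(\\.tsv)?$", "_qc.tsv", path),
                              skipped_path = sub("(\\.tsv)?$", "_skipped.tsv",
                                                 path),
                              digits = NA) {
  stopifnot(inherits(ue, "ue_set"))
  if (!length(ue$gene_ids)) stop("no fitted genes to write")
  write_expression_tsv(ue$scores, path, digits = digits)
  utils::write.table(ue_qc_table(ue), qc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ue$skipped, skipped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table from TSV
#'
#' Columns: \code{probe_id}, \code{gene_id}, \code{platform} and optionally
#' \code{copies} (replicate spotting count, >= 1, default 1). Every probe
#' maps to exactly one gene and platform.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return Data frame with the four columns.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_id", "platform")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(ann$copies)) ann$copies <- 1L
  if (any(ann$copies < 1)) stop("copies must be >= 1")
  .check_annotation(ann)
  ann
}

#' Read a replicate design from TSV
#'
#' Columns \code{group_id} and \code{sample_id}; each group is one set of
#' technical/biological replicates of the same specimen.
#'
#' @param path Path to a tab-delimited file with a header.
#' @return Named list of character vectors of sample IDs.
#' @export
read_replicate_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("group_id", "sample_id") %in% names(df))) {
    stop("replicate design must have columns group_id, sample_id")
  }
  split(df$sample_id, df$group_id)
}
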