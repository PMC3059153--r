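# Precision and accuracy statistics for comparing expression summaries:
# pooled replicate variance, squared distance to a reference technology,
# group fold changes, and ROC construction against supplied truth labels.

#' Pooled within-replicate variance per gene
#'
#' For replicate sets r = 1..n_i of sample i,
#' \deqn{s^2 = \sum_i \sum_r (y_{ir} - \bar y_i)^2 / \sum_i (n_i - 1).}
#' Summaries should be standardized per gene beforehand when the goal is to
#' compare different summaries on a common scale. Location shifts leave the
#' statistic unchanged.
#'
#' @param x Numeric matrix (genes x samples) with sample IDs as column
#'   names.
#' @param groups List of character vectors of sample IDs, one vector per
#'   replicate set; sets must be disjoint, with at least two members each,
#'   and all IDs present in \code{x}.
#' @return Named numeric vector: pooled variance per gene. Take
#'   \code{sqrt()} for pooled SDs.
#' @export
pooled_variance <- function(x, groups) {
  x <- as.matrix(x)
  ids <- unlist(groups)
  if (anyDuplicated(ids)) stop("replicate sets must be disjoint")
  missing <- setdiff(ids, colnames(x))
  if (length(missing)) {
    stop("replicate sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every replicate set needs at least 2 samples")
  num <- 0
  for (g in groups) {
    sub <- x[, g, drop = FALSE]
    num <- num + rowSums((sub - rowMeans(sub))^2)
  }
  num / sum(sizes - 1)
}

#' Sum of squared differences to a reference matrix
#'
#' Per-gene squared distance between a (standardized) expression summary and
#' a (standardized) reference measurement of the same genes and samples,
#' e.g. sequencing-based counts on the log2 scale. For per-gene standardized
#' vectors this is algebraically \code{2 (n-1) (1 - r)} with r the sample
#' correlation, so ranking by SSD is ranking by correlation.
#'
#' @param x,reference Numeric matrices (genes x samples) with identical
#'   dimnames (order included).
#' @return Named numeric vector of per-gene SSD.
#' @export
ssd_to_reference <- function(x, reference) {
  x <- as.matrix(x)
  reference <- as.matrix(reference)
  if (!identical(dim(x), dim(reference))) {
    stop("summary and reference dimensions differ")
  }
  if (!identical(rownames(x), rownames(reference)) ||
      !identical(colnames(x), colnames(reference))) {
    stop("summary and reference genes/samples do not match")
  }
  rowSums((x - reference)^2)
}

.check_groups <- function(x, group1, group2) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  missing <- setdiff(c(group1, group2), colnames(x))
  if (length(missing)) {
    stop("group sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
}

#' Per-gene log2 fold change between two sample groups
#'
#' Difference of group means of log2 values: mean(group1) - mean(group2).
#'
#' @param x Numeric matrix (genes x samples) of log2 values with sample IDs
#'   as column names.
#' @param group1,group2 Disjoint character vectors of sample IDs.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(x, group1, group2) {
  x <- as.matrix(x)
  .check_groups(x, group1, group2)
  rowMeans(x[, group1, drop = FALSE]) - rowMeans(x[, group2, drop = FALSE])
}

#' Per-gene Welch two-sample t statistic
#'
#' A ranking statistic for differential expression between two groups
#' (unequal variances). Genes where both group variances are zero get 0 when
#' the means agree and a signed infinity otherwise, reported as such.
#'
#' @inheritParams log2_fold_change
#' @return Named numeric vector of t statistics (group1 minus group2).
#' @export
group_t_statistic <- function(x, group1, group2) {
  x <- as.matrix(x)
  .check_groups(x, group1, group2)
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 samples")
  }
  a <- x[, group1, drop = FALSE]
  b <- x[, group2, drop = FALSE]
  n1 <- ncol(a)
  n2 <- ncol(b)
  d <- rowMeans(a) - rowMeans(b)
  v1 <- rowSums((a - rowMeans(a))^2) / (n1 - 1)
  v2 <- rowSums((b - rowMeans(b))^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- d / se
  t[se == 0 & d == 0] <- 0
  t[se == 0 & d != 0] <- sign(d[se == 0 & d != 0]) * Inf
  t
}

#' ROC curve and AUC against supplied truth labels
#'
#' Builds the ROC over all thresholds of the absolute ranking statistic
#' (two-sided: large magnitude in either direction calls a gene
#' differentially expressed), for genes labelled \code{"positive"} or
#' \code{"negative"}; genes labelled \code{"excluded"} are ignored. The
#' curve and trapezoidal AUC come from \pkg{pROC}.
#'
#' @param statistic Named numeric vector of per-gene ranking scores.
#' @param truth Character vector (same genes/order) with values in
#'   \code{c("positive", "negative", "excluded")}.
#' @return Object of class \code{"roc_result"}: \code{points} (data frame
#'   fpr, tpr), \code{auc}, \code{n_positive}, \code{n_negative}.
#' @export
roc_curve <- function(statistic, truth) {
  if (length(statistic) != length(truth)) {
    stop("statistic and truth differ in length")
  }
  bad <- setdiff(unique(truth), c("positive", "negative", "excluded"))
  if (length(bad)) stop("unknown truth label(s): ", paste(bad, collapse = ", "))
  keep <- truth != "excluded"
  s <- abs(statistic[keep])
  lab <- truth[keep]
  if (!any(lab == "positive") || !any(lab == "negative")) {
    stop("need at least one positive and one negative gene")
  }
  # infinities (zero-variance sentinels) still rank; map to finite extremes
  finite_max <- suppressWarnings(max(s[is.finite(s)], 0))
  s[is.infinite(s)] <- finite_max + 1
  r <- pROC::roc(response = lab, predictor = s,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  structure(
    list(points = pts, auc = as.numeric(r$auc),
         n_positive = sum(lab == "positive"),
         n_negative = sum(lab == "negative")),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC:", x$n_positive, "positives,", x$n_negative,
      "negatives, AUC =", round(x$auc, 4), "\n")
  invisible(x)
}

#' Log2-transform counts with a pseudo-count
#'
#' @param counts Non-negative numeric matrix or vector.
#' @param pseudocount Added before the log to keep zeros finite.
#' @return log2(counts + pseudocount).
#' @export
log2_counts <- function(counts, pseudocount = 1) {
  if (any(counts < 0)) stop("counts must be non-negative")
  log2(counts + pseudocount)
}

#' Median-center each sample (column)
#'
#' A simple between-sample normalization for log-scale reference matrices:
#' subtracts each column's median.
#'
#' @param x Numeric matrix (genes x samples).
#' @return Matrix with per-column medians 0.
#' @export
median_center_samples <- function(x) {
  x <- as.matrix(x)
  sweep(x, 2, apply(x, 2, stats::median))
}
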