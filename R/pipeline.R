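# Genome-wide application of the single-factor model: gene-level mode
# (one row per platform) and probe-level mode (one row per probe, pooled
# across platforms), with QC flagging.

#' QC thresholds for unified expression
#'
#' Thresholds used by [qc_classify()] to flag genes whose factor-model fit
#' is unlikely to be trustworthy: weak or negative loadings, expression near
#' background, or a small dynamic range across samples (all on the log2
#' scale of the raw summaries).
#'
#' @param min_median_expression Minimum per-platform median log2 expression
#'   considered above background. A single number, or a named vector with
#'   one entry per platform (sparser two-color platforms are often centered
#'   near 0 and warrant a lower cutoff).
#' @param min_iqr Minimum per-platform inter-quartile range (log2 units)
#'   considered a usable dynamic range.
#' @param low_loading_cutoff Loadings below this flag the gene.
#' @param high_loading_cutoff Reference level for a clearly good loading
#'   (used in reporting, not flagging).
#' @return A list of class \code{"gene_qc_thresholds"}.
#' @export
gene_qc_thresholds <- function(min_median_expression = 4.0,
                               min_iqr = 0.5,
                               low_loading_cutoff = 0.3,
                               high_loading_cutoff = 0.8) {
  stopifnot(
    all(is.finite(min_median_expression)), is.finite(min_iqr),
    is.finite(low_loading_cutoff), is.finite(high_loading_cutoff)
  )
  structure(
    list(
      min_median_expression = min_median_expression,
      min_iqr = min_iqr,
      low_loading_cutoff = low_loading_cutoff,
      high_loading_cutoff = high_loading_cutoff
    ),
    class = "gene_qc_thresholds"
  )
}

.median_cutoff <- function(thresholds, platform) {
  mm <- thresholds$min_median_expression
  if (!is.null(names(mm)) && platform %in% names(mm)) mm[[platform]]
  else mm[[1]]
}

#' Classify QC flags for one fitted gene
#'
#' Deterministic flags recomputable from the loadings and the raw
#' (unstandardized) per-platform summaries alone:
#' \describe{
#'   \item{negative_loading}{any loading below 0}
#'   \item{low_loading}{any loading below \code{low_loading_cutoff}}
#'   \item{low_expression}{any platform median below its background cutoff}
#'   \item{low_iqr}{any platform IQR below \code{min_iqr}}
#' }
#'
#' @param loadings Numeric vector of fitted loadings, one per platform row.
#' @param raw Numeric matrix of raw log2 summaries, rows matching
#'   \code{loadings}.
#' @param platforms Character vector naming the platform of each row.
#' @param thresholds A [gene_qc_thresholds()] object.
#' @return Character vector (possibly empty) of flags.
#' @export
qc_classify <- function(loadings, raw, platforms = rownames(raw),
                        thresholds = gene_qc_thresholds()) {
  raw <- as.matrix(raw)
  if (is.null(platforms)) platforms <- paste0("platform", seq_len(nrow(raw)))
  flags <- character(0)
  if (any(loadings < 0)) flags <- c(flags, "negative_loading")
  if (any(loadings < thresholds$low_loading_cutoff)) {
    flags <- c(flags, "low_loading")
  }
  med <- apply(raw, 1, stats::median)
  cuts <- vapply(platforms, function(pl) .median_cutoff(thresholds, pl),
                 numeric(1))
  if (any(med < cuts)) flags <- c(flags, "low_expression")
  iqr <- apply(raw, 1, stats::IQR)
  if (any(iqr < thresholds$min_iqr)) flags <- c(flags, "low_iqr")
  flags
}

.align_samples <- function(platform_list) {
  ids <- lapply(platform_list, colnames)
  if (any(vapply(ids, is.null, logical(1)))) {
    stop("every platform matrix needs sample IDs as column names")
  }
  ref <- ids[[1]]
  for (k in seq_along(ids)[-1]) {
    extra <- setdiff(ids[[k]], ref)
    missing <- setdiff(ref, ids[[k]])
    if (length(extra) || length(missing)) {
      stop(
        "sample IDs differ between platforms '", names(platform_list)[1],
        "' and '", names(platform_list)[k], "': missing [",
        paste(missing, collapse = ", "), "], extra [",
        paste(extra, collapse = ", "), "]"
      )
    }
  }
  lapply(platform_list, function(m) m[, ref, drop = FALSE])
}

.new_ue_set <- function(records, skipped, samples, mode, platforms) {
  if (length(records)) {
    genes <- vapply(records, function(r) r$gene_id, character(1))
    scores <- do.call(rbind, lapply(records, function(r) r$scores))
    rownames(scores) <- genes
    colnames(scores) <- samples
  } else {
    genes <- character(0)
    scores <- matrix(numeric(0), 0, length(samples),
                     dimnames = list(NULL, samples))
  }
  structure(
    list(
      gene_ids = genes,
      scores = scores,
      genes = stats::setNames(records, genes),
      skipped = skipped,
      mode = mode,
      platforms = platforms,
      samples = samples
    ),
    class = "ue_set"
  )
}

.skip_df <- function() {
  data.frame(gene_id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Unified expression from per-platform gene summaries
#'
#' Fits the single-factor model gene by gene across platform gene-level
#' summaries (p = number of platforms carrying the gene) and returns Thomson
#' factor scores as the unified expression measure, with per-gene QC. A gene
#' must be measured on at least three platforms; genes failing any
#' precondition are listed in the skipped-genes report with a reason rather
#' than dropped silently.
#'
#' @param platform_list Named list of numeric matrices (genes x samples,
#'   log2 scale), one per platform; column names are sample IDs and must
#'   agree across platforms (order may differ; alignment is by ID).
#' @param thresholds A [gene_qc_thresholds()] object.
#' @param min_platforms Minimum number of platforms a gene must appear on.
#' @param tol,max_iter,psi_floor Passed to [fit_em()].
#' @return An object of class \code{"ue_set"}: \code{scores} (gene x sample
#'   matrix of unified values), \code{genes} (per-gene records with
#'   \code{loadings}, \code{uniquenesses}, \code{weights}, \code{heywood},
#'   \code{converged}, \code{qc_flags}, \code{platforms}), and
#'   \code{skipped} (data frame of gene_id, reason).
#' @export
unify_gene_level <- function(platform_list, thresholds = gene_qc_thresholds(),
                             min_platforms = 3L, tol = 1e-10,
                             max_iter = 2000L, psi_floor = 1e-3) {
  stopifnot(is.list(platform_list), length(platform_list) >= min_platforms)
  if (is.null(names(platform_list))) {
    names(platform_list) <- paste0("platform", seq_along(platform_list))
  }
  platform_list <- .align_samples(platform_list)
  samples <- colnames(platform_list[[1]])
  n <- length(samples)
  all_genes <- unique(unlist(lapply(platform_list, rownames)))
  skipped <- .skip_df()
  records <- list()
  for (g in all_genes) {
    on_platform <- vapply(platform_list, function(m) g %in% rownames(m),
                          logical(1))
    if (sum(on_platform) < min_platforms) {
      skipped <- rbind(skipped, data.frame(
        gene_id = g,
        reason = sprintf("present on %d platform(s), need >= %d",
                         sum(on_platform), min_platforms)
      ))
      next
    }
    pls <- names(platform_list)[on_platform]
    raw <- do.call(rbind, lapply(platform_list[on_platform],
                                 function(m) m[g, ]))
    rownames(raw) <- pls
    if (ncol(raw) <= nrow(raw)) {
      skipped <- rbind(skipped, data.frame(gene_id = g,
                                           reason = "underdetermined"))
      next
    }
    rec <- tryCatch(
      .fit_one_gene(g, raw, pls, thresholds, tol, max_iter, psi_floor),
      error = function(e) conditionMessage(e)
    )
    if (is.character(rec)) {
      skipped <- rbind(skipped, data.frame(gene_id = g, reason = rec))
      next
    }
    records[[length(records) + 1L]] <- rec
  }
  .new_ue_set(records, skipped, samples, "gene", names(platform_list))
}

.fit_one_gene <- function(gene_id, raw, platforms, thresholds,
                          tol, max_iter, psi_floor) {
  std <- standardize(raw, platform_of = platforms)
  model <- fit_em(std, tol = tol, max_iter = max_iter, psi_floor = psi_floor)
  sc <- thomson_scores(model, std)
  list(
    gene_id = gene_id,
    scores = sc$scores,
    weights = sc$weights,
    loadings = stats::setNames(model$loadings, rownames(raw)),
    uniquenesses = stats::setNames(model$uniquenesses, rownames(raw)),
    platforms = platforms,
    heywood = any(model$heywood),
    converged = model$converged,
    n_iter = model$n_iter,
    qc_flags = qc_classify(model$loadings, raw, platforms, thresholds)
  )
}

#' Unified expression from pooled probe-level data
#'
#' Applies the single-factor model per gene directly to all probe rows for
#' that gene, pooled across platforms (p = total probes). Requires at least
#' \code{min_probes_total} probes and more samples than probes; genes
#' violating either are skipped with a reason (\code{"underdetermined"} when
#' p >= n). Per-platform median loadings summarize how each platform's
#' probes behave; non-converged fits are flagged, not dropped.
#'
#' QC medians/IQRs are computed on the per-platform mean probe profile of
#' the raw probe intensities.
#'
#' @param probes Numeric matrix of probe intensities (probes x samples,
#'   log2 scale), row names are probe IDs.
#' @param annotation Probe annotation data frame with columns
#'   \code{probe_id}, \code{gene_id}, \code{platform} (see
#'   [read_probe_annotation()]).
#' @param thresholds A [gene_qc_thresholds()] object.
#' @param min_probes_total Minimum pooled probe count per gene.
#' @param tol,max_iter,psi_floor Passed to [fit_em()].
#' @return A \code{"ue_set"} (see [unify_gene_level()]); per-gene records
#'   additionally carry \code{per_platform_median_loading}.
#' @export
unify_probe_level <- function(probes, annotation,
                              thresholds = gene_qc_thresholds(),
                              min_probes_total = 2L, tol = 1e-10,
                              max_iter = 2000L, psi_floor = 1e-3) {
  probes <- as.matrix(probes)
  if (is.null(rownames(probes))) stop("probe matrix needs probe IDs as row names")
  if (is.null(colnames(probes))) stop("probe matrix needs sample IDs as column names")
  ann <- .check_annotation(annotation)
  unknown <- setdiff(ann$probe_id, rownames(probes))
  if (length(unknown)) {
    stop("annotation lists probes absent from the matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  samples <- colnames(probes)
  n <- length(samples)
  skipped <- .skip_df()
  records <- list()
  for (g in unique(ann$gene_id)) {
    sub <- ann[ann$gene_id == g, , drop = FALSE]
    p <- nrow(sub)
    if (p < min_probes_total) {
      skipped <- rbind(skipped, data.frame(
        gene_id = g, reason = sprintf("%d probe(s), need >= %d",
                                      p, min_probes_total)))
      next
    }
    if (p >= n) {
      skipped <- rbind(skipped, data.frame(gene_id = g,
                                           reason = "underdetermined"))
      next
    }
    raw <- probes[sub$probe_id, , drop = FALSE]
    rec <- tryCatch({
      std <- standardize(raw, platform_of = sub$platform)
      model <- fit_em(std, tol = tol, max_iter = max_iter,
                      psi_floor = psi_floor)
      sc <- thomson_scores(model, std)
      med_lam <- tapply(model$loadings, sub$platform, stats::median)
      # platform QC on the per-platform mean probe profile
      prof <- do.call(rbind, lapply(split(seq_len(p), sub$platform),
                                    function(i) colMeans(raw[i, , drop = FALSE])))
      list(
        gene_id = g,
        scores = sc$scores,
        weights = sc$weights,
        loadings = stats::setNames(model$loadings, sub$probe_id),
        uniquenesses = stats::setNames(model$uniquenesses, sub$probe_id),
        platforms = sub$platform,
        per_platform_median_loading = med_lam,
        heywood = any(model$heywood),
        converged = model$converged,
        n_iter = model$n_iter,
        qc_flags = qc_classify(as.vector(med_lam), prof, rownames(prof),
                               thresholds)
      )
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      skipped <- rbind(skipped, data.frame(gene_id = g, reason = rec))
      next
    }
    records[[length(records) + 1L]] <- rec
  }
  .new_ue_set(records, skipped, samples, "probe",
              sort(unique(ann$platform)))
}

.check_annotation <- function(annotation) {
  need <- c("probe_id", "gene_id", "platform")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  ann <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (anyDuplicated(ann$probe_id)) {
    stop("duplicate probe_id in annotation: ",
         ann$probe_id[duplicated(ann$probe_id)][1])
  }
  ann
}

#' Check per-platform probe counts against platform minimums
#'
#' Array designs typically require a minimum number of probes per gene to
#' form a usable probe set (e.g., five for dense Affymetrix-style platforms,
#' three for a sparser two-color platform). Returns the genes violating the
#' configured minimum on any platform where they have probes.
#'
#' @param annotation Probe annotation data frame.
#' @param min_probes Named integer vector of per-platform minimums, or a
#'   single number applied to all platforms.
#' @return Data frame (gene_id, platform, n_probes, required); zero rows if
#'   all constraints hold.
#' @export
check_probe_annotation <- function(annotation, min_probes = 3L) {
  ann <- .check_annotation(annotation)
  counts <- as.data.frame(table(gene_id = ann$gene_id,
                                platform = ann$platform),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  req <- vapply(counts$platform, function(pl) {
    if (!is.null(names(min_probes)) && pl %in% names(min_probes)) {
      as.integer(min_probes[[pl]])
    } else as.integer(min_probes[[1]])
  }, integer(1))
  bad <- counts$Freq < req
  data.frame(gene_id = counts$gene_id[bad], platform = counts$platform[bad],
             n_probes = counts$Freq[bad], required = req[bad],
             stringsAsFactors = FALSE)
}

#' Correlation between gene-level and probe-level unified expression
#'
#' Pearson correlation of the two score vectors for the same gene and
#' samples, after resolving the sign non-identifiability (the sign of each
#' score vector is arbitrary, so the vectors are sign-aligned first).
#'
#' @param gene_scores,probe_scores Numeric score vectors of equal length
#'   (same samples, same order).
#' @return Scalar correlation in [0, 1], or \code{NA} with a warning if
#'   either vector is constant (correlation undefined).
#' @export
compare_gene_vs_probe <- function(gene_scores, probe_scores) {
  x <- as.numeric(gene_scores)
  y <- as.numeric(probe_scores)
  if (length(x) != length(y)) stop("score vectors differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant score vector: correlation undefined")
    return(NA_real_)
  }
  r <- stats::cor(x, y)
  if (r < 0) r <- -r  # sign alignment
  r
}

#' Assemble the per-gene QC table of a unified-expression set
#'
#' @param ue A \code{"ue_set"}.
#' @return Data frame with one row per fitted gene: loadings and
#'   uniquenesses (comma-separated, named), Heywood and convergence flags,
#'   and QC flags.
#' @export
ue_qc_table <- function(ue) {
  stopifnot(inherits(ue, "ue_set"))
  do.call(rbind, lapply(ue$genes, function(r) {
    data.frame(
      gene_id = r$gene_id,
      loadings = paste(sprintf("%s=%.6g", names(r$loadings), r$loadings),
                       collapse = ","),
      uniquenesses = paste(sprintf("%.6g", r$uniquenesses), collapse = ","),
      heywood = r$heywood,
      converged = r$converged,
      n_iter = r$n_iter,
      qc_flags = paste(r$qc_flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.ue_set <- function(x, ...) {
  cat("Unified expression (", x$mode, "-level): ", length(x$gene_ids),
      " gene(s), ", length(x$samples), " sample(s), ",
      nrow(x$skipped), " skipped\n", sep = "")
  invisible(x)
}
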