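# Deterministic synthetic data sets exercising every pipeline path: written
# as the same TSV formats the pipeline reads, so they double as integration
# fixtures and as worked-example inputs.

.rmvn_chol <- function(R, n) {
  t(chol(R)) %*% matrix(stats::rnorm(nrow(R) * n), nrow(R))
}

#' Generate a synthetic multi-platform fixture data set on disk
#'
#' Simulates three platforms measuring a shared latent expression level per
#' gene under the one-factor model, on a realistic raw log2 scale, and
#' writes a complete fixture tree:
#' \itemize{
#'   \item \code{u133.tsv}, \code{exon.tsv}, \code{agilent.tsv}: gene-level
#'     summaries (genes x samples). Gene classes: concordant (all loadings
#'     ~0.85-0.95), discordant (one platform ~0.1), null (independent
#'     noise), heywood-prone (a population correlation structure whose triad
#'     solution exceeds 1), low-expression/low-IQR, and genes present on
#'     only two platforms.
#'   \item \code{probes.tsv} + \code{probe_annotation.tsv}: probe-level data
#'     with per-platform probe counts 11 (u133), 55 (exon) and 3 probes x 2
#'     replicate spots (agilent) for the concordant gene — the dense-exon
#'     shape seen on real arrays — plus a majority-discordant gene and a
#'     single-probe gene.
#'   \item \code{reference.tsv}: a noisy sequencing-style reference tracking
#'     the true latent values (log2 scale, median-centered).
#'   \item \code{replicate_design.tsv}: nine replicate sets of sizes
#'     (2, 2, 4, 2, 3, 2, 2, 2, 2); replicate columns share their specimen's
#'     latent value and differ by measurement noise.
#'   \item \code{group_design.tsv}: a two-group contrast of sizes 7 and 24.
#'   \item \code{gene_classes.tsv}: the generating class and loadings of
#'     every gene (the truth for tests).
#'   \item \code{truth.tsv}: the latent gene x sample matrix.
#' }
#'
#' The same seed reproduces every file byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_samples Number of sample columns.
#' @return Named list of file paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1L, n_samples = 200L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(n_samples >= 40L)
  .with_seed(seed, .generate_fixtures_impl(dir, n_samples))
}

.generate_fixtures_impl <- function(dir, n) {
  samples <- sprintf("sample%03d", seq_len(n))

  # nine replicate sets occupy the first 21 columns; replicates of one
  # specimen share the latent value
  rep_sizes <- c(2L, 2L, 4L, 2L, 3L, 2L, 2L, 2L, 2L)
  rep_groups <- split(samples[seq_len(sum(rep_sizes))],
                      rep(sprintf("rep%02d", seq_along(rep_sizes)),
                          rep_sizes))
  specimen <- c(rep(seq_along(rep_sizes), rep_sizes),
                seq(length(rep_sizes) + 1L,
                    length.out = n - sum(rep_sizes)))
  n_spec <- max(specimen)

  classes <- data.frame(
    gene_id = character(0), class = character(0),
    lambda1 = numeric(0), lambda2 = numeric(0), lambda3 = numeric(0),
    stringsAsFactors = FALSE
  )
  platforms <- c("u133", "exon", "agilent")
  mats <- stats::setNames(rep(list(NULL), 3), platforms)
  truth <- NULL

  add_gene <- function(id, class, lambda, mu = c(8, 7, 0), scale = 1.2,
                       on = c(TRUE, TRUE, TRUE), y = NULL) {
    f_spec <- stats::rnorm(n_spec)
    f <- f_spec[specimen]
    if (is.null(y)) {
      e <- matrix(stats::rnorm(3 * n), 3) * sqrt(pmax(1 - lambda^2, 0))
      y <- lambda %o% f + e
    }
    y <- mu + scale * y
    for (k in which(on)) {
      row <- matrix(y[k, ], 1, dimnames = list(id, samples))
      mats[[k]] <<- rbind(mats[[k]], row)
    }
    truth <<- rbind(truth, matrix(f, 1, dimnames = list(id, samples)))
    classes <<- rbind(classes, data.frame(
      gene_id = id, class = class, lambda1 = lambda[1],
      lambda2 = lambda[2], lambda3 = lambda[3], stringsAsFactors = FALSE))
  }

  for (i in 1:15) {
    add_gene(sprintf("conc%02d", i), "concordant",
             stats::runif(3, 0.85, 0.95))
  }
  for (i in 1:10) {
    lam <- c(stats::runif(2, 0.85, 0.95), stats::runif(1, 0.0, 0.15))
    add_gene(sprintf("disc%02d", i), "discordant", lam)
  }
  for (i in 1:5) {
    add_gene(sprintf("null%02d", i), "null", rep(0, 3))
  }
  # population correlations (0.9, 0.9, 0.7): positive definite but the
  # triad solution for platform 1 exceeds 1
  R_hey <- matrix(c(1, .9, .9, .9, 1, .7, .9, .7, 1), 3)
  for (i in 1:5) {
    add_gene(sprintf("heyw%02d", i), "heywood_prone", c(NA, NA, NA),
             y = .rmvn_chol(R_hey, n))
  }
  for (i in 1:3) {
    add_gene(sprintf("lowx%02d", i), "low_expression",
             stats::runif(3, 0.6, 0.8), mu = c(2, 2, -4), scale = 0.3)
  }
  for (i in 1:2) {
    add_gene(sprintf("twop%02d", i), "two_platforms",
             c(stats::runif(2, 0.85, 0.95), 0), on = c(TRUE, TRUE, FALSE))
  }

  # sequencing-style reference: tracks truth with moderate noise, log2-ish
  reference <- 6 + 1.5 * truth +
    matrix(stats::rnorm(length(truth), sd = 0.6), nrow(truth))
  dimnames(reference) <- dimnames(truth)
  reference <- median_center_samples(reference)

  # probe-level set
  probe_rows <- NULL
  ann <- NULL
  add_probes <- function(gene, platform, k, lambda_range, f, copies = 1L) {
    for (j in seq_len(k)) {
      lam <- stats::runif(1, lambda_range[1], lambda_range[2])
      for (cp in seq_len(copies)) {
        id <- sprintf("%s_%s_p%02d%s", gene, platform, j,
                      if (copies > 1L) paste0("_c", cp) else "")
        e <- stats::rnorm(n) * sqrt(max(1 - lam^2, 0.01))
        row <- matrix(7 + 1.1 * (lam * f + e), 1,
                      dimnames = list(id, samples))
        probe_rows <<- rbind(probe_rows, row)
        ann <<- rbind(ann, data.frame(
          probe_id = id, gene_id = gene, platform = platform,
          copies = copies, stringsAsFactors = FALSE))
      }
    }
  }
  fP1 <- stats::rnorm(n)
  add_probes("geneP1", "u133", 11L, c(0.80, 0.95), fP1)
  add_probes("geneP1", "exon", 55L, c(0.70, 0.95), fP1)
  add_probes("geneP1", "agilent", 3L, c(0.80, 0.95), fP1, copies = 2L)
  # majority-discordant gene: 40 exon probes track their own latent
  fP2a <- stats::rnorm(n)
  fP2b <- stats::rnorm(n)
  add_probes("geneP2", "u133", 8L, c(0.80, 0.95), fP2a)
  add_probes("geneP2", "agilent", 2L, c(0.80, 0.95), fP2a)
  add_probes("geneP2", "exon", 40L, c(0.80, 0.95), fP2b)
  add_probes("geneP3", "u133", 1L, c(0.80, 0.95), stats::rnorm(n))

  # two-group contrast of sizes 7 and 24 drawn from the non-replicate tail
  pool <- samples[(sum(rep_sizes) + 1L):n]
  grp <- data.frame(
    group_id = rep(c("group1", "group2"), c(7L, 24L)),
    sample_id = pool[seq_len(31L)], stringsAsFactors = FALSE)

  paths <- list(
    u133 = file.path(dir, "u133.tsv"),
    exon = file.path(dir, "exon.tsv"),
    agilent = file.path(dir, "agilent.tsv"),
    probes = file.path(dir, "probes.tsv"),
    probe_annotation = file.path(dir, "probe_annotation.tsv"),
    reference = file.path(dir, "reference.tsv"),
    replicate_design = file.path(dir, "replicate_design.tsv"),
    group_design = file.path(dir, "group_design.tsv"),
    gene_classes = file.path(dir, "gene_classes.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  for (k in platforms) write_expression_tsv(mats[[k]], paths[[k]], digits = 6)
  write_expression_tsv(probe_rows, paths$probes, digits = 6)
  utils::write.table(ann, paths$probe_annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression_tsv(reference, paths$reference, digits = 6)
  utils::write.table(
    data.frame(group_id = rep(names(rep_groups), lengths(rep_groups)),
               sample_id = unlist(rep_groups), stringsAsFactors = FALSE),
    paths$replicate_design, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(grp, paths$group_design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(classes, paths$gene_classes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_expression_tsv(truth, paths$truth, digits = 6)
  invisible(paths)
}
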