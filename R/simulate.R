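# Simulation study: generate three-platform data from the one-factor model
# and compare the factor-analysis estimate of the latent expression level
# against the simple three-platform average.

#' Simulation configuration
#'
#' One configuration of the simulation study: for each simulated gene, the
#' three loadings are drawn independently and uniformly from their ranges,
#' the latent expression levels f are standard normal across samples, and
#' each platform observes y_j = lambda_j f + e_j with
#' e_j ~ N(0, 1 - lambda_j^2), so every platform has unit theoretical
#' variance.
#'
#' @param lambda_ranges 3x2 numeric matrix (or list of three (min, max)
#'   pairs): the uniform range for each platform's loading. Each range must
#'   satisfy 0 <= min <= max <= 0.98.
#' @param n_samples Samples per simulated gene (>= 4).
#' @param n_genes Genes (independent data sets) per configuration.
#' @param seed Master seed for the configuration.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(lambda_ranges, n_samples = 200L, n_genes = 200L,
                       seed = 1L) {
  if (is.list(lambda_ranges)) {
    lambda_ranges <- do.call(rbind, lambda_ranges)
  }
  lambda_ranges <- matrix(as.numeric(lambda_ranges), ncol = 2)
  if (nrow(lambda_ranges) != 3L) stop("three loading ranges are required")
  if (any(lambda_ranges < 0) || any(lambda_ranges > 0.98) ||
      any(lambda_ranges[, 1] > lambda_ranges[, 2])) {
    stop("loading ranges must satisfy 0 <= min <= max <= 0.98")
  }
  if (n_samples < 4L) stop("n_samples must be at least 4")
  structure(
    list(lambda_ranges = lambda_ranges, n_samples = as.integer(n_samples),
         n_genes = as.integer(n_genes), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' The twelve standard loading configurations
#'
#' The configurations span situations seen in real multi-platform data:
#' two strong platforms with one weak (rows 1-7, 12), all platforms strong
#' (rows 8-9), and all platforms weak (rows 10-11).
#'
#' @param n_samples,n_genes,seed Applied to every configuration; per-config
#'   seeds are offset so configurations are independent.
#' @return Named list of twelve [sim_config()] objects
#'   (\code{config1} ... \code{config12}).
#' @export
standard_sim_configs <- function(n_samples = 200L, n_genes = 200L,
                                 seed = 1L) {
  rows <- list(
    c(0.90, 0.98, 0.90, 0.98, 0.00, 0.30),
    c(0.80, 0.90, 0.80, 0.90, 0.00, 0.30),
    c(0.70, 0.80, 0.70, 0.80, 0.00, 0.30),
    c(0.60, 0.70, 0.60, 0.70, 0.00, 0.30),
    c(0.80, 0.98, 0.80, 0.98, 0.30, 0.50),
    c(0.70, 0.80, 0.70, 0.80, 0.30, 0.50),
    c(0.60, 0.70, 0.60, 0.70, 0.30, 0.50),
    c(0.70, 0.98, 0.70, 0.98, 0.70, 0.98),
    c(0.50, 0.70, 0.50, 0.70, 0.50, 0.70),
    c(0.30, 0.50, 0.30, 0.50, 0.30, 0.50),
    c(0.00, 0.30, 0.00, 0.30, 0.00, 0.30),
    c(0.80, 0.98, 0.50, 0.70, 0.00, 0.30)
  )
  out <- lapply(seq_along(rows), function(i) {
    sim_config(matrix(rows[[i]], ncol = 2, byrow = TRUE),
               n_samples = n_samples, n_genes = n_genes,
               seed = (seed + 1000L * i) %% .Machine$integer.max)
  })
  names(out) <- paste0("config", seq_along(rows))
  out
}

#' Simulate one gene from the one-factor model
#'
#' @param config A [sim_config()].
#' @param gene_seed Integer seed for this gene's draws.
#' @param lambda Optional fixed loadings (length 3, each in [0, 1])
#'   overriding the configured uniform draw; \code{lambda = c(1, 1, 1)} is
#'   the noise-free limit where every platform observes the truth exactly.
#' @return List with \code{observations} (3 x n matrix, rows
#'   \code{platform1..3}), \code{truth} (the n latent values) and
#'   \code{lambda} (the loadings used).
#' @export
simulate_gene <- function(config, gene_seed = config$seed, lambda = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(lambda)) {
    stopifnot(length(lambda) == 3L, all(lambda >= 0), all(lambda <= 1))
  }
  n <- config$n_samples
  rg <- config$lambda_ranges
  .with_seed(gene_seed, {
    if (is.null(lambda)) lambda <- stats::runif(3, rg[, 1], rg[, 2])
    f <- stats::rnorm(n)
    e <- matrix(stats::rnorm(3 * n), 3) * sqrt(1 - lambda^2)
    y <- lambda %o% f + e
    rownames(y) <- paste0("platform", 1:3)
    colnames(y) <- paste0("sample", seq_len(n))
    list(observations = y, truth = f, lambda = lambda)
  })
}

.unit_scale <- function(x) (x - mean(x)) / stats::sd(x)

.align_to <- function(x, truth) if (sum(x * truth) < 0) -x else x

#' Run one simulation configuration
#'
#' For each simulated gene: fit the gene-level factor model, compute Thomson
#' scores, and compute the simple mean of the three standardized platform
#' rows. Both estimators are standardized to unit variance and sign-aligned
#' to the truth, and their sum of squared errors (SSE) against the latent
#' values is recorded.
#'
#' @param config A [sim_config()].
#' @return Object of class \code{"sim_result"}: \code{per_gene} data frame
#'   (drawn and estimated loadings, \code{sse_fa}, \code{sse_avg},
#'   \code{converged}, \code{heywood}) and the \code{config}.
#' @export
run_configuration <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_seeds <- .with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L,
                                      config$n_genes))
  rows <- lapply(seq_len(config$n_genes), function(g) {
    sim <- simulate_gene(config, gene_seeds[g])
    std <- standardize(sim$observations)
    model <- fit_em(std)
    sc <- thomson_scores(model, std)
    fa_est <- .align_to(.unit_scale(sc$scores), sim$truth)
    avg_est <- .align_to(.unit_scale(colMeans(std$values)), sim$truth)
    data.frame(
      gene = g,
      lambda1 = sim$lambda[1], lambda2 = sim$lambda[2],
      lambda3 = sim$lambda[3],
      lambda_hat1 = model$loadings[1], lambda_hat2 = model$loadings[2],
      lambda_hat3 = model$loadings[3],
      sse_fa = sum((fa_est - sim$truth)^2),
      sse_avg = sum((avg_est - sim$truth)^2),
      converged = model$converged,
      heywood = any(model$heywood)
    )
  })
  structure(list(per_gene = do.call(rbind, rows), config = config),
            class = "sim_result")
}

#' Summarize a simulation result
#'
#' @param object A \code{"sim_result"}.
#' @param ... Unused.
#' @return One-row data frame: median SSE of each estimator, the fraction
#'   of genes where the factor estimate beats the average, and convergence /
#'   Heywood counts.
#' @export
summary.sim_result <- function(object, ...) {
  pg <- object$per_gene
  data.frame(
    n_genes = nrow(pg),
    n_samples = object$config$n_samples,
    median_sse_fa = stats::median(pg$sse_fa),
    median_sse_avg = stats::median(pg$sse_avg),
    fa_win_rate = mean(pg$sse_fa < pg$sse_avg),
    n_nonconverged = sum(!pg$converged),
    n_heywood = sum(pg$heywood)
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation result:\n")
  print(summary(x), row.names = FALSE)
  invisible(x)
}
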