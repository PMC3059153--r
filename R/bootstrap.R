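# Bootstrap uncertainty for the loadings.

# run code with a temporary RNG state so package functions do not disturb
# the caller's stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Bootstrap standard errors for factor loadings
#'
#' Nonparametric bootstrap of the loading estimates: samples (columns) are
#' resampled with replacement — keeping the cross-platform pairing of each
#' sample intact — the resampled matrix is re-standardized and refitted, and
#' each replicate's loadings are sign-aligned to the point estimate by the
#' sign of their dot product before taking per-coordinate standard
#' deviations. Replicates whose refit fails (e.g., a zero-variance resampled
#' row) are counted and excluded.
#'
#' @param data A \code{standardized_set} or numeric matrix (features x
#'   samples).
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed for the resampling stream.
#' @param tol,max_iter,psi_floor Passed to [fit_em()].
#' @return An object of class \code{"bootstrap_result"}: \code{se}
#'   (per-coordinate SE of the loadings), \code{n_boot}, \code{n_failed},
#'   \code{seed}, \code{loadings} (the point estimate) and
#'   \code{replicates} (matrix of aligned replicate loadings).
#' @export
bootstrap_loading_se <- function(data, n_boot = 100L, seed = 1L,
                                 tol = 1e-10, max_iter = 2000L,
                                 psi_floor = 1e-3) {
  if (n_boot < 2L) stop("n_boot must be at least 2")
  Y <- .values(data)
  n <- ncol(Y)
  point <- fit_em(Y, tol = tol, max_iter = max_iter, psi_floor = psi_floor)
  lam0 <- point$loadings
  reps <- .with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch({
        std <- standardize(Y[, idx, drop = FALSE])
        m <- fit_em(std, tol = tol, max_iter = max_iter,
                    psi_floor = psi_floor)
        lam <- m$loadings
        if (sum(lam * lam0) < 0) lam <- -lam
        lam
      }, error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("all bootstrap replicates failed to refit")
  mat <- do.call(rbind, reps[ok])
  colnames(mat) <- point$feature_ids %||% rownames(Y)
  structure(
    list(
      se = apply(mat, 2, stats::sd),
      n_boot = n_boot,
      n_failed = sum(!ok),
      seed = seed,
      loadings = stats::setNames(lam0, colnames(mat)),
      replicates = mat
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap SE of loadings (", x$n_boot, " replicates, ",
      x$n_failed, " failed, seed ", x$seed, ")\n", sep = "")
  print(round(rbind(loading = x$loadings, se = x$se), 4))
  invisible(x)
}
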