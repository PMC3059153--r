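# Single-factor maximum-likelihood factor analysis for one gene.
#
# Model: y = lambda * f + e, with f ~ N(0, 1), e ~ N(0, Psi) independent,
# so Sigma = lambda lambda' + Psi.  The implied covariance is constrained to
# be a correlation matrix (unit diagonal), hence psi_j = 1 - lambda_j^2 and
# lambda_j is the correlation between measurement j and the latent factor.

#' Standardize the rows of an expression matrix
#'
#' Centers and scales every feature (row) to mean 0 and unit sample variance
#' across samples, the scale on which the single-factor model is fitted.
#' Rows with zero sample variance cannot be standardized and raise an error
#' naming the offending features.
#'
#' @param x Numeric matrix, features in rows, samples in columns. Row and
#'   column names are carried through. Missing values are not supported.
#' @param platform_of Optional character vector (length \code{nrow(x)})
#'   giving the platform of each feature; stored for downstream weighting
#'   summaries.
#' @return An object of class \code{"standardized_set"}: a list with
#'   \code{values} (the standardized matrix), \code{feature_ids} and
#'   \code{platform_of}.
#' @examples
#' standardize(rbind(a = c(1, 2, 3), b = c(0, 4, 2)))
#' @export
standardize <- function(x, platform_of = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (anyNA(x)) stop("missing values are not supported; found NA in input")
  n <- ncol(x)
  if (n < 2L) stop("at least two samples are required to standardize")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("feature", seq_len(nrow(x)))
  mu <- rowMeans(x)
  centered <- x - mu
  v <- rowSums(centered^2) / (n - 1)
  if (any(v == 0)) {
    stop("zero variance in feature(s): ", paste(ids[v == 0], collapse = ", "))
  }
  out <- centered / sqrt(v)
  rownames(out) <- ids
  structure(
    list(values = out, feature_ids = ids, platform_of = platform_of),
    class = "standardized_set"
  )
}

.values <- function(data) {
  if (inherits(data, "standardized_set")) data$values else as.matrix(data)
}

# Fit criterion: Gaussian log-likelihood of n observations whose
# second-moment matrix is the sample correlation matrix R,
#   -n/2 * (p log 2pi + log det Sigma + tr(Sigma^-1 R)),
# evaluated through the Woodbury forms so only Psi^-1 is needed.
.fit_criterion <- function(lambda, psi, R, n) {
  p <- length(lambda)
  w <- lambda / psi
  a <- 1 + sum(lambda * w)
  logdet <- log(a) + sum(log(psi))
  trSinvR <- sum(diag(R) / psi) - drop(crossprod(w, R %*% w)) / a
  -n / 2 * (p * log(2 * pi) + logdet + trSinvR)
}

#' Fit the single-factor model by maximum likelihood (EM)
#'
#' Estimates the loadings \eqn{\lambda} and uniquenesses \eqn{\psi} of the
#' one-factor model \eqn{\Sigma = \lambda\lambda' + \Psi} with unit-diagonal
#' constraint \eqn{\lambda_j^2 + \psi_j = 1}, from standardized data, via the
#' EM algorithm. The fit operates on the sample correlation matrix; the
#' stored \code{loglik} is the Gaussian likelihood under that convention and
#' is non-decreasing across iterations.
#'
#' Uniquenesses are floored at \code{psi_floor}; a coordinate whose
#' uniqueness ends at the floor is flagged as a Heywood case (an improper
#' boundary solution, \eqn{\lambda \to 1}) rather than treated as an error.
#' Non-convergence within \code{max_iter} is likewise reported via
#' \code{converged = FALSE}, with the last iterate returned, so that
#' large probe-level runs can proceed and report failures.
#'
#' @param data A \code{standardized_set} from [standardize()], or a numeric
#'   matrix already standardized by rows.
#' @param tol Convergence tolerance on the relative change of the fit
#'   criterion between EM iterations.
#' @param max_iter Maximum number of EM iterations.
#' @param psi_floor Lower bound for each uniqueness; also bounds loadings
#'   away from exactly 1.
#' @return An object of class \code{"factor_model"}: list with
#'   \code{loadings}, \code{uniquenesses}, \code{loglik} (fit criterion at
#'   the returned estimate), \code{loglik_trace}, \code{n_iter},
#'   \code{converged}, \code{heywood} (logical per coordinate), \code{p},
#'   \code{n}, \code{feature_ids}, \code{platform_of}, \code{psi_floor}.
#'   The sign convention of [fix_sign()] is applied before returning.
#' @seealso [thomson_scores()], [fa_loglik()], [fix_sign()]
#' @export
fit_em <- function(data, tol = 1e-10, max_iter = 2000L, psi_floor = 1e-3) {
  Y <- .values(data)
  p <- nrow(Y)
  n <- ncol(Y)
  if (p < 2L) stop("at least two features are required")
  if (n <= p) stop("more samples than features required (n > p); got n = ",
                   n, ", p = ", p)
  R <- tcrossprod(Y) / (n - 1)
  if (!all(is.finite(R))) stop("sample correlation matrix is not finite")

  # deterministic start from the first principal component of R, scaled to
  # the unit-diagonal parameterization and kept away from the boundary
  ev <- eigen(R, symmetric = TRUE)
  l0 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
  lambda <- sign(l0) * pmin(abs(l0), 0.9)
  lambda[lambda == 0] <- 1e-3
  psi <- pmax(1 - lambda^2, psi_floor)

  lam_cap <- sqrt(1 - psi_floor)
  ll <- .fit_criterion(lambda, psi, R, n)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- lambda / psi                      # Psi^{-1} lambda
    a <- 1 + sum(lambda * w)
    beta <- w / a                          # Sigma^{-1} lambda
    Rb <- drop(R %*% beta)
    gamma <- 1 - sum(lambda * beta) + sum(beta * Rb)  # E[f^2 | data]
    lambda <- Rb / gamma
    psi <- diag(R) - gamma * lambda^2
    # pin boundary coordinates (Heywood direction) to the floored solution;
    # leaving them free makes the iteration crawl along the boundary
    hit <- psi < psi_floor
    psi[hit] <- psi_floor
    lambda[hit] <- sign(lambda[hit]) * lam_cap
    ll_new <- .fit_criterion(lambda, psi, R, n)
    trace[iter + 1L] <- ll_new
    if (abs(ll_new - ll) / abs(ll) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }

  # quasi-Newton refinement of the same criterion from the EM iterate: EM's
  # linear rate is very slow on the flat ridges that arise with weak
  # loadings, and the refinement pins down the optimum there
  obj <- function(l) {
    ps <- pmax(1 - l^2, psi_floor)
    -2 / n * .fit_criterion(l, ps, R, n)
  }
  grad <- function(l) {
    ps <- pmax(1 - l^2, psi_floor)
    Sigma <- tcrossprod(l) + diag(ps, length(l))
    Sinv <- chol2inv(chol(Sigma))
    G <- Sinv - Sinv %*% R %*% Sinv   # d(logdet + tr(Sinv R)) / dSigma
    2 * (drop(G %*% l) - l * diag(G))
  }
  pol <- tryCatch(
    stats::optim(pmin(pmax(lambda, -lam_cap), lam_cap), obj, grad,
                 method = "L-BFGS-B", lower = -lam_cap, upper = lam_cap,
                 control = list(maxit = 500L, factr = 1, pgtol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) &&
      pol$value <= obj(pmin(pmax(lambda, -lam_cap), lam_cap))) {
    lambda <- pol$par
    psi <- pmax(1 - lambda^2, psi_floor)
  }

  # Newton root-polish of the score equations at interior optima: pins the
  # estimate to the stationary point to near machine precision, so the fit
  # depends only on R, not on the optimization path
  if (all(abs(lambda) < lam_cap - 1e-8)) {
    lam_new <- lambda
    for (it in 1:25) {
      g <- grad(lam_new)
      if (max(abs(g)) < 1e-13) break
      h <- 1e-6
      H <- vapply(seq_along(lam_new), function(j) {
        d <- numeric(length(lam_new)); d[j] <- h
        (grad(lam_new + d) - grad(lam_new - d)) / (2 * h)
      }, numeric(length(lam_new)))
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- lam_new - step
      if (any(abs(cand) >= lam_cap)) break
      lam_new <- cand
    }
    if (all(is.finite(lam_new)) && obj(lam_new) <= obj(lambda) + 1e-12) {
      lambda <- lam_new
      psi <- pmax(1 - lambda^2, psi_floor)
    }
  }

  # declare convergence from the first-order (KKT) conditions rather than
  # any optimizer's exit code: interior coordinates need a vanishing
  # gradient, boundary coordinates a gradient pushing outward
  if (!converged) {
    g <- tryCatch(grad(lambda), error = function(e) NULL)
    if (!is.null(g) && all(is.finite(g))) {
      at_hi <- lambda >= lam_cap - 1e-10
      at_lo <- lambda <= -lam_cap + 1e-10
      converged <- all(abs(g[!at_hi & !at_lo]) < 1e-5) &&
        all(g[at_hi] < 1e-5) && all(g[at_lo] > -1e-5)
    }
  }

  # project onto the unit-diagonal constraint (exact at an interior optimum,
  # a vanishing adjustment otherwise), then re-apply the floor
  d <- lambda^2 + psi
  lambda <- lambda / sqrt(d)
  psi <- psi / d
  heywood <- psi <= psi_floor * (1 + 1e-6)
  psi[heywood] <- psi_floor
  lambda[heywood] <- sign(lambda[heywood]) * lam_cap
  psi <- 1 - lambda^2

  model <- structure(
    list(
      loadings = as.vector(lambda),
      uniquenesses = as.vector(psi),
      loglik = .fit_criterion(lambda, psi, R, n),
      loglik_trace = trace[seq_len(iter + 1L)],
      n_iter = iter,
      converged = converged,
      heywood = as.vector(heywood),
      p = p,
      n = n,
      feature_ids = if (inherits(data, "standardized_set")) data$feature_ids
                    else rownames(Y),
      platform_of = if (inherits(data, "standardized_set")) data$platform_of
                    else NULL,
      psi_floor = psi_floor
    ),
    class = "factor_model"
  )
  fix_sign(model)
}

#' Resolve the sign non-identifiability of a fitted model
#'
#' The one-factor likelihood is invariant to flipping the sign of all
#' loadings at once. This fixes a deterministic convention: the sum of the
#' loadings is non-negative; if the sum is exactly zero, the first nonzero
#' loading is made positive. Thomson scores computed from the fixed model
#' flip consistently.
#'
#' @param model A \code{"factor_model"}.
#' @return The model, possibly with all loadings negated.
#' @export
fix_sign <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  s <- sum(model$loadings)
  flip <- if (s != 0) s < 0 else {
    nz <- model$loadings[model$loadings != 0]
    length(nz) > 0 && nz[1] < 0
  }
  if (flip) model$loadings <- -model$loadings
  model
}

#' Exact Gaussian log-likelihood of standardized data under a fitted model
#'
#' Evaluates the multivariate-normal log density of the sample columns under
#' \eqn{\Sigma = \lambda\lambda' + \Psi}. Invariant to a global sign flip of
#' the loadings.
#'
#' @param model A \code{"factor_model"} (or a list with \code{loadings} and
#'   \code{uniquenesses}).
#' @param data A \code{standardized_set} or matrix with \code{model$p} rows.
#' @return Scalar log-likelihood.
#' @export
fa_loglik <- function(model, data) {
  Y <- .values(data)
  lambda <- model$loadings
  psi <- model$uniquenesses
  p <- length(lambda)
  if (nrow(Y) != p) stop("model has ", p, " features but data has ", nrow(Y))
  n <- ncol(Y)
  if (any(psi <= 0)) stop("singular covariance: non-positive uniqueness")
  w <- lambda / psi
  a <- 1 + sum(lambda * w)
  if (!is.finite(a) || a <= 0) stop("singular covariance")
  logdet <- log(a) + sum(log(psi))
  # Sigma^{-1} y via Woodbury: Psi^{-1} y - (w'y / a) w
  Wy <- Y / psi
  wy <- drop(crossprod(w, Y))
  quad <- sum(Y * Wy) - sum(wy^2) / a
  -n * p / 2 * log(2 * pi) - n / 2 * logdet - quad / 2
}

#' Thomson (regression) factor scores
#'
#' The unified expression estimate for each sample: the conditional
#' expectation \eqn{E[f \mid y] = \lambda'\Sigma^{-1} y}, computed through
#' the small-dimension form \eqn{(1 + \lambda'\Psi^{-1}\lambda)^{-1}
#' \lambda'\Psi^{-1} y} which inverts only the diagonal \eqn{\Psi}. The
#' returned weight vector makes the estimate an explicit weighted average of
#' the platforms/probes; weights increase with the loading of a feature, need
#' not sum to one, and can be negative.
#'
#' @param model A fitted \code{"factor_model"}.
#' @param data A \code{standardized_set} or matrix with \code{model$p} rows.
#' @return An object of class \code{"factor_scores"}: list with
#'   \code{scores} (length-n vector, named by sample) and \code{weights}
#'   (length-p vector, named by feature).
#' @export
thomson_scores <- function(model, data) {
  Y <- .values(data)
  lambda <- model$loadings
  psi <- model$uniquenesses
  if (nrow(Y) != length(lambda)) {
    stop("model has ", length(lambda), " features but data has ", nrow(Y))
  }
  w <- (lambda / psi) / (1 + sum(lambda^2 / psi))
  scores <- drop(crossprod(w, Y))
  names(scores) <- colnames(Y)
  names(w) <- model$feature_ids %||% rownames(Y)
  structure(list(scores = scores, weights = w), class = "factor_scores")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.factor_model <- function(x, ...) {
  cat("Single-factor model (p =", x$p, ", n =", x$n, ")\n")
  tab <- data.frame(
    feature = x$feature_ids %||% seq_len(x$p),
    loading = round(x$loadings, 4),
    uniqueness = round(x$uniquenesses, 4),
    heywood = x$heywood
  )
  print(tab, row.names = FALSE)
  cat("loglik:", format(x$loglik), " iterations:", x$n_iter,
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
print.factor_scores <- function(x, ...) {
  cat("Thomson factor scores for", length(x$scores), "samples\n")
  cat("weights:", paste(round(x$weights, 4), collapse = " "), "\n")
  invisible(x)
}
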