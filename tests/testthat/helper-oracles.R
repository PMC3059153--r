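# Independent oracles and data constructors shared across tests.

# discrepancy the ML fit minimizes, written directly from Sigma (no shared
# code with the package's Woodbury forms)
fa_discrepancy <- function(lambda, R, psi_floor = 1e-3) {
  psi <- pmax(1 - lambda^2, psi_floor)
  Sigma <- tcrossprod(lambda) + diag(psi)
  as.numeric(determinant(Sigma, logarithm = TRUE)$modulus +
               sum(diag(solve(Sigma, R))))
}

# direct numerical maximizer of the same Gaussian likelihood (multi-start
# box-constrained quasi-Newton), independent of the EM path
fit_direct <- function(R, psi_floor = 1e-3, n_starts = 6, seed = 990) {
  cap <- sqrt(1 - psi_floor) - 1e-9
  p <- nrow(R)
  set.seed(seed)
  starts <- rbind(
    rep(0.5, p),
    rep(0.9, p),
    matrix(stats::runif((n_starts - 2) * p, -0.9, 0.9), ncol = p)
  )
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], fa_discrepancy, R = R,
                      psi_floor = psi_floor, method = "L-BFGS-B",
                      lower = -cap, upper = cap,
                      control = list(maxit = 1000, factr = 1e3))
    if (is.null(best) || o$value < best$value) best <- o
  }
  lam <- best$par
  if (sum(lam) < 0) lam <- -lam
  lam
}

# p x n data whose *sample* correlation matrix equals R exactly
make_data_with_corr <- function(R, n, seed = 1) {
  p <- nrow(R)
  set.seed(seed)
  Y <- matrix(stats::rnorm(p * n), p)
  Y <- Y - rowMeans(Y)
  S <- tcrossprod(Y) / (n - 1)
  Y2 <- t(chol(R)) %*% solve(t(chol(S))) %*% Y
  rownames(Y2) <- paste0("f", seq_len(p))
  colnames(Y2) <- paste0("s", seq_len(n))
  Y2
}

# simulate raw data from the one-factor model y = lambda f + e
sim_from_lambda <- function(lambda, n, seed = 1, return_truth = FALSE) {
  set.seed(seed)
  f <- stats::rnorm(n)
  p <- length(lambda)
  e <- matrix(stats::rnorm(p * n), p) * sqrt(pmax(1 - lambda^2, 0))
  y <- lambda %o% f + e
  rownames(y) <- paste0("f", seq_len(p))
  colnames(y) <- paste0("s", seq_len(n))
  if (return_truth) list(y = y, truth = f) else y
}

# align the sign of estimated loadings to a reference before comparing
sign_align <- function(lambda, ref) if (sum(lambda * ref) < 0) -lambda else lambda

# AUC by brute force over all positive-negative pairs (ties count half)
brute_force_auc <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg, function(a, b) {
    (a > b) + 0.5 * (a == b)
  })
  mean(cmp)
}

# the nearest correlation matrix (used for triad targets that are not
# positive definite as written)
nearest_corr <- function(R) {
  as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
}
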