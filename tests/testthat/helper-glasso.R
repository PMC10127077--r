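# Independent single-class graphical lasso oracle: blockwise coordinate
# descent (covariance-update form), penalizing off-diagonals only.
# Solves max log det(Theta) - tr(S Theta) - rho * sum_{i!=j} |theta_ij|,
# i.e. the lambda2 = 0, per-class fused-JGL problem with rho = lambda1/n.
# Deliberately a different algorithm from the package's ADMM solver.
glasso_cd <- function(S, rho, tol = 1e-8, max_iter = 200) {
  p <- nrow(S)
  W <- S
  B <- matrix(0, p - 1, p)
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      W11 <- W[-j, -j, drop = FALSE]
      s12 <- S[-j, j]
      beta <- B[, j]
      # lasso by coordinate descent
      for (inner in seq_len(500)) {
        beta_old <- beta
        for (l in seq_len(p - 1)) {
          r <- s12[l] - sum(W11[l, -l] * beta[-l])
          beta[l] <- sign(r) * max(abs(r) - rho, 0) / W11[l, l]
        }
        if (max(abs(beta - beta_old)) < tol) break
      }
      B[, j] <- beta
      w12 <- W11 %*% beta
      W[-j, j] <- W[j, -j] <- w12
    }
    if (max(abs(W - W_old)) < tol * 10) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    theta_jj <- 1 / (W[j, j] - sum(W[-j, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[-j, j] <- -B[, j] * theta_jj
  }
  (Theta + t(Theta)) / 2
}
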