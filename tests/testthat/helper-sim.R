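# shared test utilities: standardized Gaussian draws from a planted
# precision matrix, and support-recovery F1

draw_ggm <- function(Theta, n, seed, standardized = TRUE) {
  set.seed(seed)
  Sigma <- chol2inv(chol(Theta))
  if (standardized) Sigma <- stats::cov2cor(Sigma)
  p <- nrow(Sigma)
  X <- t(matrix(stats::rnorm(n * p), n, p) %*% chol(Sigma))
  X - rowMeans(X)
}

support_f1 <- function(est, truth) {
  ut <- upper.tri(est)
  e <- est[ut] != 0
  t <- truth[ut] != 0
  tp <- sum(e & t)
  2 * tp / (2 * tp + sum(e & !t) + sum(!e & t))
}

# penalized fused-JGL objective (equal class weights), for monotonicity
# checks
jgl_objective <- function(Theta, S_set, lambda1, lambda2) {
  obj <- 0
  for (k in 1:2) {
    Th <- Theta[[k]]
    obj <- obj + determinant(Th)$modulus - sum(S_set$S[[k]] * Th) -
      lambda1 * sum(abs(Th[upper.tri(Th)])) * 2
  }
  obj - lambda2 * sum(abs(Theta[[1]] - Theta[[2]]))
}

# a small deterministic study configuration used across tests
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_perenne_parents = 10,
         n_partner_parents_per_class = c(12, 4),
         n_families_per_class = c(24, 20),
         n_snps = 120, n_gene_features = 24, n_nmr_features = 16,
         n_modules_per_class = 3, n_traits = 1,
         trait_h2 = 0.4, seed = seed),
    list(...))
  do.call(sim_config, args)
}
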