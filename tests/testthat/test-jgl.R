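test_that("empirical covariances use the 1/n convention", {
  X <- matrix(c(-1, 0, 1), 1, 3)
  S <- empirical_covariances(list(X, X))
  expect_equal(S$S[[1]][1, 1], 2 / 3)
  # orthogonal features have zero off-diagonal
  X2 <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(empirical_covariances(list(X2, X2))$S[[1]][1, 2], 0)
  # brute-force double loop oracle on a 4 x 3 matrix
  set.seed(1)
  X3 <- matrix(rnorm(12), 4, 3)
  X3 <- X3 - rowMeans(X3)
  S3 <- empirical_covariances(list(X3, X3))$S[[1]]
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    brute[i, j] <- sum(X3[i, ] * X3[j, ]) / 3
  expect_equal(S3, brute)
  expect_error(empirical_covariances(list(X3[, 1:2], X3[, 1:2])),
               "at least 3")
})

test_that("lambda1 beyond max |S| gives diagonal precision in both classes", {
  ps <- simulate_precision_set(12, 2, 1, 0.5, seed = 2)
  Xs <- lapply(1:2, function(k) draw_ggm(ps$Theta[[k]], 60, seed = k))
  S <- empirical_covariances(Xs)
  l1max <- max(abs(S$S[[1]][upper.tri(S$S[[1]])]),
               abs(S$S[[2]][upper.tri(S$S[[2]])]))
  fit <- fused_jgl(S, lambda1 = l1max * 1.001, lambda2 = 0)
  expect_equal(count_edges(fit$Theta)$per_class, c(0L, 0L))
  # with n_k-weighted likelihoods the bound scales with n_k
  fit_n <- fused_jgl(S, lambda1 = 60 * l1max * 1.001, lambda2 = 0,
                     weights = "n")
  expect_equal(count_edges(fit_n$Theta)$per_class, c(0L, 0L))
})

test_that("class estimates fuse as lambda2 grows", {
  ps <- simulate_precision_set(12, 2, 1, 0.3, seed = 3)
  Xs <- lapply(1:2, function(k) draw_ggm(ps$Theta[[k]], 80, seed = 10 + k))
  S <- empirical_covariances(Xs)
  gaps <- vapply(c(0.01, 0.05, 0.2, 1, 5), function(l2) {
    f <- fused_jgl(S, lambda1 = 0.1, lambda2 = l2)
    max(abs(f$Theta[[1]] - f$Theta[[2]]))
  }, 0)
  expect_true(all(diff(gaps) <= 1e-6))
  expect_lt(gaps[length(gaps)], 1e-4)
})

test_that("lambda2 = 0 reduces to independent graphical lassos (oracle)", {
  ps <- simulate_precision_set(10, 2, 1, 0.5, seed = 4)
  Xs <- lapply(1:2, function(k) draw_ggm(ps$Theta[[k]], 80, seed = 20 + k))
  S <- empirical_covariances(Xs)
  fit <- fused_jgl(S, lambda1 = 0.15, lambda2 = 0)
  for (k in 1:2) {
    oracle <- glasso_cd(S$S[[k]], 0.15)
    expect_lt(max(abs(fit$Theta[[k]] - oracle)), 1e-3)
  }
  # n_k-weighted variant solves the same problem at lambda1 = n * rho
  fit_n <- fused_jgl(S, lambda1 = 0.15 * 80, lambda2 = 0, weights = "n")
  expect_lt(max(abs(fit_n$Theta[[1]] - fit$Theta[[1]])), 1e-3)
})

test_that("ADMM objective does not decrease with more iterations", {
  ps <- simulate_precision_set(15, 3, 1, 0.5, seed = 5)
  Xs <- lapply(1:2, function(k) draw_ggm(ps$Theta[[k]], 60, seed = 30 + k))
  S <- empirical_covariances(Xs)
  short <- suppressWarnings(fused_jgl(S, 0.2, 0.1, max_iter = 5))
  long <- fused_jgl(S, 0.2, 0.1, max_iter = 500)
  expect_gte(jgl_objective(long$Theta, S, 0.2, 0.1),
             jgl_objective(short$Theta, S, 0.2, 0.1) - 1e-6)
  expect_true(long$converged)
})

test_that("BIC matches the closed form and charges for extra edges", {
  I3 <- diag(3)
  fit <- structure(list(Theta = list(I3, I3)), class = "jgl_fit")
  S_set <- structure(list(S = list(I3, I3), n = c(10L, 10L)),
                     class = "cov_set")
  expect_equal(bic_jgl(fit, S_set), 2 * (30 + 3 * log(10)),
               tolerance = 1e-10)
  # a (tiny) extra edge costs ~log(n) with negligible likelihood change
  Te <- I3; Te[1, 2] <- Te[2, 1] <- 1e-9
  fit2 <- structure(list(Theta = list(Te, I3)), class = "jgl_fit")
  expect_equal(bic_jgl(fit2, S_set) - bic_jgl(fit, S_set), log(10),
               tolerance = 1e-6)
})

test_that("support-constrained refit satisfies the MLE stationarity conditions", {
  ps <- simulate_precision_set(10, 2, 1, 0.5, seed = 6)
  X <- draw_ggm(ps$Theta[[1]], 200, seed = 40)
  S <- tcrossprod(X) / 200
  supp <- ps$Theta[[1]] != 0
  Th <- ggm_refit(S, supp)
  Sig <- solve(Th)
  # on the support (and diagonal) the fitted covariance matches S;
  # off-support precision entries are exactly zero
  expect_lt(max(abs((Sig - S)[supp])), 1e-5)
  offd <- !supp; diag(offd) <- FALSE
  expect_equal(max(abs(Th[offd])), 0)
})

test_that("default penalty grids have the documented shapes", {
  g_nmr <- default_penalty_grid("nmr")
  expect_length(g_nmr$lambda1, 30)
  expect_length(g_nmr$lambda2, 15)
  expect_equal(range(g_nmr$lambda1), c(0.01, 20))
  expect_equal(range(g_nmr$lambda2), c(0, 0.5))
  g_gene <- default_penalty_grid("gene")
  expect_length(g_gene$lambda1, 15)
  expect_length(g_gene$lambda2, 10)
  expect_equal(length(g_nmr$lambda1) * length(g_nmr$lambda2), 450)
  expect_equal(length(g_gene$lambda1) * length(g_gene$lambda2), 150)
})

test_that("grid search returns the single fit for a one-point grid", {
  ps <- simulate_precision_set(10, 2, 1, 0.5, seed = 7)
  Xs <- lapply(1:2, function(k) draw_ggm(ps$Theta[[k]], 50, seed = 50 + k))
  gs <- jgl_grid_search(Xs, grid = list(lambda1 = 0.2, lambda2 = 0.1))
  expect_equal(gs$best$lambda1, 0.2)
  expect_equal(gs$best$lambda2, 0.1)
  expect_equal(nrow(gs$surface), 1)
  expect_equal(gs$surface$bic, gs$best$bic)
})

test_that("partial correlations follow the precision formula", {
  expect_equal(partial_correlations(diag(3)), diag(3))
  Th <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partial_correlations(Th)[1, 2], 0.5)
  ps <- simulate_precision_set(20, 2, 2, 0.5, seed = 8)
  P <- partial_correlations(ps$Theta[[1]])
  expect_true(all(abs(P) <= 1 + 1e-12))
  expect_equal(diag(P), rep(1, 20))
  expect_equal(P == 0, ps$Theta[[1]] == 0)
})
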