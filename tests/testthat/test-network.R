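test_that("adjacency is the off-diagonal support indicator", {
  expect_equal(sum(to_adjacency(diag(3))$A[[1]]), 0)
  Th <- matrix(c(2, -1, 0, -1, 2, 0, 0, 0, 1), 3)
  adj <- to_adjacency(Th)
  expect_equal(adj$A[[1]][1, 2], 1)
  expect_equal(sum(adj$A[[1]]), 2)
  expect_equal(adj$isolated[[1]], c(f1 = FALSE, f2 = FALSE, f3 = TRUE))
  ps <- simulate_precision_set(30, 3, 1, 0.5, seed = 1)
  adj2 <- to_adjacency(ps$Theta)
  truth_shared <- sum(ps$Theta[[1]][upper.tri(ps$Theta[[1]])] != 0 &
                      ps$Theta[[2]][upper.tri(ps$Theta[[2]])] != 0)
  expect_equal(adj2$edges$shared, truth_shared)
  # support of a jgl_fit maps through unchanged
  Xs <- lapply(1:2, function(k) draw_ggm(ps$Theta[[k]], 50, seed = k))
  fit <- suppressWarnings(fused_jgl(empirical_covariances(Xs), 0.3, 0.1))
  a3 <- to_adjacency(fit)
  for (k in 1:2)
    expect_equal(unname(a3$A[[k]] != 0),
                 unname(fit$Theta[[k]] != 0) &
                   row(diag(30)) != col(diag(30)))
})

test_that("Louvain finds planted communities deterministically", {
  blk <- function(n) matrix(1, n, n) - diag(n)
  A <- as.matrix(Matrix::bdiag(blk(5), blk(5)))
  rownames(A) <- colnames(A) <- paste0("v", 1:10)
  m <- detect_modules(A, seed = 1)
  expect_equal(length(unique(m$membership)), 2)
  expect_equal(detect_modules(A, seed = 1)$membership, m$membership)
  expect_equal(length(unique(detect_modules(blk(6), seed = 2)$membership)),
               1)
  expect_error(detect_modules(matrix(0, 4, 4)), "no edges")
})

test_that("hub scores equal the Perron eigenvector of the adjacency", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  rownames(star) <- colnames(star) <- paste0("n", 1:5)
  s <- hub_scores(star)
  expect_equal(unname(s[1]), 1)
  expect_true(all(s[2:5] < 1))
  expect_equal(unname(s[2:5]), rep(unname(s[2]), 4))
  # ring: all equal by symmetry
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  expect_equal(unname(hub_scores(ring)), rep(1, 6))
  # general graph: matches the leading eigenvector of A (eigen oracle)
  set.seed(3)
  A <- matrix(rbinom(100, 1, 0.3), 10)
  A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
  ev <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
  expect_equal(unname(hub_scores(A)), ev / max(ev), tolerance = 1e-6)
  # permutation equivariance
  pm <- sample(10)
  expect_equal(unname(hub_scores(A[pm, pm])), unname(hub_scores(A)[pm]),
               tolerance = 1e-8)
})

test_that("hub selection takes top-k per module with stated tie-breaks", {
  A <- matrix(0, 7, 7)
  A[1, 2:4] <- A[2:4, 1] <- 1   # star module
  A[5, 6] <- A[6, 5] <- 1       # pair module
  rownames(A) <- colnames(A) <- paste0("x", 1:7)
  part <- detect_modules(A, seed = 1)
  sc <- hub_scores(A)
  hubs <- select_hubs(part, sc, A, k_per_module = 5)
  # pair module smaller than k: both members selected; singleton skipped
  expect_equal(sum(hubs$feature %in% c("x5", "x6")), 2)
  expect_false("x7" %in% hubs$feature)
  expect_lte(nrow(hubs), 5 * sum(!part$is_singleton))
  # within each module scores are sorted descending
  for (m in unique(hubs$module))
    expect_false(is.unsorted(rev(hubs$score[hubs$module == m])))
})

test_that("planted hubs are recovered from the true adjacency", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    ps <- simulate_precision_set(50, 5, 1, 0.5, seed = s)
    adj <- to_adjacency(ps$Theta[[1]])
    part <- detect_modules(adj$A[[1]], seed = s)
    sc <- hub_scores(adj$A[[1]])
    hubs <- select_hubs(part, sc, adj$A[[1]], k_per_module = 5)
    planted <- paste0("f", ps$hubs)
    hits <- hits + sum(planted %in% hubs$feature)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.8)
})

test_that("conserved hubs intersect by feature identity", {
  h1 <- data.frame(feature = c("a", "b", "c"), module = 1:3,
                   score = c(1, .9, .8), degree = c(5, 4, 3))
  h2 <- data.frame(feature = c("c", "d"), module = c(9, 2),
                   score = c(1, .5), degree = c(6, 2))
  cons <- conserved_hubs(h1, h2)
  expect_equal(cons$feature, "c")
  expect_equal(cons$module_class2, 9)  # module mismatch tolerated
  expect_equal(conserved_hubs(h1, h1)$feature, h1$feature)
  expect_warning(out <- conserved_hubs(h1, data.frame(feature = "z",
    module = 1, score = 1, degree = 1)), "no hub")
  expect_equal(nrow(out), 0)
})
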