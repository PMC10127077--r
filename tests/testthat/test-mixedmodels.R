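test_that("the sliding window links interior plots to 11 positions", {
  layout <- expand.grid(row = 1:10, col = 1:8)
  sp <- build_spatial_design(layout)
  expect_length(sp$S, 11)
  links <- Matrix::rowSums(sp$W)
  interior <- layout$row %in% 4:7 & layout$col %in% 3:6
  expect_true(all(links[interior] == 11))
  expect_true(all(links <= 11))
  # corner of a 2x2 grid: itself + one down + one right
  sp2 <- build_spatial_design(expand.grid(row = 1:2, col = 1:2))
  expect_equal(max(Matrix::rowSums(sp2$W)), 3)
  # a 1 x n strip keeps only the row arm (5 links at most)
  sp3 <- build_spatial_design(data.frame(row = 1, col = 1:20))
  expect_equal(max(Matrix::rowSums(sp3$W)), 5)
  expect_error(build_spatial_design(data.frame(row = 1, col = 1)),
               "at least 2")
})

test_that("dense REML agrees with lme4 on a random-intercept model", {
  skip_if_not_installed("lme4")
  set.seed(5)
  nf <- 40; reps <- 4; n <- nf * reps
  fam <- rep(1:nf, each = reps)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(nf, sd = sqrt(2))[fam] + rnorm(n, sd = 1.3)
  Z <- matrix(0, n, nf); Z[cbind(1:n, fam)] <- 1
  fit <- reml_dense(y, cbind(1, x), list(fam = tcrossprod(Z)))
  m <- lme4::lmer(y ~ x + (1 | fam), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(unname(fit$sigma2), vc, tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)), tolerance = 1e-6)
})

test_that("eigen and dense REML routes agree on a kernel model", {
  set.seed(6)
  G <- crossprod(matrix(rnorm(80 * 60), 80, 60))
  G <- G / mean(diag(G))
  y <- as.vector(2 + t(chol(G)) %*% rnorm(60) * 1.2 + rnorm(60, sd = 0.8))
  f1 <- reml_uni_eigen(y, G = G)
  f2 <- reml_dense(y, matrix(1, 60, 1), list(g = G))
  expect_equal(f1$sigma_u2, unname(f2$sigma2[1]), tolerance = 1e-3)
  expect_equal(f1$sigma_e2, unname(f2$sigma2[2]), tolerance = 1e-3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
})

test_that("feature heritability hits its limits and invariances", {
  set.seed(7)
  G <- crossprod(matrix(rnorm(120 * 60), 120, 60))
  G <- G / mean(diag(G))
  u <- as.vector(t(chol(G)) %*% rnorm(60))
  noiseless <- reml_feature_h2(u + rnorm(60, sd = 1e-4), G)
  expect_gt(noiseless$h2, 0.98)
  # location shift and scaling leave h2 unchanged
  y <- u + rnorm(60, sd = 1)
  h <- reml_feature_h2(y, G)$h2
  expect_equal(reml_feature_h2(y + 100, G)$h2, h, tolerance = 1e-5)
  expect_equal(reml_feature_h2(y * 7, G)$h2, h, tolerance = 1e-5)
  # pure noise estimates concentrate near zero
  h0 <- replicate(20, reml_feature_h2(rnorm(60), G)$h2)
  expect_lt(mean(h0), 0.1)
})

test_that("phenotype heritability is location and scale invariant", {
  cfg <- tiny_config(seed = 3)
  d <- simulate_diallel_frequencies(cfg)
  grm <- grm_from_frequencies(d$freqs$class1)
  ph <- simulate_phenotypes(grm, cfg, seed = 4)
  v1 <- reml_phenotype(ph$table, grm, trait = "trait1")
  shifted <- ph$table; shifted$value <- shifted$value + 50
  v2 <- reml_phenotype(shifted, grm, trait = "trait1")
  expect_equal(v2$h2, v1$h2, tolerance = 1e-3)
  scaled <- ph$table; scaled$value <- scaled$value * 3
  v3 <- reml_phenotype(scaled, grm, trait = "trait1")
  expect_equal(v3$h2, v1$h2, tolerance = 1e-3)
  expect_equal(v3$sigma_u2, 9 * v1$sigma_u2, tolerance = 0.05)
})

test_that("bivariate REML respects nesting and the noiseless limit", {
  cfg <- tiny_config(seed = 5, trial_block_sd = 0, spatial_variance = 0,
                     trait_h2 = 0.95)
  d <- simulate_diallel_frequencies(cfg)
  grm <- grm_from_frequencies(d$freqs$class1)
  L <- poolnet:::chol_psd(grm$G)
  set.seed(8)
  u <- as.vector(L %*% rnorm(24))
  cfg$genetic_correlations <- data.frame(hub = 1L, trait = 1L, rg = 1)
  ph <- simulate_phenotypes(grm, cfg, u_hub_std = cbind(u), seed = 9)
  y_ome <- u + rnorm(24, sd = 0.05)
  names(y_ome) <- rownames(grm$G)
  fit <- bivariate_reml(y_ome, ph$table, grm, grm$pc_scores,
                        trait = "trait1")
  expect_gte(fit$loglik_full, fit$loglik_constrained - 1e-6)
  expect_gt(fit$rg, 0.8)
  expect_lte(abs(fit$rg), 1)
  expect_equal(fit$lrt_stat,
               max(0, 2 * (fit$loglik_full - fit$loglik_constrained)))
})

test_that("boundary LRT mixes a point mass at zero with chi-square 1", {
  expect_equal(lrt_boundary(0), 0.5)
  expect_equal(lrt_boundary(qchisq(0.95, 1)), 0.025, tolerance = 1e-6)
  expect_equal(lrt_boundary(3.841), 0.5 * pchisq(3.841, 1, lower.tail = FALSE))
  fake <- structure(list(loglik_full = -10, loglik_constrained = -9.9),
                    class = "bivariate_fit")
  expect_warning(p <- lrt_boundary(fake), "flooring")
  expect_equal(p, 0.5)
})

test_that("BH FDR reproduces the step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$significant))
  r1 <- bh_fdr(rep(1, 5))
  expect_false(any(r1$significant))
  expect_equal(r1$q, rep(1, 5))
  expect_equal(bh_fdr(0.04)$q, 0.04)
  expect_true(bh_fdr(0.04)$significant)
  # boundary case: p_(i) = i * alpha / m exactly rejects all
  expect_true(all(bh_fdr(c(0.0125, 0.025, 0.0375, 0.05))$significant))
  # agreement with stats::p.adjust on random input
  set.seed(10)
  p2 <- runif(20)
  expect_equal(bh_fdr(p2)$q, p.adjust(p2, "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("hub covariate z-test flags planted effects and rejects degenerate input", {
  cfg <- tiny_config(seed = 6)
  d <- simulate_diallel_frequencies(cfg)
  grm <- grm_from_frequencies(d$freqs$class1)
  ph <- simulate_phenotypes(grm, cfg, seed = 7)
  expect_error(hub_covariate_ztest(ph$table,
    setNames(rep(0, 24), rownames(grm$G)), grm, trait = "trait1"),
    "zero variance")
  set.seed(11)
  covr <- setNames(rnorm(24), rownames(grm$G))
  tab <- ph$table[ph$table$trait == "trait1", ]
  tab$value <- tab$value + 1.5 * covr[tab$family]
  z <- hub_covariate_ztest(tab, covr, grm)
  expect_lt(z$pvalue, 0.05)
  expect_equal(z$z, z$estimate / z$se)
})

test_that("integration scan applies FDR within omic features", {
  cfg <- tiny_config(seed = 8, n_traits = 2, trait_h2 = c(0.5, 0.5))
  d <- simulate_diallel_frequencies(cfg)
  grm <- grm_from_frequencies(d$freqs$class1)
  L <- poolnet:::chol_psd(grm$G)
  set.seed(12)
  u <- as.vector(L %*% rnorm(24))
  cfg$genetic_correlations <- data.frame(hub = 1L, trait = 1L, rg = 0.9)
  ph <- simulate_phenotypes(grm, cfg, u_hub_std = cbind(u), seed = 13)
  hub_mat <- rbind(hubA = u + rnorm(24, sd = 0.3),
                   nullB = rnorm(24))
  colnames(hub_mat) <- rownames(grm$G)
  scan <- integrate_hubs(hub_mat, ph$table, grm, grm$pc_scores)
  expect_equal(nrow(scan), 4)  # 2 features x 2 traits
  wn <- build_weighted_network(list(class1 = scan))
  expect_equal(nrow(wn), sum(!is.na(scan$rg)))
  expect_equal(wn$weight, abs(wn$rg))
  # q-values computed within each feature family
  for (f in unique(scan$feature)) {
    i <- which(scan$feature == f & !is.na(scan$pvalue))
    if (length(i))
      expect_equal(scan$q[i], p.adjust(scan$pvalue[i], "BH"))
  }
})
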