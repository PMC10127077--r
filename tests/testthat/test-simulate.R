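test_that("family pool frequency is the parental midpoint", {
  expect_equal(family_pool_frequency(0, 4, ploidy = 4, pool_size = Inf),
               0.5)
  expect_equal(family_pool_frequency(c(1, 2), c(3, 2), 4, Inf),
               c(0.5, 0.5))
})

test_that("pool sampling is binomial around the midpoint", {
  set.seed(1)
  d1 <- rep(1, 1); d2 <- rep(2, 1)  # midpoint 3/8
  draws <- replicate(10000,
    family_pool_frequency(d1, d2, ploidy = 4, pool_size = 120))
  expected <- 3 / 8
  se <- sqrt(expected * (1 - expected) / (120 * 4)) / sqrt(10000)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("diallel generation is deterministic and respects the design", {
  cfg <- tiny_config(seed = 1)
  d1 <- simulate_diallel_frequencies(cfg)
  d2 <- simulate_diallel_frequencies(cfg)
  expect_identical(d1$freqs$class1$values, d2$freqs$class1$values)
  expect_identical(d1$pedigree, d2$pedigree)
  expect_equal(nrow(d1$freqs$class1$values), 24)
  expect_equal(nrow(d1$freqs$class2$values), 20)
  rng <- range(d1$freqs$class1$values, na.rm = TRUE)
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  # classes share perenne parents
  expect_true(any(d1$pedigree$parent1[d1$pedigree$class == "class1"] %in%
                  d1$pedigree$parent1[d1$pedigree$class == "class2"]))
  expect_error(
    simulate_diallel_frequencies(
      sim_config(n_perenne_parents = 2,
                 n_partner_parents_per_class = c(2, 2),
                 n_families_per_class = c(5, 4), seed = 1)),
    "distinct parent pairs")
})

test_that("families sharing a parent are more related in the realized GRM", {
  cfg <- sim_config(seed = 4, n_snps = 400)
  d <- simulate_diallel_frequencies(cfg)
  g <- compute_grm(center_frequencies(d$freqs$class1))$G
  ped <- d$pedigree[d$pedigree$class == "class1", ]
  shared <- c(); unshared <- c()
  for (i in 1:(nrow(ped) - 1)) for (j in (i + 1):nrow(ped)) {
    n_common <- length(intersect(c(ped$parent1[i], ped$parent2[i]),
                                 c(ped$parent1[j], ped$parent2[j])))
    if (n_common > 0) shared <- c(shared, g[i, j])
    else unshared <- c(unshared, g[i, j])
  }
  expect_gt(mean(shared), mean(unshared))
})

test_that("planted precision matrices honour sharing, dominance and PD", {
  full <- simulate_precision_set(30, 3, 1, 1, seed = 1)
  expect_identical(full$Theta[[1]] != 0, full$Theta[[2]] != 0)
  none <- simulate_precision_set(30, 3, 1, 0, seed = 2)
  s1 <- none$Theta[[1]][upper.tri(none$Theta[[1]])] != 0
  s2 <- none$Theta[[2]][upper.tri(none$Theta[[2]])] != 0
  expect_lte(sum(s1 & s2) / sum(s1 | s2), 0.1)
  for (s in 1:5) {
    ps <- simulate_precision_set(50, 5, 2, 0.5, seed = s)
    for (k in 1:2) {
      Th <- ps$Theta[[k]]
      expect_gt(min(eigen(Th, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
      expect_equal(diag(Th), 1 + rowSums(abs(Th)) - diag(Th))
      for (m in unique(ps$modules)) {
        idx <- which(ps$modules == m)
        mh <- intersect(ps$hubs, idx)
        deg <- rowSums(Th[idx, idx, drop = FALSE] != 0)
        names(deg) <- idx
        expect_gt(min(deg[as.character(mh)]),
                  max(c(deg[as.character(setdiff(idx, mh))], 0)))
      }
    }
  }
  expect_error(simulate_precision_set(5, 3, 1, 0.5, seed = 1),
               "too small")
})

test_that("simulated omics are reproducible and respect h2 = 0", {
  ps <- simulate_precision_set(12, 2, 1, 0.5, seed = 3)
  G <- diag(30)
  o1 <- simulate_omics(G, ps$Theta[[1]], h2 = 0, seed = 5)
  o2 <- simulate_omics(G, ps$Theta[[1]], h2 = 0, seed = 5)
  expect_identical(o1$X, o2$X)
  expect_equal(o1$sigma_u2, rep(0, 12))
  expect_equal(unname(o1$u), matrix(0, 12, 30), tolerance = 1e-12)
})

test_that("sample precision support converges to the planted support", {
  ps <- simulate_precision_set(20, 2, 1, 0.7, seed = 6)
  o <- simulate_omics(diag(5000), ps$Theta[[1]], h2 = 0, seed = 7)
  S <- tcrossprod(o$X - rowMeans(o$X)) / 5000
  pc <- -stats::cov2cor(solve(S))
  est <- abs(pc) > 0.05
  diag(est) <- FALSE
  truth <- ps$Theta[[1]] != 0; diag(truth) <- FALSE
  tp <- sum(est & truth) / 2
  f1 <- 2 * tp / (2 * tp + sum(est & !truth) / 2 + sum(!est & truth) / 2)
  expect_gt(f1, 0.9)
})

test_that("phenotype generator matches its analysis model", {
  cfg <- tiny_config(seed = 2, spatial_variance = 0)
  d <- simulate_diallel_frequencies(cfg)
  grm <- grm_from_frequencies(d$freqs$class1)
  ph <- simulate_phenotypes(grm, cfg, seed = 3)
  expect_equal(nrow(ph$table), 2 * 24)  # two replicates per family
  vc <- reml_phenotype(ph$table, grm, trait = "trait1")
  total <- vc$sigma_u2 + 11 * vc$sigma_s2 + vc$sigma_e2
  expect_lt(vc$sigma_s2 / total, 0.05)
  # perfect genetic correlation with no residual noise ranks families
  cfg2 <- tiny_config(seed = 2, trait_h2 = 0.999, spatial_variance = 0,
                      trial_block_sd = 0)
  L <- poolnet:::chol_psd(grm$G)
  set.seed(9)
  u_hub <- as.vector(L %*% rnorm(24))
  cfg2$genetic_correlations <- data.frame(hub = 1L, trait = 1L, rg = 1)
  ph2 <- simulate_phenotypes(grm, cfg2, u_hub_std = cbind(u_hub), seed = 4)
  fam_means <- tapply(ph2$table$value, ph2$table$family, mean)
  names(u_hub) <- rownames(grm$G)
  expect_gt(cor(fam_means[names(u_hub)], u_hub, method = "spearman"),
            0.95)
})

test_that("the full study bundle is deterministic under one seed", {
  cfg <- tiny_config(seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$freqs$class1$values, s2$freqs$class1$values)
  expect_identical(s1$omics$gene$class1$X, s2$omics$gene$class1$X)
  expect_identical(s1$pheno$class2$table, s2$pheno$class2$table)
})
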