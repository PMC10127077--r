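test_that("chained imputation preserves observed cells and beats column means", {
  set.seed(3)
  n <- 80
  base <- matrix(runif(n * 6, 0.1, 0.9), n)
  M <- cbind(base, base[, 1] + rnorm(n, sd = 0.02))
  M <- pmin(pmax(M, 0), 1)
  colnames(M) <- paste0("s", 1:7)
  expect_identical(impute_frequencies_chained_rf(M, rep(1, 7), seed = 1), M)
  Mm <- M
  mask <- sample(n, 8)
  Mm[mask, 7] <- NA
  imp <- impute_frequencies_chained_rf(Mm, rep(1, 7), k = 3, seed = 2)
  expect_identical(imp[!is.na(Mm)], Mm[!is.na(Mm)])
  rf_rmse <- sqrt(mean((imp[mask, 7] - M[mask, 7])^2))
  mean_rmse <- sqrt(mean((mean(Mm[, 7], na.rm = TRUE) - M[mask, 7])^2))
  expect_lt(rf_rmse, mean_rmse)
  expect_lt(rf_rmse, sd(M[, 7]))
})

test_that("masking experiment on simulated pools favours chained RF", {
  cfg <- sim_config(seed = 4, missing_rate = 0, n_snps = 300)
  d <- simulate_diallel_frequencies(cfg)
  M <- d$freqs$class1$values
  set.seed(5)
  mask <- cbind(sample(nrow(M), 200, TRUE), sample(ncol(M), 200, TRUE))
  mask <- unique(mask)
  truth <- M[mask]
  Mm <- M; Mm[mask] <- NA
  imp <- suppressWarnings(
    impute_frequencies_chained_rf(Mm, d$freqs$class1$chrom,
                                  k = 15, seed = 6))
  cm <- poolnet:::mean_impute_cols(Mm)
  expect_lte(sqrt(mean((imp[mask] - truth)^2)),
             sqrt(mean((cm[mask] - truth)^2)))
})

test_that("single-SNP clusters fall back to column means with a warning", {
  M <- matrix(c(0.1, NA, 0.3, 0.5, 0.6, 0.7), 3, 2)
  colnames(M) <- c("a", "b")
  expect_warning(out <- impute_frequencies_chained_rf(
    M, chrom = c(1, 2), seed = 1), "single SNP")
  expect_equal(unname(out[2, 1]), 0.2)
})

test_that("BLUEs reduce to family means in the balanced null design", {
  # one trial, complete blocks: the family/block classification is
  # balanced so the GLS family estimates collapse to family means
  cfg <- tiny_config(seed = 5, spatial_variance = 0, trial_block_sd = 0,
                     n_trials = 1, plots_per_block = 24)
  d <- simulate_diallel_frequencies(cfg)
  grm <- grm_from_frequencies(d$freqs$class1)
  ph <- simulate_phenotypes(grm, cfg, seed = 6)
  bl <- suppressWarnings(compute_blues(list(class1 = ph$table)))
  fm <- tapply(ph$table$value, ph$table$family, mean)
  fm <- fm - mean(fm)
  expect_equal(bl$blue, as.numeric(fm[bl$family]), tolerance = 0.05)
  # adding a constant shifts nothing after within-location centring
  ph2 <- ph$table; ph2$value <- ph2$value + 100
  bl2 <- suppressWarnings(compute_blues(list(class1 = ph2)))
  expect_equal(bl2$blue, bl$blue, tolerance = 1e-6)
})

test_that("BLUEs track true family effects when noise is small", {
  cfg <- tiny_config(seed = 7, trait_h2 = 0.8, trial_block_sd = 0)
  d <- simulate_diallel_frequencies(cfg)
  grm <- grm_from_frequencies(d$freqs$class1)
  ph <- simulate_phenotypes(grm, cfg, seed = 8)
  bl <- suppressWarnings(compute_blues(list(class1 = ph$table)))
  expect_gt(cor(bl$blue, ph$u[bl$family, 1]), 0.9)
})

test_that("random forest OOB accuracy is deterministic and calibrated", {
  set.seed(9)
  X <- matrix(rnorm(120 * 25), 120)
  colnames(X) <- paste0("p", 1:25)
  y_sig <- X[, 1] * 2 + rnorm(120, sd = 0.2)
  f1 <- rf_oob(X, y_sig, num_trees = 500, seed = 3)
  f2 <- rf_oob(X, y_sig, num_trees = 500, seed = 3)
  expect_identical(f1$oob_accuracy, f2$oob_accuracy)
  expect_gt(f1$oob_accuracy, 0.9)
  expect_equal(f1$mtry, 5)
  null_acc <- vapply(1:10, function(s)
    rf_oob(X, rnorm(120), num_trees = 300, seed = s)$oob_accuracy, 0)
  expect_lt(median(abs(null_acc)), 0.15)
  expect_error(rf_oob(X, rep(1, 120)), "zero variance")
  expect_error(rf_oob(cbind(X, NA), y_sig), "missing")
})

test_that("SNP tagging respects gene spans and the flanking window", {
  gene_map <- data.frame(id = c("g1", "g2"), chrom = c(1, 2),
                         start = c(10000, 5000), end = c(13000, 8000))
  snp_map <- data.frame(chrom = c(1, 1, 1, 2, 2),
                        pos = c(4000, 6000, 14000, 7000, 20000),
                        id = paste0("s", 1:5))
  hits <- snps_tagging_hubs(gene_map, c("g1", "g2"), snp_map,
                            window = 5000)
  expect_setequal(hits, c("s2", "s3", "s4"))
  expect_length(snps_tagging_hubs(gene_map, "g1", snp_map, window = 0), 0)
})

test_that("scenario runner produces the full accounting of fits", {
  set.seed(10)
  n <- 60
  hub <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("h", 1:4)))
  full <- cbind(hub, matrix(rnorm(n * 16), n,
                            dimnames = list(NULL, paste0("r", 1:16))))
  y <- rowSums(hub) + rnorm(n, sd = 0.5)
  res <- scenario_runner(list(gene = hub), list(gene = full),
                         list(trait1 = y), n_draws = 3, seed = 2,
                         num_trees = 300)
  expect_equal(nrow(res), 1 * 1 * (2 + 3))
  expect_setequal(unique(res$scenario),
                  c("hub", "all", paste0("draw_", 1:3)))
  smry <- summarize_scenarios(res)
  expect_equal(nrow(smry), 3)
  expect_true(is.na(smry$se[smry$scenario == "hub"]))
  expect_false(is.na(smry$se[smry$scenario == "random_draw"]))
  # single draw leaves the SE undefined
  r1 <- scenario_runner(list(gene = hub), list(gene = full),
                        list(trait1 = y), n_draws = 1, seed = 2,
                        num_trees = 200)
  expect_true(is.na(summarize_scenarios(r1)$se[2]))
  # a draw of the full size equals the all-features scenario
  rfull <- scenario_runner(list(gene = full), list(gene = full),
                           list(trait1 = y), n_draws = 1, seed = 4,
                           num_trees = 200)
  acc <- rfull$accuracy
  expect_equal(acc[rfull$scenario == "draw_1"],
               acc[rfull$scenario == "all"], tolerance = 0.05)
  # empty hub set is skipped with a message
  expect_message(
    none <- scenario_runner(list(gene = NULL), list(gene = full),
                            list(trait1 = y), n_draws = 1, seed = 2),
    "skipped")
  expect_null(none)
})
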