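#' Chained random-forest imputation of pool allele frequencies
#'
#' Imputes missing entries of a samples x SNPs frequency matrix one
#' chromosome at a time, inside clusters of SNPs formed by
#' complete-linkage clustering (distance `1 - |cor|` between columns,
#' `k` groups).  Within a cluster, missing columns are regressed on the
#' cluster's other columns with extremely randomized trees and the
#' sweep repeats until the imputed values stabilise.  Observed cells
#' are preserved exactly; single-SNP clusters fall back to column-mean
#' imputation with a warning.
#'
#' @param M samples x SNPs matrix with `NA` for missing cells.
#' @param chrom chromosome label per column.
#' @param k clusters per chromosome (default 30).
#' @param num_trees,sample_fraction,max_depth random-forest
#'   hyperparameters (defaults 100, 0.1, 6; split rule is extratrees).
#' @param max_sweeps chained-imputation sweep cap.
#' @param tol mean absolute change of imputed values declaring
#'   convergence.
#' @param seed integer seed.
#' @return the completed matrix.
#' @export
impute_frequencies_chained_rf <- function(M, chrom, k = 30,
                                          num_trees = 100,
                                          sample_fraction = 0.1,
                                          max_depth = 6,
                                          max_sweeps = 10, tol = 1e-4,
                                          seed = 1L) {
  M <- as.matrix(M)
  if (!anyNA(M)) return(M)
  stopifnot(length(chrom) == ncol(M))
  out <- M
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    if (length(cols) < 2) {
      out[, cols] <- mean_impute_cols(M[, cols, drop = FALSE])
      if (anyNA(M[, cols]))
        warning("chromosome ", ch,
                " has a single SNP; column-mean imputation used")
      next
    }
    sub <- M[, cols, drop = FALSE]
    cl <- snp_clusters(sub, k)
    for (g in unique(cl)) {
      gi <- cols[cl == g]
      if (!anyNA(M[, gi])) next
      if (length(gi) < 2) {
        out[, gi] <- mean_impute_cols(M[, gi, drop = FALSE])
        warning("single-SNP cluster on chromosome ", ch,
                "; column-mean imputation used")
        next
      }
      out[, gi] <- chain_impute(M[, gi, drop = FALSE], num_trees,
                                sample_fraction, max_depth, max_sweeps,
                                tol, seed)
    }
  }
  out
}

mean_impute_cols <- function(X) {
  for (j in seq_len(ncol(X))) {
    m <- is.na(X[, j])
    if (any(m)) X[m, j] <- mean(X[, j], na.rm = TRUE)
  }
  X
}

# complete-linkage clusters on 1 - |cor| between SNP columns
snp_clusters <- function(X, k) {
  if (ncol(X) <= k) return(seq_len(ncol(X)))
  cc <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  d <- 1 - abs(cc)
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  stats::cutree(stats::hclust(stats::as.dist(d), method = "complete"),
                k = k)
}

chain_impute <- function(X, num_trees, sample_fraction, max_depth,
                         max_sweeps, tol, seed) {
  miss <- is.na(X)
  cur <- mean_impute_cols(X)
  targets <- which(colSums(miss) > 0)
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0; nimp <- 0
    for (j in targets) {
      obs <- !miss[, j]
      dtrain <- data.frame(y = X[obs, j],
                           cur[obs, -j, drop = FALSE])
      rf <- ranger::ranger(y ~ ., data = dtrain,
                           num.trees = num_trees,
                           sample.fraction = sample_fraction,
                           max.depth = max_depth,
                           splitrule = "extratrees",
                           num.threads = 1,
                           seed = seed + sweep * 131 + j)
      newv <- stats::predict(
        rf, data.frame(cur[miss[, j], -j, drop = FALSE]))$predictions
      delta <- delta + sum(abs(newv - cur[miss[, j], j]))
      nimp <- nimp + length(newv)
      cur[miss[, j], j] <- newv
    }
    if (nimp == 0 || delta / nimp < tol) break
  }
  cur
}

#' Family BLUEs from the spatially adjusted phenotype model
#'
#' Refits the phenotype sub-model with families as fixed effects (no PC
#' scores): fixed family + trial-block effects, sliding-window spatial
#' random effect, i.i.d. residual.  Family BLUEs are extracted by GLS
#' at the REML variance estimates, mean-centred within location
#' (class), and merged across classes into one response vector per
#' trait.
#'
#' @param pheno_by_class named list of phenotype tables (one per
#'   class/location).
#' @param traits traits to process (default: all present).
#' @return data frame: family, trait, class, blue (centred within
#'   class).
#' @export
compute_blues <- function(pheno_by_class, traits = NULL) {
  out <- NULL
  for (cl in names(pheno_by_class)) {
    tab_all <- pheno_by_class[[cl]]
    trs <- traits %||% unique(tab_all$trait)
    for (tr in trs) {
      tab <- tab_all[tab_all$trait == tr, ]
      fams <- sort(unique(tab$family))
      Zf <- fam_incidence(tab$family, fams)
      colnames(Zf) <- paste0("fam_", fams)
      tb <- tb_design(tab)[, -1, drop = FALSE]  # absorb mean into families
      X <- prune_design(cbind(Zf, tb), "BLUE design")
      sp <- build_spatial_design(tab[, c("row", "col")])
      fit <- reml_dense(tab$value, X,
                        list(spatial = tcrossprod(as.matrix(sp$W))))
      b <- fit$beta[paste0("fam_", fams)]
      b <- b - mean(b, na.rm = TRUE)
      out <- rbind(out, data.frame(family = fams, trait = tr,
                                   class = cl, blue = unname(b)))
    }
  }
  dropped <- is.na(out$blue)
  if (any(dropped)) {
    warning(sum(dropped), " families without estimable BLUEs dropped")
    out <- out[!dropped, ]
  }
  out
}

#' Random-forest prediction with out-of-bag accuracy
#'
#' Regression random forest with the study hyperparameters: 2,000
#' trees, minimum node size 5 and `mtry = floor(sqrt(p))` candidate
#' features.  Accuracy is the Pearson correlation between the out-of-
#' bag predictions and the observed response; variable importance is by
#' permutation.
#'
#' @param X samples x predictors matrix (no missing values).
#' @param y response (merged centred BLUEs), aligned with rows of `X`.
#' @param num_trees,min_node_size,mtry hyperparameters.
#' @param seed integer seed (fixes both ranger's RNG and the result).
#' @param importance importance mode (default permutation).
#' @return list of class `rf_result`: `oob_accuracy`, `importance`,
#'   `n_trees`, `mtry`, `seed`.
#' @export
rf_oob <- function(X, y, num_trees = 2000, min_node_size = 5,
                   mtry = NULL, seed = 1L, importance = "permutation") {
  X <- as.matrix(X)
  if (anyNA(X)) stop("predictors contain missing values")
  if (stats::sd(y) == 0) stop("response has zero variance")
  if (length(y) != nrow(X)) stop("X rows must align with y")
  mtry <- mtry %||% max(1, floor(sqrt(ncol(X))))
  df <- data.frame(y = y, X)
  rf <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                       min.node.size = min_node_size, mtry = mtry,
                       importance = importance, oob.error = TRUE,
                       num.threads = 1, seed = seed)
  acc <- stats::cor(rf$predictions, y, use = "complete.obs")
  structure(list(oob_accuracy = acc, importance = rf$variable.importance,
                 n_trees = num_trees, mtry = mtry, seed = seed),
            class = "rf_result")
}

#' SNPs tagging hub genes
#'
#' Returns the SNP ids whose position falls within a hub gene's span
#' extended by `window` bases on each side.
#'
#' @param gene_map data frame: id, chrom, start, end.
#' @param hub_ids gene ids to tag.
#' @param snp_map data frame: chrom, pos, id.
#' @param window flanking width in bases (default 5000).
#' @return character vector of SNP ids.
#' @export
snps_tagging_hubs <- function(gene_map, hub_ids, snp_map,
                              window = 5000) {
  gm <- gene_map[gene_map$id %in% hub_ids, , drop = FALSE]
  hits <- character(0)
  for (i in seq_len(nrow(gm))) {
    sel <- snp_map$chrom == gm$chrom[i] &
      snp_map$pos >= gm$start[i] - window &
      snp_map$pos <= gm$end[i] + window
    hits <- c(hits, snp_map$id[sel])
  }
  unique(hits)
}

#' Hub vs random-draw vs all-features prediction scenarios
#'
#' For each trait and omics layer, fits (i) the hub predictor set,
#' (ii) `n_draws` random same-size draws from the layer's full feature
#' matrix, and (iii) all features, all with [rf_oob()].  Per-draw rows
#' are returned unaggregated; `summarize_scenarios()` collapses the
#' draws to mean and standard error.
#'
#' @param hub_sets named list (by layer) of samples x hub-feature
#'   matrices; empty/NULL layers are skipped with a message.
#' @param full_sets named list (by layer) of samples x all-feature
#'   matrices.
#' @param y_by_trait named list of responses aligned to the rows.
#' @param n_draws random draws per layer (default 20).
#' @param seed master seed; draw seeds derive from it.
#' @param ... passed to [rf_oob()].
#' @return data frame, one row per fitted forest: trait, layer,
#'   scenario, accuracy, n_predictors, seed.
#' @export
scenario_runner <- function(hub_sets, full_sets, y_by_trait,
                            n_draws = 20, seed = 1L, ...) {
  rows <- NULL
  for (tr in names(y_by_trait)) {
    y <- y_by_trait[[tr]]
    for (layer in names(full_sets)) {
      full <- as.matrix(full_sets[[layer]])
      hub <- hub_sets[[layer]]
      if (is.null(hub) || ncol(as.matrix(hub)) == 0) {
        message("layer ", layer, ": empty hub set, scenario skipped")
        next
      }
      hub <- as.matrix(hub)
      fit_h <- rf_oob(hub, y, seed = derive_seed(seed, paste0(tr, layer, "hub")),
                      ...)
      rows <- rbind(rows, data.frame(
        trait = tr, layer = layer, scenario = "hub",
        accuracy = fit_h$oob_accuracy, n_predictors = ncol(hub),
        seed = fit_h$seed))
      m <- min(ncol(hub), ncol(full))
      for (dr in seq_len(n_draws)) {
        ds <- derive_seed(seed, paste0(tr, layer, "draw", dr))
        set.seed(ds)
        pick <- sample.int(ncol(full), m)
        fit_d <- rf_oob(full[, pick, drop = FALSE], y, seed = ds, ...)
        rows <- rbind(rows, data.frame(
          trait = tr, layer = layer, scenario = paste0("draw_", dr),
          accuracy = fit_d$oob_accuracy, n_predictors = m, seed = ds))
      }
      fit_a <- rf_oob(full, y, seed = derive_seed(seed, paste0(tr, layer, "all")),
                      ...)
      rows <- rbind(rows, data.frame(
        trait = tr, layer = layer, scenario = "all",
        accuracy = fit_a$oob_accuracy, n_predictors = ncol(full),
        seed = fit_a$seed))
    }
  }
  rows
}

#' Aggregate scenario results
#'
#' Collapses the random draws of [scenario_runner()] to their mean and
#' standard error; hub and all-features rows pass through (SE missing,
#' as for a single draw).
#'
#' @param results data frame from [scenario_runner()].
#' @return data frame: trait, layer, scenario (`hub`, `random_draw`,
#'   `all`), accuracy, se, n_fits.
#' @export
summarize_scenarios <- function(results) {
  out <- NULL
  for (tr in unique(results$trait)) {
    for (layer in unique(results$layer)) {
      sub <- results[results$trait == tr & results$layer == layer, ]
      if (!nrow(sub)) next
      draws <- sub[grepl("^draw_", sub$scenario), ]
      se <- if (nrow(draws) > 1)
        stats::sd(draws$accuracy) / sqrt(nrow(draws)) else NA_real_
      out <- rbind(
        out,
        data.frame(trait = tr, layer = layer, scenario = "hub",
                   accuracy = sub$accuracy[sub$scenario == "hub"],
                   se = NA_real_, n_fits = 1L),
        if (nrow(draws)) data.frame(
          trait = tr, layer = layer, scenario = "random_draw",
          accuracy = mean(draws$accuracy), se = se,
          n_fits = nrow(draws)),
        data.frame(trait = tr, layer = layer, scenario = "all",
                   accuracy = sub$accuracy[sub$scenario == "all"],
                   se = NA_real_, n_fits = 1L))
    }
  }
  out
}
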