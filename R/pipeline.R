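#' Write a table or matrix as TSV with a parameter header comment
#'
#' Every pipeline output declares the stage and parameters that
#' produced it in a leading `#` comment line, so result files are
#' auditable on their own.
#'
#' @param x matrix or data frame.
#' @param path output path.
#' @param comment header comment (without the leading `#`).
#' @param rownames_as column name under which to keep matrix rownames;
#'   `NULL` drops them.
#' @export
write_tsv_commented <- function(x, path, comment = NULL,
                                rownames_as = "id") {
  if (is.matrix(x)) {
    df <- as.data.frame(x)
    if (!is.null(rownames_as) && !is.null(rownames(x)))
      df <- cbind(stats::setNames(data.frame(rownames(x)), rownames_as),
                  df)
    x <- df
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a pipeline TSV (skipping header comments)
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}

#' Run the full synthetic-study pipeline
#'
#' One-command demo: simulate the two-class diallel study, build the
#' per-class GRMs and PC scores, stratification-correct the omics
#' layers, estimate the fused joint graphical lasso per layer with BIC
#' selection, extract modules / hubs / conserved hubs, integrate hub
#' features with phenotypes by bivariate REML with boundary LRT and
#' FDR, and run the omics-assisted prediction scenarios.  All outputs
#' are TSV files under `out_dir`; a JSON manifest records every stage.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param jgl_grid named list of penalty grids per layer; the default
#'   demo grid is a reduced version of the full study grids so the demo
#'   completes quickly.
#' @param k_hubs hubs per module.
#' @param n_draws random draws in the prediction scenario.
#' @param num_trees random-forest size.
#' @return the run manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = tempfile("poolnet_run_"),
                         jgl_grid = NULL,
                         k_hubs = 5, n_draws = 5, num_trees = 2000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  stamp <- function(stage, params, outputs, t0) {
    manifest[[stage]] <<- list(
      parameters = params, outputs = outputs,
      wall_time_s = round(as.numeric(Sys.time()) - t0, 2))
  }
  if (is.null(jgl_grid))
    jgl_grid <- list(
      gene = list(lambda1 = exp(seq(log(0.05), log(20), length.out = 10)),
                  lambda2 = seq(0, 0.5, length.out = 4)),
      nmr = list(lambda1 = exp(seq(log(0.05), log(20), length.out = 10)),
                 lambda2 = seq(0, 0.5, length.out = 4)))

  ## stage 1: simulate
  t0 <- as.numeric(Sys.time())
  sim <- simulate_study(config)
  outs <- c()
  for (k in 1:2) {
    cl <- paste0("class", k)
    f <- file.path(out_dir, paste0("freqs_", cl, ".tsv"))
    write_tsv_commented(sim$freqs[[cl]]$values, f,
                        sprintf("simulate: seed=%d ploidy=%d pool_size=%s",
                                config$seed, config$ploidy,
                                format(config$pool_size)),
                        rownames_as = "family")
    outs <- c(outs, f)
  }
  f <- file.path(out_dir, "pedigree.tsv")
  write_tsv_commented(sim$pedigree, f, sprintf("simulate: seed=%d",
                                               config$seed))
  outs <- c(outs, f)
  stamp("simulate", list(seed = config$seed), outs, t0)

  ## stage 2: grm
  t0 <- as.numeric(Sys.time())
  outs <- c()
  for (cl in names(sim$grm)) {
    f <- file.path(out_dir, paste0("grm_", cl, ".tsv"))
    write_tsv_commented(sim$grm[[cl]]$G, f,
                        sprintf("grm: ploidy=%d denominator=%.6g",
                                config$ploidy, sim$grm[[cl]]$denominator),
                        rownames_as = "family")
    fp <- file.path(out_dir, paste0("pcs_", cl, ".tsv"))
    write_tsv_commented(sim$grm[[cl]]$pc_scores, fp, "grm: pc scores",
                        rownames_as = "family")
    outs <- c(outs, f, fp)
  }
  stamp("grm", list(ploidy = config$ploidy), outs, t0)

  ## stage 3: preprocess (stratification correction per layer/class)
  t0 <- as.numeric(Sys.time())
  corrected <- list()
  outs <- c()
  for (layer in c("gene", "nmr")) {
    corrected[[layer]] <- list()
    for (cl in names(sim$grm)) {
      X <- sim$omics[[layer]][[cl]]$X
      if (layer == "nmr") X <- pareto_scale(X)
      P <- min(10, nrow(sim$grm[[cl]]$pc_scores),
               ncol(sim$grm[[cl]]$pc_scores))
      Xc <- regress_out_pcs(X, sim$grm[[cl]]$pc_scores, P = P)
      corrected[[layer]][[cl]] <- Xc
      f <- file.path(out_dir, paste0("omics_", layer, "_", cl, ".tsv"))
      write_tsv_commented(Xc, f,
                          sprintf("preprocess: layer=%s pcs=%d%s", layer, P,
                                  if (layer == "nmr") " pareto" else ""),
                          rownames_as = "feature")
      outs <- c(outs, f)
    }
  }
  stamp("preprocess", list(pcs = 10), outs, t0)

  ## stage 4: jgl per layer
  t0 <- as.numeric(Sys.time())
  fits <- list()
  outs <- c()
  for (layer in c("gene", "nmr")) {
    gs <- jgl_grid_search(corrected[[layer]], grid = jgl_grid[[layer]])
    fits[[layer]] <- gs
    f <- file.path(out_dir, paste0("bic_surface_", layer, ".tsv"))
    write_tsv_commented(gs$surface, f,
                        sprintf("jgl: layer=%s grid=%dx%d", layer,
                                length(jgl_grid[[layer]]$lambda1),
                                length(jgl_grid[[layer]]$lambda2)))
    outs <- c(outs, f)
    for (k in 1:2) {
      ft <- file.path(out_dir,
                      paste0("theta_", layer, "_class", k, ".tsv"))
      write_tsv_commented(gs$best$Theta[[k]], ft,
                          sprintf("jgl: lambda1=%.4g lambda2=%.4g",
                                  gs$best$lambda1, gs$best$lambda2),
                          rownames_as = "feature")
      outs <- c(outs, ft)
    }
  }
  stamp("jgl", lapply(fits, function(g)
    list(lambda1 = g$best$lambda1, lambda2 = g$best$lambda2,
         bic = g$best$bic)), outs, t0)

  ## stage 5: network
  t0 <- as.numeric(Sys.time())
  nets <- list()
  outs <- c()
  for (layer in c("gene", "nmr")) {
    ns <- network_stage(fits[[layer]]$best, k_per_module = k_hubs,
                        seed = derive_seed(config$seed, "louvain"))
    nets[[layer]] <- ns
    for (k in 1:2) {
      fh <- file.path(out_dir, paste0("hubs_", layer, "_class", k, ".tsv"))
      write_tsv_commented(ns$hubs[[k]], fh,
                          sprintf("network: k_hubs=%d", k_hubs))
      fm <- file.path(out_dir,
                      paste0("modules_", layer, "_class", k, ".tsv"))
      write_tsv_commented(
        data.frame(feature = names(ns$modules[[k]]$membership),
                   module = as.integer(ns$modules[[k]]$membership)),
        fm, sprintf("network: modularity=%.4f",
                    ns$modules[[k]]$modularity))
      fe <- file.path(out_dir,
                      paste0("edges_", layer, "_class", k, ".tsv"))
      A <- ns$adjacency$A[[k]]
      idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
      write_tsv_commented(
        data.frame(from = rownames(A)[idx[, 1]],
                   to = colnames(A)[idx[, 2]]),
        fe, "network: edge list (i<j)")
      outs <- c(outs, fh, fm, fe)
    }
    fc <- file.path(out_dir, paste0("conserved_hubs_", layer, ".tsv"))
    write_tsv_commented(ns$conserved, fc, "network: conserved hubs")
    outs <- c(outs, fc)
  }
  stamp("network", list(k_hubs = k_hubs), outs, t0)

  ## stage 6: integrate hub features with phenotypes
  t0 <- as.numeric(Sys.time())
  scans <- list()
  for (k in 1:2) {
    cl <- paste0("class", k)
    hub_ids <- unique(unlist(lapply(nets, function(ns)
      ns$conserved$feature)))
    if (!length(hub_ids)) {
      scans[[cl]] <- NULL
      next
    }
    hub_mat <- rbind(
      sim$omics$gene[[cl]]$X[intersect(hub_ids,
                                       rownames(sim$omics$gene[[cl]]$X)),
                             , drop = FALSE],
      sim$omics$nmr[[cl]]$X[intersect(hub_ids,
                                      rownames(sim$omics$nmr[[cl]]$X)),
                            , drop = FALSE])
    scans[[cl]] <- integrate_hubs(hub_mat, sim$pheno[[cl]]$table,
                                  sim$grm[[cl]],
                                  sim$grm[[cl]]$pc_scores)
  }
  wn <- build_weighted_network(scans)
  f <- file.path(out_dir, "weighted_network.tsv")
  write_tsv_commented(wn, f, "integrate: bivariate REML + 0.5df LRT + BH")
  stamp("integrate", list(alpha = 0.05), f, t0)

  ## stage 7: omics-assisted prediction
  t0 <- as.numeric(Sys.time())
  pred <- run_prediction_stage(sim, nets, n_draws = n_draws,
                               num_trees = num_trees,
                               seed = derive_seed(config$seed, "predict"))
  f1 <- file.path(out_dir, "blues.tsv")
  write_tsv_commented(pred$blues, f1, "predict: centred family BLUEs")
  f2 <- file.path(out_dir, "prediction_results.tsv")
  write_tsv_commented(pred$results, f2,
                      sprintf("predict: trees=%d draws=%d", num_trees,
                              n_draws))
  f3 <- file.path(out_dir, "prediction_summary.tsv")
  write_tsv_commented(pred$summary, f3, "predict: aggregated scenarios")
  stamp("predict", list(num_trees = num_trees, n_draws = n_draws),
        c(f1, f2, f3), t0)

  manifest$pipeline <- list(stages = names(manifest),
                            seed = config$seed,
                            version = as.character(
                              utils::packageVersion("poolnet")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, out_dir = out_dir, sim = sim,
                 fits = fits, networks = nets, weighted_network = wn,
                 prediction = pred))
}

# prediction stage: impute frequencies, BLUEs, hub/random/all scenarios
run_prediction_stage <- function(sim, nets, n_draws, num_trees, seed) {
  cfg <- sim$config
  imp <- lapply(sim$freqs, function(f)
    impute_frequencies_chained_rf(f$values, f$chrom,
                                  seed = derive_seed(seed, "impute")))
  blues <- compute_blues(lapply(sim$pheno, `[[`, "table"))
  gene_hub <- nets$gene$conserved$feature
  nmr_hub <- nets$nmr$conserved$feature
  snp_hub <- snps_tagging_hubs(sim$gene_map, gene_hub, sim$snp_map)
  # merge classes: shared SNP panel and feature ids
  snp_all <- rbind(imp$class1, imp$class2)
  gene_all <- rbind(t(sim$omics$gene$class1$X), t(sim$omics$gene$class2$X))
  nmr_all <- rbind(t(sim$omics$nmr$class1$X), t(sim$omics$nmr$class2$X))
  full_sets <- list(snp = snp_all, gene = gene_all, nmr = nmr_all)
  hub_sets <- list(
    snp = snp_all[, intersect(snp_hub, colnames(snp_all)), drop = FALSE],
    gene = gene_all[, intersect(gene_hub, colnames(gene_all)),
                    drop = FALSE],
    nmr = nmr_all[, intersect(nmr_hub, colnames(nmr_all)), drop = FALSE])
  y_by_trait <- list()
  for (tr in unique(blues$trait)) {
    b <- blues[blues$trait == tr, ]
    y <- stats::setNames(b$blue, b$family)
    y_by_trait[[tr]] <- y[rownames(snp_all)]
  }
  keep <- stats::complete.cases(do.call(cbind, y_by_trait))
  full_sets <- lapply(full_sets, function(m) m[keep, , drop = FALSE])
  hub_sets <- lapply(hub_sets, function(m) m[keep, , drop = FALSE])
  y_by_trait <- lapply(y_by_trait, function(y) y[keep])
  results <- scenario_runner(hub_sets, full_sets, y_by_trait,
                             n_draws = n_draws, seed = seed,
                             num_trees = num_trees)
  list(blues = blues, results = results,
       summary = summarize_scenarios(results), imputed = imp)
}

#' Validate pipeline file contracts
#'
#' Checks a pipeline output directory (or explicit file list) for
#' format violations: allele frequencies outside `[0, 1]`, duplicated
#' ids, and sample-id disagreement between the frequency, GRM and
#' omics tables.  Returns a report data frame; a clean run yields zero
#' rows.
#'
#' @param dir pipeline output directory.
#' @return data frame: file, check, detail (one row per violation).
#' @export
validate_io <- function(dir) {
  report <- NULL
  note <- function(file, check, detail)
    report <<- rbind(report, data.frame(file = file, check = check,
                                        detail = detail))
  for (cl in c("class1", "class2")) {
    fq <- file.path(dir, paste0("freqs_", cl, ".tsv"))
    gr <- file.path(dir, paste0("grm_", cl, ".tsv"))
    if (!file.exists(fq) || !file.exists(gr)) next
    fd <- read_tsv_commented(fq)
    vals <- as.matrix(fd[, -1])
    if (any(vals < 0 | vals > 1, na.rm = TRUE))
      note(fq, "frequency_range",
           sprintf("%d cells outside [0,1]",
                   sum(vals < 0 | vals > 1, na.rm = TRUE)))
    if (anyDuplicated(fd[[1]]))
      note(fq, "duplicate_ids", "duplicated family ids")
    gd <- read_tsv_commented(gr)
    if (!identical(as.character(gd[[1]]), as.character(fd[[1]])))
      note(gr, "sample_mismatch",
           paste("GRM families differ from frequency families:",
                 paste(utils::head(setdiff(gd[[1]], fd[[1]])),
                       collapse = ",")))
    for (layer in c("gene", "nmr")) {
      om <- file.path(dir, paste0("omics_", layer, "_", cl, ".tsv"))
      if (!file.exists(om)) next
      od <- read_tsv_commented(om)
      samp <- colnames(od)[-1]
      if (!identical(samp, as.character(fd[[1]])))
        note(om, "sample_mismatch",
             "omics samples differ from frequency families")
      if (anyDuplicated(od[[1]]))
        note(om, "duplicate_ids", "duplicated feature ids")
    }
  }
  if (is.null(report))
    report <- data.frame(file = character(0), check = character(0),
                         detail = character(0))
  report
}
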