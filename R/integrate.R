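#' Pairwise omics-phenotype integration scan
#'
#' Fits the bivariate REML model for every (hub feature, trait) pair of
#' one pedigree class, computes the boundary LRT p-value per pair, and
#' applies Benjamini-Hochberg FDR across traits within each omic
#' feature.
#'
#' @param hub_matrix features x families matrix of hub omic values
#'   (family-level, e.g. the simulated or preprocessed layer restricted
#'   to hubs).
#' @param pheno phenotype table with one or more traits.
#' @param grm `pool_grm` or kernel of the class.
#' @param pc_scores families x >=3 genomic PC scores.
#' @param alpha FDR level.
#' @param ... passed to [bivariate_reml()].
#' @return data frame, one row per pair: feature, trait, rg, genetic
#'   and residual variances, lrt_stat, pvalue, q, significant,
#'   converged.
#' @export
integrate_hubs <- function(hub_matrix, pheno, grm, pc_scores,
                           alpha = 0.05, ...) {
  traits <- unique(pheno$trait)
  spatial_by_trait <- lapply(traits, function(tr) {
    tab <- pheno[pheno$trait == tr, ]
    build_spatial_design(tab[, c("row", "col")])
  })
  names(spatial_by_trait) <- traits
  rows <- NULL
  for (f in rownames(hub_matrix)) {
    for (tr in traits) {
      fit <- bivariate_reml(hub_matrix[f, ], pheno, grm, pc_scores,
                            spatial = spatial_by_trait[[tr]],
                            trait = tr, ...)
      p <- if (fit$converged) lrt_boundary(fit) else NA_real_
      rows <- rbind(rows, data.frame(
        feature = f, trait = tr, rg = fit$rg,
        sigma_u2_ome = fit$sigma_u2_ome,
        sigma_u2_phe = fit$sigma_u2_phe,
        sigma_u_cov = fit$sigma_u_cov,
        lrt_stat = fit$lrt_stat, pvalue = p,
        converged = fit$converged))
    }
  }
  # BH family: across traits within each omic feature
  rows$q <- NA_real_; rows$significant <- FALSE
  for (f in unique(rows$feature)) {
    i <- which(rows$feature == f & !is.na(rows$pvalue))
    if (!length(i)) next
    adj <- bh_fdr(rows$pvalue[i], alpha)
    rows$q[i] <- adj$q
    rows$significant[i] <- adj$significant
  }
  rows
}

#' Omics-phenotype weighted network table
#'
#' Assembles the per-class integration scans into one edge table
#' suitable for graph export, weighting edges by the magnitude of the
#' estimated genetic correlation.  Non-converged pairs are kept with
#' their status so the accounting is complete.
#'
#' @param fits_by_class named list of data frames from
#'   [integrate_hubs()] (one per class).
#' @return data frame: hub, trait, class, rg, weight (`|rg|`), pvalue,
#'   q, significant, converged.
#' @export
build_weighted_network <- function(fits_by_class) {
  out <- NULL
  for (cl in names(fits_by_class)) {
    fb <- fits_by_class[[cl]]
    if (is.null(fb) || !nrow(fb)) next
    out <- rbind(out, data.frame(
      hub = fb$feature, trait = fb$trait, class = cl,
      rg = fb$rg, weight = abs(fb$rg), pvalue = fb$pvalue,
      q = fb$q, significant = fb$significant,
      converged = fb$converged))
  }
  if (is.null(out))
    out <- data.frame(hub = character(0), trait = character(0),
                      class = character(0), rg = numeric(0),
                      weight = numeric(0), pvalue = numeric(0),
                      q = numeric(0), significant = logical(0),
                      converged = logical(0))
  message(sprintf(
    "weighted network: %d edges (%d converged, %d significant)",
    nrow(out), sum(out$converged), sum(out$significant, na.rm = TRUE)))
  out
}
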