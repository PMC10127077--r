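#' Expression filter: minimum median FPKM
#'
#' Retains transcripts whose median FPKM across all samples is at least
#' the threshold (boundary inclusive), discarding transcripts with
#' expression at or near zero everywhere.
#'
#' @param fpkm features x samples matrix of non-negative FPKM values.
#' @param median_fpkm_min threshold on the per-feature median (default
#'   0.5).
#' @return the filtered matrix.
#' @export
filter_transcripts_expression <- function(fpkm, median_fpkm_min = 0.5) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  med <- apply(fpkm, 1, stats::median)
  keep <- med >= median_fpkm_min
  if (!any(keep)) stop("no transcripts pass the median-FPKM filter")
  log_transform(fpkm[keep, , drop = FALSE], fpkm,
                sprintf("median_fpkm>=%g", median_fpkm_min))
}

log_transform <- function(out, input, step) {
  attr(out, "transform_log") <- c(attr(input, "transform_log"), step)
  out
}

#' Network-input expression filter and transform
#'
#' Applies the pre-network transcript rules per pedigree class: (i) drop
#' features with more than 50\% zero samples, (ii) keep features with at
#' least `min_samples` samples at or above `min_reads`, (iii) keep
#' features whose variance of non-zero elements ranks in the top 50th
#' percentile (ties at the median kept).  Feature sets are then
#' intersected across the two classes and each matrix is
#' `log2(x + 1)`-transformed.
#'
#' @param expr_by_class list of two features x samples expression
#'   matrices (shared feature ids).
#' @param zero_frac_max maximum tolerated fraction of zero samples.
#' @param min_samples,min_reads rule (ii) thresholds.
#' @param var_quantile rule (iii) percentile cut on non-zero variance.
#' @return list of two filtered, log2-transformed matrices over the
#'   common surviving features.
#' @export
filter_for_network <- function(expr_by_class, zero_frac_max = 0.5,
                               min_samples = 10, min_reads = 10,
                               var_quantile = 0.5) {
  stopifnot(length(expr_by_class) == 2)
  survivors <- lapply(expr_by_class, function(X) {
    X <- as.matrix(X)
    zero_frac <- rowMeans(X == 0)
    r1 <- zero_frac <= zero_frac_max
    r2 <- rowSums(X >= min_reads) >= min_samples
    keep12 <- r1 & r2
    vnz <- apply(X, 1, function(x) {
      x <- x[x != 0]
      if (length(x) < 2) 0 else stats::var(x)
    })
    cut <- stats::quantile(vnz[keep12], var_quantile, names = FALSE)
    rownames(X)[keep12 & vnz >= cut & vnz > 0]
  })
  common <- intersect(survivors[[1]], survivors[[2]])
  if (!length(common)) stop("no features survive in both classes")
  out <- lapply(expr_by_class, function(X) {
    Y <- log2(as.matrix(X)[common, , drop = FALSE] + 1)
    log_transform(Y, X, "network_filter+log2(x+1)")
  })
  names(out) <- names(expr_by_class)
  out
}

#' SNP hard filters
#'
#' Applies the variant-level rules: biallelic only, missing proportion
#' at most 50\%, mapping quality at least 20, read depth at least 5, and
#' minor allele frequency strictly greater than 0.05.
#'
#' @param variants data frame with columns `n_alleles` (or logical
#'   `biallelic`), `missing` (proportion), `mq`, `depth`, `maf`.
#' @param max_missing,min_mq,min_depth,min_maf thresholds as above
#'   (`min_maf` is strict).
#' @return the surviving rows; the survivor count is reported via
#'   `message()`.
#' @export
filter_snps <- function(variants, max_missing = 0.5, min_mq = 20,
                        min_depth = 5, min_maf = 0.05) {
  bi <- if ("biallelic" %in% names(variants)) variants$biallelic
        else variants$n_alleles == 2
  keep <- bi &
    variants$missing <= max_missing &
    variants$mq >= min_mq &
    variants$depth >= min_depth &
    variants$maf > min_maf
  out <- variants[keep, , drop = FALSE]
  message(sprintf("filter_snps: %d of %d variants retained",
                  nrow(out), nrow(variants)))
  if (!nrow(out)) warning("no variants pass the SNP filters")
  out
}

#' Pareto scaling of NMR features
#'
#' Per feature: subtract the mean and divide by the square root of the
#' standard deviation, damping the dominance of high-intensity spectral
#' regions while preserving more of the data structure than unit-variance
#' scaling.  Constant features are left centred (all zero) and flagged.
#'
#' @param nmr features x samples matrix of bucket intensities.
#' @return scaled matrix; attribute `constant_features` lists flagged
#'   ids.
#' @export
pareto_scale <- function(nmr) {
  nmr <- as.matrix(nmr)
  mu <- rowMeans(nmr)
  sdv <- apply(nmr, 1, stats::sd)
  centred <- nmr - mu
  scl <- ifelse(sdv > 0, sqrt(sdv), 1)
  out <- centred / scl
  out <- log_transform(out, nmr, "pareto_scale")
  attr(out, "constant_features") <- rownames(nmr)[sdv == 0]
  out
}

#' Regress population-stratification PCs out of each feature
#'
#' Fits, feature by feature, an ordinary-least-squares model of the
#' feature on an intercept plus the top `P` genomic principal-component
#' scores and returns the residuals: the stratification-corrected omics
#' matrix used for network estimation.  Collinear PC columns are dropped
#' with a warning.
#'
#' @param omics features x samples matrix.
#' @param pc_scores samples x k matrix of PC scores (rows aligned with
#'   the omics columns).
#' @param P number of leading PCs to regress out (default 10).
#' @return features x samples matrix of residuals.
#' @export
regress_out_pcs <- function(omics, pc_scores, P = 10) {
  omics <- as.matrix(omics)
  pc_scores <- as.matrix(pc_scores)
  if (nrow(pc_scores) != ncol(omics))
    stop("pc_scores rows must align with omics samples")
  if (P > ncol(pc_scores)) stop("P exceeds the available PCs")
  X <- cbind(1, pc_scores[, seq_len(P), drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X, do.NULL = FALSE)[-seq_len(qrX$rank)]
    warning("rank-deficient PC design; dropping ",
            ncol(X) - qrX$rank, " collinear column(s)")
  }
  res <- t(qr.resid(qrX, t(omics)))
  dimnames(res) <- dimnames(omics)
  log_transform(res, omics, sprintf("regress_out_pcs(P=%d)", P))
}
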