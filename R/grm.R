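#' Allele-frequency matrix for family pools
#'
#' Light container for a samples x SNPs matrix of alternative-allele
#' frequencies obtained from pooled sequencing of full-sib families.
#' Frequencies live in \[0, 1\]; missing cells are allowed and handled at
#' GRM-construction time.
#'
#' @param values numeric matrix, samples in rows, SNPs in columns, entries
#'   in \[0, 1\] or `NA`.
#' @param chrom character or integer vector of chromosome labels, one per
#'   SNP column.
#' @param pos integer vector of physical positions, one per SNP column.
#' @param ploidy ploidy of the breeding material (4 for tetraploids).
#' @param depth optional per-sample mean read depth (used by the diagonal
#'   correction).
#' @return an object of class `pool_freq`.
#' @export
pool_freq <- function(values, chrom = NULL, pos = NULL, ploidy = 4L,
                      depth = NULL) {
  values <- as.matrix(values)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("allele frequencies must lie in [0, 1]")
  if (is.null(colnames(values))) {
    if (!is.null(chrom) && !is.null(pos))
      colnames(values) <- paste0(chrom, ":", pos)
    else
      colnames(values) <- paste0("snp", seq_len(ncol(values)))
  }
  if (is.null(rownames(values)))
    rownames(values) <- paste0("fam", seq_len(nrow(values)))
  if (!is.null(pos)) {
    pos <- as.integer(pos)
    if (any(pos < 0)) stop("positions must be non-negative")
  }
  if (anyDuplicated(colnames(values))) stop("snp ids must be unique")
  structure(list(values = values, chrom = chrom, pos = pos,
                 ploidy = as.integer(ploidy), depth = depth),
            class = "pool_freq")
}

#' @export
print.pool_freq <- function(x, ...) {
  cat(sprintf("pool_freq: %d samples x %d SNPs (ploidy %d, %.1f%% missing)\n",
              nrow(x$values), ncol(x$values), x$ploidy,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Column-centre an allele-frequency matrix
#'
#' Computes `M = F - Fbar`, the column-centred frequency matrix entering
#' the genomic relationship matrix, and records the pre-centring column
#' means `p_hat` (the observed alternative-allele frequency at each
#' locus).  Missing cells are mean-imputed per column before centring, so
#' they contribute exactly zero to the centred matrix.
#'
#' @param freqs a [pool_freq] object or bare samples x SNPs matrix.
#' @return list with `M` (centred matrix), `p_hat` (pre-centring column
#'   means) and `ploidy`, class `centered_freq`.
#' @export
center_frequencies <- function(freqs) {
  if (inherits(freqs, "pool_freq")) {
    F <- freqs$values
    ploidy <- freqs$ploidy
  } else {
    F <- as.matrix(freqs)
    ploidy <- attr(freqs, "ploidy") %||% 4L
  }
  if (any(colSums(!is.na(F)) == 0))
    stop("column(s) entirely missing; drop them before centring")
  p_hat <- colMeans(F, na.rm = TRUE)
  M <- sweep(F, 2, p_hat, "-")
  M[is.na(M)] <- 0
  structure(list(M = M, p_hat = p_hat, ploidy = as.integer(ploidy)),
            class = "centered_freq")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pooled-allele-frequency genomic relationship matrix
#'
#' Realized-relationship kernel for family pools:
#' `G = MM' / ((1/ploidy) * sum_j p_hat_j (1 - p_hat_j))`, the
#' VanRaden-type cross-product of the column-centred frequency matrix
#' scaled by the expected SNP variance for the material's ploidy.  By
#' construction the grand sum of `G` is zero.
#'
#' @param M a `centered_freq` object from [center_frequencies()] (or a
#'   centred matrix with a `p_hat` attribute).
#' @param ploidy ploidy of the breeding material; taken from `M` when
#'   omitted.
#' @return object of class `pool_grm`: list with `G`, `M`, `p_hat`,
#'   `denominator`, `ploidy`, `corrected` flag.
#' @export
compute_grm <- function(M, ploidy = NULL) {
  if (inherits(M, "centered_freq")) {
    p_hat <- M$p_hat
    ploidy <- ploidy %||% M$ploidy
    M <- M$M
  } else {
    p_hat <- attr(M, "p_hat")
    if (is.null(p_hat)) stop("M must carry pre-centring column means")
    ploidy <- ploidy %||% 4L
  }
  denom <- sum(p_hat * (1 - p_hat)) / ploidy
  if (denom <= .Machine$double.eps)
    stop("all SNPs monomorphic: GRM denominator is zero")
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  structure(list(G = G, M = M, p_hat = p_hat, denominator = denom,
                 ploidy = as.integer(ploidy), corrected = FALSE,
                 pc_scores = NULL, pc_varfrac = NULL),
            class = "pool_grm")
}

#' @export
print.pool_grm <- function(x, ...) {
  cat(sprintf("pool_grm: %d x %d (denominator %.4g%s)\n",
              nrow(x$G), ncol(x$G), x$denominator,
              if (x$corrected) ", diagonal-corrected" else ""))
  invisible(x)
}

#' Diagonal correction for pool-sequencing sampling noise
#'
#' Read sampling from a finite pool inflates the GRM diagonal: the
#' observed frequency of sample i at locus j is a binomial draw around the
#' true pool frequency, and that sampling variance accumulates only on
#' `G_ii`.  The default correction subtracts
#' `c_i = sum_j p_hat_j(1 - p_hat_j) / (depth_i * ploidy) / denominator`,
#' the binomial read-sampling variance summed over loci on the kernel
#' scale.  Off-diagonals are untouched.  The correction function is
#' pluggable for other noise models.
#'
#' @param grm a `pool_grm`.
#' @param depth per-sample mean read depth (recycled if scalar).
#' @param correction_fn optional function `(grm, depth)` returning the
#'   per-sample inflation `c_i` to subtract.
#' @param floor smallest admissible diagonal value after correction.
#' @return the corrected `pool_grm` (field `diag_correction` holds `c_i`).
#' @export
diagonal_correction <- function(grm, depth, correction_fn = NULL,
                                floor = 1e-6) {
  stopifnot(inherits(grm, "pool_grm"))
  if (any(depth <= 0)) stop("depth must be positive")
  n <- nrow(grm$G)
  depth <- rep_len(depth, n)
  ci <- if (is.null(correction_fn)) {
    sum(grm$p_hat * (1 - grm$p_hat)) / (depth * grm$ploidy) / grm$denominator
  } else {
    correction_fn(grm, depth)
  }
  d <- diag(grm$G) - ci
  if (any(d < floor)) {
    warning("diagonal correction drove ", sum(d < floor),
            " diagonal entries below ", floor, "; floored")
    d <- pmax(d, floor)
  }
  diag(grm$G) <- d
  grm$corrected <- TRUE
  grm$diag_correction <- ci
  grm
}

#' Principal-component scores of a genomic relationship matrix
#'
#' Eigendecomposes `G` and returns the top `k` principal-component scores
#' (eigenvectors scaled by the square root of their eigenvalues) together
#' with explained-variance fractions.  Negative eigenvalues, which can
#' arise after the diagonal correction, are floored at zero for the
#' variance fractions.
#'
#' @param grm a `pool_grm` or a symmetric matrix.
#' @param k number of components to retain (default 10).
#' @return list with `scores` (n x k), `varfrac` (length k), `values`
#'   (all eigenvalues).
#' @export
grm_pca <- function(grm, k = 10) {
  G <- if (inherits(grm, "pool_grm")) grm$G else as.matrix(grm)
  n <- nrow(G)
  if (k > n) stop("k exceeds the matrix dimension")
  ed <- eigen(G, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  scores <- ed$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(k)]), k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  tot <- sum(lam)
  varfrac <- if (tot > 0) lam[seq_len(k)] / tot else rep(1 / n, k)
  list(scores = scores, varfrac = varfrac, values = ed$values)
}

#' One-call GRM construction from frequencies
#'
#' Centres, builds the kernel, optionally applies the diagonal
#' correction, and attaches PC scores.
#'
#' @inheritParams center_frequencies
#' @param ploidy ploidy of the material.
#' @param depth per-sample depth for the diagonal correction; `NULL`
#'   skips the correction.
#' @param pcs number of PC scores to attach.
#' @return a `pool_grm` with `pc_scores` and `pc_varfrac` filled.
#' @export
grm_from_frequencies <- function(freqs, ploidy = NULL, depth = NULL,
                                 pcs = 10) {
  cf <- center_frequencies(freqs)
  if (!is.null(ploidy)) cf$ploidy <- as.integer(ploidy)
  grm <- compute_grm(cf)
  if (is.null(depth) && inherits(freqs, "pool_freq")) depth <- freqs$depth
  if (!is.null(depth)) grm <- diagonal_correction(grm, depth)
  pcs <- min(pcs, nrow(grm$G))
  pca <- grm_pca(grm, pcs)
  grm$pc_scores <- pca$scores
  grm$pc_varfrac <- pca$varfrac
  grm
}
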