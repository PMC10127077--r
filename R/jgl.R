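#' Per-class empirical covariance matrices
#'
#' Computes, for each pedigree class, `S = (1/n) X X'` over samples,
#' where `X` is the features x samples matrix of stratification-corrected
#' omics values (zero mean per feature by construction).  The divisor is
#' `n`, not `n - 1`, matching the likelihood in the joint graphical
#' lasso.
#'
#' @param X_by_class list of features x samples matrices (same feature
#'   set and order in every class).
#' @return object of class `cov_set`: list with `S` (list of p x p
#'   matrices), `n` (per-class sample counts), `feature_ids`.
#' @export
empirical_covariances <- function(X_by_class) {
  stopifnot(is.list(X_by_class), length(X_by_class) >= 1)
  p <- nrow(X_by_class[[1]])
  ids <- rownames(X_by_class[[1]])
  S <- lapply(X_by_class, function(X) {
    X <- as.matrix(X)
    if (nrow(X) != p) stop("feature dimension differs across classes")
    n <- ncol(X)
    if (n < 3) stop("need at least 3 samples per class")
    tcrossprod(X) / n
  })
  structure(list(S = S, n = vapply(X_by_class, ncol, 1L),
                 feature_ids = ids),
            class = "cov_set")
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fused joint graphical lasso for two pedigree classes (ADMM)
#'
#' Estimates two sparse precision matrices by maximizing the penalized
#' Gaussian log-likelihood
#' `sum_k n_k (log det Theta_k - tr(S_k Theta_k)) - P(Theta)` with
#' `P = lambda1 * sum_k sum_{i != j} |theta_k,ij| +
#'  lambda2 * sum_{i,j} |theta_1,ij - theta_2,ij|`:
#' an off-diagonal lasso penalty per class plus a fused penalty shrinking
#' the two classes toward each other (the fused term also acts on the
#' diagonal).  Solved by ADMM: the Theta update is the spectral
#' (eigenvalue) step, which keeps every iterate positive definite; the
#' consensus update applies the exact closed-form fused-pair proximal
#' operator followed by soft thresholding.
#'
#' @param S_set a `cov_set` from [empirical_covariances()].
#' @param lambda1 sparsity penalty (> 0).
#' @param lambda2 fusion penalty (>= 0).
#' @param rho initial ADMM penalty parameter (adaptively rescaled).
#' @param eps_abs,eps_rel stopping tolerances on the primal and dual
#'   residuals.
#' @param max_iter iteration cap; non-convergence returns the best
#'   iterate with `converged = FALSE` and a warning.
#' @param zero_tol entries below this magnitude are set to exactly zero.
#' @param weights class weights on the log-likelihood term: `"equal"`
#'   (each class weighted 1, the joint-graphical-lasso convention under
#'   which a given `lambda1` means the same soft threshold regardless
#'   of sample size) or `"n"` (weight by `n_k`, the literal likelihood
#'   scaling; penalties are then relative to `n_k`).
#' @param warm optional previous `jgl_fit` used to warm-start.
#' @return object of class `jgl_fit`: `Theta` (list of two sparse,
#'   positive-definite precision matrices), `lambda1`, `lambda2`,
#'   `converged`, `iterations`, `partial_correlations`.
#' @export
fused_jgl <- function(S_set, lambda1, lambda2, rho = 1,
                      eps_abs = 1e-6, eps_rel = 1e-5,
                      max_iter = 500, zero_tol = 1e-6,
                      weights = c("equal", "n"), warm = NULL) {
  stopifnot(inherits(S_set, "cov_set"))
  if (lambda1 <= 0) stop("lambda1 must be > 0")
  if (lambda2 < 0) stop("lambda2 must be >= 0")
  weights <- match.arg(weights)
  K <- length(S_set$S)
  stopifnot(K == 2)
  p <- nrow(S_set$S[[1]])
  nk <- if (weights == "n") as.numeric(S_set$n) else rep(1, K)
  S <- lapply(S_set$S, function(s) (s + t(s)) / 2)
  if (!is.null(warm)) {
    Z <- lapply(warm$Theta, identity)
    U <- warm$U %||% lapply(1:K, function(k) matrix(0, p, p))
    rho <- warm$rho %||% rho
  } else {
    Z <- lapply(1:K, function(k) diag(1 / pmax(diag(S[[k]]), 1e-4)))
    U <- lapply(1:K, function(k) matrix(0, p, p))
  }
  Theta <- Z
  offd <- matrix(TRUE, p, p); diag(offd) <- FALSE
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    # Theta step: spectral update per class
    for (k in 1:K) {
      C <- Z[[k]] - U[[k]] - (nk[k] / rho) * S[[k]]
      C <- (C + t(C)) / 2
      ed <- eigen(C, symmetric = TRUE)
      th <- (ed$values + sqrt(ed$values^2 + 4 * nk[k] / rho)) / 2
      Theta[[k]] <- ed$vectors %*% (th * t(ed$vectors))
    }
    # Z step: fused prox then soft threshold (exact for K = 2)
    A1 <- Theta[[1]] + U[[1]]
    A2 <- Theta[[2]] + U[[2]]
    d <- A1 - A2
    shift <- pmin(abs(d) / 2, lambda2 / rho) * sign(d)
    Y1 <- A1 - shift
    Y2 <- A2 + shift
    Zold <- Z
    Z1 <- Y1; Z2 <- Y2
    Z1[offd] <- soft_threshold(Y1[offd], lambda1 / rho)
    Z2[offd] <- soft_threshold(Y2[offd], lambda1 / rho)
    Z <- list((Z1 + t(Z1)) / 2, (Z2 + t(Z2)) / 2)
    # dual update
    r2 <- 0; s2 <- 0; thn <- 0; zn <- 0; un <- 0
    for (k in 1:K) {
      U[[k]] <- U[[k]] + Theta[[k]] - Z[[k]]
      r2 <- r2 + sum((Theta[[k]] - Z[[k]])^2)
      s2 <- s2 + sum((Z[[k]] - Zold[[k]])^2)
      thn <- thn + sum(Theta[[k]]^2)
      zn <- zn + sum(Z[[k]]^2)
      un <- un + sum(U[[k]]^2)
    }
    r <- sqrt(r2); s <- rho * sqrt(s2)
    eps_pri <- sqrt(K * p * p) * eps_abs +
      eps_rel * max(sqrt(thn), sqrt(zn))
    eps_dua <- sqrt(K * p * p) * eps_abs + eps_rel * rho * sqrt(un)
    if (r <= eps_pri && s <= eps_dua) { converged <- TRUE; break }
    if (r > 10 * s) {
      rho <- rho * 2; U <- lapply(U, function(u) u / 2)
    } else if (s > 10 * r) {
      rho <- rho / 2; U <- lapply(U, function(u) u * 2)
    }
  }
  if (!converged)
    warning("fused_jgl: not converged in ", max_iter,
            " iterations (lambda1=", lambda1, ", lambda2=", lambda2, ")")
  # exact sparsity from the consensus variable; PD from the spectral step
  Theta_out <- lapply(1:K, function(k) {
    Th <- (Theta[[k]] + t(Theta[[k]])) / 2
    Th[offd & (Z[[k]] == 0)] <- 0
    Th[offd & (abs(Th) < zero_tol)] <- 0
    dimnames(Th) <- list(S_set$feature_ids, S_set$feature_ids)
    Th
  })
  fit <- structure(list(Theta = Theta_out, lambda1 = lambda1,
                        lambda2 = lambda2, converged = converged,
                        iterations = it, n = S_set$n,
                        feature_ids = S_set$feature_ids,
                        U = U, rho = rho),
                   class = "jgl_fit")
  fit$partial_correlations <- lapply(Theta_out, partial_correlations)
  fit
}

#' @export
print.jgl_fit <- function(x, ...) {
  ec <- vapply(x$Theta, function(t) sum(t[upper.tri(t)] != 0), 1L)
  cat(sprintf(
    "jgl_fit: lambda1=%.4g lambda2=%.4g, edges %s, %sconverged (%d it)\n",
    x$lambda1, x$lambda2, paste(ec, collapse = "/"),
    if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' BIC of a fused JGL fit
#'
#' `BIC = sum_k [ n_k {tr(S_k Theta_k) - log det Theta_k}
#'              + log(n_k) * #\{i <= j : theta_k,ij != 0\} ]`,
#' the Gaussian deviance plus a complexity charge counting nonzero
#' entries on and above the diagonal.
#'
#' @param fit a `jgl_fit`.
#' @param S_set the `cov_set` the fit was computed from.
#' @return scalar BIC (smaller is better).
#' @export
bic_jgl <- function(fit, S_set) {
  stopifnot(inherits(fit, "jgl_fit"), inherits(S_set, "cov_set"))
  total <- 0
  for (k in seq_along(fit$Theta)) {
    Th <- fit$Theta[[k]]
    R <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(R)) stop("precision estimate is not positive definite")
    logdet <- 2 * sum(log(diag(R)))
    nk <- as.numeric(S_set$n[k])
    nedge <- sum(Th[upper.tri(Th, diag = TRUE)] != 0)
    total <- total + nk * (sum(S_set$S[[k]] * Th) - logdet) +
      log(nk) * nedge
  }
  total
}

#' Support-constrained Gaussian MLE (covariance selection)
#'
#' Maximizes `log det Theta - tr(S Theta)` over precision matrices with
#' a fixed zero pattern, by blockwise coordinate descent (the graphical
#' lasso's covariance-update sweep with unpenalized least squares on
#' each column's active set).  Used to evaluate model-selection
#' criteria at the maximized likelihood of a candidate support rather
#' than at shrunken penalized estimates.
#'
#' @param S empirical covariance.
#' @param support symmetric logical (or 0/1) matrix; off-diagonal
#'   `FALSE` entries are constrained to zero.
#' @param tol,max_iter convergence controls on the covariance iterate.
#' @return the constrained precision MLE, or `NULL` when the MLE does
#'   not exist (support too dense for the sample size).
#' @export
ggm_refit <- function(S, support, tol = 1e-7, max_iter = 100) {
  p <- nrow(S)
  W <- S
  B <- matrix(0, p - 1, p)
  supp <- support != 0
  diag(supp) <- FALSE
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      act <- which(supp[-j, j])
      beta <- rep(0, p - 1)
      if (length(act)) {
        W11 <- W[-j, -j, drop = FALSE]
        A <- W11[act, act, drop = FALSE]
        b <- tryCatch(solve(A, S[-j, j][act]), error = function(e) NULL)
        if (is.null(b))  # dense support near n <= |active|: ridge it
          b <- tryCatch(solve(A + diag(1e-6 * mean(diag(A)),
                                       length(act)),
                              S[-j, j][act]),
                        error = function(e) NULL)
        if (is.null(b)) return(NULL)
        beta[act] <- b
        W[-j, j] <- W[j, -j] <- W11 %*% beta
      } else {
        W[-j, j] <- W[j, -j] <- 0
      }
      B[, j] <- beta
    }
    if (max(abs(W - W_old)) < tol) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tjj <- 1 / (W[j, j] - sum(W[-j, j] * B[, j]))
    Theta[j, j] <- tjj
    Theta[-j, j] <- -B[, j] * tjj
  }
  Theta <- (Theta + t(Theta)) / 2
  dimnames(Theta) <- dimnames(S)
  Theta
}

#' BIC of a fit's support at the refitted maximum likelihood
#'
#' Same complexity charge as [bic_jgl()], but the likelihood term is
#' evaluated at the support-constrained MLE ([ggm_refit()]) instead of
#' the shrunken penalized estimate -- the literal reading of BIC's
#' maximized-likelihood term.  Penalized estimates understate the fit
#' of sparse models (their retained entries are biased toward zero),
#' which drags the selection toward over-dense supports; refitting
#' removes that bias from the comparison.
#'
#' @inheritParams bic_jgl
#' @return scalar BIC.
#' @export
bic_jgl_refit <- function(fit, S_set) {
  total <- 0
  for (k in seq_along(fit$Theta)) {
    supp <- fit$Theta[[k]] != 0
    Th <- ggm_refit(S_set$S[[k]], supp)
    if (is.null(Th)) return(Inf)
    R <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    nk <- as.numeric(S_set$n[k])
    total <- total + nk * (sum(S_set$S[[k]] * Th) - 2 * sum(log(diag(R)))) +
      log(nk) * sum(supp[upper.tri(supp, diag = TRUE)])
  }
  total
}

#' Default penalty grids
#'
#' The metabolomics grid is 30 log-spaced `lambda1` values from 0.01 to
#' 20 crossed with 15 equally spaced `lambda2` values from 0 to 0.5; the
#' transcriptome grid spans the same ranges with 15 and 10 values.
#'
#' @param layer `"nmr"` or `"gene"`.
#' @return list with `lambda1` and `lambda2` vectors.
#' @export
default_penalty_grid <- function(layer = c("nmr", "gene")) {
  layer <- match.arg(layer)
  if (layer == "nmr")
    list(lambda1 = exp(seq(log(0.01), log(20), length.out = 30)),
         lambda2 = seq(0, 0.5, length.out = 15))
  else
    list(lambda1 = exp(seq(log(0.01), log(20), length.out = 15)),
         lambda2 = seq(0, 0.5, length.out = 10))
}

#' BIC grid search over the fused-JGL penalties
#'
#' Fits every `(lambda1, lambda2)` combination, scanning `lambda1` from
#' sparse to dense for each fixed `lambda2` with warm starts, and
#' returns the minimum-BIC fit together with the full BIC surface and
#' per-class / shared edge counts.  BIC ties are broken toward the
#' larger `lambda1` (the sparser model).
#'
#' @param X_by_class list of two features x samples matrices.
#' @param grid list with `lambda1`, `lambda2` (see
#'   [default_penalty_grid()]).
#' @param bic likelihood evaluation for the selection criterion:
#'   `"refit"` (default) scores each candidate support at its
#'   constrained maximum likelihood ([bic_jgl_refit()]); `"penalized"`
#'   scores the shrunken estimates directly ([bic_jgl()]).
#' @param standardize scale each feature to unit variance before the
#'   covariances (default `TRUE`): the penalty grids assume
#'   correlation-scale data, and partial-correlation supports are
#'   unaffected by per-feature scaling.
#' @param ... further arguments to [fused_jgl()].
#' @return list with `best` (the selected `jgl_fit`), `surface` (data
#'   frame: lambda1, lambda2, bic, edges per class, shared edges,
#'   converged) and `S_set`.
#' @export
jgl_grid_search <- function(X_by_class, grid = default_penalty_grid("nmr"),
                            bic = c("refit", "penalized"),
                            standardize = TRUE, ...) {
  bic <- match.arg(bic)
  bic_fn <- if (bic == "refit") bic_jgl_refit else bic_jgl
  if (!length(grid$lambda1) || is.null(grid$lambda2))
    stop("penalty grid is empty")
  if (standardize)
    X_by_class <- lapply(X_by_class, function(X) {
      s <- apply(X, 1, stats::sd)
      X / pmax(s, .Machine$double.eps)
    })
  S_set <- empirical_covariances(X_by_class)
  l1s <- sort(grid$lambda1, decreasing = TRUE)
  surface <- NULL
  best <- NULL; best_bic <- Inf
  any_conv <- FALSE
  for (l2 in grid$lambda2) {
    warm <- NULL
    for (l1 in l1s) {
      fit <- suppressWarnings(
        fused_jgl(S_set, lambda1 = l1, lambda2 = l2, warm = warm, ...))
      warm <- fit
      any_conv <- any_conv || fit$converged
      ec <- count_edges(fit$Theta)
      b <- bic_fn(fit, S_set)
      surface <- rbind(surface, data.frame(
        lambda1 = l1, lambda2 = l2, bic = b,
        edges_class1 = ec$per_class[1], edges_class2 = ec$per_class[2],
        edges_shared = ec$shared, converged = fit$converged))
      if (fit$converged &&
          (b < best_bic - 1e-9 ||
           (abs(b - best_bic) <= 1e-9 && !is.null(best) &&
            l1 > best$lambda1))) {
        best_bic <- b
        fit$bic <- b
        best <- fit
      }
    }
  }
  if (!any_conv) stop("no (lambda1, lambda2) combination converged")
  if (is.null(best)) stop("no converged fit available for selection")
  best$U <- NULL
  list(best = best, surface = surface, S_set = S_set)
}

#' Edge counts of a precision (or adjacency) set
#'
#' Counts off-diagonal support over unordered pairs `i < j` per class
#' and the edges common to both classes.
#'
#' @param Theta list of two symmetric matrices.
#' @return list with `per_class` and `shared`.
#' @export
count_edges <- function(Theta) {
  ut <- upper.tri(Theta[[1]])
  sup <- lapply(Theta, function(t) t[ut] != 0)
  list(per_class = vapply(sup, sum, 1L),
       shared = sum(sup[[1]] & sup[[2]]))
}

#' Partial correlations from a precision matrix
#'
#' `pcor_ij = -theta_ij / sqrt(theta_ii * theta_jj)` off-diagonal, with
#' unit diagonal.  Zeros in the precision stay exactly zero.
#'
#' @param Theta symmetric positive-definite precision matrix.
#' @return matrix of partial correlations.
#' @export
partial_correlations <- function(Theta) {
  d <- sqrt(diag(Theta))
  P <- -Theta / tcrossprod(d)
  diag(P) <- 1
  P
}
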