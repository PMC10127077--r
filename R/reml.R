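#' @name reml-engine
#' @title REML machinery for genomic mixed models
#' @description Internal-but-exported building blocks: a dense
#'   restricted-likelihood evaluator for arbitrary variance structures,
#'   an eigendecomposition fast path for single-kernel models, and
#'   derivative-free REML drivers built on them.  All log-likelihoods
#'   share the same constant (`-(n-q)/2 log(2*pi)` convention, no
#'   `log|X'X|` term) so nested models are directly comparable.
NULL

# "bend" a kernel to positive semi-definiteness: the diagonal-corrected
# GRM can carry small negative eigenvalues (of order 1/depth), which
# REML cannot tolerate when residual variances approach zero
bend_psd <- function(G, floor = 1e-6) {
  ed <- eigen(G, symmetric = TRUE)
  if (min(ed$values) >= floor) return(G)
  Gb <- ed$vectors %*% (pmax(ed$values, floor) * t(ed$vectors))
  dimnames(Gb) <- dimnames(G)
  Gb
}

# drop aliased columns of a design matrix, warning with their names
prune_design <- function(X, label = "design") {
  X <- as.matrix(X)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- q$pivot[seq_len(q$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning(sprintf("%s: dropping aliased column(s) %s", label,
                    paste(dropped, collapse = ", ")))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Restricted log-likelihood for a dense covariance
#'
#' @param y response vector.
#' @param X full-rank fixed-effects design.
#' @param V phenotypic covariance matrix.
#' @param want_P also return the projection matrix `P` (needed by the
#'   average-information updates).
#' @return list with `loglik`, `beta`, `beta_cov`, `Py`; `loglik = -Inf`
#'   when `V` or `X'V^-1 X` is not positive definite.
#' @export
reml_loglik_dense <- function(y, X, V, want_P = FALSE) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  Viy <- backsolve(R, forwardsolve(R, y, transpose = TRUE, upper.tri = TRUE))
  ViX <- backsolve(R, forwardsolve(R, X, transpose = TRUE, upper.tri = TRUE))
  XtViX <- crossprod(X, ViX)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(list(loglik = -Inf))
  XtViy <- crossprod(X, Viy)
  beta <- backsolve(Rx, forwardsolve(Rx, XtViy, transpose = TRUE,
                                     upper.tri = TRUE))
  quad <- sum(y * Viy) - sum(XtViy * beta)
  n <- length(y); qf <- ncol(X)
  ll <- -0.5 * ((n - qf) * log(2 * pi) + 2 * sum(log(diag(R))) +
                2 * sum(log(diag(Rx))) + quad)
  out <- list(loglik = ll, beta = drop(beta), beta_cov = chol2inv(Rx),
              Py = Viy - ViX %*% beta)
  if (want_P) {
    Vi <- chol2inv(R)
    out$P <- Vi - ViX %*% chol2inv(Rx) %*% t(ViX)
  }
  out
}

# average-information REML for V(theta) = sum_i theta_i * M_i with
# box/correlation constraints; returns NULL if it fails to make progress
ai_reml_linear <- function(y, X, M, theta, lower,
                           cor_triplet = NULL, max_iter = 60,
                           tol = 1e-8) {
  nth <- length(M)
  buildV <- function(th) {
    V <- th[1] * M[[1]]
    for (i in 2:nth) V <- V + th[i] * M[[i]]
    V
  }
  admissible <- function(th) {
    if (any(th[-cor_triplet[3]] < lower[-cor_triplet[3]])) return(FALSE)
    if (!is.null(cor_triplet)) {
      s1 <- th[cor_triplet[1]]; s2 <- th[cor_triplet[2]]
      if (abs(th[cor_triplet[3]]) > 0.995 * sqrt(s1 * s2)) return(FALSE)
    }
    TRUE
  }
  cur <- reml_loglik_dense(y, X, buildV(theta), want_P = TRUE)
  if (!is.finite(cur$loglik)) return(NULL)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- cur$P; Py <- drop(cur$Py)
    Tm <- vapply(M, function(m) drop(m %*% Py), numeric(length(y)))
    score <- vapply(seq_len(nth), function(i)
      -0.5 * (sum(P * M[[i]]) - sum(Py * Tm[, i])), 0)
    AI <- 0.5 * crossprod(Tm, P %*% Tm)
    step <- tryCatch(solve(AI + diag(1e-8 * max(diag(AI)), nth), score),
                     error = function(e) NULL)
    if (is.null(step)) break
    improved <- FALSE
    for (h in 0:12) {
      cand <- theta + step / 2^h
      # pull variances hitting the floor back onto it
      cand[-cor_triplet[3]] <- pmax(cand[-cor_triplet[3]],
                                    lower[-cor_triplet[3]])
      if (!admissible(cand)) next
      trial <- reml_loglik_dense(y, X, buildV(cand))
      if (is.finite(trial$loglik) &&
          trial$loglik >= cur$loglik - 1e-10) {
        delta <- trial$loglik - cur$loglik
        theta <- cand
        cur <- reml_loglik_dense(y, X, buildV(cand), want_P = TRUE)
        improved <- TRUE
        if (delta < tol && it > 2) converged <- TRUE
        break
      }
    }
    if (!improved || converged) {
      converged <- converged || improved
      break
    }
  }
  list(theta = theta, loglik = cur$loglik, converged = converged,
       iterations = it)
}

#' Dense REML over variance components
#'
#' Maximizes the restricted likelihood of
#' `y = X b + sum_r u_r + e`, `u_r ~ N(0, sigma_r^2 V_r)`,
#' `e ~ N(0, sigma_e^2 I)` by Nelder-Mead over log-variances.
#'
#' @param y,X response and (full-rank) fixed design.
#' @param structs list of n x n PSD structure matrices `V_r`.
#' @param init optional initial variances (length `length(structs)+1`,
#'   residual last).
#' @param max_iter optimizer iteration cap.
#' @return list: `sigma2` (named, residual last), `loglik`, `beta`,
#'   `beta_cov`, `converged`.
#' @export
reml_dense <- function(y, X, structs, init = NULL, max_iter = 500) {
  n <- length(y)
  nr <- length(structs)
  vy <- stats::var(y)
  if (is.null(init)) init <- rep(vy / (nr + 1), nr + 1)
  init <- pmax(init, vy * 1e-4)
  I_n <- diag(n)
  nll <- function(lt) {
    s2 <- exp(lt)
    if (any(!is.finite(s2)) || any(s2 > vy * 1e6)) return(1e10)
    V <- s2[nr + 1] * I_n
    for (r in seq_len(nr)) V <- V + s2[r] * structs[[r]]
    ll <- reml_loglik_dense(y, X, V)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(log(init), nll, method = "Nelder-Mead",
                      control = list(maxit = max_iter,
                                     reltol = 1e-10))
  s2 <- exp(opt$par)
  V <- s2[nr + 1] * I_n
  for (r in seq_len(nr)) V <- V + s2[r] * structs[[r]]
  fin <- reml_loglik_dense(y, X, V)
  names(s2) <- c(names(structs) %||% paste0("vc", seq_len(nr)), "residual")
  if (length(fin$beta) == ncol(X)) names(fin$beta) <- colnames(X)
  list(sigma2 = s2, loglik = fin$loglik, beta = fin$beta,
       beta_cov = fin$beta_cov, converged = opt$convergence == 0)
}

#' Single-kernel REML via eigendecomposition
#'
#' Fast path for `y = X b + u + e`, `u ~ N(0, G sigma_u^2)`: rotate by
#' the eigenvectors of `G`, profile out the residual variance, and
#' optimize the variance ratio in one dimension.
#'
#' @param y,X response and fixed design.
#' @param G kernel matrix (or a precomputed `eigen()` of it in `Geig`).
#' @param Geig optional `eigen(G, symmetric = TRUE)` result, reusable
#'   across many features.
#' @return list: `sigma_u2`, `sigma_e2`, `loglik`, `converged`.
#' @export
reml_uni_eigen <- function(y, X = NULL, G = NULL, Geig = NULL) {
  if (is.null(Geig)) Geig <- eigen(G, symmetric = TRUE)
  d <- pmax(Geig$values, 0)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  yt <- crossprod(Geig$vectors, y)
  Xt <- crossprod(Geig$vectors, X)
  qf <- ncol(X)
  prof <- function(lg) {
    g <- exp(lg)
    Dg <- g * d + 1
    w <- 1 / Dg
    XtWX <- crossprod(Xt, Xt * w)
    Rx <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(Rx)) return(list(nll = 1e10))
    XtWy <- crossprod(Xt, yt * w)
    beta <- backsolve(Rx, forwardsolve(Rx, XtWy, transpose = TRUE,
                                       upper.tri = TRUE))
    q0 <- sum(yt^2 * w) - sum(XtWy * beta)
    se2 <- q0 / (n - qf)
    ll <- -0.5 * ((n - qf) * (log(2 * pi) + 1 + log(se2)) +
                  sum(log(Dg)) + 2 * sum(log(diag(Rx))))
    list(nll = -ll, se2 = se2, ll = ll)
  }
  opt <- stats::optimize(function(lg) prof(lg)$nll,
                         interval = c(-15, 15), tol = 1e-8)
  # compare against the boundary gamma -> 0
  at0 <- prof(-30)
  if (at0$nll < opt$objective) {
    g <- 0; res <- at0
  } else {
    g <- exp(opt$minimum); res <- prof(opt$minimum)
  }
  list(sigma_u2 = g * res$se2, sigma_e2 = res$se2, loglik = res$ll,
       converged = TRUE)
}

#' Genomic heritability of a single omic feature
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, G sigma_u2)` by REML and
#' reports `h2 = (sigma_u2 * gbar) / (sigma_u2 * gbar + sigma_e2)`,
#' where `gbar` is the average diagonal of the GRM (the genetic variance
#' is rescaled by `gbar` inside the ratio).
#'
#' @param y one value per family, aligned with `G`.
#' @param grm `pool_grm` or kernel matrix.
#' @param Geig optional precomputed eigendecomposition (reuse across
#'   features).
#' @return list of class `varcomp`: `sigma_u2` (rescaled), `sigma_e2`,
#'   `h2`, `loglik`, `avg_G_diag`, `converged`.
#' @export
reml_feature_h2 <- function(y, grm, Geig = NULL) {
  G <- if (inherits(grm, "pool_grm")) grm$G else as.matrix(grm)
  fit <- reml_uni_eigen(y, G = G, Geig = Geig)
  gbar <- mean(diag(G))
  su2 <- fit$sigma_u2 * gbar
  structure(list(sigma_u2 = su2, sigma_e2 = fit$sigma_e2,
                 h2 = su2 / (su2 + fit$sigma_e2), loglik = fit$loglik,
                 avg_G_diag = gbar, converged = fit$converged),
            class = "varcomp")
}

# trial-block fixed design from a phenotype table
tb_design <- function(tab) {
  tb <- factor(paste(tab$trial, tab$block, sep = "_"))
  X <- stats::model.matrix(~tb)
  colnames(X) <- sub("^tb", "tb_", colnames(X))
  X
}

# family incidence matrix mapping records to GRM rows
fam_incidence <- function(families, fam_levels) {
  i <- match(families, fam_levels)
  if (anyNA(i)) stop("phenotype families missing from the GRM")
  Z <- matrix(0, length(families), length(fam_levels))
  Z[cbind(seq_along(i), i)] <- 1
  Z
}

#' Spatially adjusted phenotype REML
#'
#' Fits the plot-level model
#' `y = X beta + Z u + sum_i S_i s + e` with fixed trial-block effects,
#' `u ~ N(0, G sigma_u2)`, a shared sliding-window spatial effect
#' `s ~ N(0, I sigma_s2)` summed over the 11-cell cross window, and
#' i.i.d. residuals.  Heritability uses the window-size-weighted
#' denominator: `h2 = su2 gbar / (su2 gbar + 11 ss2 + se2)`.
#'
#' @param pheno phenotype table (family, trait, trial, block, row, col,
#'   value) for a single trait, or with a `trait` argument to select
#'   one.
#' @param grm `pool_grm` or kernel over the class's families.
#' @param spatial optional precomputed [build_spatial_design()]; built
#'   from the table otherwise.
#' @param trait trait to analyse (default: the single trait present).
#' @param extra_fixed optional extra fixed-effect columns (plots x q).
#' @return `varcomp` list: `sigma_u2` (gbar-rescaled), `sigma_s2`,
#'   `sigma_e2`, `h2`, `loglik`, `beta`, `beta_cov`, `converged`.
#' @export
reml_phenotype <- function(pheno, grm, spatial = NULL, trait = NULL,
                           extra_fixed = NULL) {
  G <- if (inherits(grm, "pool_grm")) grm$G else as.matrix(grm)
  G <- bend_psd(G)
  tab <- if (!is.null(trait)) pheno[pheno$trait == trait, ] else pheno
  if (length(unique(tab$trait)) != 1)
    stop("select a single trait")
  if (is.null(spatial))
    spatial <- build_spatial_design(tab[, c("row", "col")])
  Z <- fam_incidence(tab$family, rownames(G))
  X <- tb_design(tab)
  if (!is.null(extra_fixed)) X <- cbind(X, extra_fixed)
  X <- prune_design(X, "trial-block design")
  W <- as.matrix(spatial$W)
  structs <- list(genetic = Z %*% G %*% t(Z), spatial = tcrossprod(W))
  fit <- reml_dense(tab$value, X, structs)
  gbar <- mean(diag(G))
  su2 <- fit$sigma2[["genetic"]] * gbar
  ss2 <- fit$sigma2[["spatial"]]
  se2 <- fit$sigma2[["residual"]]
  structure(list(sigma_u2 = su2, sigma_s2 = ss2, sigma_e2 = se2,
                 h2 = su2 / (su2 + 11 * ss2 + se2),
                 loglik = fit$loglik, beta = fit$beta,
                 beta_cov = fit$beta_cov, avg_G_diag = gbar,
                 converged = fit$converged),
            class = "varcomp")
}

#' Bivariate omics-phenotype REML
#'
#' Joint model of one omic feature (one record per family; fixed
#' intercept plus three genomic PC covariates) and one phenotypic trait
#' (plot records; fixed trial-block plus the same PC covariates and a
#' sliding-window spatial random effect).  The two additive genetic
#' effects share the kernel `G` with a 2 x 2 Kronecker covariance
#' `[[s_ome, c], [c, s_phe]]`; residuals are independent between
#' sub-models.  The genetic correlation is parameterized through
#' Fisher's z so `|rg| < 1` by construction, variances through logs.
#' The constrained model (`c = 0`) factorizes exactly into the two
#' univariate fits, which also serve as starting values for the full
#' fit.
#'
#' @param y_ome named vector of the omic feature, one value per family.
#' @param pheno single-trait phenotype table.
#' @param grm `pool_grm` or kernel.
#' @param pc_scores families x >=3 matrix of genomic PC scores; the top
#'   3 are used.
#' @param spatial optional [build_spatial_design()] for the phenotype
#'   plots.
#' @param trait optional trait selector.
#' @param n_pcs PC covariates in both sub-models (default 3).
#' @param max_iter optimizer cap for the full fit.
#' @return object of class `bivariate_fit`: genetic (co)variances,
#'   `rg`, residual variances, `loglik_full`, `loglik_constrained`,
#'   `lrt_stat`, `pvalue`, `converged`.
#' @export
bivariate_reml <- function(y_ome, pheno, grm, pc_scores, spatial = NULL,
                           trait = NULL, n_pcs = 3, max_iter = 400) {
  G <- if (inherits(grm, "pool_grm")) grm$G else as.matrix(grm)
  G <- bend_psd(G)
  fams <- rownames(G)
  tab <- if (!is.null(trait)) pheno[pheno$trait == trait, ] else pheno
  if (length(unique(tab$trait)) != 1) stop("select a single trait")
  if (is.null(names(y_ome))) names(y_ome) <- fams
  y1 <- y_ome[fams]
  if (anyNA(y1)) stop("omic vector not aligned with GRM families")
  PC <- as.matrix(pc_scores)[fams, seq_len(n_pcs), drop = FALSE]
  X1 <- cbind(`(Intercept)` = 1, PC)
  if (is.null(spatial))
    spatial <- build_spatial_design(tab[, c("row", "col")])
  Z2 <- fam_incidence(tab$family, fams)
  X2 <- prune_design(cbind(tb_design(tab), Z2 %*% PC), "phenotype design")
  y2 <- tab$value
  n <- length(y1); N <- length(y2)
  W <- as.matrix(spatial$W)
  # univariate fits = the constrained model (genetic covariance 0)
  fit1 <- reml_uni_eigen(y1, X1, G)
  structs2 <- list(genetic = Z2 %*% G %*% t(Z2), spatial = tcrossprod(W))
  fit2 <- reml_dense(y2, X2, structs2)
  ll_con <- fit1$loglik + fit2$loglik
  vy1 <- stats::var(y1); vy2 <- stats::var(y2)
  lb <- c(vy1 * 1e-8, vy2 * 1e-8, NA, vy1 * 1e-8, vy2 * 1e-8, 0)
  X <- rbind(cbind(X1, matrix(0, n, ncol(X2))),
             cbind(matrix(0, N, ncol(X1)), X2))
  G12 <- G %*% t(Z2)
  G22 <- Z2 %*% G12
  WW <- tcrossprod(W)
  yy <- c(y1, y2)
  zero11 <- matrix(0, n, n); zero22 <- matrix(0, N, N)
  zero12 <- matrix(0, n, N)
  M <- list(
    s1 = rbind(cbind(G, zero12), cbind(t(zero12), zero22)),
    s2 = rbind(cbind(zero11, zero12), cbind(t(zero12), G22)),
    cc = rbind(cbind(zero11, G12), cbind(t(G12), zero22)),
    e1 = rbind(cbind(diag(n), zero12), cbind(t(zero12), zero22)),
    e2 = rbind(cbind(zero11, zero12), cbind(t(zero12), diag(N))),
    ss = rbind(cbind(zero11, zero12), cbind(t(zero12), WW)))
  th0 <- c(max(fit1$sigma_u2, vy1 * 1e-3),
           max(fit2$sigma2[["genetic"]], vy2 * 1e-3),
           0,
           max(fit1$sigma_e2, vy1 * 1e-3),
           max(fit2$sigma2[["residual"]], vy2 * 1e-3),
           max(fit2$sigma2[["spatial"]], vy2 * 1e-4))
  ai <- ai_reml_linear(yy, X, M, th0, lower = lb, cor_triplet = c(1, 2, 3))
  if (is.null(ai) || !ai$converged) {
    # derivative-free fallback on the transformed scale
    start <- if (is.null(ai)) th0 else ai$theta
    tr0 <- c(log(start[1]), log(start[2]),
             atanh(max(-0.99, min(0.99,
                                  start[3] / sqrt(start[1] * start[2])))),
             log(start[4]), log(start[5]), log(max(start[6], vy2 * 1e-8)))
    nll <- function(tr) {
      s1 <- exp(tr[1]); s2 <- exp(tr[2]); rg <- tanh(tr[3])
      V <- s1 * M$s1 + s2 * M$s2 + rg * sqrt(s1 * s2) * M$cc +
        exp(tr[4]) * M$e1 + exp(tr[5]) * M$e2 + exp(tr[6]) * M$ss
      ll <- reml_loglik_dense(yy, X, V)$loglik
      if (!is.finite(ll)) 1e10 else -ll
    }
    opt <- stats::optim(tr0, nll, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-10))
    th <- c(exp(opt$par[1]), exp(opt$par[2]),
            tanh(opt$par[3]) * sqrt(exp(opt$par[1]) * exp(opt$par[2])),
            exp(opt$par[4]), exp(opt$par[5]), exp(opt$par[6]))
    ll_full <- -opt$value
    opt_ok <- opt$convergence == 0
  } else {
    th <- ai$theta
    ll_full <- ai$loglik
    opt_ok <- TRUE
  }
  s1 <- th[1]; s2 <- th[2]
  rg <- th[3] / sqrt(s1 * s2)
  pinned <- s1 <= vy1 * 1e-6 || s2 <= vy2 * 1e-6
  converged <- opt_ok && !pinned && is.finite(ll_full) && fit2$converged
  structure(list(
    sigma_u2_ome = s1, sigma_u2_phe = s2,
    sigma_u_cov = th[3], rg = rg,
    sigma_e2_ome = th[4], sigma_e2_phe = th[5],
    sigma_s2 = th[6],
    loglik_full = ll_full, loglik_constrained = ll_con,
    lrt_stat = max(0, 2 * (ll_full - ll_con)),
    # one-tailed statistic: the covariance-nonnegative fit coincides
    # with the unconstrained one when the estimate is positive and with
    # the constrained model otherwise
    lrt_stat_onesided = if (th[3] > 0) max(0, 2 * (ll_full - ll_con))
                        else 0,
    converged = converged),
    class = "bivariate_fit")
}

#' Boundary likelihood-ratio test with 0.5 df
#'
#' Tests the genetic covariance against zero with
#' `p = 0.5 * P(chi2_1 >= D)`, the 50:50 mixture of a point mass at 0
#' and chi-square with 1 df; `D = 0` gives `p = 0.5`.  The mixture is
#' the exact asymptotic null of the one-tailed test (`alternative =
#' "greater"`, covariance constrained non-negative, so `D = 0` whenever
#' the unconstrained estimate is negative).  Applied to the two-sided
#' statistic (`alternative = "two.sided"`) the same formula is the
#' convention used in practice for signed genetic correlations, but it
#' is anti-conservative by a factor of about two under the null since
#' an interior covariance makes the unconstrained LRT chi-square 1.
#'
#' @param fit a `bivariate_fit`, or a numeric LRT statistic.
#' @param alternative which statistic to use from a `bivariate_fit`:
#'   `"two.sided"` (default) or the one-tailed `"greater"`.
#' @param tol tolerance before warning that the full likelihood fell
#'   below the constrained one.
#' @return p-value.
#' @export
lrt_boundary <- function(fit, alternative = c("two.sided", "greater"),
                         tol = 1e-4) {
  alternative <- match.arg(alternative)
  D <- if (inherits(fit, "bivariate_fit")) {
    raw <- 2 * (fit$loglik_full - fit$loglik_constrained)
    if (raw < -tol)
      warning("full model log-likelihood below constrained; flooring at 0")
    if (alternative == "greater") fit$lrt_stat_onesided else max(0, raw)
  } else max(0, fit)
  0.5 * stats::pchisq(D, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR within a test family
#'
#' Step-up FDR control; callers group tests into families (one family
#' per omic feature across its trait tests) before calling.
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return data frame with `p`, `q` (monotone BH-adjusted) and
#'   `significant`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q = q, significant = !is.na(q) & q <= alpha)
}

#' z-test of a hub feature as a phenotype covariate
#'
#' Refits the spatial phenotype model with the (family-level) omic
#' feature added as a fixed covariate and reports the GLS z-score of
#' its coefficient at the REML variance estimates.
#'
#' @param pheno single-trait phenotype table.
#' @param hub_values named vector of the hub feature per family.
#' @param grm `pool_grm` or kernel.
#' @param spatial optional spatial design.
#' @param pc_scores optional PC covariates (families x k) also added as
#'   fixed effects.
#' @param trait optional trait selector.
#' @return list: `estimate`, `se`, `z`, `pvalue`.
#' @export
hub_covariate_ztest <- function(pheno, hub_values, grm, spatial = NULL,
                                pc_scores = NULL, trait = NULL) {
  G <- if (inherits(grm, "pool_grm")) grm$G else as.matrix(grm)
  tab <- if (!is.null(trait)) pheno[pheno$trait == trait, ] else pheno
  if (stats::sd(hub_values) == 0)
    stop("hub covariate has zero variance")
  cov_plot <- hub_values[tab$family]
  extra <- cbind(hub = cov_plot)
  if (!is.null(pc_scores)) {
    Z <- fam_incidence(tab$family, rownames(G))
    extra <- cbind(extra, Z %*% as.matrix(pc_scores))
  }
  fit <- reml_phenotype(tab, G, spatial = spatial, extra_fixed = extra)
  i <- which(names(fit$beta) == "hub")
  if (!length(i)) stop("hub covariate was dropped as collinear")
  est <- fit$beta[i]
  se <- sqrt(fit$beta_cov[i, i])
  z <- est / se
  list(estimate = unname(est), se = unname(se), z = unname(z),
       pvalue = 2 * stats::pnorm(-abs(z)))
}
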