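#' Configuration for the synthetic diallel study
#'
#' Collects every knob of the synthetic-data generator.  The defaults
#' emulate the motivating field study: two pedigree classes of tetraploid
#' full-sib family pools connected through shared *Lolium perenne*
#' parents in sparse diallels, each class grown at one location in five
#' trials of about sixteen entries with two complete blocks, omics
#' features drawn from class-specific sparse Gaussian graphical models
#' with planted hubs, and phenotypes carrying trial-block, sliding-window
#' spatial, and additive genetic effects genetically correlated with
#' designated hub features.
#'
#' @param n_perenne_parents shared parents connecting the two classes.
#' @param n_partner_parents_per_class length-2 count of class-specific
#'   partner parents.
#' @param n_families_per_class length-2 count of full-sib families.
#' @param ploidy ploidy of parents and pools (tetraploid default).
#' @param pool_size plants bulked per family pool; `Inf` for noise-free
#'   pools.
#' @param n_snps,n_chromosomes marker panel dimensions.
#' @param missing_rate completely-at-random missingness of pool
#'   frequencies.
#' @param n_gene_features,n_nmr_features sizes of the two omics layers.
#' @param n_modules_per_class,hubs_per_module,shared_edge_fraction
#'   planted network structure (see [simulate_precision_set()]).
#' @param h2_beta shape parameters of the Beta distribution that per-
#'   feature genomic heritabilities are drawn from.
#' @param n_traits number of phenotypic traits.
#' @param genetic_correlations data frame with columns `hub` (index into
#'   the planted gene-layer hub list), `trait`, `rg`.
#' @param trait_h2 per-trait genomic heritability on the plot-level
#'   scale (recycled).
#' @param spatial_variance variance of a single spatial-window cell
#'   effect (the window sums 11 cells).
#' @param trial_block_sd SD of the fixed trial-block shifts.
#' @param n_trials,n_blocks,plots_per_block field design per class.
#' @param depth mean read depth of pool sequencing (drives the GRM
#'   diagonal correction).
#' @param seed master seed; every generator derives its stream from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_perenne_parents = 31,
                       n_partner_parents_per_class = c(79, 4),
                       n_families_per_class = c(79, 65),
                       ploidy = 4,
                       pool_size = 120,
                       n_snps = 500,
                       n_chromosomes = 7,
                       missing_rate = 0.05,
                       n_gene_features = 60,
                       n_nmr_features = 40,
                       n_modules_per_class = 5,
                       hubs_per_module = 1,
                       shared_edge_fraction = 0.5,
                       h2_beta = c(1.5, 8),
                       n_traits = 2,
                       genetic_correlations = data.frame(
                         hub = 1L, trait = 1L, rg = 0.6),
                       trait_h2 = 0.4,
                       spatial_variance = 0.05,
                       trial_block_sd = 0.5,
                       n_trials = 5,
                       n_blocks = 2,
                       plots_per_block = 16,
                       depth = 30,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_perenne_parents", "ploidy", "n_snps", "n_chromosomes",
              "n_gene_features", "n_nmr_features", "n_modules_per_class",
              "hubs_per_module", "n_traits", "n_trials", "n_blocks",
              "plots_per_block")
  for (nm in counts)
    if (any(cfg[[nm]] < 1)) stop(nm, " must be >= 1")
  cfg$n_partner_parents_per_class <- rep_len(n_partner_parents_per_class, 2)
  cfg$n_families_per_class <- rep_len(n_families_per_class, 2)
  cfg$trait_h2 <- rep_len(trait_h2, n_traits)
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (shared_edge_fraction < 0 || shared_edge_fraction > 1)
    stop("shared_edge_fraction must be in [0, 1]")
  if (nrow(cfg$genetic_correlations) &&
      any(abs(cfg$genetic_correlations$rg) > 1))
    stop("|rg| must be <= 1")
  if (any(cfg$trait_h2 < 0 | cfg$trait_h2 >= 1))
    stop("trait_h2 must be in [0, 1)")
  if (spatial_variance < 0) stop("spatial_variance must be >= 0")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Derive a per-stage seed from the master seed
#'
#' Deterministic fan-out so each pipeline stage is independently
#' rerunnable.  Kept below 2^31.
#' @param seed master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Family-pool allele frequency with binomial pool sampling
#'
#' The expected pool frequency of a full-sib family is the midpoint of
#' its two parents' allele frequencies (dosage / ploidy).  A finite pool
#' of `pool_size` plants contributes `pool_size * ploidy` allele copies,
#' so the observed frequency is a binomial draw around the expectation.
#'
#' @param d1,d2 parental allele dosages (vectors over loci, in
#'   `0..ploidy`).
#' @param ploidy parent ploidy.
#' @param pool_size plants per pool; `Inf` returns the expectation.
#' @return vector of observed pool frequencies.
#' @export
family_pool_frequency <- function(d1, d2, ploidy = 4, pool_size = 120) {
  expected <- (d1 / ploidy + d2 / ploidy) / 2
  if (!is.finite(pool_size)) return(expected)
  ncopies <- pool_size * ploidy
  stats::rbinom(length(expected), ncopies, expected) / ncopies
}

#' Simulate connected sparse diallels of family pools
#'
#' Draws tetraploid parental dosages, mates shared perenne parents with
#' class-specific partner parents in two sparse diallels, and produces
#' per-class family-pool alternative-allele frequency matrices with
#' binomial pool-sampling noise and completely-at-random missingness.
#'
#' @param config a [sim_config()].
#' @return list with `freqs` (list of two [pool_freq] objects, named
#'   `class1`/`class2`), `pedigree` (data frame: class, family, parent1,
#'   parent2), `parent_dosage` (loci x parents matrix), `snp_map`.
#' @export
simulate_diallel_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "diallel"))
  ns <- config$n_snps
  ploidy <- config$ploidy
  q <- stats::runif(ns, 0.05, 0.95)
  chrom <- rep(seq_len(config$n_chromosomes), length.out = ns)
  chrom <- sort(chrom)
  pos <- stats::ave(seq_len(ns), chrom, FUN = seq_along) * 1000L
  perenne <- mosaic_dosages(config$n_perenne_parents, ploidy, chrom, q)
  colnames(perenne) <- paste0("P", seq_len(ncol(perenne)))
  freqs <- vector("list", 2)
  ped <- NULL
  partner_all <- NULL
  for (k in 1:2) {
    n_part <- config$n_partner_parents_per_class[k]
    n_fam <- config$n_families_per_class[k]
    if (n_fam > config$n_perenne_parents * n_part)
      stop("n_families exceeds the number of distinct parent pairs")
    partner <- mosaic_dosages(n_part, ploidy, chrom, q)
    colnames(partner) <- paste0("Q", k, "_", seq_len(n_part))
    partner_all <- cbind(partner_all, partner)
    pairs <- expand.grid(p1 = seq_len(config$n_perenne_parents),
                         p2 = seq_len(n_part))
    pick <- pairs[sample.int(nrow(pairs), n_fam), ]
    Fmat <- matrix(NA_real_, n_fam, ns)
    for (i in seq_len(n_fam)) {
      Fmat[i, ] <- family_pool_frequency(perenne[, pick$p1[i]],
                                         partner[, pick$p2[i]],
                                         ploidy, config$pool_size)
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(Fmat)) < config$missing_rate,
                     nrow = n_fam)
      # never blank out a whole column
      full_col <- colSums(!miss) == 0
      miss[1, full_col] <- FALSE
      Fmat[miss] <- NA_real_
    }
    rownames(Fmat) <- paste0("F", k, "_", seq_len(n_fam))
    freqs[[k]] <- pool_freq(Fmat, chrom = chrom, pos = pos, ploidy = ploidy,
                            depth = rep(config$depth, n_fam))
    ped <- rbind(ped, data.frame(
      class = paste0("class", k),
      family = rownames(Fmat),
      parent1 = colnames(perenne)[pick$p1],
      parent2 = colnames(partner)[pick$p2 - 0L]))
  }
  names(freqs) <- c("class1", "class2")
  list(freqs = freqs, pedigree = ped,
       parent_dosage = cbind(perenne, partner_all),
       snp_map = data.frame(chrom = chrom, pos = pos,
                            id = paste0(chrom, ":", pos)))
}

# Parental dosages as mosaics of ancestral haplotypes: each of the
# ploidy haplotypes per parent copies one of n_anc ancestral haplotypes
# and switches ancestor with low probability between adjacent loci,
# giving realistic linkage disequilibrium along each chromosome.
mosaic_dosages <- function(n_parents, ploidy, chrom, q, n_anc = 8,
                           switch_prob = 0.05) {
  ns <- length(q)
  n_hap <- n_parents * ploidy
  hap <- matrix(0L, ns, n_hap)
  for (ch in unique(chrom)) {
    loci <- which(chrom == ch)
    L <- length(loci)
    anc <- matrix(stats::rbinom(n_anc * L, 1, rep(q[loci], each = n_anc)),
                  n_anc, L)
    state <- sample.int(n_anc, n_hap, replace = TRUE)
    for (j in seq_len(L)) {
      if (j > 1) {
        sw <- stats::runif(n_hap) < switch_prob
        if (any(sw))
          state[sw] <- sample.int(n_anc, sum(sw), replace = TRUE)
      }
      hap[loci[j], ] <- anc[state, j]
    }
  }
  idx <- matrix(seq_len(n_hap), ploidy)
  vapply(seq_len(n_parents), function(p) rowSums(hap[, idx[, p],
                                                     drop = FALSE]),
         numeric(ns))
}

#' Planted two-class sparse precision matrices with hubs
#'
#' Builds block-structured sparse precision matrices for two pedigree
#' classes.  Features are partitioned into modules; within each module a
#' few designated hub features carry edges to most module members while
#' non-hub pairs connect sparsely.  A configurable fraction of the edge
#' support is identical (same position, same weight) across classes; the
#' remainder is class-specific.  Positive definiteness is enforced by
#' diagonal dominance: each diagonal equals 1 plus the row sum of
#' absolute off-diagonals.
#'
#' @param p number of features.
#' @param n_modules number of modules.
#' @param hubs_per_module planted hubs per module.
#' @param shared_edge_fraction fraction of edges shared across classes.
#' @param seed integer seed.
#' @param hub_weight,edge_weight absolute partial-covariance weights for
#'   hub-member and member-member edges.
#' @param edge_prob within-module edge probability between non-hub pairs.
#' @param hub_link_prob probability a hub-member candidate edge exists at
#'   all (before the sharing split).
#' @return list of class `precision_set`: `Theta` (list of 2 p x p
#'   matrices), `modules` (membership), `hubs` (integer vector of planted
#'   hub indices), `hub_module` (module of each hub).
#' @export
simulate_precision_set <- function(p, n_modules, hubs_per_module,
                                   shared_edge_fraction, seed,
                                   hub_weight = 2.5, edge_weight = 2.0,
                                   edge_prob = 0.10, hub_link_prob = 0.4) {
  if (p < n_modules * (hubs_per_module + 2))
    stop("p too small for the requested module structure")
  set.seed(seed)
  membership <- sort(rep_len(seq_len(n_modules), p))
  hubs <- integer(0)
  edges <- list()  # each: i, j, class (0 = both, 1, 2), weight
  for (m in seq_len(n_modules)) {
    idx <- which(membership == m)
    h <- idx[seq_len(hubs_per_module)]
    hubs <- c(hubs, h)
    others <- setdiff(idx, h)
    # hub-member candidates
    for (hi in h) {
      for (j in setdiff(idx, hi)) {
        if (j < hi) next  # handle each unordered pair once
        if (stats::runif(1) > hub_link_prob) next
        w <- hub_weight * sample(c(-1, 1), 1)
        edges[[length(edges) + 1]] <-
          assign_edge(hi, j, shared_edge_fraction, w, hub_weight)
      }
    }
    # sparse member-member edges
    if (length(others) >= 2) {
      prs <- utils::combn(others, 2)
      for (cidx in seq_len(ncol(prs))) {
        if (stats::runif(1) > edge_prob) next
        w <- edge_weight * sample(c(-1, 1), 1)
        edges[[length(edges) + 1]] <-
          assign_edge(prs[1, cidx], prs[2, cidx], shared_edge_fraction,
                      w, edge_weight)
      }
    }
  }
  Theta <- lapply(1:2, function(k) {
    Th <- matrix(0, p, p)
    for (e in edges) {
      if (e$class == 0 || e$class == k) {
        w <- if (e$class == 0) e$weight else e$weight_cs[k]
        Th[e$i, e$j] <- Th[e$j, e$i] <- w
      }
    }
    Th
  })
  Theta <- enforce_hub_dominance(Theta, membership, hubs, hub_weight,
                                 shared_edge_fraction)
  for (k in 1:2)
    diag(Theta[[k]]) <- 1 + rowSums(abs(Theta[[k]]))
  structure(list(Theta = Theta, modules = membership, hubs = hubs,
                 hub_module = membership[hubs]),
            class = "precision_set")
}

# decide whether an edge is shared or class-specific
assign_edge <- function(i, j, shared_frac, w, base_w) {
  if (stats::runif(1) < shared_frac) {
    list(i = i, j = j, class = 0L, weight = w, weight_cs = c(w, w))
  } else {
    k <- sample(1:2, 1)
    wk <- c(0, 0)
    wk[k] <- base_w * sample(c(-1, 1), 1)
    list(i = i, j = j, class = k, weight = wk[k], weight_cs = wk)
  }
}

# guarantee planted hubs out-degree strictly exceeds every non-hub row
# of their module, in both classes; added edges avoid positions already
# occupied in the other class so low shared fractions stay honest
enforce_hub_dominance <- function(Theta, membership, hubs, hub_weight,
                                  shared_frac) {
  for (k in 1:2) {
    Th <- Theta[[k]]
    Tho <- Theta[[3 - k]]
    for (m in unique(membership[hubs])) {
      idx <- which(membership == m)
      mh <- intersect(hubs, idx)
      nonhub <- setdiff(idx, mh)
      for (pass in 1:20) {  # adding hub edges can lift member degrees
      deg <- rowSums(Th[idx, idx, drop = FALSE] != 0)
      names(deg) <- idx
      ok_all <- min(deg[as.character(mh)]) >
        max(c(deg[as.character(nonhub)], 0))
      if (ok_all) break
      for (hi in mh) {
        need <- max(c(deg[as.character(nonhub)], 0))
        while (deg[as.character(hi)] <= need) {
          free <- setdiff(idx, c(hi, which(Th[hi, ] != 0)))
          if (shared_frac < 1)  # keep low sharing honest
            free <- setdiff(free, which(Tho[hi, ] != 0))
          if (length(free) == 0) {
            # trim an edge off the max-degree non-hub instead
            top <- nonhub[which.max(deg[as.character(nonhub)])]
            peers <- intersect(which(Th[top, ] != 0), setdiff(nonhub, top))
            if (length(peers) == 0) {
              j <- setdiff(idx, c(hi, which(Th[hi, ] != 0)))
              if (!length(j)) break
              Th[hi, j[1]] <- Th[j[1], hi] <- hub_weight
            } else {
              Th[top, peers[1]] <- Th[peers[1], top] <- 0
            }
          } else {
            j <- free[1]
            w <- hub_weight * sample(c(-1, 1), 1)
            Th[hi, j] <- Th[j, hi] <- w
          }
          deg <- rowSums(Th[idx, idx, drop = FALSE] != 0)
          names(deg) <- idx
          need <- max(c(deg[as.character(nonhub)], 0))
        }
      }
      }
    }
    Theta[[k]] <- Th
  }
  Theta
}

#' Simulate network-structured omics with genomic heritability
#'
#' Each feature decomposes as `x_j = u_j + e_j`: an additive genetic
#' value `u_j ~ N(0, G sigma_u2_j)` over families and a residual drawn
#' jointly across features from the zero-mean Gaussian graphical model
#' `N(0, Theta^-1)`.  Genetic variances are scaled so the expected share
#' of genetic variance in the total equals the requested per-feature
#' heritability.
#'
#' @param grm a `pool_grm` (or plain kernel matrix) over families.
#' @param precision a p x p positive-definite precision matrix (one
#'   class).
#' @param h2 per-feature heritabilities in `[0, 1)` (recycled).
#' @param seed integer seed.
#' @param u_std optional matrix of pre-drawn standardized genetic values
#'   (columns `N(0, G)`) for designated features; named columns are
#'   matched by feature index given in `u_cols`.
#' @param u_cols integer indices of features whose genetic values are
#'   supplied in `u_std`.
#' @param feature_prefix prefix for feature ids.
#' @return list of class `omics_sim`: `X` (features x samples), `u`
#'   (features x samples genetic values), `h2`, `sigma_u2`.
#' @export
simulate_omics <- function(grm, precision, h2, seed, u_std = NULL,
                           u_cols = integer(0), feature_prefix = "feat") {
  G <- if (inherits(grm, "pool_grm")) grm$G else as.matrix(grm)
  n <- nrow(G)
  p <- nrow(precision)
  h2 <- rep_len(h2, p)
  if (any(h2 < 0 | h2 >= 1)) stop("h2 must be in [0, 1)")
  set.seed(seed)
  L <- chol_psd(G)
  Sigma <- chol2inv(chol(precision))
  E <- matrix(stats::rnorm(n * p), n, p) %*% chol(Sigma)
  U <- L %*% matrix(stats::rnorm(n * p), n, p)
  if (length(u_cols)) U[, u_cols] <- u_std
  g_eff <- (sum(diag(G)) - sum(G) / n) / (n - 1)
  if (g_eff <= 0) stop("GRM carries no usable genetic variance")
  sigma_u2 <- ifelse(h2 > 0, h2 / (1 - h2) * diag(Sigma) / g_eff, 0)
  X <- U %*% diag(sqrt(sigma_u2), p) + E
  ids <- paste0(feature_prefix, seq_len(p))
  dimnames(X) <- list(rownames(G), ids)
  Xu <- t(U %*% diag(sqrt(sigma_u2), p))
  dimnames(Xu) <- list(ids, rownames(G))
  structure(list(X = t(X), u = Xu, h2 = h2, sigma_u2 = sigma_u2,
                 u_std = U),
            class = "omics_sim")
}

# factor L with L L' ~ G for sampling N(0, G); kernels that are
# slightly indefinite (e.g. after the diagonal correction) have their
# negative eigenvalues floored at zero
chol_psd <- function(G, jitter = 1e-8) {
  R <- tryCatch(chol(G + diag(jitter, nrow(G))), error = function(e) NULL)
  if (!is.null(R)) return(t(R))
  ed <- eigen(G, symmetric = TRUE)
  if (max(ed$values) <= 0) stop("kernel has no positive eigenvalues")
  ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), nrow(G))
}

#' Simulate plot-level phenotypes over a blocked field with spatial trend
#'
#' Generates the field book of one pedigree class: families are split
#' over trials of `plots_per_block` entries, replicated in complete
#' blocks laid out on a grid.  Each plot value is the sum of a fixed
#' trial-block shift, the family's additive genetic effect, a sliding-
#' window spatial effect (the cross-shaped 11-cell window summing i.i.d.
#' cell effects), and i.i.d. residual noise.  Trait genetic effects are
#' drawn jointly with designated hub features' standardized genetic
#' values at the configured genetic correlation.
#'
#' @param grm `pool_grm` (or kernel matrix) of the class's families.
#' @param config a [sim_config()].
#' @param u_hub_std optional n_families x n_hub matrix of standardized
#'   (unit-variance-scale, `N(0, G)`) hub genetic values to correlate
#'   traits with; columns indexed by the `hub` column of
#'   `config$genetic_correlations`.
#' @param seed integer seed.
#' @return list of class `pheno_sim`: `table` (plot records: family,
#'   trait, trial, block, row, col, value), `u` (families x traits true
#'   genetic effects), `sigma` (variance components), `layout`.
#' @export
simulate_phenotypes <- function(grm, config, u_hub_std = NULL, seed) {
  G <- if (inherits(grm, "pool_grm")) grm$G else as.matrix(grm)
  fams <- rownames(G)
  n <- nrow(G)
  set.seed(seed)
  # field layout: one grid row per (trial, block), entries in columns
  n_entries <- config$plots_per_block
  trial_of <- rep(seq_len(config$n_trials), length.out = n)
  layout <- NULL
  for (tr in seq_len(config$n_trials)) {
    fam_tr <- fams[trial_of == tr]
    if (!length(fam_tr)) next
    for (b in seq_len(config$n_blocks)) {
      ord <- sample(fam_tr)
      layout <- rbind(layout, data.frame(
        family = ord,
        trial = tr, block = b,
        row = (tr - 1) * config$n_blocks + b,
        col = seq_along(ord)))
    }
  }
  sp <- build_spatial_design(layout)
  gbar <- mean(diag(G))
  L <- chol_psd(G)
  sig_e2 <- 1
  u_all <- matrix(0, n, config$n_traits, dimnames = list(fams, NULL))
  sigma_u2 <- numeric(config$n_traits)
  gc_tab <- config$genetic_correlations
  for (t in seq_len(config$n_traits)) {
    h2 <- config$trait_h2[t]
    denom_env <- 11 * config$spatial_variance + sig_e2
    sigma_u2[t] <- if (h2 > 0) h2 / (1 - h2) * denom_env / gbar else 0
    z <- as.vector(L %*% stats::rnorm(n))
    hit <- which(gc_tab$trait == t)
    u_stdt <- if (length(hit) && !is.null(u_hub_std)) {
      rg <- gc_tab$rg[hit[1]]
      rg * u_hub_std[, gc_tab$hub[hit[1]]] + sqrt(1 - rg^2) * z
    } else z
    u_all[, t] <- sqrt(sigma_u2[t]) * u_stdt
  }
  tb <- stats::rnorm(config$n_trials * config$n_blocks,
                     sd = config$trial_block_sd)
  names(tb) <- paste(rep(seq_len(config$n_trials),
                         each = config$n_blocks),
                     rep(seq_len(config$n_blocks), config$n_trials),
                     sep = "_")
  recs <- NULL
  for (t in seq_len(config$n_traits)) {
    s <- stats::rnorm(nrow(sp$positions),
                      sd = sqrt(config$spatial_variance))
    y <- tb[paste(layout$trial, layout$block, sep = "_")] +
      u_all[layout$family, t] +
      as.vector(sp$W %*% s) +
      stats::rnorm(nrow(layout), sd = sqrt(sig_e2))
    recs <- rbind(recs, data.frame(
      family = layout$family, trait = paste0("trait", t),
      trial = layout$trial, block = layout$block,
      row = layout$row, col = layout$col, value = unname(y)))
  }
  structure(list(table = recs, u = u_all,
                 sigma = list(u2 = sigma_u2, s2 = config$spatial_variance,
                              e2 = sig_e2, gbar = gbar),
                 layout = layout),
            class = "pheno_sim")
}

#' Run the full synthetic study
#'
#' Orchestrates all generators: diallel family-pool frequencies, per-
#' class GRMs, planted two-class precision structures for the gene and
#' NMR layers, network-structured omics with per-feature heritability,
#' and spatially structured phenotypes genetically correlated with
#' designated gene-layer hubs.  Everything is deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `freqs`, `pedigree`, `grm` (per class), `precision`
#'   (per layer), `omics` (`gene`/`nmr`, each per class), `pheno` (per
#'   class) and `truth` (ground-truth bundle).
#' @export
simulate_study <- function(config = sim_config()) {
  dial <- simulate_diallel_frequencies(config)
  grms <- lapply(dial$freqs, function(f)
    grm_from_frequencies(f, pcs = min(10, nrow(f$values))))
  prec <- list(
    gene = simulate_precision_set(config$n_gene_features,
                                  config$n_modules_per_class,
                                  config$hubs_per_module,
                                  config$shared_edge_fraction,
                                  seed = derive_seed(config$seed, "prec_gene")),
    nmr = simulate_precision_set(config$n_nmr_features,
                                 config$n_modules_per_class,
                                 config$hubs_per_module,
                                 config$shared_edge_fraction,
                                 seed = derive_seed(config$seed, "prec_nmr")))
  set.seed(derive_seed(config$seed, "h2"))
  h2 <- list(gene = stats::rbeta(config$n_gene_features,
                                 config$h2_beta[1], config$h2_beta[2]),
             nmr = stats::rbeta(config$n_nmr_features,
                                config$h2_beta[1], config$h2_beta[2]))
  gc_tab <- config$genetic_correlations
  # annotate gene features with genomic spans (for SNP tagging)
  pg <- config$n_gene_features
  gchrom <- rep(seq_len(config$n_chromosomes), length.out = pg)
  max_pos <- tapply(dial$snp_map$pos, dial$snp_map$chrom, max)
  gstart <- numeric(pg)
  for (ch in unique(gchrom)) {
    idx <- which(gchrom == ch)
    gstart[idx] <- round(seq(1000, max(4000, max_pos[[ch]] - 3000),
                             length.out = length(idx)))
  }
  gene_map <- data.frame(id = paste0("gene", seq_len(pg)),
                         chrom = gchrom, start = gstart,
                         end = gstart + 3000)
  hub_feat <- prec$gene$hubs  # planted gene-layer hubs carry the links
  omics <- list(gene = list(), nmr = list())
  pheno <- list()
  truth_u_hub <- list()
  for (k in 1:2) {
    cl <- paste0("class", k)
    sim_gene <- simulate_omics(
      grms[[cl]], prec$gene$Theta[[k]], h2$gene,
      seed = derive_seed(config$seed, paste0("omics_gene", k)),
      feature_prefix = "gene")
    sim_nmr <- simulate_omics(
      grms[[cl]], prec$nmr$Theta[[k]], h2$nmr,
      seed = derive_seed(config$seed, paste0("omics_nmr", k)),
      feature_prefix = "nmr")
    # standardized genetic values of the planted hubs drive the traits
    u_hub_std <- sim_gene$u_std[, hub_feat, drop = FALSE]
    ph <- simulate_phenotypes(
      grms[[cl]], config, u_hub_std = u_hub_std,
      seed = derive_seed(config$seed, paste0("pheno", k)))
    omics$gene[[cl]] <- sim_gene
    omics$nmr[[cl]] <- sim_nmr
    pheno[[cl]] <- ph
    truth_u_hub[[cl]] <- u_hub_std
  }
  list(config = config, freqs = dial$freqs, pedigree = dial$pedigree,
       snp_map = dial$snp_map, gene_map = gene_map, grm = grms,
       precision = prec, omics = omics, pheno = pheno,
       truth = list(h2 = h2, precision = prec, gc = gc_tab,
                    hub_features = hub_feat, u_hub_std = truth_u_hub))
}
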