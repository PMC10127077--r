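#' Precision support to adjacency
#'
#' Converts precision matrices to symmetric 0/1 adjacency matrices:
#' `A_ij = 1` iff `theta_ij != 0` for `i != j`.  Isolated nodes are
#' retained (and flagged) so feature indexing is stable across classes.
#'
#' @param Theta a symmetric matrix, a list of them, or a `jgl_fit`.
#' @param zero_tol additional magnitude below which entries count as
#'   zero (the JGL fit is already exactly sparse; default 0 extra).
#' @return object of class `adjacency_set`: `A` (list of 0/1 matrices),
#'   `feature_ids`, `edges` (per-class and shared counts over `i < j`),
#'   `isolated` (list of logical vectors).
#' @export
to_adjacency <- function(Theta, zero_tol = 0) {
  if (inherits(Theta, "jgl_fit")) Theta <- Theta$Theta
  if (!is.list(Theta)) Theta <- list(Theta)
  A <- lapply(Theta, function(t) {
    a <- (abs(t) > zero_tol) * 1
    diag(a) <- 0
    dimnames(a) <- dimnames(t)
    a
  })
  ids <- rownames(A[[1]]) %||% paste0("f", seq_len(nrow(A[[1]])))
  for (k in seq_along(A)) dimnames(A[[k]]) <- list(ids, ids)
  edges <- if (length(A) == 2) count_edges(A)
           else list(per_class = vapply(
             A, function(a) sum(a[upper.tri(a)] != 0), 1L), shared = NA)
  structure(list(A = A, feature_ids = ids, edges = edges,
                 isolated = lapply(A, function(a) rowSums(a) == 0)),
            class = "adjacency_set")
}

#' Louvain module detection
#'
#' Partitions an unweighted graph into modules by multi-level modularity
#' optimization (Louvain).  Isolated nodes land in singleton modules
#' which are excluded from hub selection downstream.  A fixed seed makes
#' the partition reproducible.
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @param seed integer seed for the (stochastic) node-visit order.
#' @return object of class `module_partition`: `membership` (named
#'   integer vector), `modularity`, `sizes`, `is_singleton` (per module).
#' @export
detect_modules <- function(A, seed = 1L) {
  if (sum(A) == 0) stop("graph has no edges")
  g <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  membership <- igraph::membership(cl)
  names(membership) <- rownames(A)
  sizes <- table(membership)
  structure(list(membership = membership,
                 modularity = igraph::modularity(cl),
                 sizes = as.integer(sizes),
                 is_singleton = as.integer(sizes) == 1L),
            class = "module_partition")
}

# power iteration for the leading eigenvector of A^2, resolved toward
# the Perron vector of A when A^2 has tied leading eigenvalues
# (bipartite components); A and A^2 commute so the small A term leaves
# untied eigenvectors exactly unchanged
power_iteration <- function(M, tol = 1e-10, max_iter = 10000) {
  n <- nrow(M)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.vector(M %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(v * 0)
    w <- w / nw
    if (max(abs(w - v)) < tol) return(w)
    v <- w
  }
  v
}

#' Kleinberg hub centrality scores
#'
#' Scores each node by the principal eigenvector of `A A'` (equal to
#' `A^2` for an undirected graph), computed by power iteration on the
#' full graph, signs fixed non-negative (Perron) and max-normalized to
#' 1.  For a symmetric adjacency this coincides with the leading
#' eigenvector of `A` itself.
#'
#' @param A symmetric 0/1 adjacency matrix.
#' @param tol,max_iter power-iteration controls.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
hub_scores <- function(A, tol = 1e-10, max_iter = 10000) {
  A <- as.matrix(A)
  if (sum(A) == 0)
    return(stats::setNames(rep(0, nrow(A)), rownames(A)))
  M <- A %*% A + 0.01 * A
  v <- abs(power_iteration(M, tol, max_iter))
  v <- v / max(v)
  stats::setNames(v, rownames(A))
}

#' Top hub features per module
#'
#' Within every non-singleton module, selects the `k_per_module`
#' highest-scoring nodes (all of them if the module is smaller).  Ties
#' are broken by degree, then lexicographic feature id.
#'
#' @param partition a `module_partition`.
#' @param scores named hub scores from [hub_scores()].
#' @param A the adjacency matrix (for degrees).
#' @param k_per_module hubs retained per module (default 5).
#' @param score_scope `"global"` ranks whole-graph scores within
#'   modules; `"module"` recomputes scores on each module subgraph.
#' @return data frame: feature, module, score, degree, sorted by module
#'   then score descending.
#' @export
select_hubs <- function(partition, scores, A, k_per_module = 5,
                        score_scope = c("global", "module")) {
  score_scope <- match.arg(score_scope)
  membership <- partition$membership
  deg <- rowSums(A != 0)
  out <- NULL
  for (m in sort(unique(membership))) {
    nodes <- names(membership)[membership == m]
    if (length(nodes) < 2) next  # singleton modules carry no hubs
    sc <- if (score_scope == "module")
      hub_scores(A[nodes, nodes, drop = FALSE])
    else scores[nodes]
    ord <- order(-sc, -deg[nodes], nodes)
    take <- nodes[ord][seq_len(min(k_per_module, length(nodes)))]
    out <- rbind(out, data.frame(
      feature = take, module = m, score = unname(sc[take]),
      degree = unname(deg[take])))
  }
  out
}

#' Conserved hubs across pedigree classes
#'
#' Intersects two per-class hub tables by feature identity (module
#' assignment is ignored) and attaches each class's degree.
#'
#' @param hubs_class1,hubs_class2 data frames from [select_hubs()].
#' @return data frame: feature, module per class, score and degree per
#'   class.  Empty (with a warning) if the lists are disjoint.
#' @export
conserved_hubs <- function(hubs_class1, hubs_class2) {
  common <- intersect(hubs_class1$feature, hubs_class2$feature)
  if (!length(common)) {
    warning("no hub features are conserved across classes")
    return(data.frame(feature = character(0)))
  }
  i1 <- match(common, hubs_class1$feature)
  i2 <- match(common, hubs_class2$feature)
  data.frame(feature = common,
             module_class1 = hubs_class1$module[i1],
             module_class2 = hubs_class2$module[i2],
             score_class1 = hubs_class1$score[i1],
             score_class2 = hubs_class2$score[i2],
             degree_class1 = hubs_class1$degree[i1],
             degree_class2 = hubs_class2$degree[i2])
}

#' Full network stage for a two-class fit
#'
#' Adjacency, modules, hub scores, per-module hub selection and the
#' conserved-hub intersection, in one call.
#'
#' @param fit a `jgl_fit` (or list of two precision matrices).
#' @param k_per_module hubs per module.
#' @param seed seed for module detection.
#' @return list with `adjacency`, `modules`, `scores`, `hubs` (per
#'   class) and `conserved`.
#' @export
network_stage <- function(fit, k_per_module = 5, seed = 1L) {
  adj <- to_adjacency(fit)
  mods <- lapply(adj$A, detect_modules, seed = seed)
  scores <- lapply(adj$A, hub_scores)
  hubs <- lapply(1:2, function(k)
    select_hubs(mods[[k]], scores[[k]], adj$A[[k]],
                k_per_module = k_per_module))
  list(adjacency = adj, modules = mods, scores = scores, hubs = hubs,
       conserved = conserved_hubs(hubs[[1]], hubs[[2]]))
}
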