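validate_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(!is.finite(A))) stop("adjacency contains non-finite values")
  if (any(A < 0)) stop("negative edge weight")
  if (any(diag(A) != 0)) stop("diagonal (auto-loops) must be zero")
  invisible(A)
}

# Directed shortest-path distance matrix under the reciprocal length
# transform L_ij = 1 / A_ij (A_ij > 0), via igraph; unreachable pairs are
# Inf. Stronger edges are shorter: the shortest path maximises weight.
weighted_distances <- function(A) {
  n <- nrow(A)
  L <- ifelse(A > 0, 1 / A, 0)
  g <- igraph::graph_from_adjacency_matrix(L, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, mode = "out", weights = igraph::E(g)$weight)
}

#' Global efficiency of a weighted directed network
#'
#' Average inverse shortest-path length over all ordered node pairs, with
#' edge length `1 / weight` (so edges with higher weights correspond to
#' shorter distances) and `1 / Inf = 0` for disconnected pairs:
#' `GE = (1 / (n (n - 1))) * sum_{i != j} 1 / d_ij`.
#'
#' @param A non-negative R x R adjacency with zero diagonal
#'   (`A[i, j]` = weight of the directed edge i -> j).
#' @return scalar efficiency, on the scale of the edge weights.
#' @export
global_efficiency <- function(A) {
  validate_adjacency(A)
  n <- nrow(A)
  if (n < 2) return(0)
  D <- weighted_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency of a weighted directed network
#'
#' For each node, the subgraph over its neighbours (nodes sharing an in- or
#' out-edge with it, the node itself removed) is extracted and its global
#' efficiency computed; LE is the mean over all nodes. Nodes with fewer
#' than two neighbours contribute 0. This measures how efficiently a
#' node's neighbourhood communicates when the node is removed
#' (fault tolerance / segregation).
#'
#' @inheritParams global_efficiency
#' @return scalar local efficiency.
#' @export
local_efficiency <- function(A) {
  validate_adjacency(A)
  n <- nrow(A)
  if (n < 2) return(0)
  eff <- vapply(seq_len(n), function(i) {
    nbrs <- which(A[i, ] > 0 | A[, i] > 0)
    nbrs <- setdiff(nbrs, i)
    if (length(nbrs) < 2) return(0)
    global_efficiency(A[nbrs, nbrs, drop = FALSE])
  }, numeric(1))
  mean(eff)
}

#' Weighted degree centralities of a directed network
#'
#' Outdegree of node i is the summed weight of edges originating from i
#' (row sum); indegree the summed weight of edges entering i (column sum).
#'
#' @inheritParams global_efficiency
#' @return object of class `node_centrality`: `outdegree`, `indegree`
#'   (named numeric vectors).
#' @export
degree_centralities <- function(A) {
  validate_adjacency(A)
  structure(list(outdegree = rowSums(A), indegree = colSums(A)),
            class = "node_centrality")
}

#' Nodewise group permutation tests with Bonferroni correction
#'
#' Per-node two-tailed permutation t-test (same machinery as the edgewise
#' test) on a centrality metric, Bonferroni-corrected by the number of
#' nodes: node i is significant iff `p_i * n_nodes < alpha`.
#'
#' @param low,high lists of `node_centrality` objects (or plain named
#'   numeric vectors) per subject.
#' @param metric `"outdegree"` or `"indegree"` (ignored when plain vectors
#'   are supplied).
#' @param n_perm permutations (analysis default 5000).
#' @param seed integer seed.
#' @param alpha significance level after correction (default 0.05).
#' @return object of class `node_significance`: `significant_nodes`
#'   (labels), `p_raw`, `p_bonferroni`, `t_obs`, `metric`, `alpha`.
#' @export
node_significance <- function(low, high, metric = c("outdegree", "indegree"),
                              n_perm = 5000L, seed = 1L, alpha = 0.05) {
  metric <- match.arg(metric)
  pick <- function(x) if (inherits(x, "node_centrality")) x[[metric]] else x
  Xl <- t(vapply(low, pick, numeric(length(pick(low[[1]])))))
  Xh <- t(vapply(high, pick, numeric(length(pick(high[[1]])))))
  stopifnot(ncol(Xl) == ncol(Xh))
  labels <- colnames(Xl)
  if (is.null(labels)) labels <- names(pick(low[[1]]))
  if (is.null(labels)) labels <- sprintf("node%02d", seq_len(ncol(Xl)))
  X <- rbind(Xl, Xh)
  grp1 <- rep(c(TRUE, FALSE), c(nrow(Xl), nrow(Xh)))
  res <- perm_t_test(X, grp1, n_perm = n_perm, seed = seed)
  n_nodes <- ncol(X)
  p_bonf <- pmin(1, res$p * n_nodes)
  sig <- labels[p_bonf < alpha]
  structure(list(significant_nodes = sig,
                 p_raw = stats::setNames(res$p, labels),
                 p_bonferroni = stats::setNames(p_bonf, labels),
                 t_obs = stats::setNames(res$t_obs, labels),
                 metric = metric, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "node_significance")
}

#' @export
print.node_significance <- function(x, ...) {
  cat("node_significance (", x$metric, "): ",
      length(x$significant_nodes), " significant of ", length(x$p_raw),
      " nodes at Bonferroni-corrected alpha = ", x$alpha, "\n", sep = "")
  if (length(x$significant_nodes)) {
    cat("  ", paste(x$significant_nodes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy table of global efficiency metrics for a cohort of band matrices
#'
#' @param matrices named list (band -> list of per-subject adjacencies).
#' @param subject_ids,groups per-subject metadata, recycled across bands.
#' @return data frame (subject_id, group, band, GE, LE).
#' @export
global_metrics_table <- function(matrices, subject_ids, groups) {
  rows <- lapply(names(matrices), function(band) {
    mats <- matrices[[band]]
    data.frame(subject_id = subject_ids,
               group = as.character(groups),
               band = band,
               GE = vapply(mats, global_efficiency, numeric(1)),
               LE = vapply(mats, local_efficiency, numeric(1)))
  })
  do.call(rbind, rows)
}
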