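# Functional connectivity networks: Pearson correlation matrix, variable
# thresholding to a target mean degree, Newman-Girvan modularity, Louvain
# communities, hub classification.

#' Pearson correlation matrix over an analysis window
#'
#' Correlates the (filtered) traces of every cell pair over `window`.
#' Zero-variance cells get zero off-diagonal entries (they can never gain an
#' edge) and a warning.
#'
#' @param ts a `trace_set` (filtered traces recommended; see vignette).
#' @param window `c(t0, t1)` in seconds; default the full recording.
#' @return symmetric N x N matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
correlation_matrix <- function(ts, window = NULL) {
  assert_trace_set(ts)
  v <- ts$values
  if (!is.null(window)) {
    sel <- ts$time_s >= window[1] & ts$time_s < window[2]
    if (sum(sel) < 3) stop("analysis window contains fewer than 3 frames")
    v <- v[sel, , drop = FALSE]
  }
  sds <- apply(v, 2L, stats::sd)
  flat <- sds <= .Machine$double.eps^0.5
  r <- matrix(0, ncol(v), ncol(v), dimnames = list(colnames(v), colnames(v)))
  if (any(!flat))
    r[!flat, !flat] <- stats::cor(v[, !flat, drop = FALSE])
  if (any(flat)) {
    warning(sum(flat), " zero-variance cell(s) excluded from correlations")
  }
  diag(r) <- 1
  r
}

#' Threshold a correlation matrix to a target mean degree
#'
#' Implements the variable-threshold network construction: the N(N-1)/2
#' off-diagonal correlations are sorted and the threshold is placed at rank
#' `round(N * k_target / 2)`, so the surviving pairs give a mean node degree
#' of `k_target` exactly (up to ties at the cut). The achieved mean degree is
#' reported and a warning is emitted when ties push it outside `tol`.
#'
#' @param R symmetric correlation matrix.
#' @param k_target target mean degree (default 8, the construction constant
#'   used throughout this kind of analysis).
#' @param tol tolerance on the achieved mean degree.
#' @return object of class `functional_network`: `adjacency` (logical,
#'   symmetric, zero diagonal), `threshold` (r at the cut), `k_avg`,
#'   `degrees`.
#' @export
threshold_to_degree <- function(R, k_target = 8, tol = 0.2) {
  n <- ncol(R)
  if (k_target >= n - 1) stop("k_target must be below N - 1 = ", n - 1)
  iu <- which(upper.tri(R))
  vals <- R[iu]
  m_target <- round(n * k_target / 2)
  ord <- order(-vals, iu)  # deterministic under ties
  take <- ord[seq_len(m_target)]
  r_th <- vals[ord[m_target]]
  if (m_target < length(vals) && vals[ord[m_target + 1L]] == r_th)
    warning("tied correlation values at the threshold r = ", signif(r_th, 4),
            "; rank cut keeps the lower-index pairs")
  adj <- matrix(FALSE, n, n, dimnames = dimnames(R))
  adj[iu[take]] <- TRUE
  adj <- adj | t(adj)
  degrees <- rowSums(adj)
  k_avg <- 2 * m_target / n
  if (abs(k_avg - k_target) > tol)
    warning("achieved mean degree ", k_avg, " misses target ", k_target,
            " by more than tol = ", tol)
  structure(list(adjacency = adj, threshold = r_th, k_avg = k_avg,
                 k_target = k_target, degrees = degrees),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d nodes, %d edges, k_avg = %.3g (r > %.3g)\n",
              length(x$degrees), sum(x$degrees) / 2, x$k_avg, x$threshold))
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` with `m` the number of edges,
#' `e_c` the number of intra-community edges and `d_c` the total degree of
#' community `c`. The all-in-one partition scores 0 by construction.
#'
#' @param adjacency symmetric logical/0-1 matrix, zero diagonal.
#' @param labels per-node community labels.
#' @return Q, or `NA` for an empty graph.
#' @export
modularity_q <- function(adjacency, labels) {
  adjacency <- adjacency * 1
  m <- sum(adjacency) / 2
  if (m == 0) return(NA_real_)
  q <- 0
  for (cc in unique(labels)) {
    sel <- labels == cc
    e_c <- sum(adjacency[sel, sel, drop = FALSE]) / 2
    d_c <- sum(adjacency[sel, , drop = FALSE])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Detect communities by modularity maximization
#'
#' Louvain multilevel modularity optimization (resolution 1) with a fixed
#' seed for reproducibility. Isolated nodes come out as singleton
#' communities. The reported Q is recomputed with [modularity_q()] on the
#' same adjacency, so the two routes cross-check each other.
#'
#' @param net a `functional_network` (or adjacency matrix).
#' @param seed integer seed for the (stochastic) optimizer.
#' @return object of class `community_partition`: `labels`, `Q`,
#'   `n_communities`.
#' @export
detect_communities <- function(net, seed = 1) {
  adj <- if (inherits(net, "functional_network")) net$adjacency else net
  if (sum(adj) == 0) stop("cannot detect communities in an empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = 1)
  labels <- as.integer(igraph::membership(cl))
  structure(list(labels = labels, Q = modularity_q(adj, labels),
                 n_communities = length(unique(labels)), seed = seed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f\n",
              x$n_communities, x$Q))
  invisible(x)
}

#' Flag hub cells
#'
#' Hubs are the top 1/6 of cells (exactly `ceiling(N/6)`) with the highest
#' functional-network degree; isolated nodes are not eligible; ties are
#' broken by cell index.
#'
#' @param net a `functional_network`.
#' @return logical vector of hub flags.
#' @export
identify_hubs <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  n <- length(net$degrees)
  if (n < 6) stop("need at least 6 cells to define hubs")
  top_fraction_flags(net$degrees, eligible = net$degrees > 0)
}

#' Export a functional network as GraphML
#'
#' Writes the network with node attributes `x_um`, `y_um`, `degree`,
#' `community`, `hub` for use in external graph tools.
#'
#' @param net a `functional_network`.
#' @param positions N x 2 matrix (um).
#' @param communities optional `community_partition`.
#' @param hubs optional logical hub flags.
#' @param path output file.
#' @export
write_network_graphml <- function(net, positions, communities = NULL,
                                  hubs = NULL, path) {
  g <- igraph::graph_from_adjacency_matrix(net$adjacency * 1,
                                           mode = "undirected")
  g <- igraph::set_vertex_attr(g, "x_um", value = positions[, 1])
  g <- igraph::set_vertex_attr(g, "y_um", value = positions[, 2])
  g <- igraph::set_vertex_attr(g, "degree", value = net$degrees)
  if (!is.null(communities))
    g <- igraph::set_vertex_attr(g, "community", value = communities$labels)
  if (!is.null(hubs))
    g <- igraph::set_vertex_attr(g, "hub", value = as.integer(hubs))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
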