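#' Network density
#'
#' Density of an undirected simple graph, `2E / (V (V - 1))`.
#'
#' @param x A [gene_set_network()], or the number of vertices `V` when `E` is
#'   supplied.
#' @param E Number of edges (used when `x` is a vertex count).
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(x, E = NULL) {
  if (inherits(x, "gene_set_network")) {
    v <- length(x$nodes)
    e <- nrow(x$edges)
  } else {
    v <- x
    e <- E
    if (is.null(e)) stopf("supply E when x is a vertex count")
  }
  if (v < 2) stopf("density requires at least 2 vertices")
  2 * e / (v * (v - 1))
}

# Deterministic Fiedler bisection of the subgraph induced on `nodes`.
# Returns a list of two node vectors, or NULL when no cut is possible.
fiedler_split <- function(nodes, edge_a, edge_b) {
  nodes <- sort(nodes)
  nv <- length(nodes)
  if (nv < 2L) return(NULL)
  adj <- matrix(0, nv, nv, dimnames = list(nodes, nodes))
  keep <- edge_a %in% nodes & edge_b %in% nodes
  ia <- match(edge_a[keep], nodes)
  ib <- match(edge_b[keep], nodes)
  adj[cbind(ia, ib)] <- 1
  adj[cbind(ib, ia)] <- 1
  lap <- diag(rowSums(adj)) - adj
  es <- eigen(lap, symmetric = TRUE)
  v <- es$vectors[, nv - 1L]           # second-smallest eigenvalue
  # fixed sign convention: first node on the non-positive side
  if (v[[1]] > 0) v <- -v
  left <- nodes[v < 0]
  right <- nodes[v >= 0]
  if (length(left) == 0L || length(right) == 0L) return(NULL)
  list(left, right)
}

subgraph_edge_count <- function(nodes, edge_a, edge_b) {
  sum(edge_a %in% nodes & edge_b %in% nodes)
}

#' Cluster a gene set network by density-guided recursive bisection
#'
#' Each connected component is recursively bisected with a deterministic
#' spectral (Fiedler-vector) cut. A split is accepted only when both children
#' have at least `min_size` vertices and both child densities strictly exceed
#' the parent density (`2E / (V (V - 1))`); accepted children are split
#' further, rejected splits leave the parent as a cluster. Components smaller
#' than `2 * min_size` are never split. All accept/reject decisions are
#' logged.
#'
#' @param network A [gene_set_network()].
#' @param min_size Minimum cluster size for an accepted split. Default 5.
#' @return An object of class `gsn_clustering`: `$clusters` (list of node-id
#'   vectors partitioning the node set) and `$split_log` (data.frame of all
#'   attempted splits).
#' @export
cluster_network <- function(network, min_size = 5) {
  if (length(network$nodes) == 0L) stopf("network has no nodes")
  ea <- network$edges$set_a
  eb <- network$edges$set_b
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  frontier <- split(network$nodes, comp$membership[network$nodes])

  clusters <- list()
  log_rows <- list()
  while (length(frontier) > 0) {
    nodes <- sort(frontier[[1]])
    frontier <- frontier[-1]
    nv <- length(nodes)
    ne <- subgraph_edge_count(nodes, ea, eb)
    if (nv < 2L * min_size || nv < 2L || ne == 0L) {
      clusters <- c(clusters, list(nodes))
      next
    }
    parent_density <- network_density(nv, ne)
    parts <- fiedler_split(nodes, ea, eb)
    if (is.null(parts)) {
      clusters <- c(clusters, list(nodes))
      next
    }
    sizes <- lengths(parts)
    dens <- vapply(parts, function(p) {
      if (length(p) < 2L) return(NA_real_)
      network_density(length(p), subgraph_edge_count(p, ea, eb))
    }, numeric(1))
    accepted <- all(sizes >= min_size) &&
      !anyNA(dens) && all(dens > parent_density)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      parent_size = nv, parent_density = parent_density,
      child1_size = sizes[[1]], child2_size = sizes[[2]],
      child1_density = dens[[1]], child2_density = dens[[2]],
      accepted = accepted, stringsAsFactors = FALSE)
    if (accepted) {
      frontier <- c(parts, frontier)
    } else {
      clusters <- c(clusters, list(nodes))
    }
  }
  clusters <- clusters[order(vapply(clusters, `[[`, character(1), 1L))]
  split_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(parent_size = integer(0), parent_density = numeric(0),
               child1_size = integer(0), child2_size = integer(0),
               child1_density = numeric(0), child2_density = numeric(0),
               accepted = logical(0), stringsAsFactors = FALSE)
  structure(list(clusters = clusters, split_log = split_log),
            class = "gsn_clustering")
}

#' @export
print.gsn_clustering <- function(x, ...) {
  cat(sprintf("Clustering: %d clusters (sizes %s); %d splits attempted, %d accepted\n",
              length(x$clusters),
              paste(sort(lengths(x$clusters), decreasing = TRUE), collapse = ", "),
              nrow(x$split_log), sum(x$split_log$accepted)))
  invisible(x)
}

#' Label clusters by overrepresented node groups
#'
#' For each (cluster, group) pair a 2x2 table over all nodes (in-cluster vs
#' not, in-group vs not) is tested with a one-sided Fisher's exact test; BH
#' runs across all (cluster, group) tests; a cluster is labelled with every
#' group at `q <= alpha`.
#'
#' @param clustering A [cluster_network()] result.
#' @param groups Named character vector: node id -> group label (may cover
#'   only a subset of nodes).
#' @param alpha Significance threshold. Default 0.05.
#' @return A list with `$labels` (named list cluster index -> labels) and
#'   `$tests` (full data.frame of tests).
#' @export
label_modules <- function(clustering, groups, alpha = 0.05) {
  all_nodes <- unlist(clustering$clusters, use.names = FALSE)
  n <- length(all_nodes)
  glabels <- sort(unique(groups))
  if (length(glabels) == 0L || length(clustering$clusters) == 0L) {
    return(list(labels = stats::setNames(list(), character(0)),
                tests = NULL))
  }
  rows <- list()
  for (ci in seq_along(clustering$clusters)) {
    cl <- clustering$clusters[[ci]]
    for (gl in glabels) {
      gnodes <- names(groups)[groups == gl]
      a <- length(intersect(cl, gnodes))
      b <- length(cl) - a
      c <- length(intersect(gnodes, all_nodes)) - a
      d <- n - length(cl) - length(intersect(gnodes, all_nodes)) + a
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = ci, group = gl, a = a, b = b, c = c, d = d,
        p_raw = min(1, phyper_right(a, b, c, d)), stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$q_bh <- bh_adjust(tests$p_raw)
  tests$labelled <- tests$q_bh <= alpha
  labels <- lapply(seq_along(clustering$clusters), function(ci) {
    tests$group[tests$cluster == ci & tests$labelled]
  })
  names(labels) <- as.character(seq_along(clustering$clusters))
  list(labels = labels, tests = tests)
}
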