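#' @title Weighted PPI core-network extraction
#' @description Builds the weighted protein-protein interaction graph from a
#'   STRING-style edge list, reduces it to its giant component, converts the
#'   weighted adjacency into a topological-overlap (TOM) similarity and the
#'   corresponding 1 - TOM distance, computes all-pairs shortest paths, and
#'   scores every node by its relative shortest-path proximity to a core
#'   gene set (Dj).  Nodes with strictly positive Dj, together with the core
#'   nodes, form the extracted core network.
#' @name core_network
NULL

#' Build a simple undirected weighted graph
#'
#' @param edges data.frame `(node1, node2, weight)` with weights in (0, 1\]
#'   (as returned by [read_string_edgelist()]).
#' @param nodes Optional character vector of node names to include even if
#'   isolated.
#' @return An igraph object with a `weight` edge attribute.
#' @export
build_graph <- function(edges, nodes = NULL) {
  if (nrow(edges)) {
    if (any(edges$weight <= 0 | edges$weight > 1))
      stop_io("edge weights must lie in (0, 1]")
    if (any(edges$node1 == edges$node2)) stop_io("self-loop in edge list")
  }
  verts <- unique(c(edges$node1, edges$node2, nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$node1, to = edges$node2, weight = edges$weight),
    directed = FALSE, vertices = verts)
  if (igraph::any_multiple(g)) stop_io("duplicate edge in edge list")
  g
}

#' Extract the giant component
#'
#' Induced subgraph on the largest connected node set; ties between equally
#' large components are broken by the lexicographically smallest member
#' node.
#'
#' @param graph An igraph object.
#' @return The giant-component subgraph.
#' @export
giant_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop_io("empty graph")
  comp <- igraph::components(graph)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    nm <- igraph::V(graph)$name
    first_member <- vapply(big, function(ci) min(nm[comp$membership == ci]),
                           "")
    big <- big[order(first_member)][1L]
  }
  igraph::induced_subgraph(graph, which(comp$membership == big))
}

#' Weighted adjacency matrix of a graph
#' @param graph igraph object with `weight` edge attribute.
#' @return Dense symmetric numeric matrix, zero diagonal.
#' @export
adjacency_matrix <- function(graph) {
  a <- igraph::as_adjacency_matrix(graph, attr = if (igraph::ecount(graph))
    "weight" else NULL, sparse = FALSE)
  diag(a) <- 0
  a
}

#' Topological overlap similarity
#'
#' Unsigned TOM on a weighted adjacency `a` (weights in \[0, 1\]):
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (shared-neighbor weight) and row connectivity
#' `k_i = sum_u a_iu`; `TOM_ii = 1`.  Non-adjacent pairs still earn
#' similarity through shared neighbors.
#'
#' @param graph An igraph object, or a symmetric numeric adjacency matrix
#'   with zero diagonal and entries in \[0, 1\].
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(graph) {
  a <- if (inherits(graph, "igraph")) adjacency_matrix(graph) else as.matrix(graph)
  if (any(a < 0 | a > 1)) stop_io("adjacency weights must lie in [0, 1]")
  diag(a) <- 0
  l <- a %*% a                       # diag(a)=0 so u = i, j terms vanish
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  tom <- (l + a) / denom
  tom[denom == 0] <- 0               # isolated pair of nodes
  diag(tom) <- 1
  tom
}

#' Distance form of the TOM similarity
#'
#' `1 - TOM` off-diagonal, zero diagonal.
#'
#' @param tom Matrix from [tom_similarity()].
#' @return Distance matrix in \[0, 1\].
#' @export
tom_distance <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' All-pairs shortest-path matrix
#'
#' Dijkstra from every source over the TOM-distance matrix.  Under
#' `mode = "complete"` (default) every finite off-diagonal entry of the
#' distance matrix is a traversable edge, so the direct step is always
#' available and `SP <= 1`; under `mode = "edges_only"` traversal is
#' restricted to the original graph edges, carrying their `1 - TOM`
#' distances.
#'
#' @param dist Distance matrix from [tom_distance()] (non-negative,
#'   symmetric, zero diagonal).
#' @param mode `"complete"` or `"edges_only"`.
#' @param graph Original igraph object; required for `mode = "edges_only"`.
#' @return Symmetric shortest-path matrix, zero diagonal.
#' @export
all_shortest_paths_matrix <- function(dist, mode = c("complete", "edges_only"),
                                      graph = NULL) {
  mode <- match.arg(mode)
  if (any(dist < 0)) stop_io("negative distances are not allowed")
  n <- nrow(dist)
  if (mode == "complete") {
    g <- igraph::graph_from_adjacency_matrix(dist, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    # zero-distance pairs are dropped by graph_from_adjacency_matrix;
    # that is harmless for SP since a 0-length edge cannot shorten paths
    # below the two-step bound through either endpoint only when the
    # endpoints are distinct yet coincident -- restore them explicitly.
    zero_pairs <- which(dist == 0 & upper.tri(dist), arr.ind = TRUE)
    if (nrow(zero_pairs)) {
      g <- igraph::add_edges(
        g, t(cbind(rownames(dist)[zero_pairs[, 1L]],
                   rownames(dist)[zero_pairs[, 2L]])),
        weight = rep(0, nrow(zero_pairs)))
    }
    sp <- igraph::distances(g, weights = igraph::E(g)$weight,
                            algorithm = "dijkstra")
    sp <- sp[rownames(dist), colnames(dist)]
  } else {
    if (is.null(graph)) stop_io("mode = 'edges_only' needs the graph")
    el <- igraph::as_edgelist(graph, names = TRUE)
    w <- dist[cbind(match(el[, 1L], rownames(dist)),
                    match(el[, 2L], colnames(dist)))]
    g2 <- igraph::graph_from_data_frame(
      data.frame(from = el[, 1L], to = el[, 2L], weight = w),
      directed = FALSE, vertices = rownames(dist))
    sp <- igraph::distances(g2, weights = igraph::E(g2)$weight,
                            algorithm = "dijkstra")
    sp <- sp[rownames(dist), colnames(dist)]
  }
  diag(sp) <- 0
  sp
}

#' Shortest-path proximity scores to a core gene set
#'
#' For each node j,
#' `Dj = (mean_{i not in core} SP_ij - mean_{i in core} SP_ij) /
#'       (mean_i SP_ij)`,
#' where sums run over all nodes (the self term `SP_jj = 0` contributes
#' nothing) and `C`/`NC` are the global core / non-core counts.  A positive
#' score means node j is closer, on average, to the core nodes than to the
#' rest of the network.
#'
#' @param sp Shortest-path matrix from [all_shortest_paths_matrix()].
#' @param core Character vector of core node names; must be a non-empty
#'   proper subset of the nodes.
#' @return A `core_scores` data.frame: node, Dj, is_core; attributes `C`,
#'   `NC`.
#' @export
dj_scores <- function(sp, core) {
  nodes <- rownames(sp)
  core <- unique(core)
  if (!length(core)) stop_io("core set is empty")
  missing_core <- setdiff(core, nodes)
  if (length(missing_core) == length(core))
    stop_io("no core node present in the SP matrix")
  core <- intersect(core, nodes)
  if (length(core) == length(nodes))
    stop_io("core set must be a proper subset of the nodes")
  is_core <- nodes %in% core
  C <- sum(is_core); NC <- sum(!is_core)
  sum_core <- colSums(sp[is_core, , drop = FALSE])
  sum_all <- colSums(sp)
  sum_noncore <- sum_all - sum_core
  denom <- sum_all / (NC + C)
  dj <- (sum_noncore / NC - sum_core / C) / denom
  zero <- sum_all == 0
  if (any(zero)) {
    warning("node(s) at zero distance from every node; Dj set to 0",
            call. = FALSE)
    dj[zero] <- 0
  }
  structure(data.frame(node = nodes, Dj = unname(dj), is_core = is_core,
                       stringsAsFactors = FALSE),
            C = C, NC = NC, class = c("core_scores", "data.frame"))
}

#' Extract the core network
#'
#' Induced subgraph (original edges and weights) on the core nodes plus all
#' nodes with strictly positive Dj; a node scoring exactly 0 is no closer
#' to the core than the rest and is dropped.  The result may have several
#' components.
#'
#' @param graph The weighted PPI graph the scores were computed on.
#' @param scores A `core_scores` table covering all graph nodes.
#' @return igraph object with node attributes `Dj` and `is_core`.
#' @export
extract_core_network <- function(graph, scores) {
  nm <- igraph::V(graph)$name
  idx <- match(nm, scores$node)
  if (anyNA(idx)) stop_io("scores do not cover all graph nodes")
  keep <- scores$is_core[idx] | scores$Dj[idx] > 0
  sub <- igraph::induced_subgraph(graph, which(keep))
  sidx <- match(igraph::V(sub)$name, scores$node)
  igraph::set_vertex_attr(
    igraph::set_vertex_attr(sub, "Dj", value = scores$Dj[sidx]),
    "is_core", value = scores$is_core[sidx])
}

#' Descriptive statistics of a network
#'
#' Reports node and edge counts, unweighted diameter and mean shortest-path
#' distance (on the giant component), global transitivity (3 x triangles /
#' connected triples, unweighted), edge density on the full graph, and
#' per-node degree and betweenness (betweenness uses `1 - weight` edge
#' distances, normalized).
#'
#' @param graph igraph object with a `weight` edge attribute.
#' @return list with elements n_nodes, n_edges, diameter, transitivity,
#'   density, mean_distance, degree, betweenness.
#' @export
network_descriptives <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop_io("empty graph")
  gc <- giant_component(graph)
  has_w <- "weight" %in% igraph::edge_attr_names(graph) &&
    igraph::ecount(graph) > 0
  bw_weights <- if (has_w) 1 - igraph::E(graph)$weight else NULL
  if (!is.null(bw_weights)) bw_weights <- pmax(bw_weights, 1e-12)
  list(
    n_nodes = igraph::vcount(graph),
    n_edges = igraph::ecount(graph),
    diameter = igraph::diameter(gc, weights = NA),
    transitivity = igraph::transitivity(graph, type = "global"),
    density = igraph::edge_density(graph),
    mean_distance = igraph::mean_distance(gc, weights = NA),
    degree = igraph::degree(graph),
    betweenness = igraph::betweenness(graph, weights = bw_weights,
                                      normalized = TRUE)
  )
}

#' @export
print.core_scores <- function(x, ...) {
  cat(sprintf("<core_scores> %d nodes (%d core, %d non-core); %d with Dj > 0\n",
              nrow(x), attr(x, "C"), attr(x, "NC"),
              sum(x$Dj > 0 & !x$is_core)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
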