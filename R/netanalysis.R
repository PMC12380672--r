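#' Construct a directed gene network from an edge tibble
#'
#' Edges are ordered `(source, target)` pairs with an optional regulation
#' sign. Self-loops are rejected and duplicate ordered pairs collapsed
#' with a warning, so at most one edge per ordered pair remains.
#'
#' @param edges Tibble/data frame with columns `source`, `target` and
#'   optionally `sign` (`"+"`, `"-"`, or `"unsigned"`).
#' @param nodes Optional character vector of node names; defaults to the
#'   union of edge endpoints. Isolated nodes may be added here.
#' @return Tibble of edges with class `gene_network`; the node set is
#'   attached as `attr(x, "nodes")`.
#' @export
gene_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  edges <- tibble::tibble(
    source = as.character(edges$source),
    target = as.character(edges$target),
    sign = if ("sign" %in% names(edges)) as.character(edges$sign)
           else rep("unsigned", nrow(edges)))
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) rejected", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) collapsed",
            call. = FALSE)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, edges$source, edges$target)))
  structure(edges, nodes = nodes,
            class = c("gene_network", class(tibble::tibble())))
}

#' Read a directed edge list from TSV
#'
#' Expects columns `source`, `target`, and optionally `sign`. Rows whose
#' source equals target (self-loops) and duplicate ordered pairs are
#' dropped with a warning via [gene_network()].
#'
#' @param path TSV file path.
#' @return A [gene_network()].
#' @export
read_edgelist <- function(path) {
  stopifnot(file.exists(path))
  edges <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  gene_network(edges)
}

#' Write a network's edge list to TSV
#' @param net A [gene_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  readr::write_tsv(tibble::as_tibble(net)[, c("source", "target", "sign")],
                   path)
  invisible(path)
}

.net_nodes <- function(net) attr(net, "nodes")

# igraph view of the network; directed by default, undirected projection
# (collapsed, no multi-edges) when directed = FALSE
.as_igraph <- function(net, directed = TRUE) {
  g <- igraph::graph_from_data_frame(
    tibble::as_tibble(net)[, c("source", "target")],
    directed = TRUE, vertices = .net_nodes(net))
  if (!directed) {
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  g
}

#' Directed network density
#'
#' `m / (n (n - 1))`: the fraction of possible ordered pairs that carry
#' an edge.
#'
#' @param net A [gene_network()].
#' @return Density in \[0, 1\].
#' @export
#' @examples
#' net <- generate_network(n_nodes = 9, m_edges = 29, seed = 1)
#' network_density(net)   # 29 / 72
network_density <- function(net) {
  n <- length(.net_nodes(net))
  if (n < 2) stop("density requires at least 2 nodes")
  igraph::edge_density(.as_igraph(net))
}

#' Average shortest-path length and diameter
#'
#' Shortest directed path lengths over all *reachable* ordered pairs
#' (u != v); unreachable pairs are excluded rather than treated as
#' infinite, so the metrics stay finite on networks that are not
#' strongly connected.
#'
#' @param net A [gene_network()].
#' @return Tibble with `average_path_length` and `diameter`.
#' @export
path_metrics <- function(net) {
  g <- .as_igraph(net)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  if (length(finite) == 0) stop("no reachable ordered pairs")
  tibble::tibble(average_path_length = mean(finite),
                 diameter = as.integer(max(finite)))
}

#' Average local clustering coefficient
#'
#' Computed on the undirected projection of the network (the triad
#' definition under which published values for small directed regulatory
#' networks are attainable): each node's local coefficient is the
#' fraction of its neighbour pairs that are themselves connected, nodes
#' with fewer than two neighbours contribute 0, and the network value is
#' the mean over all nodes.
#'
#' @param net A [gene_network()].
#' @return Clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  if (length(.net_nodes(net)) < 3) stop("clustering requires >= 3 nodes")
  g <- .as_igraph(net, directed = FALSE)
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  local[is.na(local)] <- 0
  mean(local)
}

#' All network-level topology metrics
#'
#' @param net A [gene_network()].
#' @return One-row tibble: `n_nodes`, `n_edges`, `density`,
#'   `average_path_length`, `clustering_coefficient`, `diameter`,
#'   `connected_component_count` (weak components).
#' @export
network_metrics <- function(net) {
  pm <- path_metrics(net)
  g <- .as_igraph(net)
  tibble::tibble(
    n_nodes = length(.net_nodes(net)),
    n_edges = nrow(net),
    density = network_density(net),
    average_path_length = pm$average_path_length,
    clustering_coefficient = clustering_coefficient(net),
    diameter = pm$diameter,
    connected_component_count = igraph::count_components(g, mode = "weak")
  )
}

#' Per-node centrality profile
#'
#' In- and out-degree centralities are normalized by `n - 1`;
#' betweenness counts directed shortest paths and is normalized by
#' `(n - 1)(n - 2)`; eigenvector centrality is computed on the
#' undirected projection and scaled to max-norm 1. The composite rank is
#' the unweighted mean of the four per-metric ranks (rank 1 = highest,
#' ties share their mean rank).
#'
#' @param net A [gene_network()].
#' @return Tibble of class `centrality_profile`, one row per node:
#'   `gene`, `in_degree`, `out_degree`, `betweenness`, `eigenvector`,
#'   `composite_rank`, ordered by composite rank then gene symbol.
#' @export
centralities <- function(net) {
  nodes <- .net_nodes(net)
  n <- length(nodes)
  if (n < 2) stop("centralities require at least 2 nodes")
  g <- igraph::graph_from_data_frame(
    tibble::as_tibble(net)[, c("source", "target")],
    directed = TRUE, vertices = nodes)
  indeg <- igraph::degree(g, mode = "in") / (n - 1)
  outdeg <- igraph::degree(g, mode = "out") / (n - 1)
  btw <- igraph::betweenness(g, directed = TRUE, normalized = TRUE)
  gu <- igraph::as_undirected(g, mode = "collapse")
  eig <- igraph::eigen_centrality(gu)$vector  # max-norm 1
  prof <- tibble::tibble(
    gene = nodes,
    in_degree = unname(indeg[nodes]),
    out_degree = unname(outdeg[nodes]),
    betweenness = unname(btw[nodes]),
    eigenvector = unname(eig[nodes])
  )
  ranks <- vapply(
    prof[, c("in_degree", "out_degree", "betweenness", "eigenvector")],
    function(v) rank(-v, ties.method = "average"), numeric(nrow(prof)))
  prof$composite_rank <- rowMeans(ranks)
  prof <- dplyr::arrange(prof, .data$composite_rank, .data$gene)
  structure(prof, class = c("centrality_profile", class(tibble::tibble())))
}

#' Designate hub genes from a centrality profile
#'
#' The top `k` genes by composite mean rank across the four centrality
#' measures; ties broken lexicographically by gene symbol.
#'
#' @param profile A [centralities()] result.
#' @param k Number of hubs to return (default 4).
#' @return Character vector of `k` gene symbols, best first.
#' @export
hub_genes <- function(profile, k = 4) {
  stopifnot(k <= nrow(profile))
  ord <- order(profile$composite_rank, profile$gene)
  profile$gene[ord][seq_len(k)]
}
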