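#' Build the weighted patient-sharing network
#'
#' Nodes are providers; the weight of the undirected edge \{A, B\} is
#' `F_AB`, the number of fragmented transitions between A and B *in either
#' order*. Non-fragmented transitions contribute nothing. Providers never
#' involved in a fragmented transition can be kept as isolated nodes by
#' supplying them in `node_universe` (so that density and community
#' assignment cover the full provider set).
#'
#' @param transitions transition table from [extract_transitions()].
#' @param node_universe optional character vector of provider codes to include
#'   as nodes regardless of their transitions.
#' @return a `patient_sharing_network`: list with sorted `nodes` and an
#'   `edges` data.table (`provider_a < provider_b`, `weight >= 1`).
#' @export
build_network <- function(transitions, node_universe = NULL) {
  frag <- transitions[fragmented == TRUE]
  edges <- frag[, .(
    provider_a = pmin(from_provider, to_provider),
    provider_b = pmax(from_provider, to_provider)
  )][, .(weight = .N), by = .(provider_a, provider_b)]
  setorder(edges, provider_a, provider_b)
  nodes <- sort(unique(c(node_universe, frag$from_provider, frag$to_provider)))
  new_network(nodes, edges)
}

new_network <- function(nodes, edges) {
  stopifnot(all(edges$provider_a <= edges$provider_b))
  structure(list(nodes = nodes, edges = edges),
            class = "patient_sharing_network")
}

#' @export
print.patient_sharing_network <- function(x, ...) {
  cat(sprintf("Patient-sharing network: %d providers, %d edges, total weight %s\n",
              length(x$nodes), nrow(x$edges),
              format(sum(x$edges$weight), big.mark = ",")))
  invisible(x)
}

#' Summarise a patient-sharing network
#'
#' Reports node and edge counts, the number of possible edges
#' `n(n-1)/2`, the density as a percentage, the total edge weight, and — for
#' each requested threshold — the number and share of present edges whose
#' weight strictly exceeds it.
#'
#' @param net a `patient_sharing_network`.
#' @param thresholds numeric vector of edge-weight thresholds (strict `>`).
#' @return list with `n_nodes`, `n_edges`, `n_possible`, `density_pct`
#'   (`NULL` when fewer than 2 nodes), `total_weight`, and a data.table
#'   `threshold_counts` (`threshold`, `n_edges_above`, `pct_of_edges`).
#' @export
network_summary <- function(net, thresholds = numeric()) {
  n <- length(net$nodes)
  n_possible <- if (n < 2L) 0 else n * (n - 1) / 2
  n_edges <- nrow(net$edges)
  thr <- data.table(
    threshold = as.numeric(thresholds),
    n_edges_above = vapply(thresholds, function(t) sum(net$edges$weight > t), numeric(1)),
    pct_of_edges = vapply(thresholds, function(t)
      pct_of(sum(net$edges$weight > t), n_edges), numeric(1))
  )
  list(
    n_nodes = n,
    n_edges = n_edges,
    n_possible = n_possible,
    density_pct = if (n_possible == 0) NULL else 100 * n_edges / n_possible,
    total_weight = sum(net$edges$weight),
    threshold_counts = thr
  )
}

#' Drop weak edges from a network
#'
#' Keeps edges whose weight is strictly greater than `min_weight` ("edges
#' above" a case count); the node set is unchanged, so thresholding can only
#' isolate nodes, never remove them.
#'
#' @param net a `patient_sharing_network`.
#' @param min_weight non-negative threshold.
#' @return the thresholded network.
#' @export
threshold_network <- function(net, min_weight) {
  stopifnot(min_weight >= 0)
  new_network(net$nodes, net$edges[weight > min_weight])
}

#' Convert to an igraph object
#'
#' @param net a `patient_sharing_network`.
#' @return an undirected weighted `igraph` graph including isolated nodes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, .(provider_a, provider_b, weight)],
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}

#' Write / read the weighted edge list
#'
#' Tab-separated `provider_a provider_b weight`, each pair sorted
#' lexicographically and rows sorted, so output is byte-stable. The reader
#' accepts the same dialect; isolated nodes are not representable in an edge
#' list and may be re-supplied via `node_universe`.
#'
#' @param net a `patient_sharing_network`.
#' @param path file path.
#' @return `path` (writer, invisibly) or a `patient_sharing_network` (reader).
#' @export
write_edge_list <- function(net, path) {
  data.table::fwrite(net$edges, path, sep = "\t")
  invisible(path)
}

#' @rdname write_edge_list
#' @param node_universe optional providers to include as isolated nodes.
#' @export
read_edge_list <- function(path, node_universe = NULL) {
  edges <- data.table::fread(path, sep = "\t",
                             colClasses = list(character = c("provider_a", "provider_b")))
  if (!all(c("provider_a", "provider_b", "weight") %in% names(edges)))
    stop_carefrag("edge list must have columns provider_a, provider_b, weight",
                  class = "carefrag_schema_error")
  swap <- edges$provider_a > edges$provider_b
  if (any(swap)) {
    tmp <- edges$provider_a[swap]
    edges[swap, provider_a := provider_b]
    edges[swap, provider_b := tmp]
  }
  setorder(edges, provider_a, provider_b)
  nodes <- sort(unique(c(node_universe, edges$provider_a, edges$provider_b)))
  new_network(nodes, edges)
}

#' Write the network as GraphML
#'
#' GraphML with a `weight` edge attribute, readable by standard network
#' tools.
#'
#' @param net a `patient_sharing_network`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
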