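#' Read a molecular network from GraphML
#'
#' Nodes are MS features (vertex names castable to feature ids); edges
#' carry MS2 spectral similarity or ion-identity relations. igraph performs
#' the parsing; this wrapper validates that every vertex name is a feature
#' id and that no edge dangles (guaranteed by GraphML, re-checked for
#' defensive symmetry with the writer).
#'
#' @param path Path to a GraphML file.
#' @return An `igraph` object.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(sprintf("GraphML file not found: %s", path))
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id)) {
    g <- igraph::set_vertex_attr(g, "name", value = igraph::V(g)$id)
  }
  ids <- suppressWarnings(as.integer(igraph::V(g)$name))
  if (anyNA(ids)) {
    abort("network node ids must be castable to integer feature ids.")
  }
  g
}

#' Write a molecular network to GraphML
#'
#' @param network An `igraph` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Build a network from node and edge tables
#'
#' Convenience constructor used by the fixture generator and tests: errors
#' on edges whose endpoints are not in the node table, listing them.
#'
#' @param nodes Tibble with a `feature_id` column (plus attribute columns).
#' @param edges Tibble with `from` and `to` feature-id columns (plus
#'   attribute columns such as `weight`, `type`).
#' @return An `igraph` object with vertex names set to the feature ids.
#' @export
network_from_tables <- function(nodes, edges) {
  known <- nodes$feature_id
  dangling <- edges |>
    filter(!(.data$from %in% known) | !(.data$to %in% known))
  if (nrow(dangling) > 0L) {
    abort(sprintf(
      "edge(s) reference absent node(s): %s",
      paste(sprintf("%s-%s", dangling$from, dangling$to), collapse = ", ")
    ))
  }
  igraph::graph_from_data_frame(
    mutate(edges, from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = mutate(nodes, feature_id = as.character(feature_id))
  )
}
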