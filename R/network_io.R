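#' Write a bipartite RN-effector network to GEXF or GraphML
#'
#' Exports a Gephi-readable graph: nodes carry a `type` attribute (RN or
#' effector) and a `signal` attribute, edges carry integer co-occurrence
#' weights. An edge referencing a missing node, or joining two nodes of
#' the same type, aborts with both endpoint ids (the network must be
#' bipartite).
#'
#' @param network an `rn_bipartite_network` from [build_network()].
#' @param path output path.
#' @param format `"gexf"` (default) or `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_gexf <- function(network, path, format = c("gexf", "graphml")) {
  format <- match.arg(format)
  nodes <- network$nodes; edges <- network$edges
  if (nrow(edges) > 0L) {
    bad <- !(edges$rn %in% nodes$id) | !(edges$effector %in% nodes$id)
    if (any(bad))
      stop_fmt("edge references missing node(s): %s -- %s",
               edges$rn[which(bad)[1]], edges$effector[which(bad)[1]])
    t1 <- nodes$type[match(edges$rn, nodes$id)]
    t2 <- nodes$type[match(edges$effector, nodes$id)]
    same <- t1 == t2
    if (any(same))
      stop_fmt("same-type edge violates bipartiteness: %s -- %s",
               edges$rn[which(same)[1]], edges$effector[which(same)[1]])
  }
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      if (nrow(edges) > 0L)
        data.frame(from = edges$rn, to = edges$effector,
                   weight = edges$weight) else
        data.frame(from = character(), to = character(),
                   weight = numeric()),
      directed = FALSE,
      vertices = data.frame(name = nodes$id, type = nodes$type,
                            signal = ifelse(is.na(nodes$signal), "",
                                            nodes$signal)))
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://gexf.net/1.3", version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "type",
                      type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "signal",
                      type = "string")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(nodes_el, "node", id = nodes$id[i],
                              label = nodes$id[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = nodes$type[i])
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = ifelse(is.na(nodes$signal[i]), "",
                                       nodes$signal[i]))
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(edges))) {
    xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1L),
                        source = edges$rn[i], target = edges$effector[i],
                        weight = as.character(edges$weight[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GEXF network written by [write_gexf()]
#'
#' Round-trip reader used for validation; restores nodes with their
#' type/signal attributes and integer edge weights.
#'
#' @param path GEXF file path.
#' @return an `rn_bipartite_network`.
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = xml2::xml_ns(doc)[[1]])
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- data.frame(
    id = xml2::xml_attr(node_els, "id"),
    type = xml2::xml_attr(
      xml2::xml_find_first(node_els, ".//g:attvalue[@for='0']", ns),
      "value"),
    signal = xml2::xml_attr(
      xml2::xml_find_first(node_els, ".//g:attvalue[@for='1']", ns),
      "value"),
    stringsAsFactors = FALSE)
  nodes$signal[nodes$signal == ""] <- NA_character_
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(
    rn = xml2::xml_attr(edge_els, "source"),
    effector = xml2::xml_attr(edge_els, "target"),
    weight = as.integer(xml2::xml_attr(edge_els, "weight")),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges),
            class = "rn_bipartite_network")
}
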