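#' Export a hybridization graph to XGMML
#'
#' Writes the bipartite probe-transcript graph in the XGMML dialect consumed
#' by network-visualization tools (e.g. Cytoscape). Each node carries a
#' \code{type} attribute (\code{probe} or \code{transcript}); each edge
#' carries the percent identity and alignment length of its best hit.
#'
#' @param graph a \code{\link{hyb_graph}}.
#' @param path output path.
#' @param label graph label attribute.
#' @return \code{path}, invisibly.
#' @export
write_graph_xgmml <- function(graph, path, label = "hybridization graph") {
  stopifnot(inherits(graph, "HybGraph"))
  doc <- xml2::xml_new_root("graph", label = label, directed = "0",
                            xmlns = "http://www.cs.rpi.edu/XGMML")
  add_node <- function(id, type) {
    nd <- xml2::xml_add_child(doc, "node", id = id, label = id)
    xml2::xml_add_child(nd, "att", name = "type", type = "string", value = type)
  }
  for (p in graph$probes) add_node(p, "probe")
  for (t in graph$transcripts) add_node(t, "transcript")
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(doc, "edge", source = e$probe_id[i],
                              target = e$transcript_id[i])
    xml2::xml_add_child(ed, "att", name = "percent_identity", type = "real",
                        value = format(e$percent_identity[i]))
    xml2::xml_add_child(ed, "att", name = "alignment_length", type = "integer",
                        value = format(e$alignment_length[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a hybridization graph to GraphML
#'
#' @inheritParams write_graph_xgmml
#' @return \code{path}, invisibly.
#' @export
write_graph_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "HybGraph"))
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "type", `for` = "node",
                      attr.name = "type", attr.type = "string")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  add_node <- function(id, type) {
    nd <- xml2::xml_add_child(g, "node", id = id)
    dt <- xml2::xml_add_child(nd, "data", key = "type")
    xml2::xml_set_text(dt, type)
  }
  for (p in graph$probes) add_node(p, "probe")
  for (t in graph$transcripts) add_node(t, "transcript")
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    xml2::xml_add_child(g, "edge", source = e$probe_id[i],
                        target = e$transcript_id[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Re-import an XGMML file written by write_graph_xgmml
#'
#' Round-trip reader used to verify exports: returns node ids with their type
#' attribute and the edge list.
#'
#' @param path path to an XGMML file.
#' @return list with \code{nodes} (data frame: id, type) and \code{edges}
#'   (data frame: source, target).
#' @export
read_graph_xgmml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "./node")
  ids <- xml2::xml_attr(nodes, "id")
  types <- vapply(nodes, function(n) {
    att <- xml2::xml_find_first(n, "./att[@name='type']")
    xml2::xml_attr(att, "value")
  }, character(1))
  edges <- xml2::xml_find_all(doc, "./edge")
  list(nodes = data.frame(id = ids, type = types, stringsAsFactors = FALSE),
       edges = data.frame(source = xml2::xml_attr(edges, "source"),
                          target = xml2::xml_attr(edges, "target"),
                          stringsAsFactors = FALSE))
}
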