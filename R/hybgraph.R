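#' Filter similarity hits to likely hybridization edges
#'
#' Heterologous hybridization is modeled by sequence similarity: a transcript
#' is predicted to hybridize to a probe when a hit reaches at least 80%
#' identity over at least a 100 bp aligned region. Both thresholds are
#' inclusive. Duplicate (probe, transcript) hits collapse to the single best
#' edge (highest bit score, then highest identity): the graph models presence
#' of likely hybridization, not hit multiplicity.
#'
#' @param hits a \code{\link{hit_table}}.
#' @param min_identity minimum percent identity (default 80).
#' @param min_length minimum alignment length in bp (default 100).
#' @param probe_side which hit-table side holds the probe ids:
#'   \code{"subject"} (default: transcripts were searched against probes) or
#'   \code{"query"}.
#' @return A \code{HybEdge} data frame with columns \code{probe_id},
#'   \code{transcript_id}, \code{percent_identity}, \code{alignment_length},
#'   \code{bitscore}; zero rows allowed.
#' @export
filter_hits <- function(hits, min_identity = 80, min_length = 100,
                        probe_side = c("subject", "query")) {
  probe_side <- match.arg(probe_side)
  keep <- hits$percent_identity >= min_identity &
    hits$alignment_length >= min_length
  h <- hits[keep, , drop = FALSE]
  if (probe_side == "subject") {
    e <- data.frame(probe_id = h$subject_id, transcript_id = h$query_id,
                    percent_identity = h$percent_identity,
                    alignment_length = h$alignment_length,
                    bitscore = h$bitscore, stringsAsFactors = FALSE)
  } else {
    e <- data.frame(probe_id = h$query_id, transcript_id = h$subject_id,
                    percent_identity = h$percent_identity,
                    alignment_length = h$alignment_length,
                    bitscore = h$bitscore, stringsAsFactors = FALSE)
  }
  if (nrow(e)) {
    o <- order(e$probe_id, e$transcript_id, -e$bitscore, -e$percent_identity)
    e <- e[o, , drop = FALSE]
    e <- e[!duplicated(e[c("probe_id", "transcript_id")]), , drop = FALSE]
    rownames(e) <- NULL
  }
  class(e) <- c("HybEdge", "data.frame")
  e
}

#' Build the bipartite probe-transcript hybridization graph
#'
#' Nodes are exactly the endpoints of the retained edges plus any
#' caller-supplied probes with no predicted hybridizing transcript, which are
#' kept as isolated nodes (and reported as "no predicted target" by
#' \code{\link{probe_metrics}}) rather than dropped. Probe and transcript id
#' namespaces must not collide.
#'
#' @param edges edge table from \code{\link{filter_hits}}.
#' @param isolated_probes probe ids to keep even without edges.
#' @param thresholds the (min_identity, min_length) pair the edges satisfy;
#'   recorded for provenance.
#' @return An object of class \code{HybGraph} with elements \code{probes},
#'   \code{transcripts}, \code{edges}, \code{thresholds}.
#' @export
build_graph <- function(edges, isolated_probes = character(),
                        thresholds = c(min_identity = 80, min_length = 100)) {
  probes <- sort(unique(c(edges$probe_id, as.character(isolated_probes))))
  transcripts <- sort(unique(edges$transcript_id))
  clash <- intersect(probes, transcripts)
  if (length(clash))
    stop("probe id(s) collide with transcript id(s) (namespacing required): ",
         paste(utils::head(clash, 5), collapse = ", "))
  e <- as.data.frame(edges)
  if (nrow(e)) {
    e <- e[order(e$probe_id, e$transcript_id), , drop = FALSE]
    rownames(e) <- NULL
  }
  structure(list(probes = probes, transcripts = transcripts, edges = e,
                 thresholds = thresholds),
            class = "HybGraph")
}

#' @export
print.HybGraph <- function(x, ...) {
  cat("HybGraph:", length(x$probes), "probes,", length(x$transcripts),
      "transcripts,", nrow(x$edges), "edges",
      sprintf("(>= %g%% identity over >= %g bp)\n",
              x$thresholds[["min_identity"]], x$thresholds[["min_length"]]))
  invisible(x)
}

# internal: undirected igraph over the bipartite node set
as_igraph <- function(graph) {
  verts <- data.frame(name = c(graph$probes, graph$transcripts),
                      type = c(rep("probe", length(graph$probes)),
                               rep("transcript", length(graph$transcripts))),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    graph$edges[c("probe_id", "transcript_id")],
    directed = FALSE, vertices = verts)
}

#' Per-probe ambiguity and redundancy metrics
#'
#' Ambiguity of a probe is the number of distinct transcripts predicted to
#' hybridize to it; its redundancy partners are the other probes sharing at
#' least one transcript with it. A probe with ambiguity 1 and no redundancy
#' partners is "specific"; an isolated probe has "no predicted target".
#' (The source workflow estimates specificity and redundancy from the graph
#' without fixing formulas; these definitions are one faithful reading and
#' are labeled as such.)
#'
#' @param graph a \code{\link{build_graph}} result.
#' @return Data frame with columns \code{probe_id}, \code{ambiguity},
#'   \code{redundancy_partners}, \code{status} (specific / ambiguous /
#'   redundant / no predicted target).
#' @export
probe_metrics <- function(graph) {
  e <- graph$edges
  amb <- integer(length(graph$probes))
  names(amb) <- graph$probes
  if (nrow(e)) {
    tab <- table(e$probe_id)
    amb[names(tab)] <- as.integer(tab)
  }
  partners <- setNames(integer(length(graph$probes)), graph$probes)
  if (nrow(e)) {
    by_t <- split(e$probe_id, e$transcript_id)
    plist <- setNames(vector("list", length(graph$probes)), graph$probes)
    for (ps in by_t) {
      ups <- unique(ps)
      if (length(ups) > 1) for (p in ups) plist[[p]] <- c(plist[[p]], setdiff(ups, p))
    }
    partners[] <- vapply(plist, function(v) length(unique(v)), integer(1))
  }
  status <- ifelse(amb == 0L, "no predicted target",
            ifelse(partners > 0L, "redundant",
            ifelse(amb == 1L, "specific", "ambiguous")))
  data.frame(probe_id = graph$probes, ambiguity = unname(amb),
             redundancy_partners = unname(partners), status = status,
             stringsAsFactors = FALSE)
}

#' Connected components of the hybridization graph
#'
#' Standard undirected components via igraph, with deterministic ordering:
#' components are sorted by their smallest contained node id and members
#' within a component are sorted.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @return An object of class \code{ComponentPartition}: list with
#'   \code{components} (list of sorted node-id vectors) and
#'   \code{component_of} (named integer vector).
#' @export
connected_components <- function(graph) {
  g <- as_igraph(graph)
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1L))]
  names(comps) <- NULL
  component_of <- integer(0)
  for (i in seq_along(comps))
    component_of[comps[[i]]] <- i
  structure(list(components = comps, component_of = component_of),
            class = "ComponentPartition")
}

#' Estimate the number of genes behind a probe set
#'
#' Cross-hybridization makes the probe-to-gene map many-to-many, so a set of
#' differentially expressed probes overstates the number of genes monitored.
#' The estimate is the number of connected components of the subgraph induced
#' by the given probes, their adjacent transcripts, and all edges among them;
#' probes sharing a transcript collapse into one putative gene, and isolated
#' probes count as singleton components.
#'
#' @param graph a \code{\link{build_graph}} result.
#' @param probes probe ids (must all be probe nodes of the graph).
#' @return Integer component count.
#' @export
estimate_gene_count <- function(graph, probes) {
  probes <- unique(as.character(probes))
  unknown <- setdiff(probes, graph$probes)
  if (length(unknown)) stop("unknown probe id(s): ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  e <- graph$edges[graph$edges$probe_id %in% probes, , drop = FALSE]
  sub <- build_graph(e, isolated_probes = probes, thresholds = graph$thresholds)
  length(connected_components(sub)$components)
}
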