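#' Propagate annotations up the ontology (true-path rule)
#'
#' An entity annotated to a term is implicitly annotated to all of that
#' term's ancestors via \code{is_a}/\code{part_of} links, with set semantics:
#' an entity reaching an ancestor along several paths is counted once.
#'
#' @param dag a \code{\link{go_dag}}.
#' @param direct an \code{\link{annotation_table}}; every annotated term must
#'   exist in the DAG.
#' @return An object of class \code{PropagatedAnnotation}: list with
#'   \code{entities} (term -> character vector of entity ids) and
#'   \code{counts} (named integer vector).
#' @export
propagate <- function(dag, direct) {
  stopifnot(inherits(dag, "GoDag"), inherits(direct, "AnnotationTable"))
  used <- unique(unlist(direct, use.names = FALSE))
  unknown <- setdiff(used, dag$terms)
  if (length(unknown)) stop("annotation uses term(s) absent from the ontology: ",
                            paste(unknown, collapse = ", "))
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    res <- t
    for (p in dag$parents[[t]]) res <- union(res, ancestors(p))
    anc_cache[[t]] <- res
    res
  }
  ents <- list()
  for (e in names(direct)) {
    for (t in direct[[e]]) {
      for (a in ancestors(t)) ents[[a]] <- c(ents[[a]], e)
    }
  }
  ents <- lapply(ents, function(v) sort(unique(v)))
  structure(list(entities = ents,
                 counts = vapply(ents, length, integer(1))),
            class = "PropagatedAnnotation")
}

#' Hypergeometric GO-term enrichment
#'
#' For each term annotated (after propagation) to at least one selected
#' entity, the one-sided upper-tail hypergeometric probability of drawing at
#' least \code{k} annotated entities in a selection of size \code{n} from a
#' universe of size \code{N} containing \code{K} annotated entities. The
#' default multiplicity adjustment is Benjamini-Yekutieli, appropriate for
#' the strongly dependent tests along a DAG; BH and Bonferroni are options.
#' Results are sorted by p-value with term id as the deterministic
#' tie-breaker. Namespaces can be tested separately via \code{namespace}.
#'
#' @param selected character vector of selected entity (probe) ids.
#' @param universe character vector of universe ids; must contain
#'   \code{selected}. The conventional choice is all probes carrying at least
#'   one propagated term.
#' @param ann a \code{\link{propagate}} result.
#' @param adjust "BY" (default), "BH" or "bonferroni".
#' @param dag optional \code{\link{go_dag}} to attach term names/namespaces.
#' @param namespace optional single namespace to restrict testing to.
#' @return Data frame of class \code{EnrichmentResult}: \code{term},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{enrichment_ratio},
#'   \code{p}, \code{q}, plus \code{name}/\code{namespace} when a DAG is
#'   given.
#' @export
enrich <- function(selected, universe, ann,
                   adjust = c("BY", "BH", "bonferroni"),
                   dag = NULL, namespace = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(ann, "PropagatedAnnotation"))
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!all(selected %in% universe))
    stop("selected set is not contained in the universe")
  terms <- names(ann$entities)
  if (!is.null(namespace)) {
    if (is.null(dag)) stop("namespace filtering needs the dag")
    terms <- terms[dag$namespaces[terms] %in% namespace]
  }
  N <- length(universe); n <- length(selected)
  rows <- lapply(terms, function(tm) {
    hits <- intersect(ann$entities[[tm]], universe)
    K <- length(hits)
    k <- length(intersect(hits, selected))
    if (k == 0L) return(NULL)  # untestable for over-representation
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               enrichment_ratio = (k / n) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(),
                      enrichment_ratio = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("EnrichmentResult", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$term), , drop = FALSE]        # canonical pre-order
  out$q <- fdr_adjust(out$p, method = adjust)
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (!is.null(dag)) {
    out$name <- if (is.null(dag$names)) NA_character_ else
      unname(dag$names[out$term])
    out$namespace <- if (is.null(dag$namespaces)) NA_character_ else
      unname(dag$namespaces[out$term])
  }
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
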