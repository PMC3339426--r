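#' Gene Ontology DAGs
#'
#' A \code{GoDag} holds term ids, their names and namespaces, and the
#' propagating parent links (\code{is_a} and \code{part_of} only — the
#' relations the true-path rule runs over). The graph must be acyclic.
#'
#' @param terms character vector of term ids.
#' @param parents named list mapping each term to its (possibly empty)
#'   character vector of parent term ids.
#' @param names named character vector of term labels.
#' @param namespaces named character vector with values in
#'   \code{biological_process}, \code{molecular_function},
#'   \code{cellular_component} (or NA when unstated).
#' @return An object of class \code{GoDag}.
#' @export
go_dag <- function(terms, parents, names = NULL, namespaces = NULL) {
  terms <- unique(as.character(terms))
  parents <- parents[intersect(base::names(parents), terms)]
  missing_p <- setdiff(terms, base::names(parents))
  parents[missing_p] <- replicate(length(missing_p), character(), simplify = FALSE)
  endpoints <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(endpoints, terms)
  if (length(unknown)) stop("parent link(s) to unknown term(s): ",
                            paste(unknown, collapse = ", "))
  dag <- structure(list(terms = terms, parents = parents,
                        names = names, namespaces = namespaces),
                   class = "GoDag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) stop("ontology graph is cyclic: ",
                          paste(cyc, collapse = " -> "))
  dag
}

# Depth-first search for a directed cycle; returns one cycle or NULL.
find_cycle <- function(dag) {
  color <- setNames(rep(0L, length(dag$terms)), dag$terms)  # 0 white 1 grey 2 black
  stack_path <- character()
  cycle <- NULL
  visit <- function(t) {
    if (!is.null(cycle)) return()
    color[t] <<- 1L
    stack_path <<- c(stack_path, t)
    for (p in dag$parents[[t]]) {
      if (color[p] == 1L) {
        i <- match(p, stack_path)
        cycle <<- c(stack_path[i:length(stack_path)], p)
        return()
      }
      if (color[p] == 0L) visit(p)
      if (!is.null(cycle)) return()
    }
    color[t] <<- 2L
    stack_path <<- stack_path[-length(stack_path)]
  }
  for (t in dag$terms) if (color[t] == 0L) visit(t)
  cycle
}

#' Read an OBO 1.2 ontology file
#'
#' Loads all \code{[Term]} stanzas. Obsolete terms are excluded; \code{is_a}
#' and \code{relationship: part_of} links are kept as propagating parent
#' edges, all other relationship types are ignored. A cycle among the kept
#' edges is an error.
#'
#' @param path path to an OBO file.
#' @return A \code{\link{go_dag}}.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) stop("no stanzas in OBO file: ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(); nm <- character(); ns <- character()
  parents <- list()
  for (i in seq_along(stanza_starts)) {
    if (lines[stanza_starts[i]] != "[Term]") next
    blk <- lines[(stanza_starts[i] + 1L):(bounds[i + 1L] - 1L)]
    blk <- blk[nzchar(blk)]
    field <- function(key) sub(paste0("^", key, ":\\s*"), "",
                               grep(paste0("^", key, ":"), blk, value = TRUE))
    if (any(grepl("^is_obsolete:\\s*true", blk))) next
    id <- field("id")[1]
    if (is.na(id)) next
    isa <- sub("\\s*!.*$", "", field("is_a"))
    rel <- field("relationship")
    po <- sub("\\s*!.*$", "", sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)]))
    ids <- c(ids, id)
    nm[id] <- if (length(field("name"))) field("name")[1] else NA_character_
    ns[id] <- if (length(field("namespace"))) field("namespace")[1] else NA_character_
    parents[[id]] <- unique(c(isa, po))
  }
  if (!length(ids)) stop("no non-obsolete [Term] stanzas in: ", path)
  # drop parent links to terms that were obsolete/absent
  parents <- lapply(parents, function(p) intersect(p, ids))
  go_dag(ids, parents, nm, ns)
}

#' Write a GoDag as an OBO 1.2 file
#'
#' Inverse of \code{\link{read_obo}} on the fields the package tracks; used
#' by the synthetic-data generators.
#'
#' @param dag a \code{\link{go_dag}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "GoDag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    if (!is.null(dag$names) && !is.na(dag$names[t]))
      writeLines(paste0("name: ", dag$names[t]), con)
    if (!is.null(dag$namespaces) && !is.na(dag$namespaces[t]))
      writeLines(paste0("namespace: ", dag$namespaces[t]), con)
    for (p in dag$parents[[t]]) writeLines(paste0("is_a: ", p), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @export
print.GoDag <- function(x, ...) {
  cat("GoDag with", length(x$terms), "terms and",
      sum(lengths(x$parents)), "parent links\n")
  invisible(x)
}
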