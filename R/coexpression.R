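#' Expression compendium container
#'
#' A probeset-by-array matrix of expression values standing in for a large
#' public single-channel compendium. All-constant rows are dropped with a
#' warning because Pearson correlation is undefined for them.
#'
#' @param matrix numeric matrix, probesets x arrays, with dimnames.
#' @return An object of class \code{ExpressionCompendium}.
#' @export
expression_compendium <- function(matrix) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("compendium matrix needs probeset rownames and array colnames")
  if (any(!is.finite(m))) stop("non-finite expression values")
  const <- apply(m, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    warning("dropping ", sum(const), " all-constant probeset row(s): ",
            paste(utils::head(rownames(m)[const], 5), collapse = ", "))
    m <- m[!const, , drop = FALSE]
  }
  structure(list(matrix = m, probesets = rownames(m), arrays = colnames(m)),
            class = "ExpressionCompendium")
}

#' Read a compendium from a TSV matrix
#'
#' Rows are probesets (first column = id), header row holds array ids.
#'
#' @param path path to the TSV file.
#' @return An \code{\link{expression_compendium}}.
#' @export
read_compendium <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  expression_compendium(as.matrix(tab))
}

#' Write a compendium as a TSV matrix
#'
#' @param comp an \code{\link{expression_compendium}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_compendium <- function(comp, path) {
  tab <- data.frame(probeset = comp$probesets, comp$matrix,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map orthologous clusters to reference-species probesets
#'
#' Each cluster maps to the union of the probesets its reference-species
#' members hit at the similarity thresholds; clusters with no passing hit are
#' reported as unmappable rather than silently dropped.
#'
#' @param clusters an \code{OrthoClusterSet}.
#' @param gene_to_probeset_hits \code{\link{hit_table}} relating reference
#'   gene ids (query) to probeset ids (subject).
#' @param min_identity,min_length thresholds as in \code{\link{filter_hits}}.
#' @return list of class \code{ClusterProbesetMap}: \code{map} (cluster_id ->
#'   probeset ids) and \code{unmappable} (cluster ids).
#' @export
map_clusters <- function(clusters, gene_to_probeset_hits,
                         min_identity = 80, min_length = 100) {
  stopifnot(inherits(clusters, "OrthoClusterSet"))
  h <- gene_to_probeset_hits[
    gene_to_probeset_hits$percent_identity >= min_identity &
      gene_to_probeset_hits$alignment_length >= min_length, , drop = FALSE]
  gene_ps <- split(h$subject_id, h$query_id)
  map <- lapply(clusters$clusters, function(members) {
    sort(unique(unlist(gene_ps[intersect(members, names(gene_ps))],
                       use.names = FALSE)))
  })
  unmappable <- names(map)[lengths(map) == 0L]
  structure(list(map = map[lengths(map) > 0L], unmappable = unmappable),
            class = "ClusterProbesetMap")
}

#' Extract expression vectors for a probeset list
#'
#' One vector per probeset in the compendium's array order; probesets absent
#' from the compendium are reported in the \code{missing} attribute, never
#' silently skipped.
#'
#' @param comp an \code{\link{expression_compendium}}.
#' @param probesets character vector of probeset ids.
#' @return Numeric matrix (found probesets x arrays) with attribute
#'   \code{missing}.
#' @export
expression_vectors <- function(comp, probesets) {
  probesets <- unique(as.character(probesets))
  found <- intersect(probesets, comp$probesets)
  out <- comp$matrix[found, , drop = FALSE]
  attr(out, "missing") <- setdiff(probesets, comp$probesets)
  out
}

#' Pairwise Pearson correlation matrix
#'
#' @param vectors numeric matrix, items x observations (at least 3
#'   observations; no constant rows).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(vectors) {
  v <- as.matrix(vectors)
  if (ncol(v) < 3L) stop("need at least 3 observations per vector")
  const <- apply(v, 1, function(r) stats::sd(r) == 0)
  if (any(const)) stop("constant vector(s): ",
                       paste(rownames(v)[const], collapse = ", "))
  r <- stats::cor(t(v))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Co-expressed groups by hierarchical clustering of 1 - r
#'
#' Agglomerative clustering on the dissimilarity \eqn{d = 1 - r} with the
#' chosen linkage; the tree is cut at height = \code{threshold} and groups of
#' size at least 2 are declared co-expressed — i.e. their members correlate
#' at \eqn{r \ge 1 - threshold} at the linkage level. The small thresholds
#' (0.05, 0.1, 0.2) therefore select the most tightly co-expressed sets;
#' smaller is stricter. Items are ordered canonically by id before
#' clustering so results are input-order invariant.
#'
#' @param r_matrix correlation matrix from \code{\link{pearson_matrix}}.
#' @param threshold cut height in (0, 2); conventional values 0.05, 0.1, 0.2.
#' @param linkage "average" (default), "single" or "complete".
#' @return list of class \code{CoexpressionResult}: \code{groups} (list of
#'   member-id vectors, size >= 2), \code{singletons}, \code{threshold},
#'   \code{linkage}, \code{r} (the reordered matrix).
#' @export
coexpressed_groups <- function(r_matrix, threshold = 0.2,
                               linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (threshold <= 0 || threshold >= 2) stop("threshold must be in (0, 2)")
  ids <- sort(rownames(r_matrix))
  r <- r_matrix[ids, ids, drop = FALSE]
  if (length(ids) < 2L) {
    return(structure(list(groups = list(), singletons = ids,
                          threshold = threshold, linkage = linkage, r = r),
                     class = "CoexpressionResult"))
  }
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  memb <- stats::cutree(hc, h = threshold)
  groups <- split(ids, memb)
  sizes <- lengths(groups)
  multi <- unname(groups[sizes >= 2L])
  multi <- lapply(multi, sort)
  multi <- multi[order(vapply(multi, `[`, character(1), 1L))]
  structure(list(groups = multi,
                 singletons = sort(unlist(groups[sizes == 1L], use.names = FALSE)),
                 threshold = threshold, linkage = linkage, r = r),
            class = "CoexpressionResult")
}

#' @export
print.CoexpressionResult <- function(x, ...) {
  cat("CoexpressionResult:", length(x$groups), "co-expressed group(s) and",
      length(x$singletons), "singleton(s) at cut height", x$threshold,
      paste0("(", x$linkage, " linkage)\n"))
  invisible(x)
}
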