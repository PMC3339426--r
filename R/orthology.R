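#' Translate ESTs by six-frame longest-ORF prediction
#'
#' A deterministic stand-in for heavyweight EST translation pipelines: each
#' EST is translated in all six frames under the standard genetic code and
#' the longest ATG-to-stop open reading frame of at least \code{min_orf_aa}
#' residues is kept. If no ATG ORF qualifies, the longest stop-free stretch
#' of at least the same length is used as a fallback. Ties break
#' deterministically to the lowest frame (+1, +2, +3, -1, -2, -3), then the
#' leftmost start. ESTs with no qualifying ORF are omitted and reported in
#' the \code{skipped} attribute. Externally produced translations can be
#' supplied downstream instead; nothing else depends on this stand-in.
#'
#' @param ests a nucleotide \code{\link{SequenceSet}}.
#' @param min_orf_aa minimum peptide length in amino acids (default 30).
#' @param species species tag recorded per protein.
#' @return A \code{ProteinSet} data frame with columns \code{protein_id},
#'   \code{source_est_id}, \code{species}, \code{sequence}, \code{frame};
#'   attribute \code{skipped} lists ESTs without a qualifying ORF.
#' @export
translate_ests <- function(ests, min_orf_aa = 30, species = "unknown") {
  stopifnot(inherits(ests, "SequenceSet"))
  if (attr(ests, "alphabet") != "nucleotide") stop("ests must be nucleotide sequences")
  res <- lapply(seq_len(nrow(ests)), function(i) {
    orf <- best_orf(ests$sequence[i], min_orf_aa)
    if (is.null(orf)) return(NULL)
    data.frame(protein_id = paste0(ests$id[i], "_p1"),
               source_est_id = ests$id[i], species = species,
               sequence = orf$peptide, frame = orf$frame,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(res, is.null, logical(1))
  out <- if (any(keep)) do.call(rbind, res[keep]) else
    data.frame(protein_id = character(), source_est_id = character(),
               species = character(), sequence = character(),
               frame = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- ests$id[!keep]
  class(out) <- c("ProteinSet", "data.frame")
  out
}

# translate one frame; frames ordered +1,+2,+3,-1,-2,-3
frame_peptide <- function(seq, frame) {
  s <- if (frame > 0) seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  off <- abs(frame) - 1L
  s <- substr(s, off + 1L, nchar(s))
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(s, 1L, n)),
                          no.init.codon = TRUE, if.fuzzy.codon = "X")))
}

# longest ATG..stop ORF across six frames (fallback: longest stop-free run)
best_orf <- function(seq, min_orf_aa) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  best <- NULL
  scan <- function(pattern, trim_m = FALSE) {
    for (f in frames) {
      pep <- frame_peptide(seq, f)
      if (!nzchar(pep)) next
      m <- gregexpr(pattern, pep, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (j in seq_along(m)) {
        cand <- substr(pep, m[j], m[j] + attr(m, "match.length")[j] - 1L)
        cand <- sub("\\*$", "", cand)
        if (nchar(cand) < min_orf_aa) next
        if (is.null(best) || nchar(cand) > nchar(best$peptide))
          best <<- list(peptide = cand, frame = f, start = m[j])
      }
    }
  }
  scan("M[^*]*\\*")                  # complete ORFs: ATG .. stop
  if (is.null(best)) scan("M[^*]*$") # else: ORF running off the 3' end
  if (is.null(best)) scan("[^*]+")   # else: longest stop-free stretch
  best
}

#' Cluster proteins into orthologous groups by Markov clustering
#'
#' A documented, simplified stand-in for graph-based ortholog inference:
#' all-vs-all protein hits are turned into a symmetric similarity
#' \eqn{s(i,j) = -\log_{10}(\mathrm{evalue})} (capped at \code{cap},
#' symmetrized by the maximum over directions, hits above
#' \code{evalue_cutoff} discarded), and the similarity matrix is clustered by
#' Markov clustering: column-normalize, then iterate expansion (matrix
#' square) and inflation (elementwise power \code{inflation},
#' renormalize) until the matrix changes by less than \code{tol} or
#' \code{max_iter} iterations. Clusters are the connected components of the
#' converged matrix's nonzero structure. Proteins with no retained hit become
#' singleton clusters. Reciprocal-best-hit normalization between species is
#' deliberately omitted; precomputed cluster files
#' (\code{\link{read_cluster_file}}) are accepted as an alternative input.
#'
#' @param protein_hits all-vs-all \code{\link{hit_table}} (self-hits allowed).
#' @param inflation granularity parameter, must exceed 1 (default 1.5).
#' @param evalue_cutoff discard hits with larger e-value (default 1e-5).
#' @param cap ceiling for -log10(evalue) (handles evalue = 0).
#' @param tol,max_iter convergence controls.
#' @param proteins optional full protein universe; ids absent from the hits
#'   are appended as singleton clusters.
#' @return An \code{OrthoClusterSet}: list with \code{clusters} (named list
#'   of member-id vectors, named \code{OC000001}, ...) and \code{inflation}.
#' @export
cluster_orthologs <- function(protein_hits, inflation = 1.5,
                              evalue_cutoff = 1e-5, cap = 200,
                              tol = 1e-6, max_iter = 100L,
                              proteins = NULL) {
  if (inflation <= 1) stop("inflation must be > 1")
  h <- protein_hits[protein_hits$evalue <= evalue_cutoff, , drop = FALSE]
  ids <- sort(unique(c(h$query_id, h$subject_id, as.character(proteins))))
  n <- length(ids)
  if (n == 0)
    return(structure(list(clusters = list(), inflation = inflation),
                     class = "OrthoClusterSet"))
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(h)) {
    sim <- pmin(-log10(pmax(h$evalue, 10^(-cap))), cap)
    i <- match(h$query_id, ids); j <- match(h$subject_id, ids)
    for (k in seq_along(i)) {
      v <- max(S[i[k], j[k]], sim[k])
      S[i[k], j[k]] <- v
      S[j[k], i[k]] <- v
    }
  }
  diag(S) <- pmax(diag(S), apply(S, 2, max), 1)  # self-loops stabilize MCL
  M <- sweep(S, 2, colSums(S), "/")
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2 ^ inflation                # inflation
    M2[M2 < 1e-12] <- 0                 # prune
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  # clusters = connected components of the converged nonzero structure
  A <- (M > 1e-9) | t(M > 1e-9)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership
  comps <- split(ids, memb)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1L))]
  names(comps) <- sprintf("OC%06d", seq_along(comps))
  structure(list(clusters = comps, inflation = inflation),
            class = "OrthoClusterSet")
}

#' Read a precomputed cluster file
#'
#' Format: one cluster per line, \code{cluster_id<TAB>member1,member2,...}.
#'
#' @param path path to the TSV file.
#' @return An \code{OrthoClusterSet} (inflation recorded as NA).
#' @export
read_cluster_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  cl <- lapply(parts, function(p) sort(strsplit(p[2], ",", fixed = TRUE)[[1]]))
  names(cl) <- vapply(parts, `[[`, character(1), 1L)
  structure(list(clusters = cl, inflation = NA_real_),
            class = "OrthoClusterSet")
}

#' Write an OrthoClusterSet as a cluster file
#'
#' @param clusters an \code{OrthoClusterSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cluster_file <- function(clusters, path) {
  lines <- vapply(seq_along(clusters$clusters), function(i) {
    paste0(names(clusters$clusters)[i], "\t",
           paste(clusters$clusters[[i]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.OrthoClusterSet <- function(x, ...) {
  cat("OrthoClusterSet:", length(x$clusters), "clusters over",
      sum(lengths(x$clusters)), "proteins (inflation ", x$inflation, ")\n")
  invisible(x)
}

#' Project annotations through orthologous clusters
#'
#' Every cluster member receives the union of the GO/InterPro terms of all
#' annotated members of its cluster (accumulation, not voting). Members of
#' clusters with no annotated partner receive the empty set. Provenance is
#' recorded per projected entity and term as the source entities carrying it.
#'
#' @param clusters an \code{OrthoClusterSet}.
#' @param reference_annotations an \code{\link{annotation_table}} keyed by
#'   reference-species protein ids (ids absent from the clusters are ignored).
#' @return A \code{ProjectedAnnotation}: list with \code{terms} (an
#'   \code{AnnotationTable} over all cluster members) and \code{provenance}
#'   (per member, a named list term -> source ids).
#' @export
project_annotations <- function(clusters, reference_annotations) {
  stopifnot(inherits(clusters, "OrthoClusterSet"),
            inherits(reference_annotations, "AnnotationTable"))
  terms <- list(); provenance <- list()
  for (members in clusters$clusters) {
    annotated <- intersect(members, names(reference_annotations))
    annotated <- annotated[lengths(reference_annotations[annotated]) > 0]
    pooled <- sort(unique(as.character(
      unlist(reference_annotations[annotated], use.names = FALSE))))
    prov <- NULL
    if (length(pooled)) {
      prov <- lapply(pooled, function(tm) {
        annotated[vapply(annotated,
                         function(a) tm %in% reference_annotations[[a]],
                         logical(1))]
      })
      names(prov) <- pooled
    }
    for (m in members) {
      terms[[m]] <- pooled
      provenance[[m]] <- prov
    }
  }
  structure(list(terms = annotation_table(terms), provenance = provenance),
            class = "ProjectedAnnotation")
}

#' Transfer projected EST annotations onto array probes
#'
#' A probe inherits the union of the annotations of every transcript (EST)
#' predicted to hybridize to it in the graph. Isolated probes are listed with
#' empty term sets rather than dropped, matching the published
#' probe-annotation table layout.
#'
#' @param graph a \code{\link{build_graph}} whose transcripts are the ESTs.
#' @param est_annotations a \code{ProjectedAnnotation} (keyed by protein id)
#'   or an \code{AnnotationTable} keyed directly by EST id.
#' @param est_to_protein named character vector EST id -> protein id; omit
#'   when \code{est_annotations} is already keyed by EST id.
#' @return An \code{\link{annotation_table}} keyed by probe id covering every
#'   probe node of the graph.
#' @export
annotate_probes <- function(graph, est_annotations, est_to_protein = NULL) {
  ann <- if (inherits(est_annotations, "ProjectedAnnotation"))
    est_annotations$terms else est_annotations
  stopifnot(inherits(ann, "AnnotationTable"))
  est_terms <- function(est) {
    key <- if (is.null(est_to_protein)) est else unname(est_to_protein[est])
    if (is.na(key) || is.null(ann[[key]])) character() else ann[[key]]
  }
  by_probe <- split(graph$edges$transcript_id, graph$edges$probe_id)
  out <- setNames(replicate(length(graph$probes), character(),
                            simplify = FALSE), graph$probes)
  for (p in names(by_probe)) {
    out[[p]] <- sort(unique(unlist(lapply(by_probe[[p]], est_terms),
                                   use.names = FALSE)))
  }
  annotation_table(out)
}
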