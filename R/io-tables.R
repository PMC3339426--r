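#' Read a BLAST-style tabular hit table
#'
#' Reads the 12-column tab-separated dialect (query, subject, percent
#' identity, alignment length, mismatches, gap opens, q.start, q.end,
#' s.start, s.end, e-value, bit score) or a caller-declared column map.
#' Comment lines starting with \code{#} are skipped. Only the six columns the
#' workflow uses are retained and typed.
#'
#' @param path path to the tab-separated file.
#' @param dialect either "blast12" (default) or a named integer vector giving
#'   the 1-based positions of \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{alignment_length}, \code{evalue},
#'   \code{bitscore}.
#' @return A \code{HitTable}: data frame with the six typed columns.
#' @export
read_hit_table <- function(path, dialect = "blast12") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  if (identical(dialect, "blast12")) {
    cols <- c(query_id = 1L, subject_id = 2L, percent_identity = 3L,
              alignment_length = 4L, evalue = 11L, bitscore = 12L)
  } else {
    cols <- dialect
    need <- c("query_id", "subject_id", "percent_identity",
              "alignment_length", "evalue", "bitscore")
    if (!all(need %in% names(cols))) stop("dialect must map columns: ",
                                          paste(need, collapse = ", "))
  }
  if (length(lines) == 0) {
    return(hit_table(character(), character(), numeric(), integer(),
                     numeric(), numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < max(cols))) {
    stop("line ", which(keep)[which(n < max(cols))[1]],
         ": fewer columns than the dialect requires")
  }
  grab <- function(i) vapply(parts, `[[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(grab(i)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("line ", which(keep)[bad], ": non-numeric ", what)
    }
    v
  }
  hit_table(grab(cols["query_id"]), grab(cols["subject_id"]),
            num(cols["percent_identity"], "percent identity"),
            as.integer(num(cols["alignment_length"], "alignment length")),
            num(cols["evalue"], "e-value"),
            num(cols["bitscore"], "bit score"))
}

#' Construct a HitTable from vectors
#'
#' @param query_id,subject_id character ids.
#' @param percent_identity real in [0, 100].
#' @param alignment_length integer, at least 1.
#' @param evalue non-negative real.
#' @param bitscore real.
#' @return A validated \code{HitTable} data frame.
#' @export
hit_table <- function(query_id, subject_id, percent_identity,
                      alignment_length, evalue, bitscore) {
  out <- data.frame(query_id = as.character(query_id),
                    subject_id = as.character(subject_id),
                    percent_identity = as.numeric(percent_identity),
                    alignment_length = as.integer(alignment_length),
                    evalue = as.numeric(evalue),
                    bitscore = as.numeric(bitscore),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (anyNA(out)) stop("NA/NaN in required hit-table columns")
    if (any(out$percent_identity < 0 | out$percent_identity > 100))
      stop("percent_identity outside [0, 100]")
    if (any(out$alignment_length < 1L)) stop("alignment_length < 1")
    if (any(out$evalue < 0)) stop("negative e-value")
  }
  class(out) <- c("HitTable", "data.frame")
  out
}

#' Write a HitTable in 12-column BLAST tabular format
#'
#' Columns the workflow does not track (mismatches, gaps, coordinates) are
#' written as zeros so the file round-trips through \code{read_hit_table}.
#'
#' @param hits a \code{HitTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  z <- rep(0L, nrow(hits))
  tab <- data.frame(hits$query_id, hits$subject_id,
                    format(hits$percent_identity, trim = TRUE),
                    hits$alignment_length, z, z, z, z, z, z,
                    format(hits$evalue, trim = TRUE),
                    format(hits$bitscore, trim = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Probe/gene annotation tables
#'
#' An \code{AnnotationTable} maps entity ids (probes, genes or proteins) to
#' sets of GO and/or InterPro term ids. Empty term sets are meaningful: they
#' mark an entity as explicitly unannotated.
#'
#' @param terms named list; each element a character vector of term ids
#'   (possibly empty). Names are the entity ids and must be unique.
#' @return An object of class \code{AnnotationTable} (a named list).
#' @export
annotation_table <- function(terms) {
  if (length(terms) == 0) {
    terms <- stats::setNames(list(), character())
    class(terms) <- "AnnotationTable"
    return(terms)
  }
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stop("all entities must be named")
  if (anyDuplicated(names(terms)))
    stop("duplicate entity id(s): ",
         paste(unique(names(terms)[duplicated(names(terms))]), collapse = ", "))
  terms <- lapply(terms, function(x) sort(unique(as.character(x))))
  class(terms) <- "AnnotationTable"
  terms
}

#' Write a probe-to-GO annotation table
#'
#' Tab-delimited, one entity per line: \code{id<TAB>terms}, with terms joined
#' by a separator (default \code{" // "}, a comma is the documented
#' alternative). The layout matches GO-enrichment tools that accept custom
#' tab-delimited annotation files. Entities with empty term sets are written
#' with an empty second field.
#'
#' @param table an \code{\link{annotation_table}}.
#' @param path output path.
#' @param sep within-field term separator.
#' @return \code{path}, invisibly.
#' @export
write_probe_annotation <- function(table, path, sep = " // ") {
  stopifnot(inherits(table, "AnnotationTable"))
  lines <- vapply(seq_along(table), function(i) {
    paste0(names(table)[i], "\t", paste(table[[i]], collapse = sep))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-GO annotation table written by write_probe_annotation
#'
#' @inheritParams write_probe_annotation
#' @return An \code{\link{annotation_table}}.
#' @export
read_probe_annotation <- function(path, sep = " // ") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  terms <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) character() else
      strsplit(p[2L], sep, fixed = TRUE)[[1]]
  })
  names(terms) <- ids
  annotation_table(terms)
}
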