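#' Read a run configuration
#'
#' The configuration is a flat YAML-like key-value file: one \code{key:
#' value} pair per line, \code{#} comments allowed. Every workflow tunable
#' surfaces as a named key with its conventional default (identity 80,
#' length 100, normexp offset 50, alpha 0.05, co-expression thresholds
#' 0.05/0.1/0.2). Values are coerced to numeric where possible;
#' comma-separated values become vectors.
#'
#' @param path path to the config file, or NULL for pure defaults.
#' @param overrides named list merged over the file values.
#' @return A named list of class \code{RunConfig}.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    hits = NULL, probes_fasta = NULL, ests_fasta = NULL,
    protein_hits = NULL, reference_annotations = NULL,
    obo = NULL, compendium = NULL, cluster_file = NULL,
    gene_to_probeset_hits = NULL, targets = NULL, gpr_dir = NULL,
    min_identity = 80, min_length = 100, min_orf_aa = 30,
    inflation = 1.5, evalue_cutoff = 1e-5,
    normexp_offset = 50, loess_span = 0.3, alpha = 0.05,
    fdr_method = "BH", enrich_adjust = "BY",
    coexpression_thresholds = c(0.05, 0.1, 0.2), linkage = "average",
    seed = 1, out_dir = "results")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[grepl(":", lines)])
    for (ln in lines[nzchar(lines)]) {
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (grepl(",", val)) val <- trimws(strsplit(val, ",")[[1]])
      num <- suppressWarnings(as.numeric(val))
      if (!anyNA(num)) val <- num
      cfg[[key]] <- val
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Write the resolved configuration next to results
#'
#' @param config a \code{RunConfig}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  lines <- vapply(names(config)[keep], function(k)
    paste0(k, ": ", paste(config[[k]], collapse = ", ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Probe reannotation workflow
#'
#' Composes the annotation chain on in-memory inputs: hit filtering, graph
#' construction, EST translation, ortholog clustering, annotation projection
#' and transfer onto probes. Equivalent to running the stages by hand; any
#' stage error aborts with the stage name.
#'
#' @param hits probe/transcript \code{\link{hit_table}}.
#' @param ests nucleotide \code{\link{SequenceSet}} of transcripts.
#' @param probe_ids full probe universe (isolated probes are kept).
#' @param protein_hits all-vs-all protein \code{\link{hit_table}} (the
#'   EST-derived proteins plus reference proteins); ignored when
#'   \code{clusters} is supplied.
#' @param reference_annotations \code{\link{annotation_table}} keyed by
#'   reference protein id.
#' @param clusters optional precomputed \code{OrthoClusterSet}.
#' @param config a \code{\link{read_run_config}}.
#' @return list of class \code{ReannotationResult}: \code{graph},
#'   \code{metrics}, \code{proteins}, \code{clusters}, \code{projected},
#'   \code{probe_annotations}.
#' @export
run_reannotation <- function(hits, ests, probe_ids,
                             protein_hits = NULL,
                             reference_annotations = annotation_table(list()),
                             clusters = NULL,
                             config = read_run_config()) {
  edges <- stage("filter_hits",
                 filter_hits(hits, config$min_identity, config$min_length))
  graph <- stage("build_graph", build_graph(edges, isolated_probes = probe_ids,
                 thresholds = c(min_identity = config$min_identity,
                                min_length = config$min_length)))
  metrics <- stage("probe_metrics", probe_metrics(graph))
  proteins <- stage("translate_ests",
                    translate_ests(ests, min_orf_aa = config$min_orf_aa))
  if (is.null(clusters)) {
    if (is.null(protein_hits)) stop("stage 'cluster_orthologs' failed: ",
                                    "need protein_hits or precomputed clusters")
    clusters <- stage("cluster_orthologs",
                      cluster_orthologs(protein_hits,
                                        inflation = config$inflation,
                                        evalue_cutoff = config$evalue_cutoff,
                                        proteins = proteins$protein_id))
  }
  projected <- stage("project_annotations",
                     project_annotations(clusters, reference_annotations))
  est_to_protein <- setNames(proteins$protein_id, proteins$source_est_id)
  probe_ann <- stage("annotate_probes",
                     annotate_probes(graph, projected, est_to_protein))
  if (length(graph$edges$probe_id) == 0)
    warning("empty edge set: all probes unannotated")
  structure(list(graph = graph, metrics = metrics, proteins = proteins,
                 clusters = clusters, projected = projected,
                 probe_annotations = probe_ann),
            class = "ReannotationResult")
}

#' End-to-end workflow on in-memory inputs
#'
#' Runs reannotation, the two-color DE chain, GO enrichment of the jointly
#' significant probes and cross-species co-expression of their clusters, and
#' (optionally) writes every intermediate under \code{config$out_dir}.
#'
#' @param inputs list with elements \code{hits}, \code{ests},
#'   \code{probe_ids}, \code{reference_annotations}, \code{clusters} (or
#'   \code{protein_hits}), \code{arrays}, \code{targets}, \code{dag},
#'   \code{compendium}, \code{gene_to_probeset_hits}.
#' @param config a \code{\link{read_run_config}}.
#' @param write_outputs write TSV/XGMML/JSON outputs under
#'   \code{config$out_dir}.
#' @return list of class \code{WorkflowResult}: \code{reannotation},
#'   \code{de}, \code{enrichment}, \code{coexpression}, \code{summary}.
#' @export
run_full <- function(inputs, config = read_run_config(), write_outputs = FALSE) {
  reann <- run_reannotation(inputs$hits, inputs$ests, inputs$probe_ids,
                            protein_hits = inputs$protein_hits,
                            reference_annotations = inputs$reference_annotations,
                            clusters = inputs$clusters, config = config)
  de <- stage("de_pipeline",
              de_pipeline(inputs$arrays, inputs$targets,
                          offset = config$normexp_offset,
                          span = config$loess_span, alpha = config$alpha,
                          fdr_method = config$fdr_method))
  sig <- de$classification$table$probe_id[
    de$classification$table$category != "not-significant"]
  if (is.null(inputs$dag)) stop("stage 'enrich' failed: no ontology input")
  prop <- stage("propagate", propagate(inputs$dag, reann$probe_annotations))
  universe <- names(reann$probe_annotations)[
    lengths(reann$probe_annotations) > 0]
  selected <- intersect(sig, universe)
  enrichment <- stage("enrich",
                      enrich(selected, universe, prop,
                             adjust = config$enrich_adjust, dag = inputs$dag))
  coexpr <- NULL
  if (!is.null(inputs$compendium) && !is.null(inputs$gene_to_probeset_hits)) {
    coexpr <- stage("coexpression", {
      cmap <- map_clusters(reann$clusters, inputs$gene_to_probeset_hits,
                           config$min_identity, config$min_length)
      ps <- unique(unlist(cmap$map, use.names = FALSE))
      vec <- expression_vectors(inputs$compendium, ps)
      if (nrow(vec) >= 2L) {
        r <- pearson_matrix(vec)
        lapply(setNames(nm = as.character(config$coexpression_thresholds)),
               function(th) coexpressed_groups(r, as.numeric(th),
                                               linkage = config$linkage))
      } else list()
    })
  }
  n_genes <- if (length(sig))
    estimate_gene_count(reann$graph, intersect(sig, reann$graph$probes)) else 0L
  summary <- list(n_probes = length(reann$graph$probes),
                  n_edges = nrow(reann$graph$edges),
                  de_counts = de$classification$counts,
                  n_de_probes = length(sig),
                  estimated_genes = n_genes,
                  n_enriched_terms = sum(enrichment$q <= config$alpha,
                                         na.rm = TRUE),
                  duplicate_correlation = de$rho)
  res <- structure(list(reannotation = reann, de = de, enrichment = enrichment,
                        coexpression = coexpr, summary = summary,
                        config = config),
                   class = "WorkflowResult")
  if (write_outputs) write_workflow_outputs(res, config$out_dir)
  res
}

write_workflow_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_probe_annotation(res$reannotation$probe_annotations, p("probe_go.tsv"))
  utils::write.table(res$reannotation$metrics, p("probe_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_graph_xgmml(res$reannotation$graph, p("hybridization_graph.xgmml"))
  utils::write.table(res$de$results, p("de_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cc <- res$de$classification$counts
  utils::write.table(data.frame(category = names(cc), probes = as.integer(cc)),
                     p("de_summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(res$enrichment), p("go_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$coexpression)) {
    rows <- list()
    for (th in names(res$coexpression)) {
      gs <- res$coexpression[[th]]$groups
      for (i in seq_along(gs))
        rows[[length(rows) + 1L]] <- data.frame(
          threshold = th, group_id = i,
          members = paste(gs[[i]], collapse = ","))
    }
    if (length(rows))
      utils::write.table(do.call(rbind, rows), p("coexpression_groups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  write_run_config(res$config, p("config_resolved.txt"))
  invisible(out_dir)
}
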