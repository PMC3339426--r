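# Seeded generators for every input the workflow consumes, with planted
# ground truth. All generators are pure functions of (params, seed): they
# save and restore the caller's RNG state.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Synthetic probe/transcript hybridization fixture
#'
#' Generates probe and transcript sequence sets and a BLAST-style hit table
#' in which planted true edges sit above the (80% identity, 100 bp)
#' hybridization thresholds and decoy hits sit below at least one of them,
#' so \code{\link{filter_hits}} must recover exactly the planted edges.
#'
#' @param n_probes,n_transcripts set sizes.
#' @param edge_density probability of a planted edge per (probe, transcript)
#'   pair.
#' @param identity_range range of planted-edge percent identities (must stay
#'   at or above 80).
#' @param n_decoys number of sub-threshold decoy hits.
#' @param seed RNG seed.
#' @return list: \code{probes}, \code{transcripts} (SequenceSets),
#'   \code{hits} (HitTable, probes on the subject side), \code{truth}
#'   (data frame of planted edges plus the seed).
#' @export
make_hybridization_fixture <- function(n_probes = 100, n_transcripts = 150,
                                       edge_density = 0.02,
                                       identity_range = c(85, 99),
                                       n_decoys = 2 * n_probes, seed = 1) {
  stopifnot(n_probes > 0, n_transcripts > 0, identity_range[1] >= 80)
  with_seed(seed, {
    probe_ids <- sprintf("PRB%04d", seq_len(n_probes))
    tx_ids <- sprintf("EST%04d", seq_len(n_transcripts))
    probes <- SequenceSet(probe_ids, "probe",
                          random_seq(n_probes, 300), "nucleotide")
    transcripts <- SequenceSet(tx_ids, "transcript",
                               random_seq(n_transcripts, 600), "nucleotide")
    pairs <- expand.grid(probe = probe_ids, tx = tx_ids,
                         stringsAsFactors = FALSE)
    planted <- pairs[stats::runif(nrow(pairs)) < edge_density, , drop = FALSE]
    n_e <- nrow(planted)
    true_ident <- stats::runif(n_e, identity_range[1], identity_range[2])
    true_len <- sample(100:300, n_e, replace = TRUE)
    # decoys fail identity, length, or both
    d_probe <- sample(probe_ids, n_decoys, replace = TRUE)
    d_tx <- sample(tx_ids, n_decoys, replace = TRUE)
    mode <- sample(1:3, n_decoys, replace = TRUE)
    d_ident <- ifelse(mode != 2L, stats::runif(n_decoys, 40, 79.9),
                      stats::runif(n_decoys, 80, 99))
    d_len <- ifelse(mode != 1L, sample(30:99, n_decoys, replace = TRUE),
                    sample(100:300, n_decoys, replace = TRUE))
    ident <- c(true_ident, d_ident)
    len <- as.integer(c(true_len, d_len))
    bits <- round(2 * len * ident / 100, 1)
    hits <- hit_table(query_id = c(planted$tx, d_tx),
                      subject_id = c(planted$probe, d_probe),
                      percent_identity = round(ident, 1),
                      alignment_length = len,
                      evalue = signif(10^(-bits / 10), 3),
                      bitscore = bits)
    truth <- data.frame(probe_id = planted$probe, transcript_id = planted$tx,
                        stringsAsFactors = FALSE)
    truth <- unique(truth[order(truth$probe_id, truth$transcript_id), ])
    rownames(truth) <- NULL
    list(probes = probes, transcripts = transcripts, hits = hits,
         truth = list(edges = truth, seed = seed))
  })
}

#' Wire a probe set into an exact number of graph components
#'
#' Constructs a hybridization graph in which \code{n_probes} probes form
#' exactly \code{n_components} connected components: component sizes are
#' dealt round-robin, multi-probe components share a single transcript, and
#' size-1 components are either a probe with its own transcript or an
#' isolated probe. Used to validate probe-to-gene collapse counting (e.g.
#' 318 probes wired into 250 putative genes).
#'
#' @param n_probes number of probes.
#' @param n_components target component count (at most \code{n_probes}).
#' @param isolated_frac fraction of the singleton components kept isolated
#'   (no transcript at all).
#' @param seed RNG seed.
#' @return list: \code{graph} (HybGraph), \code{probes} (ids), \code{truth}
#'   (component assignment).
#' @export
make_component_fixture <- function(n_probes = 318, n_components = 250,
                                   isolated_frac = 0.2, seed = 1) {
  stopifnot(n_components <= n_probes)
  with_seed(seed, {
    probe_ids <- sprintf("PRB%04d", seq_len(n_probes))
    comp <- sort(rep_len(seq_len(n_components), n_probes))
    groups <- split(probe_ids, comp)
    edges <- list(); isolated <- character()
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      if (length(g) == 1L && stats::runif(1) < isolated_frac) {
        isolated <- c(isolated, g)
      } else {
        edges[[length(edges) + 1L]] <- data.frame(
          probe_id = g, transcript_id = sprintf("EST%04d", i),
          percent_identity = 95, alignment_length = 150L, bitscore = 300,
          stringsAsFactors = FALSE)
      }
    }
    e <- do.call(rbind, edges)
    class(e) <- c("HybEdge", "data.frame")
    graph <- build_graph(e, isolated_probes = isolated)
    list(graph = graph, probes = probe_ids,
         truth = list(component_of = setNames(comp, probe_ids),
                      n_components = n_components, seed = seed))
  })
}

#' Synthetic two-color experiment with planted differential expression
#'
#' Emulates the three-slide heterologous design: two dye-swapped slides
#' comparing transgenic line 37 to wild type and one slide comparing line 45
#' to wild type (preset \code{design = "two-line-3-slide"}). Every probe is
#' printed twice per array. Per spot, the log2 ratio is
#' effect x line + duplicate-correlated noise; channel intensities add an
#' intensity-dependent dye bias (a smooth function of A, exercising
#' print-tip loess), an additive normal background and scanner noise
#' (exercising normexp). Truth lists the planted DE probes and their signs
#' per line.
#'
#' @param n_probes number of distinct probes (default 2000).
#' @param design \code{"two-line-3-slide"} (the only preset) or a targets
#'   data frame with columns \code{array_id}, \code{line},
#'   \code{dye_orientation}.
#' @param n_de_shared probes differentially expressed in both lines.
#' @param shared_down_frac fraction of shared-DE probes that are
#'   down-regulated (default 0.8, the down-dominated regime typical of this
#'   kind of contrast).
#' @param n_de_discordant probes with opposite signs in the two lines.
#' @param effect_log2 absolute log2 fold change of planted effects.
#' @param dup_correlation true within-array duplicate correlation.
#' @param dye_effect amplitude (log2) of the intensity-dependent dye bias.
#' @param noise_sd per-spot log2-ratio noise sd.
#' @param flag_frac fraction of spots flagged bad.
#' @param n_blocks print-tip groups per array.
#' @param seed RNG seed.
#' @return list: \code{arrays} (list of TwoColorArray), \code{targets}
#'   (data frame), \code{truth} (per-probe signed effects per line, plus
#'   parameters and seed).
#' @export
make_two_color_experiment <- function(n_probes = 2000,
                                      design = "two-line-3-slide",
                                      n_de_shared = 50,
                                      shared_down_frac = 0.8,
                                      n_de_discordant = 0,
                                      effect_log2 = 1.5,
                                      dup_correlation = 0.7,
                                      dye_effect = 0.3,
                                      noise_sd = 0.25,
                                      flag_frac = 0.02,
                                      n_blocks = 4, seed = 1) {
  targets <- if (is.data.frame(design)) design else {
    if (!identical(design, "two-line-3-slide"))
      stop("unknown design preset: ", design)
    data.frame(array_id = c("slide37a", "slide37b", "slide45"),
               line = c("line37", "line37", "line45"),
               dye_orientation = c("treatment_in_ch1", "treatment_in_ch2",
                                   "treatment_in_ch1"),
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    probe_ids <- sprintf("PRB%05d", seq_len(n_probes))
    eff37 <- eff45 <- setNames(rep(0, n_probes), probe_ids)
    de_ids <- character(); disc_ids <- character()
    if (n_de_shared + n_de_discordant > 0) {
      picked <- sample(probe_ids, n_de_shared + n_de_discordant)
      de_ids <- picked[seq_len(n_de_shared)]
      disc_ids <- setdiff(picked, de_ids)
      n_down <- round(shared_down_frac * n_de_shared)
      sgn <- c(rep(-1, n_down), rep(1, n_de_shared - n_down))
      eff37[de_ids] <- sgn * effect_log2
      eff45[de_ids] <- sgn * effect_log2
      if (length(disc_ids)) {
        dsgn <- rep_len(c(-1, 1), length(disc_ids))
        eff37[disc_ids] <- dsgn * effect_log2
        eff45[disc_ids] <- -dsgn * effect_log2
      }
    }
    baseline <- stats::runif(n_probes, 7, 15)
    n_spots <- 2L * n_probes
    spot_probe <- rep(seq_len(n_probes), each = 2L)
    per_block <- ceiling(n_spots / n_blocks)
    block <- rep(seq_len(n_blocks), each = per_block)[seq_len(n_spots)]
    idx_in_block <- stats::ave(seq_len(n_spots), block, FUN = seq_along)
    arrays <- lapply(seq_len(nrow(targets)), function(a) {
      line <- targets$line[a]
      eff <- if (line == "line37") eff37 else eff45
      z0 <- stats::rnorm(n_probes)                       # shared duplicate part
      zi <- matrix(stats::rnorm(n_spots), ncol = 2L)     # spot-specific part
      e <- noise_sd * (sqrt(dup_correlation) * z0 +
                         sqrt(1 - dup_correlation) * zi)
      m_spot <- eff[spot_probe] + c(t(e))                # 2 spots per probe
      a_spot <- baseline[spot_probe] + stats::rnorm(n_spots, 0, 0.15)
      log_trt <- a_spot + m_spot / 2
      log_ref <- a_spot - m_spot / 2
      bias <- dye_effect * (0.5 + ((a_spot - 10) / 6)^2)  # smooth in A
      if (targets$dye_orientation[a] == "treatment_in_ch1") {
        l1 <- log_trt + bias; l2 <- log_ref
      } else {
        l1 <- log_ref + bias; l2 <- log_trt
      }
      bg1 <- pmax(stats::rnorm(n_spots, 100, 15), 0)
      bg2 <- pmax(stats::rnorm(n_spots, 90, 15), 0)
      fg1 <- pmax(bg1 + 2^l1 + stats::rnorm(n_spots, 0, 15), 0)
      fg2 <- pmax(bg2 + 2^l2 + stats::rnorm(n_spots, 0, 15), 0)
      flag <- ifelse(stats::runif(n_spots) < flag_frac, -50L, 0L)
      spots <- data.frame(
        spot_id = sprintf("%d.%d.1", block, idx_in_block),
        probe_id = probe_ids[spot_probe],
        block = block, row = idx_in_block, column = 1L,
        fg_ch1 = round(fg1, 1), bg_ch1 = round(bg1, 1),
        fg_ch2 = round(fg2, 1), bg_ch2 = round(bg2, 1),
        flag = flag, stringsAsFactors = FALSE)
      two_color_array(spots, targets$dye_orientation[a], targets$array_id[a])
    })
    truth <- list(de_shared = sort(de_ids), de_discordant = sort(disc_ids),
                  effect_line37 = eff37, effect_line45 = eff45,
                  dup_correlation = dup_correlation,
                  effect_log2 = effect_log2, seed = seed)
    list(arrays = arrays, targets = targets, truth = truth)
  })
}

#' Synthetic GO DAG, annotations and a selected set with planted enrichment
#'
#' Builds a layered random DAG (\code{depth} levels below a single root, one
#' or two parents per term from the previous level), annotates entities at a
#' uniform background rate, and draws a selected set in which the planted
#' term's carriers are over-represented \code{fold_enrichment}-fold relative
#' to their background frequency.
#'
#' @param n_terms total terms including the root.
#' @param depth DAG depth below the root (1 = star).
#' @param n_entities number of annotatable entities (probes).
#' @param n_selected size of the selected set.
#' @param background_rate fraction of entities carrying any given leaf-level
#'   term (default 0.1).
#' @param planted_term term id to enrich; default the last term.
#' @param fold_enrichment carrier over-representation factor among selected.
#' @param terms_per_entity mean number of direct annotations per entity.
#' @param seed RNG seed.
#' @return list: \code{dag} (GoDag), \code{annotations} (AnnotationTable),
#'   \code{selected}, \code{universe}, \code{truth}.
#' @export
make_go_fixture <- function(n_terms = 50, depth = 4, n_entities = 500,
                            n_selected = 50, background_rate = 0.1,
                            planted_term = NULL, fold_enrichment = 5,
                            terms_per_entity = 3, seed = 1) {
  stopifnot(n_terms >= depth + 1, depth >= 1, n_selected <= n_entities)
  with_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    root <- terms[1]
    level <- c(0L, sort(rep_len(seq_len(depth), n_terms - 1L)))
    parents <- list()
    parents[[root]] <- character()
    for (i in 2:n_terms) {
      pool <- terms[level == level[i] - 1L]
      k <- min(length(pool), sample(1:2, 1))
      parents[[terms[i]]] <- sample(pool, k)
    }
    dag <- go_dag(terms, parents,
                  names = setNames(paste("term", seq_len(n_terms)), terms),
                  namespaces = setNames(rep("biological_process", n_terms), terms))
    if (is.null(planted_term)) planted_term <- terms[n_terms]
    entities <- sprintf("PRB%05d", seq_len(n_entities))
    annotatable <- terms[level == depth]           # annotate at the leaves
    ann <- lapply(entities, function(e)
      sample(annotatable, min(length(annotatable),
                              max(1, stats::rpois(1, terms_per_entity)))))
    names(ann) <- entities
    # force the planted term's carrier frequency to the background rate
    carriers <- sample(entities, round(background_rate * n_entities))
    for (e in entities) {
      has <- planted_term %in% ann[[e]]
      if (e %in% carriers && !has) ann[[e]] <- c(ann[[e]], planted_term)
      if (!(e %in% carriers) && has) ann[[e]] <- setdiff(ann[[e]], planted_term)
    }
    ann <- lapply(ann, function(x) if (length(x)) x else annotatable[1])
    n_carr <- min(round(fold_enrichment * background_rate * n_selected),
                  n_selected, length(carriers))
    selected <- c(sample(carriers, n_carr),
                  sample(setdiff(entities, carriers), n_selected - n_carr))
    list(dag = dag, annotations = annotation_table(ann),
         selected = sort(selected), universe = entities,
         truth = list(planted_term = planted_term,
                      fold_enrichment = fold_enrichment,
                      carriers = sort(carriers), seed = seed))
  })
}

#' Synthetic expression compendium with planted co-expression modules
#'
#' Module members share a latent factor so their expected pairwise Pearson
#' correlation is \code{within_r}; all other probesets are independent
#' standard normals.
#'
#' @param n_probesets,n_arrays compendium dimensions.
#' @param modules list of \code{c(size, within_r)} pairs.
#' @param seed RNG seed.
#' @return list: \code{compendium} (ExpressionCompendium), \code{truth}
#'   (module membership, seed).
#' @export
make_compendium <- function(n_probesets = 200, n_arrays = 200,
                            modules = list(c(10, 0.9), c(10, 0.9)),
                            seed = 1) {
  with_seed(seed, {
    ids <- sprintf("PS%05d_at", seq_len(n_probesets))
    m <- matrix(stats::rnorm(n_probesets * n_arrays), n_probesets, n_arrays,
                dimnames = list(ids, sprintf("ARR%04d", seq_len(n_arrays))))
    membership <- setNames(rep(0L, n_probesets), ids)
    at <- 1L
    for (k in seq_along(modules)) {
      size <- modules[[k]][1]; r <- modules[[k]][2]
      stopifnot(r >= 0, r < 1, at + size - 1L <= n_probesets)
      latent <- stats::rnorm(n_arrays)
      rows <- at:(at + size - 1L)
      m[rows, ] <- sqrt(r) * matrix(latent, size, n_arrays, byrow = TRUE) +
        sqrt(1 - r) * matrix(stats::rnorm(size * n_arrays), size, n_arrays)
      membership[rows] <- k
      at <- at + size
    }
    list(compendium = expression_compendium(m),
         truth = list(membership = membership, modules = modules, seed = seed))
  })
}
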