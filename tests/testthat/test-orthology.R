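test_that("single-ORF ESTs translate on both strands", {
  # ORF "ATGGCCTAA" -> peptide MA, embedded at frame +1
  est <- SequenceSet("e1", sequence = "ATGGCCTAA", alphabet = "nucleotide")
  p <- translate_ests(est, min_orf_aa = 2)
  expect_equal(p$sequence, "MA")
  expect_equal(p$frame, 1L)
  expect_equal(p$source_est_id, "e1")

  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit("ATGGCCTAA", "")[[1]]),
                                     collapse = ""))
  est_rc <- SequenceSet("e1rc", sequence = rc, alphabet = "nucleotide")
  p_rc <- translate_ests(est_rc, min_orf_aa = 2)
  expect_equal(p_rc$sequence, "MA")
  expect_lt(p_rc$frame, 0L)
})

test_that("six-frame translation equals exhaustive ORF enumeration on 50 ESTs", {
  set.seed(31)
  seqs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(90:240, 1), replace = TRUE),
          collapse = ""), character(1))
  ests <- SequenceSet(sprintf("e%02d", 1:50), sequence = seqs,
                      alphabet = "nucleotide")
  got <- translate_ests(ests, min_orf_aa = 10)
  for (i in 1:50) {
    want <- orf_oracle(seqs[i], 10)
    row <- got[got$source_est_id == ests$id[i], ]
    if (is.null(want)) {
      expect_equal(nrow(row), 0L)
      expect_true(ests$id[i] %in% attr(got, "skipped"))
    } else {
      expect_equal(nchar(row$sequence), nchar(want$peptide),
                   info = ests$id[i])
    }
  }
})

test_that("ESTs without a qualifying ORF are omitted and logged", {
  # 18 nt can carry at most a 6-residue peptide, below the cutoff
  est <- SequenceSet("junk", sequence = "TAATAGTGATAATAGTGA",
                     alphabet = "nucleotide")
  p <- translate_ests(est, min_orf_aa = 10)
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "skipped"), "junk")
})

test_that("Markov clustering keeps disconnected blocks and singletons", {
  ht <- hit_table(query_id = c("a1", "a1", "a2", "b1", "b1", "b2"),
                  subject_id = c("a2", "a3", "a3", "b2", "b3", "b3"),
                  percent_identity = 90, alignment_length = 200L,
                  evalue = 1e-50, bitscore = 300)
  oc <- cluster_orthologs(ht, proteins = c("a1", "a2", "a3", "b1", "b2", "b3", "lone"))
  members <- lapply(oc$clusters, identity)
  expect_true(any(vapply(members, setequal, logical(1), c("a1", "a2", "a3"))))
  expect_true(any(vapply(members, setequal, logical(1), c("b1", "b2", "b3"))))
  expect_true(any(vapply(members, setequal, logical(1), "lone")))
  expect_error(cluster_orthologs(ht, inflation = 1), "inflation")
})

test_that("planted ortholog clusters are recovered at inflation 1.5", {
  set.seed(37)
  n_cl <- 10; per <- 5
  ids <- sprintf("P%03d", seq_len(n_cl * per))
  truth <- rep(seq_len(n_cl), each = per)
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
    same <- truth[i] == truth[j]
    if (same || runif(1) < 0.02) {
      ev <- if (same) 10^(-runif(1, 30, 80)) else 10^(-runif(1, 5, 8))
      rows[[length(rows) + 1L]] <- data.frame(q = ids[i], s = ids[j], ev = ev)
    }
  }
  h <- do.call(rbind, rows)
  ht <- hit_table(h$q, h$s, 90, 200L, h$ev, 300)
  oc <- cluster_orthologs(ht, inflation = 1.5, proteins = ids)
  memb <- membership_of(oc$clusters, ids)
  expect_gte(adjusted_rand(truth, memb), 0.9)
  exact <- sum(vapply(split(ids, truth), function(g)
    any(vapply(oc$clusters, setequal, logical(1), g)), logical(1)))
  expect_gte(exact, 9)
})

test_that("clustering is invariant to hit-table row order", {
  fx <- make_hybridization_fixture(n_probes = 10, n_transcripts = 10, seed = 41)
  set.seed(43)
  ids <- sprintf("Q%02d", 1:12)
  truth <- rep(1:3, each = 4)
  rows <- list()
  for (i in 1:12) for (j in 1:12) if (i < j && truth[i] == truth[j])
    rows[[length(rows) + 1L]] <- data.frame(q = ids[i], s = ids[j],
                                            ev = 10^(-runif(1, 20, 60)))
  h <- do.call(rbind, rows)
  ht1 <- hit_table(h$q, h$s, 90, 200L, h$ev, 300)
  perm <- sample(nrow(h))
  ht2 <- hit_table(h$q[perm], h$s[perm], 90, 200L, h$ev[perm], 300)
  expect_equal(cluster_orthologs(ht1)$clusters, cluster_orthologs(ht2)$clusters)
})

test_that("annotation projection takes unions and keeps provenance", {
  cl <- structure(list(clusters = list(
    OC1 = c("arath_g1", "tobacco_e1"),
    OC2 = c("arath_g2", "osat_g3", "tobacco_e2"),
    OC3 = "tobacco_e3"), inflation = 1.5), class = "OrthoClusterSet")
  ref <- annotation_table(list(arath_g1 = "GO:A",
                               arath_g2 = "GO:A", osat_g3 = "GO:B"))
  pr <- project_annotations(cl, ref)
  expect_equal(pr$terms[["tobacco_e1"]], "GO:A")
  expect_setequal(pr$terms[["tobacco_e2"]], c("GO:A", "GO:B"))
  expect_equal(pr$terms[["tobacco_e3"]], character(0))
  expect_equal(pr$provenance[["tobacco_e2"]][["GO:B"]], "osat_g3")
})

test_that("projection equals per-cluster unions on a 200-cluster fixture and is monotone", {
  set.seed(47)
  clusters <- list()
  ref_terms <- list()
  for (k in 1:200) {
    n_ref <- sample(0:3, 1)
    refs <- if (n_ref) sprintf("ref_%03d_%d", k, seq_len(n_ref)) else character()
    ests <- sprintf("est_%03d_%d", k, seq_len(sample(1:3, 1)))
    clusters[[sprintf("OC%03d", k)]] <- c(refs, ests)
    for (r in refs) ref_terms[[r]] <- sprintf("GO:%04d", sample(1:60, sample(1:4, 1)))
  }
  cl <- structure(list(clusters = clusters, inflation = 1.5),
                  class = "OrthoClusterSet")
  ref <- annotation_table(ref_terms)
  pr <- project_annotations(cl, ref)
  for (k in sample(200, 40)) {
    members <- clusters[[k]]
    want <- sort(unique(unlist(ref_terms[intersect(members, names(ref_terms))])))
    if (is.null(want)) want <- character()
    for (m in members) expect_equal(pr$terms[[m]], want)
  }
  # monotone: annotating one more reference member never removes terms
  k <- 7
  extra <- ref_terms
  newm <- "ref_extra"
  cl2 <- cl; cl2$clusters[[k]] <- c(cl2$clusters[[k]], newm)
  extra[[newm]] <- "GO:9999"
  pr2 <- project_annotations(cl2, annotation_table(extra))
  for (m in clusters[[k]])
    expect_true(all(pr$terms[[m]] %in% pr2$terms[[m]]))
})

test_that("probe annotation composes graph adjacency with projected terms", {
  e <- filter_hits(hit_table(c("e1", "e2", "e3"), c("p1", "p1", "p2"),
                             90, 150L, 1e-30, 250))
  g <- build_graph(e, isolated_probes = c("p1", "p2", "p3"))
  ann <- annotation_table(list(prot1 = c("GO:A"), prot2 = c("GO:B"),
                               prot3 = character()))
  e2p <- c(e1 = "prot1", e2 = "prot2", e3 = "prot3")
  pa <- annotate_probes(g, ann, e2p)
  expect_setequal(pa[["p1"]], c("GO:A", "GO:B"))
  expect_equal(pa[["p2"]], character(0))   # only unannotated e3
  expect_equal(pa[["p3"]], character(0))   # isolated, still listed
  expect_setequal(names(pa), c("p1", "p2", "p3"))
  # idempotent under re-application
  expect_equal(annotate_probes(g, ann, e2p), pa)
})

test_that("cluster files round-trip", {
  oc <- structure(list(clusters = list(OC1 = c("a", "b"), OC2 = "c"),
                       inflation = 1.5), class = "OrthoClusterSet")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_file(oc, f)
  back <- read_cluster_file(f)
  expect_equal(back$clusters, oc$clusters)
})
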