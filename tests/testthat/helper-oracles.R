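# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's own code paths.

# undirected connected components by explicit depth-first search
dfs_components <- function(nodes, edges_from, edges_to) {
  adj <- setNames(replicate(length(nodes), character(), simplify = FALSE), nodes)
  for (i in seq_along(edges_from)) {
    adj[[edges_from[i]]] <- c(adj[[edges_from[i]]], edges_to[i])
    adj[[edges_to[i]]] <- c(adj[[edges_to[i]]], edges_from[i])
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[start]) next
    stack <- start
    comp <- character()
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

# Benjamini-Hochberg step-up straight from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# hypergeometric upper tail by explicit summation over the support
hyper_tail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# six-frame longest-ORF oracle by exhaustive enumeration of start positions
codon_translate <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  codons <- substring(s, seq(1, n - 2, 3), seq(3, n, 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}
revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
orf_oracle <- function(seq, min_orf_aa) {
  best <- NULL
  consider <- function(pep, frame) {
    if (nchar(pep) >= min_orf_aa &&
        (is.null(best) || nchar(pep) > nchar(best$peptide)))
      best <<- list(peptide = pep, frame = frame)
  }
  frames <- list(c(1, 1), c(1, 2), c(1, 3), c(-1, 1), c(-1, 2), c(-1, 3))
  for (pass in c("atg", "openend", "stopfree")) {
    for (fr in frames) {
      s <- if (fr[1] > 0) seq else revcomp(seq)
      s <- substr(s, fr[2], nchar(s))
      aa <- codon_translate(s)
      if (!nzchar(aa)) next
      frame <- fr[1] * fr[2]
      if (pass == "atg") {
        for (st in gregexpr("M", aa)[[1]]) {
          if (st < 0) next
          stop_at <- regexpr("\\*", substr(aa, st, nchar(aa)))
          if (stop_at > 0) consider(substr(aa, st, st + stop_at - 2), frame)
        }
      } else if (pass == "openend") {
        for (st in gregexpr("M", aa)[[1]]) {
          if (st < 0) next
          tail_aa <- substr(aa, st, nchar(aa))
          if (!grepl("\\*", tail_aa)) consider(tail_aa, frame)
        }
      } else {
        for (run in strsplit(aa, "*", fixed = TRUE)[[1]]) consider(run, frame)
      }
    }
    if (!is.null(best)) return(best)
  }
  best
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# membership vector from a list of groups (+ singleton fill)
membership_of <- function(groups, all_ids) {
  m <- setNames(rep(0L, length(all_ids)), all_ids)
  for (i in seq_along(groups)) m[groups[[i]]] <- i
  k <- max(m)
  singles <- names(m)[m == 0L]
  m[singles] <- k + seq_along(singles)
  m
}
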