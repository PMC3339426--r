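---
title: "Cross-species microarray analysis with xhyb: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species microarray analysis with xhyb: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xhyb)
```

## The problem

Heterologous (cross-species) hybridization probes one species' transcripts on
a microarray designed for a related species — for example, tobacco RNA on a
potato cDNA array when no platform exists for the species of interest. Two
complications follow. First, sequence divergence makes the probe-to-gene map
many-to-many: one probe may capture several transcripts (ambiguity) and
several probes may report the same transcript (redundancy). Second, the
array's original probe annotation describes the design species, not the
hybridized one, so downstream functional analysis (GO enrichment) inherits
stale or wrong labels.

`xhyb` addresses both with an explicit model: a **bipartite hybridization
graph** between probes and transcripts, built from sequence-similarity hits,
which carries (i) specificity/redundancy metrics, (ii) a principled collapse
of differentially expressed probes into an approximate gene count, and
(iii) a channel for transferring functional annotation from well-annotated
reference genomes onto the probes via orthologous protein clusters. Around
the graph sits a fully specified two-color differential-expression chain and
the usual follow-ups: hypergeometric GO enrichment and cross-species
co-expression.

## The hybridization graph

A transcript is predicted to hybridize to a probe when a similarity hit
reaches **at least 80% identity over at least 100 bp**; both thresholds are
inclusive, and duplicate (probe, transcript) hits collapse to the single
best-scoring edge — the graph models the *presence* of likely hybridization,
not hit multiplicity. Probes with no qualifying hit remain in the graph as
isolated nodes ("no predicted target") rather than being dropped: they are
part of the array and must appear in the annotation table.

Probe **ambiguity** is the number of adjacent transcripts; **redundancy
partners** are the other probes sharing at least one transcript. The source
workflow never fixes formulas for "specificity" and "redundancy", so these
definitions are one faithful reading and are labeled as such in the output.

The number of genes behind a set of differentially expressed probes is
estimated as the number of connected components of the subgraph induced by
those probes and their adjacent transcripts. Probes joined through a shared
transcript collapse into one putative gene; the estimate is always at most
the number of probes, with equality exactly when no two probes share a
transcript.

## Annotation transfer

ESTs are translated by a deterministic six-frame longest-ORF rule (complete
ATG-to-stop first; an ORF running off the 3' end, then the longest stop-free
stretch, only as fallbacks; ties break to the lowest frame, then the
leftmost start; default minimum 30 aa). This is a deliberate stand-in for
heavyweight EST-translation pipelines, which are external software; every
downstream step only needs one protein per EST, and externally produced
translations can be substituted.

Ortholog clustering is a documented simplification of graph-based ortholog
inference: similarity $s(i,j) = -\log_{10}(\text{e-value})$, capped at 200
and symmetrized by the maximum, hits above the e-value cutoff ($10^{-5}$)
discarded, then **Markov clustering** (expansion power 2, inflation 1.5,
column renormalization, convergence when the matrix changes by less than
$10^{-6}$ or after 100 iterations; clusters are the connected components of
the converged nonzero structure). Reciprocal-best-hit normalization between
species is intentionally omitted; precomputed cluster files are accepted as
an alternative input because the projection logic, not the clusterer, is the
reusable contribution. The inflation default (1.5) and cutoff are
conventional choices — the source protocol treats clustering as a black box
and states no parameters.

Annotation projection is **accumulation, not voting**: every cluster member
receives the union of the GO/InterPro terms of all annotated members of its
cluster, with provenance retained per term. All evidence is projected; no
evidence-code filtering is applied (the alternative is not recoverable from
the protocol). A probe then inherits the union over its adjacent
transcripts. Both steps are monotone (adding an annotated member never
removes a term) and idempotent.

## The two-color statistics chain

The chain follows the classical two-color cDNA protocol exactly, each stage
implemented from first principles:

1. **Flag weights.** Spots with negative scanner flags get weight 0; spots
   are never deleted, so array geometry survives for print-tip work.
2. **normexp background correction, offset 50.** The net intensity
   $X = \mu + \sigma Z + S$, with $S \sim \text{Exp}(\alpha)$ the true
   signal and normal noise for the background. Parameters are estimated per
   array per channel by direct maximum likelihood on the closed-form
   convolution density; because the likelihood can be multimodal at small
   spot counts, the optimizer runs from a moment-based and a low-background
   start and keeps the better optimum. The corrected value is the posterior
   expectation $E[S \mid X = x]$ plus the offset (default 50), which keeps
   every intensity strictly positive and damps log-ratio variance at low
   intensity. Constant input (unidentifiable model) falls back to floored
   subtraction with a warning. The cited method family includes a
   saddle-point estimator; exact MLE was chosen for transparency and is
   oracle-tested against an independent implementation.
3. **M/A transform with dye orientation.** $M = \log_2(\text{trt}/\text{ref})$
   is resolved per array from the targets table, so dye-swapped slides need
   no later sign handling; the whole pipeline is invariant (to $10^{-10}$)
   under relabeling channels and flipping the orientation flag.
4. **Print-tip loess.** Within each print-tip group, $M \gets M -
   \text{loess}(M \sim A)$ (span 0.3, degree 1, tricube, 4 robustifying
   iterations — conventional values; the protocol states none). Flagged
   spots are excluded from fitting but still normalized. Groups with fewer
   than 10 usable spots fall back to a global fit with a warning.
5. **Duplicate correlation.** Within-array duplicate spots are technically
   correlated. The consensus correlation here is a deterministic stand-in
   for the classical REML mixed-model estimator: per-probe Pearson
   correlations of the two duplicate M-series across arrays, Fisher-z
   transformed, 15%-trimmed mean, back-transformed, clamped to
   $(-0.99, 0.99)$. Parameter recovery is within about 0.05 of truth at
   2000 probes and 6 arrays; the method is recorded in the result metadata.
6. **Per-probe GLS.** Each probe's M-values are regressed on the array-level
   design, with duplicate spots given correlation $\rho$ within arrays
   (whitened via Cholesky); $\rho = 0$ reduces exactly to OLS. Probes with
   fewer usable observations than coefficients are marked unestimable.
7. **Empirical-Bayes moderation.** Hyperparameters $(d_0, s_0^2)$ are
   estimated by matching the mean and variance of $\log s_g^2$ to the
   scaled-F model via digamma/trigamma identities; the moderated variance is
   $\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the moderated
   $t$ uses $d_0 + d_g$ degrees of freedom. Degenerate branches: identical
   variances give $d_0 = \infty$ (normal reference); forcing $d_0 = 0$
   recovers ordinary per-probe $t$-tests.
8. **FDR and classification.** Benjamini–Hochberg per line (the protocol
   says only "FDR control"; BH is the standard default, BY and Bonferroni
   available). A probe is *jointly* significant when $q \le \alpha$ in
   **both** per-line contrasts — the two transgenic lines are treated as
   separate contrasts in one shared model, not pooled as replicates,
   because independent insertion events make their genotypic backgrounds
   different; the intersection is the conservative reading. The category is
   the sign pair of the two log2 fold changes (Down/Down, Down/Up, Up/Down,
   Up/Up). A zero fold change at significance is tie-broken to "up" with a
   warning (impossible for continuous data).

The experimental design preset mirrors the three-slide layout the chain was
built for: two dye-swapped slides for line 37 vs wild type and a single
slide for line 45 vs wild type, every probe printed twice per slide.

## GO enrichment

Direct probe annotations are propagated up the ontology by the true-path
rule over `is_a` and `part_of` edges only (standard practice; other
relations do not propagate annotation), with set semantics so diamonds count
an entity once. Enrichment of a selected probe set against a universe is the
one-sided hypergeometric upper tail $P(X \ge k)$; terms with $k = 0$ are not
testable for over-representation and are excluded. The default universe is
all probes carrying at least one propagated term; the default adjustment is
Benjamini–Yekutieli, appropriate for the strongly dependent tests along a
DAG (the original web tool's exact 2011 defaults are not recoverable, so
both choices are configurable and logged). Namespaces can be tested
separately. No monotonicity of p-values along the DAG is assumed — only set
containment.

## Cross-species co-expression

Differentially expressed orthologous clusters are mapped (via their
reference-species members' similarity hits, same 80%/100 bp thresholds) to
probesets of a reference-species compendium. Probeset vectors across the
compendium give a Pearson correlation matrix; agglomerative clustering on
$d = 1 - r$ (average linkage by default) is cut at height equal to the
threshold, and groups of size at least 2 are declared co-expressed.

The thresholds 0.05/0.1/0.2 are read as **dissimilarity cut heights**
($r \ge 1 - \text{threshold}$ at the linkage level, so smaller is stricter) —
this is the package's largest interpretive decision: the stated purpose is to
"select the clusters representing the highest levels of co-expression", which
small correlation *thresholds* on $r$ itself would not do. The alternative
reading (p-value thresholds on $r$) was considered and not shipped; the cut
height used is recorded in every result. Items are re-ordered canonically
before clustering, so results are input-order invariant, and group
membership is monotone in the threshold on a fixed tree.

## What the synthetic generators emulate — and what they do not

All fixtures are pure functions of (parameters, seed) and carry their planted
truth, so every stage is testable offline:

* `make_hybridization_fixture` plants true probe–transcript edges above the
  (80, 100) thresholds and decoys failing at least one threshold, so
  filtering must recover exactly the planted edges.
* `make_two_color_experiment` generates the three-slide preset with per-spot
  log-ratio = planted effect + duplicate-correlated noise (shared-factor
  construction), a smooth intensity-dependent dye bias in A (exercising
  loess), additive normal background and scanner noise (exercising normexp),
  and a 2% bad-spot flag rate. Defaults: 2000 probes, 50 shared-DE probes at
  $|\log_2 FC| = 1.5$ (80% down — the down-dominated regime typical of this
  contrast), duplicate correlation 0.7, replicate-spot log-ratio sd 0.25,
  baseline $\log_2$ intensity uniform on (7, 15), scanner noise sd 15 —
  values a good-quality cDNA array scan would show. The generator does not
  emulate spatial artifacts, saturation, or carry sequence content; a green
  recovery test establishes statistical correctness of the chain at a
  realistic operating point, not robustness to image-level pathology.
* `make_go_fixture` builds a layered random DAG and over-represents one
  planted term's carriers among the selected set by a stated fold.
* `make_compendium` plants co-expression modules through shared latent
  factors at a target within-module correlation.

## Numerical choices and degenerate inputs

* normexp: two-start MLE as above; `pmax(., 1e-10)` guards cancellation in
  the extreme left tail of the posterior mean.
* loess: `surface = "direct"` so prediction extrapolates to flagged spots
  outside the fitted A-range.
* Markov clustering: self-loops set to each column's maximum (at least 1)
  before normalization, entries below $10^{-12}$ pruned each iteration.
* Trigamma inversion for the eBayes prior uses Newton's method with the
  asymptotic branches for extreme arguments.
* FDR: NA/NaN p-values propagate as NA and are excluded from the number of
  tests.
* Ties everywhere break on sorted identifiers, so all outputs are
  deterministic for a given input.

## Known limitations

* The ortholog clusterer is a simplified MCL pipeline, not a full
  reciprocal-best-hit normalized implementation; for publication-grade
  orthology, supply precomputed clusters.
* The duplicate-correlation estimator is a deterministic consensus, not
  REML; with very few arrays its per-probe correlations are noisy and the
  consensus can be mildly biased upward.
* The six-frame translator ignores frameshifts and sequencing error, which
  dedicated EST translation tools model explicitly.
* Between-array scale normalization is deliberately not applied after
  print-tip loess (matching the documented steps only); compendium-scale
  normalization is out of scope.
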