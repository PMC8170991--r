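---
title: "Methods: cis-proximity enrichment for non-coding RNA gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-proximity enrichment for non-coding RNA gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisenrich)
options(cisenrich.log_level = "WARN")
```

## The problem

Most non-coding RNA (ncRNA) genes — lncRNAs, antisense transcripts, miRNAs —
have no direct functional annotation, so the standard gene-set enrichment
toolbox cannot be applied to an ncRNA list. Many ncRNAs, however, act in
*cis*: they regulate genes close by on the linear genome, and regulatory
contacts are further constrained by chromatin structure (topologically
associating domains, TADs) and reflected in co-expression. `cisenrich`
operationalizes this guilt-by-association logic: annotate each input ncRNA
$r_i$ with the protein-coding genes in its genomic neighborhood $C_i$, pool
the neighborhoods into $C = \cup_i C_i$, optionally refine $C$ with
orthogonal evidence, and test $C$ for over-representation in functional gene
sets. Enriched terms are then attributed back to the ncRNAs whose
neighborhoods contributed the overlapping genes.

## The neighborhood model

Each ncRNA's search window is its full gene span extended by `upstream` bp
before the start and `downstream` bp after the end (defaults: 10,000 bp each
side — a conventional cis-regulatory scale; there is no canonical value and
the window is the single most influential tuning parameter, so it is always
explicit in the configuration). With `strand_aware = TRUE` the two extensions
swap on minus-strand ncRNAs so "upstream" follows transcription; the default
is strand-blind genomic left/right, because cis-proximity itself is not a
stranded notion. A coding gene is a neighbor when its region overlaps the
window by at least 1 bp on the same chromosome, irrespective of strand.
`region_mode` selects what counts as the coding gene's region: its whole
span (default), its merged exon union, or its introns (the gaps between
merged exons; single-exon genes then contribute nothing). Merging exons
across transcripts avoids a transcript-selection policy; the ncRNA side
always uses its full span. An input gene never neighbors itself, and an
input gene that is itself protein-coding is excluded from its own
neighborhood with a warning.

Design choices worth stating explicitly, since the underlying convention is
genuinely open:

* *Anchoring.* The window anchors on the span (start − upstream,
  end + downstream) rather than separately on the TSS or TES; one rule
  covers both "start and/or end" readings and degrades gracefully for short
  genes.
* *Overlap semantics.* Any-overlap (≥ 1 bp) defines proximity; no minimum
  overlap fraction is imposed.
* *Coordinates.* Everything internal is a `GRanges` (1-based, closed
  intervals). GTF input is native; BED input is shifted on read and back on
  write. One convention internally eliminates off-by-one drift.

## Refinement stages

All refinements shrink (or, for co-expression expansion, grow) the pool and
compose in a fixed order in the pipeline: biotype → neighborhood → TAD →
co-expression → miRNA targets. Each stage is optional and a disabled stage
is a true no-op.

**Biotype.** The input set can be restricted to, or purged of, given GTF
biotypes (e.g. analyze only lincRNAs); an empty result is an error rather
than a silently empty analysis.

**TADs.** A gene is assigned to every TAD its span overlaps by ≥ 1 bp — genes
commonly straddle boundary calls, and full-containment would silently drop
them, so any-overlap is the default and only behavior. $C_i$ keeps the
coding genes sharing at least one TAD with $r_i$; an ncRNA overlapping no
TAD keeps nothing (the conservative reading of "same TAD"), which is logged.

**Co-expression.** Genes are pre-filtered in a fixed order: optional
low-expression filter (drop genes below `low_expr_value` in more than
`low_expr_fraction` of samples — the classical RPKM < 0.05 in > 20% of
samples preset), optional `log2(x+1)` transform, variance filter (default
cutoff 0.0025), optional MAD filter (keep MAD > `mad_cutoff`, e.g. 0.5).
Correlation is Pearson (default), Spearman, or Kendall; p-values are
two-sided (sidedness is a choice — two-sided is the conservative default
given that the coefficient rule already handles sign), using the t
distribution with n−2 df for Pearson/Spearman and the normal approximation
of tau-b for Kendall. An edge is retained when the coefficient passes the
rule (`absolute` |r| ≥ 0.3 by default; `positive`/`negative` for signed
analyses) *and* p ≤ 0.05. The Pearson Fisher-z confidence interval (default
level 0.95) is reported but does not gate retention — the p-value cutoff
already does, and double-gating would make the effective error rate opaque.
In `filter` mode each $C_i$ is intersected with the genes co-expressed with
$r_i$; in `expand` mode genes co-expressed with *any* input ncRNA join the
pool (recorded in a dedicated pseudo-entry so the pool remains exactly the
union of the stored sets). Missing expression values are an error, not an
imputation: silent imputation changes correlations invisibly.

**miRNA targets.** For miRNA inputs, $C_i$ is intersected with the target
genes recorded for $r_i$; keys match case-insensitively on gene id or
symbol, optionally after stripping a miRBase species prefix (`hsa-` etc.,
never the `mir-`/`let-` stem). An input absent from the target table keeps
no neighbors and is warned about.

## Enrichment

The background $B$ defaults to the union of all genes in the collection
(the annotation source defines the universe) and can be overridden by an
explicit gene list. The effective query is $Q = C \cap B$ with $n = |Q|$;
query genes outside the background are dropped from $n$ (a test universe
must contain its query) and counted in the log. Terms with fewer than
`min_set_size` genes *within the background* (default 5; measured after
intersection, not raw GMT line length) are skipped. For each surviving term
with gene set $T$: $K = |T \cap B|$, $k = |Q \cap T|$, and the p-value is
one of

* hypergeometric: $P(X \ge k)$, $X \sim \mathrm{HG}(N, K, n)$ (default);
* Fisher's exact, one-sided greater on the 2×2 table
  $(k,\, n-k;\, K-k,\, N-K-n+k)$ — mathematically identical to the
  hypergeometric tail, kept as a separate route and verified to $10^{-12}$;
* binomial: $P(X \ge k)$, $X \sim \mathrm{Bin}(n, K/N)$;
* Pearson chi-square without continuity correction, df = 1, upper tail
  (the uncorrected statistic is the classical definition; the exact tests
  are available precisely when cells are small, so a Yates-corrected hybrid
  adds nothing).

Terms with $k = 0$ are neither reported nor counted in the multiple-testing
family — the family is exactly the set of reported terms, matching common
enrichment-tool behavior, and its size is logged for transparency. The
adjustment is Benjamini–Hochberg by default (the procedure behind
"p adjusted" is a choice; BH is the field standard), with Bonferroni and
none available. Each row carries GeneRatio $k/n$, BGRatio $K/N$, EGNo
($=k$), the overlapping genes, and the contributing ncRNAs
$\{r_i : C_i \cap \text{overlap} \neq \emptyset\}$.

## Reporting

Rows are ranked ascending by p or adjusted p with deterministic tie-breaks
(overlap $k$ descending, then term id — ties are real at small $n$, and an
unstated tie order would break reproducibility). The dot-plot table carries
term, chosen p metric and $k$; rendering is a thin optional ggplot2 layer.
The network is bipartite term–gene (restricted to overlap genes) extended by
gene–ncRNA edges from the neighbor map — the gene-mediated construction is
this package's documented choice where a direct term–ncRNA drawing would
also have been defensible. Nodes are clustered by greedy modularity
maximization (`igraph::cluster_fast_greedy`, deterministic), and all outputs
(TSV, optional GraphML) are byte-identical across runs with the same inputs
and seed: p-values are serialized with `%.17g` so re-parsing reproduces the
exact doubles, string sorts use the C locale, and the run manifest contains
no timestamps.

## The synthetic study generator

Everything is testable offline through `fixture_spec()` /
`simulate_fixtures()`, which generate a genome annotation, TAD tiles, an
expression matrix, a target table and a gene-set collection with planted
signal, all a pure function of the seed. The default study: 2 chromosomes
of 1 Mb; 150 protein-coding genes (2–8 kb, 1–4 exons) and 30 ncRNAs
(0.5–3 kb, rotating lincRNA/antisense/miRNA biotypes) placed with ≥ 1 kb
intergenic gaps — a density at which the default 10 kb window finds a
handful of neighbors per ncRNA and pools roughly 40 coding genes, so the
neighborhood stage is neither saturated nor empty; 8 TAD tiles per
chromosome with boundaries snapped to intergenic gaps (so boundary-straddling
genes are an explicit opt-in in tests, constructed by hand where that edge
case is the point); 100 expression samples with unit-variance Gaussian
profiles (log-scale expression; the raw-scale RPKM preset is exercised with
separate raw-scale matrices in tests) and planted pairs built as
$b = \rho\,\mathrm{std}(a) + \sqrt{1-\rho^2}\,\varepsilon$ at $\rho = 0.8$,
anchored by `simulate_fixtures()` to actual cis-neighbor pairs; a planted
term containing 8 pool genes plus 2 non-pool fillers among 40 decoy terms of
matched size drawn from the non-pool coding genes, so exactly one term
carries cis signal.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: realistic gene density and clustering, isoform
structure, GC/mappability artifacts, heavy-tailed and zero-inflated
expression, batch effects, correlated decoy terms, or annotation errors.
The planted-recovery results certify the machinery (windowing, filtering,
counting, testing, correction), not biological discovery power.

## Numerical and degenerate-input policy

* Contingency counts are validated ($0 \le k \le \min(n,K)$, $n \le N$,
  $K \le N$); violations are errors, never clamped.
* $k = 0$ gives p = 1 exactly; hypergeometric tails come from `phyper`
  upper-tail evaluation (stable in log space internally).
* Chi-square with any zero expected cell is an error that names the exact
  tests as the remedy.
* Correlation on fewer than 3 samples is an error; a zero-variance profile
  yields no edge rather than NaN.
* `intron` regions of single-exon genes are empty lists, not errors.
* Unknown configuration keys are rejected outright — a misspelled cutoff
  silently reverting to its default is the worst failure mode of an
  enrichment tool.
* All randomness flows from the single configured seed; fixture generation
  restores the caller's RNG state.

## Problem sizes used in the checks

The shipped test-suite verifies the hypergeometric tail against exhaustive
enumeration for every table with $N \le 30$, the Fisher identity on 500
random tables with $N \le 1000$, binomial/chi-square against direct formula
evaluation on 200 tables, the neighborhood search against an all-pairs
brute-force oracle on 50 simulated genomes of 1,000 coding and 200 ncRNA
genes across region modes and strandedness, filter algebra on 20 studies,
BH against the textbook step-up on 1,000 random vectors, and planted
co-expression/enrichment recovery over 100 replicate studies each. The
same quantities are recomputed end-to-end by `scripts/acceptance.R`.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile()
fx <- simulate_fixtures(fixture_spec(seed = 11), dir)
cfg <- validate_config(list(
  input      = file.path(dir, "ncrna_input.txt"),
  gtf        = file.path(dir, "genome.gtf"),
  genesets   = file.path(dir, "genesets.gmt"),
  output_dir = file.path(dir, "out"),
  seed       = 5))
res <- run_pipeline(cfg)
head(res$ranked[, c("term_id", "p_value", "p_adjusted", "k", "n", "K", "N")])
```

## Known limitations

Proximity is purely 1-D: enhancer–promoter loops, trans-acting ncRNAs and
contact maps beyond TAD co-membership are out of scope. Identifier
resolution is local (annotation ids, symbols, user alias table); there is no
online lookup, so transcript-level identifiers resolve only through the
alias table. The four tests share the over-representation framing — no
ranked/GSEA-style statistics, no permutation nulls, no term-topology
awareness. P-values inherit the usual caveat of enrichment analysis on
correlated, user-chosen backgrounds: the background choice moves results
more than the test choice.
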