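---
title: "Estimating alternative splicing prevalence and level from junction counts"
author: "spliceprev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating alternative splicing prevalence and level from junction counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceprev)
```

## The problem

How much alternative splicing a species performs — and whether that amount
tracks organism complexity or merely genome architecture such as intron size —
can only be compared across species if the estimate is robust to sequencing
depth, tissue composition and annotation quality. `spliceprev` implements a
junction-level protocol for this comparison:

1. **Splicing measurement.** Split-read junction counts (the intron intervals
   excised by the spliceosome, with read support) are merged across samples,
   clustered into *intron clusters* — sets of two or more junctions sharing a
   donor or acceptor site, i.e. alternative excisions of one locus — and
   assigned to genes. Alternative splicing prevalence (**ASP**) is the
   fraction of expressed multi-exon genes with at least one intron cluster.
   Alternative splicing level (**ASL**) is quantified per cluster by the
   Shannon entropy of junction usage,
   $$H = -\sum_{k=1}^{m} f_k \log_2 f_k,\qquad f_k = n_k \Big/ \sum_k n_k,$$
   where $n_k$ is the read count of junction $k$; per-gene ASL sums $H$ over
   the gene's clusters, and species ASL averages that over expressed
   multi-exon genes.
2. **Depth correction.** Lowly expressed genes under-report splicing simply
   because junction reads are scarce. Genes are ranked by expression
   (approximated by the maximum coverage depth over exons), grouped into
   equal-size bins, and per-bin ASP/ASL is fitted as a logistic function of
   bin rank $x$:
   $$F(x) = \frac{\alpha}{1 + e^{(x_{mid} - x)/s}}.$$
   The upper asymptote $\alpha$ is the depth-corrected, "predicted" ASP/ASL
   (**PASP/PASL**). The mean of the observed values over *plateau bins* —
   bins past the midpoint whose successive fitted values change by less than
   $10^{-4}$ — is reported alongside; four or more plateau bins indicate the
   sequencing depth is saturated.
3. **Comparative layer.** Species-level estimates are related to organism
   complexity (cell type number, CTN) and three intron-size statistics (mean
   intron size; CDS density = mean CDS length / gene length; intron density =
   introns per kb exon) by Spearman correlation, ordinary least squares, and
   phylogenetic generalized least squares (PGLS) with Pagel's $\lambda$
   estimated by maximum likelihood, plus partial Spearman correlations to
   control either complexity or intron size.

## Default parameters and what they mean

| parameter | default | meaning |
|---|---|---|
| `max_intron_len` | 500000 bp | junctions longer than this are implausible introns and removed |
| `min_cluster_reads` | 30 | minimum summed read support for a cluster |
| `min_depth` | 2 | a gene is expressed when some exonic base has depth strictly above this |
| `fpkm_threshold` | 0.1 | expression floor (strict) in isoform/event counting modes |
| `min_event_reads` | 5 | read support needed for a splicing event to count |
| bin sizes | 100, 500 | genes per expression bin for the saturation fit |
| plateau `tol` | 1e-4 | successive fitted-value change defining plateau bins |
| saturation | 4 bins | plateau bins needed to call depth saturated |

These defaults are the analysis protocol's operating point; a bare
`pipeline_config()` therefore reproduces the standard analysis.

## Counting modes

Junction mode is primary (it is what the clustering machinery feeds).
Isoform mode (ASP = fraction of expressed multi-exon genes with more than one
isoform; ASL = mean isoform count) and event mode (same with splicing events
passing the 5-read filter) consume externally produced isoform/event counts
with an FPKM expression column; the package computes the statistics but not
transcript quantification itself. For junction-mode species ASL the per-gene
entropy sums are averaged over all expressed multi-exon genes, genes without
clusters entering as zeros — the gene-level definition fixes only the sum,
and averaging with zeros keeps ASP and ASL consistent denominators.

## The synthetic-data generator

Real cross-species RNA-Seq at the scale this protocol targets is terabytes of
reads; validation instead uses a seeded generator that reproduces the
statistical structure the analysis assumes, end to end:

- a pure-birth phylogeny; log cell-type number evolves on it as Brownian
  motion (Pagel's $\lambda$ transform available), exponentiated and clipped
  to a configurable range (default 20–220, matching the span of published
  cell-type counts);
- per species, a gene catalog with 20% single-exon genes, 2+Poisson(5) exons
  otherwise, lognormal exon widths and lognormal intron sizes whose variance
  is split evenly between a gene-level location and within-gene scatter (so
  genes have their own characteristic intron size, as real genes do);
- a species-level fraction of alternatively spliced genes coupled linearly
  to scaled log complexity (default baseline 0.6, slope 0.7, spanning roughly
  0.25–0.95 across the complexity range — the span reported for metazoan
  genomes); alternatively spliced genes carry a second, exon-skipping
  isoform, giving a three-junction cluster with Beta(2, 2) inclusion usage;
- lognormal expression (median 20, log-SD 1.2) written as rectangular exon
  coverage, and junction reads drawn Poisson(expression × rate). Detection
  of a cluster therefore requires enough expression to clear the 30-read
  filter, which is exactly the depth bias the binning correction removes;
- optional couplings: species intron size to complexity (negative in the
  large-intron study design), and per-gene alternative-splicing probability
  to the gene's intron-size location (the within-genome effect).

What the generator does **not** emulate: tissue heterogeneity, mapping
artefacts, annotation errors, 5'/3' coverage bias, isoform structures beyond
single exon skipping, and overdispersed (non-Poisson) counts. Passing tests
therefore demonstrate the statistical machinery is correct under the model's
assumptions, not that real-data noise sources are harmless.

`make_study_designs()` returns three ready-made configurations mirroring
the comparative designs the protocol is built around: wide complexity with
large (2–42 kb scale) introns coupled negatively to complexity; wide
complexity with small (0.7–3 kb) introns; fixed complexity (CTN 59) with
0.3–14 kb intron variation.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_species = 8, n_genes = 800)
bundle <- simulate_species_set(cfg, seed = 17)
res <- analyze_species_set(bundle, bin_size = 100,
                           methods = c("spearman", "pgls"))
res$summary[, c("species", "ctn", "true_asp", "asp", "pasp")]
subset(res$grid, measure == "pasp" & predictor == "ctn")
```

The raw `asp` underestimates the simulated truth (many genes are too lowly
expressed for their clusters to clear the read filter); `pasp` — the fitted
asymptote — recovers it, and the correlation grid reports how each estimate
tracks complexity.

## Numerical and design choices

- **Coordinates** are 0-based half-open internally; GTF2/GFF3 (1-based
  inclusive) are converted on read and restored on write.
- **Cluster linkage** is exact sharing of a donor or acceptor coordinate,
  not interval overlap: alternative excision requires a shared splice site,
  and exact linkage makes clustering order-invariant and testable against a
  brute-force components oracle. Single-junction components are not clusters
  (a lone junction is consistent with constitutive splicing). The iterative
  low-usage pruning some junction-clustering tools apply is off by default
  (`min_junction_fraction = 0`).
- **Gene assignment** uses the gene span rather than exon overlap, because
  junction coordinates are intronic by construction; clusters touching two
  or more gene spans connect multiple genes and are discarded.
- **Binning** uses rank order, dropping the trailing partial bin, with
  gene-id tie-breaking so equal expression values bin deterministically.
  The fitted x is the bin index: the midpoint and scale are then
  well-conditioned regardless of the expression scale (log mean expression
  is available via `x_scale`).
- **Sigmoid fitting** uses bounded Levenberg–Marquardt least squares with
  data-derived starts; $\alpha \in (0, 1.5]$ for ASP (a proportion) and
  $(0, \infty)$ for ASL; the scale is bounded positive so fits are monotone.
  A flat response short-circuits to the constant model. Non-convergence is
  reported, and the plateau estimate remains available as a fallback.
- **Plateau bins** use absolute successive differences of fitted values
  (threshold $10^{-4}$), restricted to the upper-asymptote side of the
  midpoint — a logistic is also flat at its undetected low-expression tail,
  which is not a saturation plateau.
- **Genome-level intron statistics** default to per-intron averaging with a
  per-gene-mean alternative, since species summaries can reasonably weight
  by intron or by gene; the representative transcript is the longest isoform
  (union mode available). Genes lacking CDS features are excluded from CDS
  density.
- **PGLS** scales only the off-diagonal Brownian covariance by $\lambda$,
  maximizing the profile multivariate-normal likelihood over $[0, 1]$ by
  bounded scalar optimization (tolerance $10^{-6}$, endpoints checked). With
  $\lambda = 0$ on an ultrametric tree the fit reduces exactly to OLS.
  Spearman p-values use the t approximation, appropriate at comparative
  sample sizes (tens of species); partial Spearman uses the first-order
  recursive formula, with the rank-residual construction retained as a
  cross-check in the test suite.
- **Chi-square** pathway-count tests are Pearson without continuity
  correction (the tables are 2 × S, S ≥ 2).

## Problem sizes used in validation

The test suite and acceptance script run entirely on generated data, sized
for a laptop-class machine: 15 species × 1200 genes for end-to-end
complexity-recovery runs (20 coupled and 20 null replicates), 2500 genes for
the within-genome intron-size effect, 50-tip trees × 200 replicates for
$\lambda$ recovery, and 100 seeds for saturation-asymptote bias. These sizes
keep every per-species estimate's sampling error well below the effect sizes
being recovered while completing in minutes.

## Known limitations

- Junction mode sees only splicing that alters junction usage; intron
  retention without a competing junction is invisible.
- The ML $\lambda$ estimator is noisy at a few dozen tips (per-replicate SD
  around 0.25 at $\lambda = 0.5$ with 50 tips) and mildly biased toward the
  interior at the boundaries of $[0, 1]$; conclusions should rest on the
  regression coefficients, not on $\hat\lambda$ itself.
- With ~15 species, a null Spearman correlation has SD $\approx 0.27$;
  individual runs can show $|\rho|$ up to ~0.5 by chance, so replication
  over seeds (as the tests do) is essential.
- FPKM-based modes trust the supplied quantification; no uncertainty in
  isoform/event counts is propagated.
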