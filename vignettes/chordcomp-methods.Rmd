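---
title: "chordcomp: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chordcomp: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chordcomp` implements the comparative analyses used to contrast the
functional genome of an invertebrate chordate outgroup (amphioxus) with
vertebrates: developmental transcriptome divergence, conserved
co-expression, cross-species module and motif comparison, regulatory
landscape quantification, CpG-methylation clustering of regulatory
elements, and the classification of expression fates after the two
rounds of vertebrate whole-genome duplication (WGD). This vignette
documents the statistical models, the tunable parameters that matter,
the synthetic-data generator the test suite relies on, and the design
decisions taken where the methods left genuine freedom.

## Transcriptome divergence and the hourglass model

Two developmental transcriptomes are compared with the Jensen--Shannon
distance over a 1-to-1 orthologue set. Each sample is first quantile
normalized (jointly across all samples entering a comparison, so both
species share one reference distribution; a within-species option
exists and the choice is recorded by the caller) and then rescaled to
proportions $p_g$ with $\sum_g p_g = 1$. For two samples $p, q$ and
$m = (p+q)/2$:

$$\mathrm{JSD}(p, q) \;=\; \sqrt{\tfrac12 \sum_g p_g \log_2 \frac{p_g}{m_g}
 \;+\; \tfrac12 \sum_g q_g \log_2 \frac{q_g}{m_g}}$$

Choices and conventions:

* **Log base.** The defining equation is written with an unspecified
  logarithm; we default to base 2, which bounds the distance by 1 and
  makes it a metric. `base = "ln"` is available; every bundled test
  pins base 2.
* **Probability conversion.** Proportions over the orthologue set are
  the minimal reading of "distance between transcriptomes"; nothing
  stronger is assumed.
* **Zeros.** $p \log(p/m)$ terms with $p = 0$ are 0 by continuity.
* **Bootstrap.** Dispersion comes from resampling orthologue
  *identities* with replacement to the original set size (100
  replicates in the reference analysis); the point estimate always
  uses the unresampled set. Quantile normalization is computed once on
  the full orthologue set and replicates resample rows of the
  normalized matrices, which keeps replicates comparable and the run
  fast.
* **Ties.** `minimal_divergence_stages()` breaks argmin ties toward the
  earlier developmental stage and flags them.

## Conserved co-expression (NACC)

For a family with a single species-1 member $A$ and species-2 members
$B$, with $\bar A$ the mean distance from $A$ to its $k = 20$ nearest
genes in species-1 expression space, $\overline{AB}$ the mean
species-2 distance from $B$ to the orthologues of those neighbours,
and $\bar B$, $\overline{BA}$ the reciprocal quantities:

$$\mathrm{NACC} = \tfrac12\left[(\overline{AB} - \bar A) +
(\overline{BA} - \bar B)\right]$$

Conserved co-expression gives values near 0; random orthology inflates
$\overline{AB}$ and $\overline{BA}$. The underlying distance is not
specified by the method description; we use Euclidean distance on
per-gene z-scored $\log_2(x+1)$ profiles (a `correlation` option
exists), candidate neighbours are restricted to orthologue-bearing
genes, the query gene (and for the species-2 side, the whole family)
is excluded from its own neighbourhood, and multi-member families
average member-level quantities (a `minimum` alternative was
considered and rejected as less stable at small family sizes). The
null (`nacc_null()`) permutes which member set each species-1 gene is
paired with, preserving family-size structure, and reports
$(1 + \#\{\text{null} \le \text{obs}\})/(n_\text{perm}+1)$ as the
empirical one-sided p-value for conservation.

## Module and motif comparison

Cross-species co-expression modules (WGCNA or fuzzy clustering
assignments are *inputs*; the algorithms themselves are out of scope)
are compared by upper-tail hypergeometric tests over the universe of
1-to-1 orthologue pairs in which both genes carry a module label;
unassigned ("grey") genes are excluded so the margins are
well-defined. Raw p-values are reported with an optional
Benjamini--Hochberg column, matching the reference figures which show
raw significance.

Motif enrichment uses position weight matrices scanned as log-odds
(base 2) against a background composition (uniform by default, with a
pseudocount of $10^{-3}$ per frequency so zero cells stay finite). A
window is a hit when it reaches 80% of the motif's maximum attainable
score, on either strand; windows containing `N` are skipped. Counts
are converted to hits per kilobase scanned before z-scoring each motif
across groups, because groups differ in total scanned length; the
standard deviation convention is the sample sd ($n-1$), pinned in the
tests. Motif super-families (e.g. the 242 clusters used for
module-level comparisons) are an input mapping; member counts are
summed per cluster with `collapse_motif_clusters()`.

## Regulatory landscapes

All coordinates are 0-based half-open internally; GTF input is
converted on read. Peak membership throughout is decided by the peak
*midpoint*, since overlap semantics are not specified by the source
method descriptions; this is configurable in principle but midpoint is
what the tests pin, and it guarantees each peak has exactly one
location.

* **Classification** (promoter $>$ gene body $>$ proximal $>$ distal):
  promoter = within 1 kb upstream to 0.5 kb downstream of a TSS
  (strand-aware); gene body = inside an annotated gene; proximal =
  within 5 kb upstream of a TSS; distal = everything else. The
  precedence follows from "not in the aforementioned categories".
* **GREAT-style domains**: every gene receives a basal region (TSS
  $-5$ kb to $+1$ kb, strand-aware, always retained even when it
  overlaps a neighbour's domain) and an extension per side that stops
  at the nearest other gene's basal *boundary*, the TSS $\pm$ 1 Mb
  cap, or the chromosome end. The cap is measured from the TSS, which
  matches the published regulatory-domain tool. Note that neighbouring
  extensions meet at basal boundaries, so inter-basal territory is
  shared by the two flanking genes and a peak there counts for both
  (multi-assignment is deliberate and tested).
* **Size-stratified matching** bins landscape sizes into fixed 500-bp
  bins and down-samples both species to the per-bin minimum, without
  replacement, under a named sub-stream of the seed.
* **Conservation aggregation** averages per-base scores within each
  peak; uncovered bases are excluded from the mean by default
  (`missing_as_zero` inverts this), and fully uncovered peaks are NA
  with a warning rather than silently 0.
* **Bidirectional promoters** are divergent adjacent gene pairs (minus
  strand upstream of plus strand, TSSs facing away) with TSS
  separation at most 1,000 bp by default. The reference analysis
  defines these from CAGE tag clusters, whose pairing rule is not
  reproduced here; the 1 kb default over annotation TSSs is a package
  choice, not a published value, and the full separation histogram is
  returned so users can pick their own threshold.

## Expression binarization and WGD fates

Expression is binarized per gene over nine homologous expression
domains with a *strict* threshold (on iff normalized cRPKM $> 5$; a
value of exactly 5 is off). "Normalized" is interpreted as quantile
normalization across the nine samples within each species, exposed as
a switch (`none|quantile`) because the source text does not specify
it. Bias records subtract the outgroup's on-count from the vertebrate
entity's on-count, where the entity is a single orthologue, an
individual ohnologue, the union of a family, or the family after
summing raw expression and re-binarizing.

Fate classification considers ohnologue families (one outgroup member,
2--4 vertebrate copies) whose ancestral expression covered all nine
domains, inferred from the outgroup member and the family union both
being fully on. Fates: *redundancy* (every copy fully on),
*subfunctionalization* (no copy fully on), *specialization* (at least
one fully on and at least one not). Specialized members are subtyped
`spec_equal` (all domains), `spec_mild` (lost some, more than two
remain) and `spec_strong` (two or fewer remain); a member with exactly
two retained domains is `spec_strong`. Families with members missing
expression data are dropped and counted, not imputed. Rank-sum tests
use exact enumeration when both groups have at most 25 tie-free
values and the normal approximation with continuity correction
otherwise, so small oracle tests are deterministic.

## Methylation

CpG levels are methylated/total reads, with a coverage floor of 5
reads; region summaries are unweighted means over at least 3 covered
CpGs per region per sample (both defaults are package choices — the
source states neither — and both are arguments). Genome-wide category
fractions use the boundaries zero $= 0$, low $(0, 0.2]$, medium
$(0.2, 0.8]$, high $(0.8, 1]$. Two-cluster separation of
tissue-specific elements is Euclidean k-means with $k = 2$ and 20
restarts under a fixed seed; labels are anchored so cluster 1 is the
cluster whose centroid drops most in the defining tissue relative to
the other samples (the tissue-specifically demethylated,
"differential" cluster) and cluster 2 is the constitutive cluster,
making labels reproducible across runs and row orders.

## The synthetic-data generator

Every analysis stage is testable without downloads because the
`generate_*` functions plant known truth:

* **Hourglass series**: species A has per-gene log-normal baselines
  (meanlog 3, sdlog 1.2, an RNA-seq-like abundance spread) with a mild
  per-stage effect (sdlog 0.1); species B at the homologous stage is
  species A times multiplicative log-normal noise whose sdlog follows
  the divergence profile. The default profile
  (0.8, 0.6, 0.4, 0.2, 0.4, 0.6, 0.8) over seven stages has a unique
  minimum mid-series, the planted phylotypic stage. Log-normal
  multiplicative noise was chosen because expression is non-negative
  and heavy-tailed; it is a stand-in, not an inference about the noise
  model of real inter-species divergence.
* **Fate families**: the outgroup gene is on in all nine domains and
  vertebrate copies realise the planted fate exactly; on = 4x the
  binarization threshold, off = 0.1x, so binarization is unambiguous
  at zero noise. "Moderate noise" in the tests is sdlog 0.5, at which
  on/off flips are rare (per-cell flip probability about 0.3%) but
  recovery is measurably below 1. The default fate mix (0.15
  redundancy, 0.35 subfunctionalization, 0.50 specialization) mirrors
  the reported predominance of specialization.
* **Genomes with peaks**: genes are placed non-overlapping on one
  synthetic chromosome; planted peaks sit within $\pm 900$ bp of the
  TSS — inside the basal window, the only territory owned by exactly
  one gene once GREAT extensions meet at basal boundaries — so
  per-gene counting recovers the planted counts exactly when
  background peaks are disabled. Species B's mean count (8 versus 3)
  emulates the vertebrate regulatory expansion.
* **Methylome**: regions are planted as differential (low in the
  defining tissue, high elsewhere) or constitutive (low everywhere),
  with modes 0.1/0.9 and binomial read sampling at or above the
  coverage floor.
* **Motif dataset**: sharp PWMs (consensus probability 0.88) are
  planted into i.i.d. background sequences at per-group rates, with
  one group/motif combination enriched 10-fold by default.

One master seed spawns an independent, named sub-stream per generator,
so adding a generator never perturbs the others and each generator is
bit-identical under a fixed seed. What a green test establishes is
recovery of *planted* structure under these simplified conditions —
i.i.d. noise, clean orthology, a single chromosome, no mappability or
coverage artefacts; it does not establish performance on real data
with correlated noise, assembly gaps or annotation errors.

## Known limitations

* The union-mode bias histogram is degenerate (all zeros) at zero
  noise because the generator plants fully-on outgroup genes and
  fully-covering unions; under multiplicative noise the union is more
  robust to losses than the single outgroup gene, so the union-mode
  ratio of negative to positive biases is not a symmetric statistic in
  this synthetic world. The symmetric control is the 1-to-1
  construction, which both species traverse with identically
  distributed noise.
* Quantile normalization with ties equalizes tie-free columns exactly,
  but a column with ties keeps its tied value (the mean of the spanned
  reference values), so sorted columns agree only up to tie blocks.
* `nacc_score` is quadratic in the number of orthologue-bearing genes
  (a full distance matrix is built); tens of thousands of genes are
  fine, but the permutation null recomputes scores per permutation.
* Module assignments, motif super-family maps, conservation tracks and
  sequence-similarity values are consumed, never inferred.
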