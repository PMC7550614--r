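---
title: "Shared transcriptome signatures and interactome modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared transcriptome signatures and interactome modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pesignet` analyses whether four overlapping maternal conditions —
preeclampsia (PE), asthma, excess BMI (≥ 25 kg/m²) and vitamin D
insufficiency (25OHD < 30 ng/mL) — share an early-pregnancy peripheral-blood
transcriptome signature, whether that shared signature forms a coherent
module in the protein–protein interaction (PPI) network, and whether it
replicates in placental tissue. This vignette documents the statistical
model behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## 1. Rank-product differential expression

Each condition defines a two-class unpaired contrast on a log2 expression
matrix. For a case–control sample pairing $k$ the per-gene log2 differences
are ranked so that rank 1 is the most upregulated gene (ties receive average
ranks); the rank product is the geometric mean over $K$ pairings,

$$\mathrm{RP}_g = \Big(\prod_{k=1}^{K} r_{gk}\Big)^{1/K},$$

computed in log space. Small RP under the ascending ordering indicates
consistent upregulation; the mirrored ordering (with average ties,
$r^{down} = n + 1 - r^{up}$) tests downregulation. The statistic is
non-parametric and robust at small sample sizes and under sample
heterogeneity, which is why it is preferred here over moderated-t
alternatives.

**Pairings.** For an unpaired design the natural comparison set is all
$n_1 n_2$ case–control pairings. All pairings are used when
$n_1 n_2 \le$ `n_pairs_cap` (default 10,000); beyond that a seeded random
subset of `n_pairs_cap` pairings is drawn. (The choice matters little: RP is
a mean of per-pairing ranks, and 10,000 pairings estimate it tightly.)

**Permutation inference.** Class labels are permuted $B$ times (default
$B = 100$, configurable) and RP recomputed for every gene, pooling
$B \times n$ null values. The per-gene p-value uses add-one smoothing,
$p_g = (1 + \#\{\mathrm{RP}^{null} \le \mathrm{RP}_g\})/(1 + Bn)$, so it is
never exactly zero — the correct finite-$B$ estimator. The percentage of
false prediction divides the expected number of null genes at the cutoff by
the gene's rank position:
$\mathrm{pfp}_g = \big(\#\{\mathrm{RP}^{null} \le \mathrm{RP}_g\}/B\big) / \mathrm{rank}(\mathrm{RP}_g)$.
pfp is an FDR-like quantity and may exceed 1; it is stored raw and clipped at
1 only for display. Discovery signatures are called at pfp < 0.05 per
direction; a gene meeting both directions (pathological) is excluded and
counted. The per-pairing ranking loop is compiled (Rcpp) — it is the only
hot loop in the package.

**Heterogeneity adjustment.** Surrogate-variable analysis is out of scope;
`residualize()` offers a known-covariate hook that replaces each gene's
values with least-squares residuals. It is a stand-in for situations where
the nuisance structure is measured rather than latent.

## 2. Replication, intersection, sensitivity

RP p-values are one-tailed per direction; the replication rule is
"two-sided p < 0.05", reconciled as $p = \min(1, 2\min(p^{up}, p^{down}))$ —
the standard two-sided reading of a pair of one-tailed tests. Replication
additionally requires direction concordance by default (the analysis tracks
upregulated counts through replication, implying directionality); the
requirement can be disabled. Intersection of the four replicated signatures
is by gene symbol, with direction taken from the PE signature and discordance
counted, and exclusive (UpSet-style) counts reported for all 15 non-empty
label subsets; these counts partition the union, which the tests verify. The
sensitivity contrast compares subjects positive for all four conditions with
subjects positive for none, calls genes at two-sided permutation p < 0.05,
and reports the percentage of the overlap signature so recovered.

## 3. Interactome modules

Edge lists (gene A, gene B, combined confidence) are filtered at combined
score > 0.4 — the conventional "more than 50% confidence" STRING threshold —
with reversed duplicates merged at the maximum score and self-loops dropped.
A signature's module is the subgraph induced by its mapped genes. Module
statistics: average internal degree $2E/N$; mean local clustering
coefficient ($2\,\mathrm{triangles}/(d(d-1))$, defined as 0 for degree < 2);
Brandes betweenness normalized by $(N-1)(N-2)/2$; and the largest connected
component (LCC), with ties broken by the lexicographically smallest member
gene so the result is deterministic.

**Edge enrichment.** The null draws `n_iter` random node sets of the module's
size and compares induced edge counts; empirical p uses add-one smoothing, so
the smallest attainable value is $1/(n_\mathrm{iter}+1)$ — echoing a
"p < 0.0001" claim requires $n_\mathrm{iter} \ge 10^4$. The pipeline default
is 999 (smallest p 0.001), a deliberate compromise for routine runs.

**Closeness.** The observed distance between modules A and B is the mean
shortest-path length over all cross pairs, with genes shared by both modules
contributing distance 0 and unreachable pairs excluded (their fraction is
reported so fragmentation is visible). The all-pairs mean was chosen as the
default convention because observed/random distances of the magnitude seen
in interactome module analyses of this kind (~2.7 vs ~2.74) sit on a
network-average-distance scale rather than a closest-neighbour scale; a
symmetrized `closest` convention is available as an option. The null re-draws both node sets `n_iter` times (default 1,000)
with degree-binned sampling and reports $z = (d_{obs}-\mu)/\sigma$; one-sided
significance at z < −1.65 is labelled "significantly close".

**Degree-binned sampling.** Nodes are grouped by degree and consecutive
groups merged until each bin holds ≥ 100 nodes (the short tail merges
backwards); random sets draw from each module node's bin. This preserves the
degree profile of typical modules to within a few percent but cannot resolve
a narrow slice of the extreme hub tail (a bin of 100 heterogeneous hub
degrees is coarser than a 40-hub module) — the standard limitation of this
scheme. Uniform sampling is available via `degree_binned = FALSE`. On graphs
small enough to cache (≤ 6,000 nodes) the full BFS distance matrix is
computed once per interactome and reused across randomizations.

## 4. Ontology enrichment and semantic similarity

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, per term with at least
`min_term_size` (default 3) annotated universe genes, Benjamini–Hochberg
adjusted across tested terms (q < 0.05 reported as significant; BH replaces
proprietary multiple-testing schemes with identical threshold semantics).
Annotations propagate to ancestor terms. The universe is the expression
platform's gene set, not the genome — enrichment is relative to what could
have been measured.

Wang-method similarity assigns each term an S-value surface over its ancestor
closure: $S(\mathrm{term}) = 1$ and
$S(t) = \max_{c \in \mathrm{children}(t)} w_{e(c,t)} S(c)$, with semantic
contribution factors $w_{is\_a} = 0.8$ and $w_{part\_of} = 0.6$ — the
established constants for this method. Term similarity is
$\sum_{t \in A \cap B}(S_a(t) + S_b(t)) / (SV(a) + SV(b))$; gene and gene-set
similarities aggregate by best-match-average (sum of row maxima plus column
maxima over the similarity matrix, divided by the number of rows plus
columns). Similarities are computed within one namespace; when annotations
span namespaces, per-namespace scores are combined by maximum (a documented
choice; nothing in the method fixes it). The minimal OBO parser consumes
only `[Term]`, `id`, `name`, `namespace`, `is_a`, `relationship: part_of`
and `is_obsolete` — full OBO 1.4 parsing is out of scope.

## 5. Cross-tissue (placental) replication

The blood overlap signature is tested in a second tissue by (i) an
expressed-in-all filter (a gene must be present with a non-missing value in
every sample), (ii) genome-wide rank-product DE on the full matrix — rank
statistics are computed against all genes, then intersected with the
signature, mirroring the staged design rather than re-ranking within the
signature — and (iii) calling at two-sided permutation p < 0.05 (pfp
optionally) and re-mapping the called subset onto the interactome. Identifier
translation collapses many-to-one probe mappings by keeping the
highest-mean-expression probe when expression is supplied (first occurrence
otherwise), a documented, configurable rule.

## 6. The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, sized
to the study design it stands in for:

* **Cohort**: 157 samples (discovery), condition prevalences 0.30 / 0.40 /
  0.66 / 0.76 for PE, asthma, excess BMI and vitamin D insufficiency —
  matching the cohort's 47/157 PE cases, 63 asthmatics, 104 with BMI ≥ 25
  and 119 insufficient — assigned as independent Bernoulli flags (the
  analysis treats conditions as separate contrasts on one cohort; correlated
  prevalences are deferred).
* **Expression**: per-gene baseline mean ~ U(4, 12) and biological SD ~
  U(0.2, 0.6) on the log2 scale plus Gaussian measurement noise
  (SD 0.5) — the simplest model consistent with background-adjusted,
  log2-transformed, quantile-normalized arrays.
* **Planted signatures**: 96/121/111/79 genes per condition sharing a
  24-gene core (the emulated design's 965/1,214/1,107/789 discovery
  signatures and 238-gene overlap, scaled to a 1,000-gene universe ≈ one
  tenth of an array); sets are disjoint outside the core; effect = ±1.0 log2 units
  (twice the measurement-noise SD), sign random per gene and fixed across
  conditions so "upregulated" counts cohere. Effect magnitudes recoverable
  in the real cohorts are not reported anywhere; this default is chosen for
  testability, not biological realism.
* **Interactome**: preferential attachment with triad closure (heavy-tailed
  degrees, non-trivial clustering), planted signatures densified by an
  internal edge-probability boost (pipeline default 0.12) with boosted edges
  scored above the 0.4 confidence threshold, so planted structure survives
  filtering.
* **Ontology**: a single-rooted DAG with typed edges (`part_of` fraction
  0.2, occasional second parents) and exactly `annotations_per_gene`
  annotations per gene. Annotations are independent of the planted
  signatures, so GO enrichment of the overlap is expected to be null — the
  generator validates the machinery, not a biological story.
* **Placenta**: a balanced two-group study over the same gene universe in
  which a configurable fraction (pipeline default 0.41, matching the
  emulated design's 98/238 placental replication rate) of the blood core is planted
  with concordant direction; fractional counts round half-to-even.

What passing tests on these data do **not** show: robustness to batch
effects or latent heterogeneity (no surrogate-variable structure is
simulated), array-platform artifacts, correlated condition prevalences, or
realistic PPI topology beyond degree heterogeneity and local clustering.
Headline counts of the emulated design (965/1,214/1,107/789 discovery genes,
the 238-gene overlap, specific closeness distances) depend on cohorts and a
curated interactome that are not shipped here; they are treated as
data-shape anchors, not reproduction targets.

## 7. Numerical and design notes

* Replication cohort default: 60 samples. The real replication sets were
  small (30 and 24); 60 gives the synthetic replication stage enough power
  that a failed end-to-end core recovery indicates a defect rather than
  sampling noise, which is what the test suite needs to detect.
* Master seed → per-stage substreams via a fixed linear-congruential step,
  so any stage can be re-run in isolation; all generator functions save and
  restore the caller's RNG state.
* Ties in fold-change ranking receive average ranks; with average ties the
  down-ranking is the exact mirror of the up-ranking, halving the work. Tie
  sensitivity is negligible for continuous expression values.
* Degenerate inputs: empty classes, B = 0, zero margins in 2×2 tables,
  constant covariates, unannotated genes, modules with no mapped gene and
  cyclic ontologies all raise typed errors or logged warnings rather than
  propagating NaN.
* Problem sizes in the tests and the acceptance script (1,000-gene cohorts,
  20 null replicates, 200 closeness-null repeats, 999/150 randomization
  iterations) were chosen so the full suite exercises every stage at
  meaningful power on a single CPU.
* The pooled-variance t-test (not Welch) and the Yates-corrected chi-square
  are the defaults for the baseline tables because they are the tests whose
  recomputed p-values match the printed ones (0.042, 0.047, 0.025); Welch
  and Fisher variants are provided.

## 8. Known limitations

* The exact distance convention and randomization scheme behind reported
  closeness tables vary across studies; both supported conventions
  (`all_pairs`, `closest`) are documented rather than asserting one as
  canonical.
* pfp, like any FDR-type quantity, is unstable at the very top ranks for
  small B; raise B for publication-grade calls.
* Whether replication "two-sided P" and the placental "P < 0.05" refer to
  permutation p or pfp is ambiguous in such designs; permutation p is the
  default here and pfp is exposed as an option (`use_pfp`).
* `mclusterSim`-style set similarity on hundreds of genes is quadratic in
  set sizes; the pipeline computes it for replicated signatures of ~100
  genes in seconds, but genome-scale sets would need memoized term caches.
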