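---
title: "Diagnostic SNP panels and hierarchical cascade classifiers"
author: "snpcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic SNP panels and hierarchical cascade classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcascade)
```

# Scope

`snpcascade` turns a dense reference genotype matrix (samples × SNP loci,
allele dosages 0/1/2 with missing calls) into two reusable artifacts: a
small *diagnostic panel* of loci that separates the reference populations,
and a *knowledge-base network* (KBN) — a rooted tree of per-node
discriminant classifiers that assigns unknown samples to a population
label, from broad lineage down to local population, while tolerating
missing loci. This vignette is the package's account of the underlying
models, the defaults, and the choices made where the design was open.

# The discriminant model

## DAPC

Every classifier in the package is a Discriminant Analysis of Principal
Components. Given genotypes $X$ ($n$ samples × $p$ loci, mean-imputed) and
group labels, we:

1. center columns (optionally scale to unit variance; default unscaled,
   since 0/1/2 dosages are already on a common scale);
2. project onto the leading $n_{\mathrm{pca}}$ principal components via
   SVD;
3. run Fisher LDA on the PC scores: discriminant axes $a$ maximize
   $a^\top B a / a^\top W a$, with $B$ and $W$ the between- and
   within-group covariances of the scores. We solve the symmetric
   whitened eigenproblem $W^{-1/2} B W^{-1/2}$, which scales axes to unit
   within-group variance.

Running the LDA in PC space rather than on raw loci keeps $W$ well
conditioned when $p \gg n$, the normal regime for SNP panels. At full PCA
rank the procedure coincides with plain LDA on the centered matrix — a
property the test suite checks against an independent LDA implementation.

**Posteriors.** Because axes have unit within-group variance, group
densities are modelled as Gaussians with a shared spherical covariance in
discriminant space:
$\Pr(g \mid z) \propto \pi_g \exp(-\tfrac12 \lVert z - \mu_g \rVert^2)$.
How the original DAPC formulation computes membership probabilities is not
fully documented; this explicit model is recorded here and pinned by
tests (posterior rows sum to 1; a sample equidistant from two equal-prior
centroids gets 0.5/0.5). Priors default to group proportions;
`priors = "uniform"` or a named vector overrides.

**Numerical conventions.** The within-group covariance gets a ridge of
$10^{-8} \cdot \overline{\mathrm{diag}(W)}$ so degenerate small groups
cannot make it singular. PCA components and discriminant axes fix their
sign so the largest-magnitude loading is positive, making results
identical across platforms and BLAS builds. Argmax ties (posterior,
assignment) break lexicographically on the group label.

**Missing data at prediction.** Loci absent from a query, and missing
calls, are filled with the training-set locus means — i.e. they contribute
exactly zero after centering. Inside the cascade this is *node-local*:
each node fills from its own reference subset, so the imputed value
sharpens as a sample descends into more specific groups. Whether the
original cascade refilled per node or once globally is unstated in the
literature this design follows; the node-local policy is this package's
choice, recorded and tested (masking 25% of the panel costs only a few
points of accuracy on simulated data).

## Choosing the number of PCs

`xval_select_npca()` repeats stratified splits (default 90% training /
10% held out, 30 replicates, seeded) for each candidate $n_{\mathrm{pca}}$
and scores the proportion of held-out samples re-assigned to their true
group; the RMSE of $1 - \Pr(\text{true group})$ is reported secondarily.
The candidate maximizing mean success wins; ties go to the smallest
candidate — retaining too many PCs overfits the within-group scatter, so
parsimony is the right tie-break. Inside `build_kbn()` the per-node
cross-validation uses a reduced default (grid 5/10/20/40, 5 replicates):
node classifiers usually have 2–3 classes and hundreds of samples, where
this grid is ample and keeps network construction fast; both knobs are
exposed.

# Panel discovery

`iterative_select()` operationalizes the iterative, sequential panel
search. A DAPC over the full candidate pool ranks loci by **LD value** —
the per-locus contribution summed over retained discriminant axes, where
the contribution of locus $j$ to axis $a$ is the squared composition of
PCA loadings with discriminant coefficients, normalized per axis. The top
`batch_size` (default 25) loci seed the panel; each round refits on the
current panel and evaluates the separation criterion for the target group:

* **separated** iff every target sample has posterior $\ge \tau$ for the
  target *and* no non-target sample is assigned to it; the scalar metric
  is the minimum target posterior.

While unseparated, the next batch down the ranking is tried; a batch is
kept only if it achieves separation or raises the metric by at least
$\varepsilon$; otherwise it is discarded and never revisited for that
target. The published procedure states the retain/discard rule but no
numeric criterion; $\tau = 0.95$ and $\varepsilon = 0.01$ are this
package's operationalization of "clearly discriminated" — posterior
purity is the testable surrogate for visually non-overlapping clusters.
`select_all_groups()` repeats the search per group (broad groups first,
order configurable; simulations show reordering moves accuracy by little)
and returns the union panel.

# The knowledge-base network

## Ward dendrogram

`ward_cluster()` implements minimum-variance agglomeration: merge cost
$2\,\frac{|A||B|}{|A|+|B|}\lVert \mu_A - \mu_B \rVert^2$ (for singletons,
the squared Euclidean distance), via Lance–Williams updates on squared
distances. Heights are therefore twice the increase in within-cluster sum
of squares and are monotone. Ties merge the lexicographically smallest
pair, indexing each cluster by its smallest member — a deterministic rule
the brute-force oracle in the tests reproduces independently. The
dendrogram converts to `hclust` (for `cutree` and plotting) and exports
to Newick.

## Topology

The cascade topology is **explicit configuration**, not an automatic
derivation: group labels on a dendrogram are a judgment call (the
reference networks in this domain were labeled by hand), so
`topology_from_dendrogram()` only *proposes* a binary topology from a
dendrogram of group centroids — with level-lettered node ids (`A_1`,
`B_1_2`, ...) — which the user can edit or replace via `kbn_node()`.
Terminals carry one label, or two for *double-assignation* terminals
(pairs that the primary cascade cannot reliably split, e.g. the
scutellata/capensis, Madagascar/Seychelles and Malta/Tunisia pairs of the
shipped honey-bee skeleton, `default_bee_topology()`); each such terminal
gets a secondary (Tier II) DAPC over just its two groups. The shipped
honey-bee topology is a faithful skeleton of the published network's
named nodes, not the full reference tree.

## Build and predict

`build_kbn()` fits, for every internal node, a DAPC on the node's
reference samples with one class per child branch, $n_{\mathrm{pca}}$
chosen by per-node cross-validation; every node derives its own split
seed from the base seed, so rebuilding is bit-identical. Classes smaller
than `min_group_size` (default 3 — the smallest size that still admits a
90/10 split with two training samples) abort construction.

`predict_kbn()` routes each sample root→terminal by per-node argmax
posterior (no reject option by default; an optional `min_posterior`
abstention threshold is available for screening use, default off).
Samples missing more than `max_missing` panel loci (default 96, the
published cutoff for a 272-SNP panel, read as inclusive-keep: exactly 96
missing is still accepted) are rejected into a report rather than
labeled. Networks serialize to a directory of JSON files (topology + one
model per node) at full double precision, so a deserialized network
routes identically.

# Reference-frequency assignment

`assign_sample()` is a deliberately simple comparator in the tradition of
classical assignment software: per-population alternate-allele
frequencies with a pseudocount
($\hat q = (\text{alt count} + c)/(2n + 2c)$, $c = 0.5$ so fixed loci
cannot yield $-\infty$ log-likelihoods), then either the sum of log
Hardy–Weinberg genotype probabilities over non-missing loci
(`"loglik"`), or the Euclidean distance between dosage/2 and the
frequency vector (`"distance"` — the smallest-genetic-distance
criterion). Monte Carlo resampling p-values and exclusion tests are out
of scope; rank-based assignment is what reference-set sensitivity
analyses report. The two methods agree on well-separated populations
(checked at $F = 0.2$); the tests also reproduce, on simulated admixture,
the qualitative phenomenon that an admixed sample's winning label flips
when a genetically closer reference population joins the reference set —
the reason assignments must always be read relative to the reference
panel.

# Genotype input and QC

* **Tabular dialect**: TSV, header row of locus ids, first column sample
  id, cells 0/1/2 or the missing token (default `"NA"`); read/write
  round-trips exactly.
* **VCF**: GT fields map by alternate-allele count; `diplotize = TRUE`
  doubles haploid calls (0→0, 1→2) so haploid callsets can join diploid
  references; multiallelic records are skipped or rejected per
  configuration. Coordinates are 1-based; internal locus keys are
  `chrom:pos`.
* **Hard filtering**: a record is rejected iff any rule fires — QUAL<30,
  QD<2.0, MQ<4.0, MQRankSum<−12.4, ReadPosRankSum<−8.0, FS>60.0, SOR>3.0 —
  with *strict* comparisons (a record exactly on every boundary passes)
  and per-record reason lists. Note MQ<4.0 / MQRankSum<−12.4 differ from
  the common GATK convention (40 / −12.5); the defaults follow the
  workflow this package standardizes, and every threshold is
  configurable. Missing annotations cannot fire a rule in lenient mode;
  `strict = TRUE` makes them an error.
* **QC**: loci first, then samples — monomorphic loci are dropped (they
  carry no signal and would be constant columns under scaling), then
  samples over the missing-data thresholds (count and/or fraction, both
  inclusive-keep). The order is fixed because dropping loci changes
  per-sample missing fractions.
* **Flank filter**: for assay design, a locus is kept only if no other
  variant lies within `window` bases (default 32, closed window: a
  neighbour exactly 32 bases away excludes the locus).

# The simulator, and what passing tests do not show

`simulate_populations()` is the Balding–Nichols F-model: ancestral
frequency $p \sim U(0.05, 0.95)$, population frequency
$q \sim \mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ (so
$\mathrm{Var}(q) = F p(1-p)$; at $F=0$, $q = p$ exactly), genotypes
$\sim \mathrm{Binomial}(2, q)$, missingness completely at random.
Admixed samples mix population frequencies per locus;
`simulate_hybrid_cline()` produces ancestry gradients whose expected PC1
score is linear in the admixture proportion $q$.
`simulate_planted_panel()` plants high-$F$ loci on a near-undifferentiated
background and additionally rejection-samples the planted loci to a
minimum realized frequency divergence (default 0.4): an ancestry
informative marker is divergent *by definition*, and an unconstrained
high-$F$ draw can fix the same allele in every population, leaving a
"diagnostic" locus with no signal.

The simulator's defaults define the conditions under which the package's
claims are tested: e.g. six populations at $F = 0.15$, 300 loci, 60
samples per population for cascade recovery; $F(\text{diagnostic}) = 0.5$
against $F(\text{background}) = 0.01$ among 500 loci for panel discovery.
Loci are unlinked (diagnostic panels average hundreds of kilobases
between markers, so independence is a reasonable fixture assumption),
Hardy–Weinberg holds within populations, and missingness is MCAR. Real
data violate all three — linkage, inbreeding and wahlund effects, and
platform-specific (informative) missingness — so passing tests establish
correctness of the algorithms under the stated model, not field accuracy
on any particular organism.

# Problem sizes and defaults

| Parameter | Default | Where |
|---|---|---|
| `n_pca` | cross-validated; grid 10..300 by 10 (`xval_select_npca`), 5/10/20/40 at KBN nodes | DAPC |
| `n_da` | `min(n_pca, groups − 1)` | DAPC |
| ridge on $W$ | $10^{-8}\cdot\overline{\mathrm{diag}(W)}$ | DAPC |
| `tau`, `eps` | 0.95, 0.01 | panel selection |
| `batch_size`, `max_rounds` | 25, 40 | panel selection |
| impute `rank`, `tol`, `max_iter` | 10, $10^{-6}$, 100 | SVD imputation |
| `max_missing` | 96 (inclusive-keep) | cascade predict |
| `max_missing_frac` | 0.5 | sample QC |
| flank `window` | 32 bases, closed | assay QC |
| pseudocount | 0.5 | frequency assigner |
| `min_group_size` | 3 | KBN build |

The test suite and the acceptance script run everything at desk scale
(hundreds of samples, hundreds of loci, seconds per scenario); those
sizes are the package's chosen demonstration conditions and all scale up
linearly in samples × loci.

# Known limitations

* The iterative selector is greedy per target group; it does not search
  over joint panels, and the historical panels it emulates depended on
  intermediate analyst decisions that no algorithm can replay exactly.
* DAPC posteriors assume spherical within-group covariance in
  discriminant space; heavy admixture violates the single-group model and
  degrades posterior calibration before it degrades argmax accuracy
  (admixed samples are assigned to the *closest* reference, never flagged
  as mixtures — no ancestry-proportion estimation is attempted).
* SVD hard-imputation recovers exactly low-rank structure and is intended
  for PCA preprocessing; at high rank-to-size ratios the alternating
  projection can stall short of exact completion, and it is not a
  substitute for linkage-aware genotype imputation.
* The assignment comparator has no exclusion test: a sample from a
  population absent from the reference set will still be confidently
  assigned to the nearest available label — reference-set sensitivity is
  a feature of the method family, demonstrated in the tests.
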