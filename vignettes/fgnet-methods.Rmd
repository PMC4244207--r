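---
title: "Functional gene networks from ontology annotations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional gene networks from ontology annotations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgnet)
```

fgnet infers a weighted functional gene network for a species whose only
genome-scale functional resource is its Gene Ontology annotation — the
situation of most non-model organisms, where protein-interaction,
co-expression and genetic-interaction compendia are too sparse to integrate.
The pipeline has four stages: term-level semantic similarity, gene-level
similarity, network thresholding, and downstream analysis (topology,
validation, candidate prioritization). This vignette explains each model,
the tunable parameters, and the design decisions taken where more than one
reading was defensible.

## Semantic totipotency and the SSDD term distance

The Gene Ontology is three rooted DAGs (biological process, molecular
function, cellular component), with `is_a` and `part_of` treated identically
as parent edges and `has_part`, cross-aspect and obsolete entries excluded.
Every term carries a *semantic totipotency* T-value: the capacity of a term
to differentiate into more specific meanings. Roots have T = 1; every other
term attenuates its parents' values,

$$T(t) = \operatorname{mean}_{p \in \mathrm{parents}(t)}
  \big[\, \omega(t, p)\, T(p) \,\big],$$

where the per-edge differentiation factor is the descendant-count ratio
$\omega(t,p) = n(t)/n(p)$, with $n(\cdot)$ counting descendants including
the term itself. This ratio is the one function of local density that meets
every constraint the measure imposes: it is strictly inside (0, 1) on any
true child edge, it shrinks toward the leaves, and it grows with the
child's own subtree size. Because a multi-parent term may sit at different
depths under its parents, ω is evaluated per parent *inside* the average
rather than once outside it; `term_stats()` accepts any replacement
strategy through its `omega` argument.

The shortest semantic differentiation distance (SSDD) between two terms of
one aspect sums the T-values of every term on the shortest path connecting
them through a lowest common ancestor, then maps the sum into (0, 1):

$$d(t_1, t_2) = \frac{2}{\pi}\,
  \arctan\!\Big(\sum_{u \in \mathrm{path}(t_1, t_2)} T(u)\Big),
  \qquad s = 1 - d.$$

The $2/\pi$ factor is what makes the stated (0, 1) range true — a bare
arctangent exceeds 1 as soon as the path accumulates more than
$\tan(1) \approx 1.56$ of totipotency, which already happens for two
siblings under a root.

Two path conventions needed fixing:

* **Tie-breaks.** Among minimum-hop paths we pick the one with the smallest
  summed T-value — the quantity the distance accumulates — and break any
  remaining tie lexicographically, so `lca_shortest_path()` is deterministic
  and exactly symmetric in its arguments.
* **Identical terms.** Read literally, the path for a term against itself
  is the single term, whose positive T-value makes self-similarity less
  than 1 (exactly 0.5 at a root). We keep the literal rule as the default
  because nothing in the measure's definition exempts the self-pair, and
  expose `identical_term_sim = 1` for users who want the conventional fixed
  point. All shipped results use the literal rule.

## From terms to genes

A gene pair is compared per aspect by the best-match average (BMA) of its
two annotation sets: each term is paired with its most similar counterpart
in the other set, both directions are averaged. A gene unannotated in an
aspect contributes aspect similarity 0 — not an error — because the
integration step below is designed to absorb exactly that case.

The three aspect similarities combine by a similarity-weighted average,

$$s_{\mathrm{INT}} =
  \frac{s_{BP}^2 + s_{MF}^2 + s_{CC}^2}{s_{BP} + s_{MF} + s_{CC}},$$

with $s_{\mathrm{INT}} = 0$ when all three vanish. Weighting each aspect by
its own similarity lets the aspect in which two genes genuinely resemble
each other dominate, and prevents one missing aspect from collapsing the
integrated value; algebraically the result always lies between the smallest
nonzero input and the largest input. The integrated gene universe is the
union of genes annotated in any aspect, whereas each per-aspect table runs
over that aspect's own universe.

`all_pairs_similarity()` streams the $n(n-1)/2$ unordered pairs block-wise
with a memoised term-pair cache and deterministic (sorted) output; at
genome scale the table is written incrementally via `file=`.

## Threshold selection by the clustering gap

Filtering the similarity table at a threshold yields a network whose nodes
are the genes with at least one surviving edge (isolated genes are dropped,
so node counts shrink as the threshold rises). The network clustering
coefficient is the mean over nodes of $C_i = 2e_i / (k_i(k_i-1))$ with
$C_i = 0$ for degree below 2, and its degree-matched random expectation is
the configuration-model closed form

$$C_{\mathrm{rand}} =
  \frac{(\langle k^2\rangle - \langle k\rangle)^2}
       {N\,\langle k\rangle^3},$$

computed from the observed degree sequence (`random_clustering_expectation()`
is pluggable for other null models). A genuinely modular biological network
should sit far above this expectation, so the scan walks thresholds
0.00–1.00 in 0.01 steps and tracks
$\Delta C = C_{\mathrm{obs}} - C_{\mathrm{rand}}$.

The selected threshold is the *first stop of the monotone increase* of
ΔC: scanning upward from 0.01, the first grid point whose ΔC is not
exceeded by the next one. Three boundary rules make this well defined:
plateaus terminate the increasing run (they are a stop, not a
continuation); the unfiltered complete table at threshold 0.00 takes no
part in the comparison; and a ΔC that still rises at 1.00 selects 1.00
with a warning. A monotone-decreasing ΔC therefore selects 0.01 — the
most permissive meaningful cutoff.

```{r scan, eval = FALSE}
pn <- simulate_planted_network(seed = 1)
scan <- threshold_scan(pn$pairs, "INT")
attr(scan, "selected")   # 0.8, the planted value
plot(scan)
```

## Topology characterisation

Degree distributions are summarised as relative frequencies at raw
(unbinned) degrees and fitted by nonlinear least squares to three
candidate models — four-parameter lognormal
$y = y_0 + \frac{A}{\sqrt{2\pi}\sigma x} e^{-(\ln x - \mu)^2 / 2\sigma^2}$,
power law $y = a x^b$, and exponential $y = y_0 + A e^{bx}$ — ranked by
$R^2 = 1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$. Starting values come from
log-linear pre-fits, σ and A are bounded below by zero, and a model that
fails to converge is flagged in the report instead of raising. Relative
frequency (not probability density) is the fitted y-variable. Note that
the four-parameter lognormal can occasionally edge out the true generating
family on noisy data; the fit report always carries all three $R^2$ values
so that near-ties are visible.

Degree correlation is reported at three levels of compression: the joint
degree distribution (one count per unordered endpoint-degree pair, summing
to the edge count), the knn curve (mean neighbour degree per observed
degree class, missing degrees skipped), and the Pearson degree correlation
(correlation of endpoint degrees over all edges, both orientations, which
equals the standard assortativity coefficient). A zero-variance degree
sequence — a regular graph — returns PDC 0 with a `degenerate` flag rather
than NaN.

Global properties (diameter, radius, characteristic path length,
centralisation, heterogeneity as the degree coefficient of variation)
follow the conventions of common network-analysis desktops; diameter and
radius are computed on the largest connected component, since they are
undefined on disconnected graphs.

## Validation against reference networks

Three reference constructions are supported: a clique per shared pathway
term (from a two-column gene–term link table), a co-expression union over
datasets (|Pearson r| strictly above 0.8 within each dataset of at least 20
samples; constant-expression genes are skipped with a warning), and
orthology transfer (every source edge expanded through a possibly
one-to-many ortholog map, self-pairs dropped).

Agreement is measured by gene coverage $C_g = 100\,N_s/N_k$ (shared genes
over reference genes) and linkage accuracy $L_a = 100\,L_s/L_k$. The
published definition of $L_a$'s denominator is ambiguous — "linkages
between the shared genes" could count them in the query or in the
reference. We define $L_k$ as the query's edges among shared genes and
$L_s$ as those of them present in the reference, which makes $L_a$ a true
precision bounded by 100; `la_mode = "reference"` switches to the literal
reference-denominator reading. Both reproduce the published percentages
from their printed count fractions.

Significance comes from a degree-preserving null: 400 double-edge-swap
randomizations of the query (10·|E| accepted swaps each, loops and
multi-edges rejected), each scored for $L_a$ against the reference. The
empirical one-sided p-value is the add-one-corrected rank of the observed
accuracy among the randomized ones — with 400 replicates its resolution is
1/401 ≈ 0.0025. A one-way ANOVA mode (`la_anova()`) is provided for
contrasting several query networks' backgrounds; the empirical p remains
the primary per-network statistic.

## Guilt-by-association prioritization

Candidates are the direct network neighbours of the query
(function-known) genes, minus the queries; the induced subgraph on queries
plus candidates is reduced to its largest connected component — the densest
module the queries anchor. Each candidate in the module gets $v$ (query
neighbours), $F$ (mean weight of its query edges), and the weighted rating

$$WR = \frac{v}{v + m}\,F + \frac{m}{v + m}\,C,$$

the Bayesian shrinkage estimator popularised by movie-rating aggregation:
a candidate with few known neighbours is pulled toward the cross-candidate
mean $C$, one with many is trusted at its own $F$. The prior count $m$ is
the first quartile of the candidates' $v$ distribution, computed with the
linear-interpolation quantile (R type 7) — quartile conventions differ
enough between packages that this is worth pinning down. $F$ averages
edges to the supplied queries only; passing a wider gene set as the
`queries` argument of `wr_scores()` reproduces the alternative reading in
which all known genes in the module contribute. Ranking is by WR
descending with lexicographic tie-break, so results are reproducible to
the byte. An optional one-step weight-normalised diffusion smoother
(`gba_diffusion()`, single parameter α) is provided as a clearly-labelled
extension; the default pipeline uses direct neighbours only.

## Synthetic data: what it emulates and what it does not

The generators produce every input format the pipeline reads, with
seed-deterministic output and ground truth recorded by independent
brute-force bookkeeping (reachability counting and direct recursion, not
the production code paths):

* `simulate_ontology()` — single-rooted random DAGs per aspect with a
  tunable multi-parent fraction, written as OBO with both `is_a` and
  `part_of` edges. Defaults (15/10/8 terms) keep exhaustive oracles
  instant while still exercising multi-parent averaging and LCA ties.
* `simulate_annotations()` — genes partitioned into modules drawing term
  sets from disjoint (optionally overlapping) per-module pools, so
  within-module similarity dominates between-module similarity by
  construction; written as GAF 2.1.
* `simulate_planted_network()` — disjoint cliques whose weights sit at or
  above a planted grid threshold, plus a stratified background of
  triangle-free pendant edges filling every 0.01 bin below it. Each scan
  step removes some background, so ΔC rises strictly until the background
  is exhausted and plateaus at the planted value — the first-peak rule
  recovers it exactly. Defaults: 60 genes, three 10-cliques, threshold
  0.8.
* `simulate_expression()` — one-factor-per-block Gaussian model giving
  exact planted within-block correlations, with sample counts chosen to
  exercise the 20-sample dataset cut.

These fixtures validate the algorithms' arithmetic and selection rules,
not their biological performance: real annotation corpora have highly
skewed term frequencies, shared ancestors between functional modules,
evidence-code biases, and similarity distributions far from the planted
two-level structure. Passing the planted-threshold suite shows the ΔC rule
finds a genuine clustering-gap peak, not that 0.99-type genome-scale
thresholds are optimal for any particular species.

## Numerical choices and problem sizes

Floating-point ties in path search use a 1e-12 tolerance before the
lexicographic tie-break. The threshold grid is fixed at 0.01 steps to match
the published scan. Degenerate cases are defined, not raised: empty
networks have clustering 0, zero-degree sequences have expectation 0,
regular graphs have PDC 0 (flagged), zero-denominator validation reports
carry NA with a `degenerate` flag. The test and acceptance suites run the
exhaustive oracles on graphs of up to 30 nodes, 100 random replicates per
invariant, 20 planted-threshold fixtures of 60 genes, and 400-replicate
randomization nulls on 40-node networks — sizes at which every
brute-force oracle is exact and the whole suite completes in about a
minute on one core.

## Known limitations

* Annotation propagation to ancestors is deliberately absent: SSDD
  operates on the DAG directly, and propagating first would double-count
  shared ancestry.
* The co-expression "uninformative dataset" pre-filter of the original
  workflow is under-specified and omitted; dataset filtering is by sample
  count only.
* Community detection, GO-slim mapping and regulates-edge handling are out
  of scope.
* At genome scale (tens of thousands of genes) the all-pairs stage is the
  bottleneck; the streaming writer keeps memory bounded, but wall-clock
  time grows quadratically and calls for chunked parallel runs outside
  this package.
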