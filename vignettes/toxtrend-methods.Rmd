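---
title: "Methods: trend tests for synergy and toxicity metrics against ordinal DDI severity"
author: "toxtrend authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend tests for synergy and toxicity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Computational synergy-prediction models for cancer drug combinations
sometimes add a "toxicity penalty" to their objective: a proxy score meant
to disfavor combinations likely to interact adversely. Common proxies are
the overlap of the two drugs' protein targets or of the pathways those
targets belong to, the structural similarity of the two molecules, and
distance- or neighborhood-based scores on a protein–protein interaction
network (PPIN). Whether any of these proxies — or the synergy scores
themselves — actually track *clinically documented* drug–drug interaction
(DDI) severity is an empirical question.

`toxtrend` implements the full evaluation as a reusable pipeline. Severity
is treated as an ordinal variable with three levels, Minor < Moderate <
Major. For every numeric variable of interest (a synergy score such as
Bliss, HSA, Loewe, ZIP, S\_max/S\_mean/S\_sum, or a per-pair metric), the
package asks: do the distributions differ across severity levels, which
pairs of levels differ, and is there a monotone trend in either direction
along the severity ordering?

Because the clinical databases that motivate the analysis are licensed,
the package ships readers for their table dialects but performs all of its
testing and validation on a synthetic data generator whose statistical
structure is known by construction.

## The statistical battery

For each (variable, severity source) cell, the pipeline runs, in order:

1. **Normality screen** — the D'Agostino–Pearson omnibus test,
   $K^2 = Z_{\text{skew}}^2 + Z_{\text{kurt}}^2 \sim \chi^2_2$, using the
   classical moment approximations (valid from roughly $n \ge 20$; the
   function refuses smaller samples). The screen is *reported only*: the
   nonparametric battery runs regardless of its outcome, because the
   screen's role is to justify nonparametric tests, not to select
   parametric ones.
2. **Kruskal–Wallis omnibus test** with tie-corrected $H$ and the rank
   eta-squared effect size defined as $\eta^2 = H/(N-1)$ — the proportion
   of rank variance explained by group membership. The more common
   chance-corrected variant $(H-k+1)/(N-k)$ is available via
   `effectVariant = "adjusted"`, but the $H/(N-1)$ form is the default the
   report tables use.
3. **Dunn's post-hoc test** on pooled mean ranks with the pooled tie
   correction, Bonferroni-corrected over the three level contrasts
   (Moderate–Minor, Major–Minor, Major–Moderate), each contrast carrying
   **Cliff's delta** $\delta = (\#\{x>y\} - \#\{x<y\})/(|x||y|)$ as its
   dominance effect size, signed later-vs-earlier level.
4. **Jonckheere–Terpstra trend test** in *both* directions (severity
   increasing and decreasing). $J$ sums the between-group Mann–Whitney
   counts concordant with the ordering, ties half-weighted. The normal
   approximation uses the tie-corrected null mean and variance; the effect
   size is $r = Z/\sqrt{N}$, interpretable like a correlation coefficient.
   A permutation mode (exhaustive when the number of distinct label
   assignments is small, Monte Carlo otherwise) serves as the arbiter for
   the approximation.

Synergy-vs-overlap relationships are summarized separately by
`correlationSuite()`: Pearson and Spearman coefficients with p-values and
the least-squares line with its $R^2$.

### Numerical choices

* **Continuity correction.** $J$ lives on a half-integer lattice. The
  one-sided p-value in the normal-approximation mode applies a 0.5
  continuity correction toward the null mean. This choice was validated
  against the package's own permutation mode: over random all-distinct
  datasets with group sizes 3–8, the corrected approximation stays within
  0.01 of the permutation p-value, whereas the uncorrected form deviates
  by up to ~0.03 at the smallest sizes. The correction affects only the
  p-value; the reported $Z$ and $r = Z/\sqrt N$ are uncorrected.
* **Ties.** All rank statistics use midranks; Kruskal–Wallis and
  Jonckheere–Terpstra use the standard tie-corrected variances; Cliff's
  delta counts ties as zero.
* **Degenerate inputs.** All-identical samples, empty groups, or groups
  below the configurable minimum size (`nMin`, default 20) are never
  silently dropped: the pipeline emits the complete per-variable row grid
  (1 normality, 1 omnibus, 3 post-hoc, 2 trend rows) with an explicit
  `insufficient_data` reason code, so the report grid is always auditable.
* **Empty-set Jaccard.** `jaccard(∅, ∅)` is 0 ("no demonstrated
  overlap"), but a drug with *no target data at all* yields an absent
  (`NA`) metric — "no data" and "no overlap" are deliberately distinct.
* **Unreachable network pairs.** In the average target distance
  $D_{avg}(T_A,T_B) = \frac{1}{|T_A||T_B|}\sum_{t_A}\sum_{t_B} d_G(t_A,t_B)$,
  pairs that are unmappable or in different components are excluded from
  the mean by default (an imputation constant would dominate it and there
  is no principled constant); the number of dropped pairs is recorded, and
  `unreachable = "impute"` provides the sensitivity alternative.
* **Neighborhoods.** $k$-hop neighborhoods include the seed targets
  themselves (a node is within $k$ hops of itself); $k=0$ returns the
  mapped targets.

## Pair metrics

* **Target and pathway Jaccard.** $J(A,B) = |A\cap B|/|A\cup B|$ on target
  sets, and on the unions of the targets' pathway sets under two hierarchy
  views: *lowest* (leaf pathways only) and *all* (leaf plus ancestors).
  The union-over-targets construction (one pathway set per drug, then one
  Jaccard per pair) is used rather than per-target averaging, matching the
  per-drug set flow the analysis describes.
* **Tanimoto on circular fingerprints.**
  $T(M_A,M_B) = M_A{\cdot}M_B / (|M_A|^2+|M_B|^2-M_A{\cdot}M_B)$, which on
  bit vectors is exactly the Jaccard similarity of the on-bit sets — an
  identity the test suite asserts bit-for-bit. Fingerprints are
  Morgan-type circular substructure hashes computed through OpenBabel's
  ECFP implementation (radius 2 ⇒ ECFP4, the conventional default; the
  analysis fixes 2048 bits). OpenBabel hashes into 4096 bits natively; the
  vector is folded by bitwise OR to the requested width, so the width must
  divide 4096. Unparseable SMILES mark the metric absent for all pairs
  involving that drug, with a warning, never a hard error.
* **Network scores.** Edges are unweighted (unit cost) despite the
  confidence scores interaction databases attach: no weighting scheme is
  defined for the analysis, and shortest paths on unit weights are exactly
  breadth-first hop counts (Dijkstra's algorithm degenerates to BFS).
  The two-hop neighborhood Jaccard compares the $k{=}2$ neighborhoods of
  the two target sets.

Metrics are functions of the pair only, so they are computed once per pair
and broadcast to the (drug A, drug B, cell line) observation rows — the
unit of observation throughout; `collapsePairs = "mean"` offers per-pair
averaging as a sensitivity analysis.

## Data ingestion policies

* Drug names are matched across sources by lowercasing and stripping
  whitespace and punctuation — deterministic and auditable; no fuzzy
  matching. A synonym table hook covers genuinely divergent spellings.
* Severity dialects: numeric 0/1/2 and the words Minor/Moderate/Major map
  onto one ordered scale; severities outside the three-level scale (e.g.
  "Unknown") are dropped with a logged count.
* Conflicting duplicate severities for one pair within a source keep the
  *maximum* (clinically precautionary); the conflict count is logged.
* Protein accessions lose isoform suffixes after "-" (configurable).
* The retention filter keeps observations carrying at least one synergy
  score and at least one severity label among the supplied sources;
  per-source analyses subset later. Counts before/after are logged in the
  dataset provenance.
* The interaction-network edge score threshold (`minEdgeScore`) defaults
  to 0 — every "known interaction" edge is kept — and exists because
  distributed edge lists carry confidence scores.

## The synthetic data generator

`simConfig()` + `simulateUniverse()` + `simulateObservations()` emit a
complete input bundle — drugs with SMILES, target sets over a synthetic
proteome, a PPIN, a two-view pathway hierarchy, severity labels in both
severity dialects, and per-(pair, cell line) synergy scores — in exactly
the file dialects the readers consume.

Design choices, fixed once as the package's study conditions:

* **Severity marginals** default to (Minor 0.108, Moderate 0.304, Major
  0.588), the strong skew toward Major interactions typical of curated
  clinical DDI resources.
* **Synergy coupling.** Each score is drawn as
  $z \cdot \texttt{synergyToxicityTrend} + \varepsilon$, with $z$ the
  standardized severity level and $\varepsilon \sim N(0,
  \texttt{noiseSd}^2)$, `noiseSd` defaulting to 1 — a monotone trend of
  known strength.
* **Metric coupling.** A Gaussian copula on ranks reorders the severity
  labels to correlate with a chosen pair metric at the requested strength:
  marginals are preserved exactly and the planted coupling is invariant to
  the metric's marginal distribution (additive shifts would not be).
* **SMILES** come from an embedded palette of 50 valid, structurally
  diverse drug-like molecules — random SMILES strings are rarely valid —
  and `randomFingerprint()` provides a chemistry-free mode for bit-vector
  tests at arbitrary widths.
* **PPIN models**: preferential attachment (default, $m=2$; heavy-tailed
  degrees like real interactomes) or random geometric.
* **Pathway tree**: complete tree (default depth 3, branching 3); each
  protein sits in exactly one leaf, so the lowest view has one pathway per
  protein and the all view has `pathwayDepth` pathways.
* **Cell lines**: each pair gets 1–3 synthetic cell lines, exercising the
  triplicate unit of observation.
* Everything is byte-deterministic under `seed`.

What the generator does *not* emulate: real pharmacology (scores are
emulated at the summary level, not from dose–response surfaces),
correlated score families, name-spelling noise between sources, or the
partial-overlap structure of real synergy/toxicity databases. Passing
tests therefore demonstrate the statistical machinery's correctness and
calibration, not conclusions about any real database.

## Validation strategy and problem sizes

The test suite validates every metric against independent brute-force
oracles (exhaustive set operations, Floyd–Warshall all-pairs distances,
depth-limited BFS) on hundreds of random fixtures; the rank tests against
hand-worked examples, frozen values from an independent implementation of
the normality test, the stock Kruskal–Wallis implementation (as a
cross-check only), and exhaustive permutation enumeration; and the whole
pipeline against planted couplings. Problem sizes were chosen to give the
checks real statistical teeth while keeping a default test run fast:
10,000 replicates for null-calibration rates, 200 seeds × 3,000 pairs for
planted-trend recovery, 10,000 pairs for marginal-recovery and
independence checks, and graphs up to 50 nodes for exact oracle
equivalence.

## Known limitations

* The Jonckheere–Terpstra permutation mode enumerates exhaustively only
  when the assignment count is below `nPerm`; exact small-sample null
  tables are out of scope.
* No multiple-testing correction is applied across metrics or sources
  (only Bonferroni within each post-hoc family); the provenance notes the
  number of tests run.
* Fingerprint widths must divide OpenBabel's native 4096 bits.
* Name normalization is intentionally exact; heavily divergent synonym
  spellings across sources need a user-supplied synonym table.
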