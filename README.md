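# toxtrend

Do cancer drug-combination **synergy scores**, and the **toxicity-penalty
metrics** that synergy-prediction models bolt onto their objectives,
actually track clinically documented drug–drug interaction (DDI) severity?

`toxtrend` is an R package for answering that question. It treats DDI
severity as an ordinal variable (Minor < Moderate < Major) and evaluates,
for every variable of interest —

* the seven common synergy scores (Bliss, HSA, Loewe, ZIP, S_max, S_mean,
  S_sum),
* drug target overlap and pathway overlap (Jaccard similarity
  J(A,B) = |A∩B| / |A∪B|, with pathway sets taken at the lowest hierarchy
  level or across all levels),
* structural similarity (Tanimoto similarity
  T(M_A,M_B) = M_A·M_B / (|M_A|² + |M_B|² − M_A·M_B) of Morgan-type
  2048-bit circular fingerprints),
* protein-interaction-network scores (average target distance
  D_avg(T_A,T_B) = (1/|T_A||T_B|) Σ_a Σ_b d_G(t_a, t_b) over shortest
  paths, and the Jaccard overlap of two-hop target neighborhoods)

— whether its distribution differs across severity levels and whether it
trends monotonically with severity, using a from-scratch nonparametric
battery:

1. D'Agostino–Pearson normality screen (K² omnibus statistic);
2. tie-corrected Kruskal–Wallis with rank eta-squared **η² = H/(N−1)**;
3. Dunn's post-hoc contrasts with Bonferroni correction and Cliff's δ;
4. Jonckheere–Terpstra ordered trend test in both directions, with
   tie-corrected normal approximation, an exhaustive/Monte-Carlo
   permutation mode, and effect size **r = Z/√N**;
5. Pearson/Spearman/R² correlation summaries for synergy-vs-overlap.

The package ships readers for the field's table dialects (DrugComb-style
synergy summaries, DrugBank-style numeric 0/1/2 severities, DDInter-style
severity words, Reactome-style protein→pathway mappings at two hierarchy
views, STRING-style scored edge lists with a UniProt→node ID map) and a
**synthetic data generator** that emits a complete, drop-in input bundle
with plantable severity–synergy and severity–metric couplings, so every
stage runs and is validated without any licensed download.

## Worked example

Simulate a universe and observations with a planted increasing
severity–synergy coupling of 0.4, ingest through the file readers, compute
pair metrics, and run the full battery:

```r
library(toxtrend)

cfg <- simConfig(nDrugs = 60, nProteins = 120, nPairs = 800,
                 synergyToxicityTrend = 0.4, seed = 101)
dir <- tempfile()
u <- simulateUniverse(cfg, file.path(dir, "universe"))
o <- simulateObservations(cfg, u, file.path(dir, "obs"))

syn   <- loadSynergyTable(o$paths$synergy, dialect = "synthetic")
toxDb <- loadToxicityTable(o$paths$drugbank, dialect = "drugbank")
toxDd <- loadToxicityTable(o$paths$ddinter,  dialect = "ddinter")
ds <- assembleDataset(syn, list(drugbank = toxDb, ddinter = toxDd),
                      targets = loadTargets(u$paths$targets),
                      drugTable = read.csv(u$paths$drugs))
ds
#> ComboToxDataset: 60 drugs, 1602 observations (800 distinct pairs)
#>   toxicity sources: drugbank, ddinter
#>   synergy scores: bliss, hsa, loewe, zip, s_max, s_mean, s_sum

metrics <- computePairMetrics(ds,
  loadPathways(u$paths$pathways_lowest, u$paths$pathways_all),
  loadNetwork(u$paths$edges, u$paths$id_map))
report <- runAnalysis(ds, metrics, scores = c("bliss", "s_sum"), nMin = 20)

subset(report@trend, source == "drugbank" & variable == "bliss",
       select = c(test, statistic, z, p_value, effect_size, direction))
#>                 test statistic        z      p_value effect_size  direction
#>  jonckheere_terpstra  490804.5 14.13829 1.103739e-45   0.3532365 increasing
#>  jonckheere_terpstra  490804.5 14.13829 1.000000e+00   0.3532365 decreasing
```

Reading the output: the J statistic (490,804.5 concordant between-group
pairs, ties half-weighted) standardizes to Z = 14.1, so the Bliss score
rises monotonically with severity — the one-sided p-value is ~1e−45 in
the increasing direction and ~1 in the decreasing direction, and the
effect size r = Z/√N = 0.35 recovers the planted coupling of 0.4 up to
the simulation noise. The omnibus table tells the same story with
Kruskal–Wallis H and η² = H/(N−1):

```r
subset(report@omnibus, source == "drugbank" & variable %in% c("bliss", "tanimoto"),
       select = c(variable, statistic, p_value, effect_size))
#>  variable  statistic      p_value effect_size
#>     bliss 201.664156 1.618769e-44 0.125961372
#>  tanimoto   6.516794 3.844999e-02 0.004070452
```

The planted synergy coupling shows a large η²; the structural-similarity
metric, which was *not* coupled to severity in this simulation, sits near
zero. `writeReport(report, dir)` serializes the six tidy tables plus a
JSON bundle and a text summary, byte-identically across reruns.

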