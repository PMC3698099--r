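# tcmepi

Traditional Chinese medicine (TCM) annotates every medicinal with a
seven-grade cold–hot *nature* and a set of *flavors* (sweet, pungent and
plain are yang; sour, bitter and salty are yin). `tcmepi` asks whether those
two-millennia-old annotations line up with modern chromatin biology: do the
chemical constituents of cold/yin medicinals preferentially hit the human
enzymes that condense chromatin, and do hot/yang medicinals hit the enzymes
that open it?

The package implements, as a tested and reusable pipeline over plain TSV /
Newick inputs:

* **Quantitative TCM scoring** — nature tokens map to integers, cold (−3)
  through hot (+3); flavor tokens sum additively (+1 yang, −1 yin, ±0.5 for
  "mild" grades), so a sweet + mild-pungent herb scores 1.5; the yin-yang
  score is nature + flavor.
* **Phylogenetic autocorrelation** — Moran's
  *I* = (N/Σwᵢⱼ) · Σwᵢⱼ(yᵢ−Ȳ)(yⱼ−Ȳ)/Σ(yᵢ−Ȳ)² with inverse cophenetic-distance
  weights wᵢⱼ = 1/dᵢⱼ on a tree over the medicinals, with analytic
  (randomization-assumption) and permutation significance. Trees are read
  from Newick or built as cladograms from taxonomy lineages.
* **Chemo-epigenetic potency profiling** — each medicinal's chemicals are
  mapped through a chemical–protein interaction table onto 18 histone/DNA
  modification attributes (DNMT, HAT, HDAC, residue-specific methylation and
  demethylation such as H3K9 and H3K4i, H3S10 (de)phosphorylation, and
  ATP-dependent remodeling). The X potency is the count of interacting
  chemical–enzyme pairs for X; unspecified interaction directions are
  treated as inhibition. Attributes carry a chromatin conformation
  (7 euchromatic, 10 heterochromatic, ATP ambivalent) and the net tally
  labels each medicinal condensing, unpacking or poising.
* **Correlation screens** — Pearson r between cold-hot / yin-yang / flavor
  scores and each attribute's potency across the histone-modifying
  medicinals, at a per-attribute α = 0.05 (no multiplicity correction, by
  design — the flag is a screen).
* **Hierarchical clustering** — complete-linkage Euclidean clustering of
  entities × 18 potency arrays with TSV/Newick exports.
* **Formula synergy** — a formula's profile is the sum of its members'; the
  normalized net heterochromatinization f = (n_het − n_eu)/(n_het + n_eu)
  of each formula is compared with the mean over its histone-modifying
  members (Δ), against size- and composition-matched random control
  formulas drawn from the real member pool, via a two-sided rank test on
  |Δ|.
* **A seeded synthetic-data generator** — Yule tree, Brownian nature trait
  with tip noise, yin/yang-composed flavors, enzyme families, interaction
  tables with plantable score–potency effects, and formulas with plantable
  chromatin-class homophily, so the whole pipeline is testable offline.

## Worked example

Everything below is computed from a synthetic bundle; no network access or
proprietary database export is needed.

```r
library(tcmepi)

cfg     <- generator_config(seed = 42L)       # 300 medicinals, 100 formulas
bundle  <- generate_bundle(cfg)

profiles <- build_potency_profiles(bundle$catalog, bundle$interactions,
                                   bundle$modcat)
calls    <- chromatin_call(profiles, bundle$modcat)
materia_medica_summary(calls)
#> modifying 180/300 (60%)
#> condensing  unpacking    poising
#>      0.583      0.322      0.094

scores <- score_catalog(bundle$catalog)
W <- inverse_distance_weights(cophenetic_distances(bundle$tree))
morans_i_test(scores$cold_hot[match(rownames(W), scores$medicinal_id)], W)
#> Moran's I phylogenetic autocorrelation (analytic)
#>   I = 0.3981, E[I] = -0.003717, n = 270
#>   two-sided P = 0.0001138

correlate_scores_with_potency(scores, profiles, "H3K9", "cold_hot")
#>   attribute score_mode          r            p   n
#> 1      H3K9   cold_hot -0.4114678 5.344054e-08 162

synergy_analysis(bundle$formulas, profiles, bundle$modcat, seed = 42L)
#> Formula synergy (82 real vs 199 control formulas)
#>   me  median |D| real 0.109 vs control 0.190, p = 9.37e-05  [real closer to zero]
#>   all median |D| real 0.028 vs control 0.152, p = 3.36e-09  [real closer to zero]
```

Reading the output: 60% of the synthetic medicinals touch at least one
modification attribute, and most of those condense chromatin. The positive
Moran's I with P ≈ 10⁻⁴ says cold-hot natures cluster on the phylogeny (the
generator planted that signal). The negative H3K9 correlation says colder
medicinals carry more H3K9-methylation pairs — the planted cold →
heterochromatinization effect. In the synergy report, real formulas sit
closer to their members' heterochromatinization than random control
formulas do (smaller |Δ|, rank-test p ≪ 0.05): like-minded medicinals team
up.

The same functions run on real exports: `read_medicinal_catalog()`,
`read_interaction_table()`, `read_modification_catalog()`,
`read_formulas()` and `read_tcm_tree()` document the expected TSV/Newick
dialects, and `run_pipeline()` orchestrates all stages from a YAML/JSON
config (see `inst/scripts/tcmepi.R` for a thin command-line wrapper).

## Vignette

`vignettes/methods.Rmd` describes the scoring model, the Moran's I
implementation, the potency and chromatin-call definitions, the synergy
statistic, what the synthetic generator does and does not emulate, and the
numerical/design choices (tie-breaking, granularities, control matching).
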