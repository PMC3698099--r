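---
title: "Methods: scoring, phylogenetic autocorrelation, potency profiling and formula synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, phylogenetic autocorrelation, potency profiling and formula synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `tcmepi`, the tunable
parameters and their defaults, the design choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. It states no empirical result that the test suite does not itself
compute.

## 1. Quantifying TCM annotations

The seven-grade nature vocabulary maps to integers −3 (cold), −2 (mild
cold), −1 (cool), 0 (neutral), +1 (mild warm), +2 (warm), +3 (hot). Flavor
tokens carry +1 for the yang flavors (sweet, pungent, plain), −1 for the
yin flavors (sour, bitter, salty), and exactly half those values for every
"mild" grade; a medicinal's flavor score is the unrestricted sum over its
tokens (sweet + mild pungent = 1.5). The yin-yang score is nature + flavor.

Two deliberate choices:

* **No clamping.** A three-flavor yang medicinal can exceed a ±4 composite
  range; an observed range in any particular catalog is a property of that
  catalog, not of the scoring rule, so the sum is left unrestricted.
* **NA policy.** A medicinal without a nature annotation has `NA` cold-hot
  and `NA` full yin-yang scores and is excluded listwise from the
  autocorrelation and correlation analyses (it still participates in
  potency profiling). Nothing is imputed from related species.

## 2. Moran's I on a tree

Phylogenetic autocorrelation of a score $y$ uses

$$ I \;=\; \frac{N}{\sum_{ij} w_{ij}}\,
   \frac{\sum_{ij} w_{ij}(y_i-\bar y)(y_j-\bar y)}
        {\sum_i (y_i-\bar y)^2},
   \qquad w_{ij} = 1/d_{ij},\; w_{ii}=0, $$

with $d_{ij}$ the cophenetic distance (sum of branch lengths on the leaf
path, delegated to `ape`). The null expectation is $-1/(N-1)$.

* **Significance.** The default is the analytic normal approximation under
  the randomization assumption, with the classical variance formula
  including the sample-kurtosis term (the same formula the reference
  implementation in `ape::Moran.I` uses; the test suite verifies agreement
  to $10^{-10}$). A permutation test (label shuffles,
  $p = (1+\#\{|I_b - E|\ge|I_{obs}-E|\})/(1+B)$, $B \ge 99$) is provided as
  a cross-check; the suite verifies the two agree on exhaustive
  enumeration at small $n$ within the approximation error of the normal
  tail (tolerance 0.06 at $n=8$, the scale of the normal-approximation
  error there).
* **Weight convention.** $w_{ij}=1/d_{ij}$ is used exactly as written.
  Note that `ape::Moran.I` row-normalizes its weight matrix internally;
  the two conventions give slightly different statistics and both are
  legitimate Moran weightings. Cross-check tests feed the row-normalized
  matrix to this package when comparing against `ape`.
* **Degenerate inputs.** A constant trait (zero variance), fewer than 3
  non-missing leaves, or a zero off-diagonal distance (duplicate taxa —
  the error message points at deduplication rather than silently adding an
  epsilon) are errors.
* **Trees without branch lengths.** Edges missing a length are imputed to
  1, so cophenetic distance equals path edge count on taxonomy-derived
  cladograms. When only lineage strings are available, a cladogram is
  built with one unit edge per rank step and each medicinal as the leaf at
  the end of its lineage; medicinals sharing an identical full lineage
  become siblings one edge below the terminal taxon. Under this
  construction two congeneric species are at distance 2 and two species in
  different families of one order (full rank chain order → family → genus
  → species) at distance 6.

## 3. Potency profiles and chromatin calls

A medicinal's potency for attribute $X$ is the number of (chemical, enzyme)
interaction pairs between its constituent chemicals and the enzyme family
of $X$; pairs, not distinct enzymes, so two chemicals hitting one enzyme
count twice. Interactions with an unspecified direction are tallied as
inhibition (the common case for small-molecule–protein interactions). The
18 attributes partition into 7 euchromatic, 10 heterochromatic and one
ambivalent (ATP-dependent remodeling, which counts toward histone-modifying
status but contributes to neither side of any net tally).

Chromatin calls tally heterochromatic vs euchromatic modifications per
chemistry class (`me` = DNA/histone (de)methylation, `ph` = H3S10
(de)phosphorylation, `ac` = (de)acetylation, `all` = every attribute with a
defined conformation) and label each entity condensing (net > 0), unpacking
(net < 0), poising (net 0 with at least one touched attribute) or
non-modifying. Two axes are configurable:

* **Granularity** — `distinct_modifications` (an attribute counts once when
  touched; the default for the condensing/unpacking/poising labels, which
  speak of the modifications an entity makes) or `interaction_pairs`
  (pair counts; used for potency matrices and the synergy statistic, see
  §5).
* **Direction** — `count` (default; every pair counts toward its
  attribute's conformation, matching the literal potency definition) or
  `direction_aware` (an activating pair counts toward the attribute's
  conformation, an inhibiting pair toward the opposite). The two
  disagree on purpose — inhibiting a heterochromatic mark opens chromatin
  under the direction-aware reading — and both are kept because the
  count-based arithmetic is what the condensing/unpacking proportions
  require while the direction-aware reading is the conventional
  pharmacology. Tests pin the difference on constructed fixtures.

Correlation screens report Pearson r between a score column and each
attribute's potency over the histone-modifying medicinals with non-missing
scores, with the exact t transform on $n-2$ degrees of freedom. The
α = 0.05 flag is per attribute with **no multiple-testing correction** —
this mirrors a screen, not a confirmatory family, and the report says so.

## 4. Hierarchical clustering

Entities × 18 matrices are clustered agglomeratively under Euclidean
distance; linkage defaults to complete (the common default of the R
heatmap tooling this analysis style uses), with average and single
available. No scaling is applied by default; per-row z-scoring sits behind
a flag. Merge-height monotonicity (complete linkage) and equivalence with a
brute-force agglomeration oracle for ≤ 8 items are part of the test suite,
compared via cophenetic matrices, which are invariant to the order of
tied merges. Dendrograms export as Newick with heights embedded as branch
lengths.

## 5. Formula synergy

A formula's attribute array is the elementwise sum of its members'. A
formula is histone-modifying when at least one member is. For each class
the normalized net heterochromatinization is
$f = (n_{het}-n_{eu})/(n_{het}+n_{eu})$ ($f = 0$ for an untouched class),
and the synergy statistic is $\Delta = f(\text{formula}) -
\text{mean}_{\text{modifying members}} f$, compared between real formulas
and random controls by a two-sided rank test on $|\Delta|$, with a
direction flag when the real median $|\Delta|$ is smaller.

* **Why pair-count granularity for $f$.** Under distinct-mark tallies,
  pooling and averaging nearly coincide whenever members touch comparable
  numbers of marks, so $\Delta$ cannot respond to the mixing of
  counteracting medicinals; worse, member-weight dispersion then pushes
  real $|\Delta|$ *above* controls. With pair counts a pooled formula
  tracks its most interaction-rich member, which is precisely the
  dominance contrast the analysis is after ("a potent heterochromatic
  medicinal plus minor euchromatic medicinals" looks very different from a
  coherent formula). The granularity remains configurable.
* **Why the mean over modifying members.** Non-modifying members carry no
  chromatin information; including them would shrink every member average
  toward zero by bookkeeping alone.
* **Controls.** Each control formula draws `size` members (the real
  formulas' median size) uniformly without replacement from the pool of
  medicinals making up the real formulas; a control set is accepted only
  when its median count of histone-modifying members matches the real
  median (tolerance 0.5, because an even real set can have a half-integer
  median no odd control set attains), with bounded redraws. When the real
  formulas are more enriched in modifying members than uniform draws can
  reproduce — exactly the homophilous regime the analysis is designed to
  detect — the rejection scheme cannot terminate; the default then falls
  back to stratified draws whose modifying-member counts are bootstrapped
  from the real formulas, which is the conditioning that "matched on the
  median number of modifying members" implies. Under null conditions the
  plain rejection scheme succeeds on early draws, so the fallback never
  distorts calibration. `n_controls` defaults to 199; the whole control
  set is reproducible from its seed, byte for byte.

## 6. The synthetic-data generator

`generator_config()` fixes the study conditions used across the test
suite. The generator emulates, per seed and fully deterministically:

* a Yule (pure-birth) tree over `n_medicinals` (default 300 — large enough
  for stable correlation screens, small enough that the calibration and
  recovery suites run in minutes on one CPU);
* a latent nature trait evolved by Brownian motion (rate `sigma_bm`,
  default 1.5) plus independent tip noise (`trait_noise_sd`, default 1).
  A pure Brownian trait would make Moran's I scale-invariant in the rate,
  so the noise term is what makes the signal tunable: `sigma_bm = 0` is
  the null, and with noise 0 as well the trait is constant and every leaf
  lands in the root (neutral) bin. Tip values are discretized into the
  seven nature tokens by equal-probability bins; 10% of leaves lose their
  annotation (`na_fraction`), exercising the NA policy;
* flavors (1–3 tokens) whose yang probability follows the nature score
  logistically (`flavor_nature_corr = 0.5`), mirroring the doctrinal
  cold–yin association;
* enzyme families of 2–10 synthetic proteins per attribute, and 2–5
  chemicals per medicinal (chemicals are not shared between medicinals —
  real catalogs share constituents, which the generator does not emulate);
* an interaction table in which every chemical–enzyme pair enters
  independently at `base_interaction_rate` (5 × 10⁻⁴), modulated by
  planted structure: a cold-enriched H3K9 effect
  (`planted_associations`, effect size 3: the H3K9 rate scales as
  $\max(0, 1 - 3\,y/3)$ in the nature score $y$), a preferred chemistry
  group per medicinal (`group_boost = 4`), a heterochromatic or
  euchromatic lean per medicinal (`conformation_coherence = 3` — without
  it medicinals are conformation-incoherent and no formula-level synergy
  signal exists to recover), and a lognormal per-medicinal activity
  multiplier (`activity_dispersion = 1`, emulating the heavily skewed
  interaction coverage of real chemical–protein databases). Actions are
  20% activation / 50% inhibition / 30% unspecified, the unspecified share
  deliberately exercising the unspecified→inhibition rule;
* 100 formulas of 4–12 members with chromatin-class homophily
  (`homophily_strength = 0.8`): each subsequent member is drawn from the
  first member's class with that probability, falling back to a uniform
  draw if the class is exhausted (an error at homophily 1, where no
  fallback exists).

Defaults were fixed once by a design-time power analysis so that each
planted signal is recoverable with ≥ 80% probability at the default sizes,
and the interaction rate keeps a realistic minority-to-moderate share of
medicinals histone-modifying; they are recorded in every bundle's
manifest. The calibration suite uses zero-signal bundles (`sigma_bm = 0`,
no planted associations, homophily 0) at n = 200 medicinals over 200
replicates; the recovery suite runs 100 replicates at the defaults. Both
finish in roughly a minute on one CPU.

What passing these suites shows — and does not show. They show the
implementation is calibrated (nominal false-positive rates on null data)
and powerful against the specific planted alternatives. They do not show
that real materia-medica exports carry those signals: real catalogs have
shared constituents across medicinals, non-uniform taxon sampling,
database-specific interaction ascertainment bias, and annotation
conventions that the generator deliberately does not model.

## 7. Numerical and interface choices

* Deduplication of repeated medicinal entries keeps the first occurrence's
  annotations and unions the chemical sets across occurrences (the union
  maximizes interaction recall; how source databases merged such entries
  is not documented anywhere authoritative, so this is a package choice).
* Chemical identifiers are opaque strings; an optional two-column mapping
  file converts legacy registry numbers at load time, replacing any live
  conversion service.
* Strict parsing is the default (unknown vocabulary tokens are errors);
  lenient mode drops the offending token with a warning for messy exports.
* All randomness flows from explicit integer seeds; the pipeline splits
  its master seed per stage, and rerunning any configuration reproduces
  every stage output byte for byte (report file pointers are stored as
  basenames for that reason).
* Ties at equal merge distances in clustering follow the underlying
  agglomeration's deterministic order; tests compare trees via cophenetic
  matrices, which do not depend on tie order.

## 8. Known limitations

* Binding affinity, dose, pharmacokinetics and tissue exposure are out of
  scope; the analysis is presence/count-based by construction.
* The per-attribute α = 0.05 screen is intentionally uncorrected; with 18
  attributes roughly one false flag per screen is expected under the null.
* The analytic Moran p-value is a large-sample approximation; at very
  small n (< 10) prefer the permutation method.
* Inverse-distance weights make the statistic sensitive to very short
  cophenetic distances (near-duplicate taxa); deduplicate before testing.
* The chemistry-group clade structure in attribute clustering is only
  recoverable when group-correlated usage dominates the profile
  covariance; when a conformation lean dominates instead, the column
  dendrogram instead tends to group attributes by conformation — a
  different, equally interpretable structure. The clustering test pins the
  group regime on a bundle generated with group usage dominant.
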