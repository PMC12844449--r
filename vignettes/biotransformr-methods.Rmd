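---
title: "Methods: phase I metabolite identification and temporal profiling"
author: "biotransformr developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase I metabolite identification and temporal profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biotransformr)
```

## Scope and model

`biotransformr` implements a desk-scale version of the workflow used to
characterize phase I metabolites of fluoropentyl ADB-type synthetic
cannabinoids (an indazole-3-carboxamide parent such as 5F-ADB-PINACA and an
indole-3-carboxamide parent such as 5F-ADBICA) in liver-microsome
incubations, and to profile metabolite abundances over a 1–24 h time
course. The pipeline has four stages:

1. **Formula algebra.** Neutral elemental compositions with exact
   monoisotopic masses. Protonated-molecule m/z is neutral mass + proton
   mass (1.00727646688 Da); acylium-type fragment m/z is the cation
   composition's mass − electron mass (0.00054857990 Da). These two
   conventions — rather than "neutral + H atom" — reproduce published
   4-decimal ion tables exactly, which we verified against the packaged
   reference inventories (51/51 values to ≤ 0.0005 Da). Atomic masses are
   pinned to the CODATA 2018 / IUPAC 2021 monoisotopic table, shipped with
   a version string (`attr(atomic_masses(), "version")`).

2. **Biotransformation enumeration.** Phase I reactions are signed
   element-count deltas with site constraints (core, side chain, ADB
   residue): hydroxylation (+O, up to ×2 — dihydroxylation is two
   applications), dehydrogenation (−2H), amide hydrolysis and deamination
   (both −H −N +O, formula-degenerate by design), hydrolytic
   defluorination (−F +H +O), oxidative defluorination to aldehyde
   (−F −H +O), defluorination to carboxylic acid (−F −H +2O), oxidation to
   aldehyde (−2H +O) and N-dealkylation (−C5H9F). Candidates are rule
   *multisets* up to depth 3 (the deepest combination observed in the
   reference data); reaction order is not modeled because no intra-
   metabolite kinetic ordering is observable at MS1. The four F-consuming
   reactions and N-dealkylation are mutually exclusive (single fluorine),
   and side-chain reactions are blocked after dealkylation.

3. **Annotation.** MS1 peaks match candidate composition groups within a
   signed ppm tolerance (default ±5 ppm, the conventional identification
   tolerance for Orbitrap-class instruments). Site localization enumerates
   every legal assignment of rule instances to moieties, predicts each
   scaffold diagnostic fragment as base m/z plus the delta masses of the
   rules assigned to moieties the fragment retains, and scores hypotheses
   by the count of observed MS2 ions within the fragment tolerance
   (default 10 ppm — the identification tolerance binds precursors only,
   so the fragment value is a package default). The argmax wins; ties are
   reported, never broken silently. Modifications that can only sit on
   the ADB residue are localized there by elimination: no shipped fragment
   retains the residue alone, so an unshifted core and chain plus a
   shifted precursor is itself the evidence.

4. **Temporal profiling.** Replicates are mean-aggregated, the matrix is
   normalized ("normalized to the most abundant" is read as global-max
   scaling; per-metabolite scaling is available since the phrasing is
   ambiguous), trends are classified, metabolites are clustered as
   connected components of the |ρ| > 0.8 Pearson graph, and biomarkers
   are nominated by a composite of abundance, persistence and cluster
   centrality.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| MS1 tolerance | 5 | ppm | conventional accurate-mass identification window |
| MS2 tolerance | 10 | ppm | fragment tolerance unstated in source workflows; looser than MS1 because product-ion statistics are poorer |
| depth limit | 3 | reactions | deepest observed combination; configurable |
| hydroxylation cap | 2 | applications | dihydroxylation observed, trihydroxylation not |
| correlation threshold | 0.8 | \|ρ\| | the stated clustering cut |
| fold (rising) | ≥ 2 | final/first | trend classes are described only verbally in the source; these cut points are package defaults exposed in `default_trend_thresholds()` and in the run config |
| persistence (rising / decaying) | ≥ 0.8 / ≤ 0.5 | final/max | idem |
| early peak | ≤ 4 | h | "peaks at 2 h then declines" generalized to the first third of the grid |
| CV (stable) | ≤ 0.3 | – | idem |
| noise sigma | 0.2 | log scale | typical day-to-day multiplicative spread for triplicate incubations |
| m/z jitter | 1 | ppm | well inside a 5 ppm window, matching high-resolution instrument behavior |

Trend classification applies its rules in a fixed order (rising →
early-peak-decaying → stable → fluctuating), so every metabolite gets
exactly one class; fewer than 4 usable points yields the sentinel
`undetermined` rather than an error.

Category precedence (dominant_stable > rapidly_decaying > core_cluster >
fluctuating_independent) resolves overlaps deterministically. The
four-way categorization formalizes what the source work describes
narratively; the defaults here are the package's own operationalization,
not a published algorithm.

## The biomarker score

For each metabolite, with min–max scaled components across the dataset:

score = 0.5 · AUC + 0.3 · persistence + 0.2 · centrality

AUC is the trapezoid integral of the (normalized) time course over the
sampled grid, persistence is final/max, and centrality is the mean |ρ| to
the metabolite's own correlation component (0 for singletons). The
weights encode the qualitative argument used to pick defluorination
products as biomarkers: sustained abundance first, late-window
detectability second, representativeness of the metabolic network third.
Ties break by raw AUC and then id, making the ranking order-invariant.

## The synthetic-data generator

No raw instrument data is published for this class of study, so the
package ships a ground-truthed generator instead. `simulate_kinetics()`
solves linear first-order networks; simple chains use the closed-form
Bateman cascade and everything else classical RK4 with step ≤ 0.01 h (the
two agree to ~1e-9 on chains, which the tests assert; the automatic mode
falls back to RK4 when chain rates are not pairwise distinct, where the
closed form is singular). Sampling applies mean-one log-normal noise
(`exp(N(-σ²/2, σ²))`) so that replicate means are unbiased estimators of
the true trajectory — a deliberate choice; with mean-zero log noise the
3-replicate mean would carry a systematic +σ²/2 bias.

`default_paper_like_study()` encodes the qualitative kinetics reported
for these compounds: fast first-order parent depletion, a persistent
hydrolytic-defluorination sink (largest AUC; the planted analog of the
headline biomarkers), an early-peaking monohydroxy intermediate that is
consumed further, and a depth-3 terminal product that keeps rising. The
indole parent uses slower depletion rates than the indazole parent,
mirroring the reported difference in metabolic stability.
`planted_family_study()` plants two kinetically distinct families (fast
transients peaking ~2 h vs delayed products peaking ~8 h) whose
cross-family correlations stay below the 0.8 threshold (|ρ| ≤ ~0.55
noiselessly) while within-family correlations are ≈ 1.

What a green synthetic test establishes — and what it does not: the
generator produces isolated, correctly centered peaks with Gaussian mass
error and log-normal intensity error. It does not emulate co-elution,
chromatographic peak shape, isotope interference, matrix effects,
saturation (Michaelis–Menten) kinetics, or missing peaks, so perfect
recall on synthetic data bounds algorithmic correctness, not instrument
performance.

## Numerical and design choices

* Masses are kept at full double precision; 4-decimal rounding
  (half-even, R's `round()`) happens only at presentation.
* The packaged reference tables store *structure-consistent* neutral
  formulas (parent formula plus reaction deltas). A handful of printed
  formulas in the source inventories are internally inconsistent with
  their own printed m/z by one hydrogen (including one parent row); in
  every such case the printed m/z corresponds to the structure-consistent
  formula, which is the one shipped. All 51 printed protonated masses are
  reproduced to ≤ 0.0005 Da from these formulas.
* One reference row lists two hydroxylations plus deamination while its
  formula supports deamination plus a single hydroxylation; the fixture
  records the formula-consistent multiset.
* Formula-degenerate reaction multisets (amide hydrolysis vs deamination;
  F→COOH vs F→CHO + OH) are retained as separate provenances of one
  composition group. When their predicted fragments coincide the
  localization reports a tie with the ambiguity flag set — this mirrors a
  genuine limit of MS1+MS2 evidence, and downstream consumers must
  respect the flag.
* Correlation uses replicate-mean raw series (not z-scored), matching the
  stated procedure; with only 6 time points ρ is a noisy estimate, so the
  matrix carries `n_timepoints` and rows with more than 2 missing points
  are excluded with a warning.
* Clustering is connected components on the thresholded graph — the
  simplest reading of "metabolites with |ρ| > 0.8 were classified into
  strongly correlated clusters". Raising the threshold can only refine
  the partition (tested property). Hierarchical alternatives would change
  membership at the margins; they are intentionally out of scope for the
  core contract.
* All randomness flows from a single seed through R's default generator;
  study CSV emitters format numerics with fixed precision so identical
  seeds give byte-identical files.

## Known limitations

* Site localization is moiety-granular; positional isomers within a
  moiety (five side-chain monohydroxy isomers sharing one formula) are
  indistinguishable by design and are reported as one composition group
  with isomer multiplicity carried by distinct peak ids.
* Retention-time modeling, isotope-pattern scoring and vendor raw-file
  parsing are out of scope; inputs are plain CSV peak lists.
* Phase II conjugation is not modeled.
* The trend-class thresholds and the biomarker weights are reasoned
  defaults, not fitted quantities; conclusions that hinge on them should
  be checked under perturbed settings via the run config.
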