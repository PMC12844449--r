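# biotransformr

Phase I biotransformation enumeration, accurate-mass metabolite
annotation, and temporal metabolic profiling for synthetic-cannabinoid
drug-metabolism studies.

## The problem

Synthetic cannabinoids are cleared so quickly that the parent drug is
often undetectable in biological samples; forensic confirmation rests on
*metabolite biomarkers*. Given a parent compound's neutral formula and
scaffold (here the fluoropentyl ADB-type compounds 5F-ADB-PINACA,
indazole core, C19H27FN4O2, and 5F-ADBICA, indole core, C20H28FN3O2),
the package answers three questions a toxicology lab asks of
liver-microsome incubation data:

1. **Which peaks are metabolites?** Phase I reactions are modeled as
   element-count deltas (hydroxylation +O, dehydrogenation −2H, amide
   hydrolysis/deamination −H−N+O, hydrolytic defluorination −F+H+O,
   oxidative defluorination to aldehyde −F−H+O, defluorination to
   carboxylic acid −F−H+2O, oxidation to aldehyde −2H+O, N-dealkylation
   −C5H9F). Candidate metabolites are rule multisets to depth ≤ 3;
   observed MS1 peaks match candidates when
   |1e6·(m_obs − m_theo)/m_theo| ≤ 5 ppm, with
   m_theo([M+H]+) = monoisotopic mass + 1.00727646688 Da.

2. **Where on the molecule did the reaction happen?** Scaffold
   diagnostic fragments (e.g. the indazole-3-carbonyl acylium C8H5N2O+
   at m/z 145.0396, or the indole analog C9H6NO+ at 144.0444) each
   retain a known moiety subset {core, side chain, ADB residue}. A
   modification assigned to a retained moiety shifts the fragment by the
   reaction's delta mass; scoring all legal assignments against the
   observed MS2 ions localizes the modification, with ties reported
   honestly as ambiguous.

3. **Which metabolite is the best biomarker?** Time courses
   (1, 2, 4, 8, 12, 24 h, 3 replicates) are mean-aggregated, normalized,
   classified into trends, clustered as connected components of the
   Pearson |ρ| > 0.8 graph, and ranked by
   score = 0.5·AUC + 0.3·persistence + 0.2·cluster centrality.

A ground-truthed first-order kinetic simulator (closed-form Bateman
cascades + RK4 for general DAGs, log-normal replicate noise, ppm-scale
mass jitter) makes the whole pipeline testable without instrument data.
See `vignettes/biotransformr-methods.Rmd` for the model details and
design rationale.

## Worked example

Annotate the packaged reference peak list (the transcribed metabolite
inventory of 5F-ADB-PINACA) against enumerated candidates:

```r
library(biotransformr)
p  <- parent_compound("5F-ADB-PINACA")
rs <- default_ruleset(p$scaffold)
res <- annotate_dataset(reference_peaklist("5F-ADB-PINACA", include_parent = FALSE),
                        reference_ms2("5F-ADB-PINACA"), p, rs)
res
#> <annotation_result> 21/21 peaks matched; 8 ambiguous localization(s)
annotation_table(res)[c(12, 13, 19), ]
#>    peak_id     formula theoretical_mz observed_mz         ppm          reactions ambiguous n_supporting_ions
#> 12     M12 C19H27FN4O3       379.2140    379.2140  0.01204921      oh@side_chain     FALSE                 5
#> 13     M13  C19H28N4O3       361.2234    361.2234 -0.04773456 f_to_oh@side_chain     FALSE                 5
#> 19     M19 C19H27FN4O3       379.2140    379.2140  0.01204921            oh@core     FALSE                 4
```

All 21 inventory peaks receive a candidate within 5 ppm. M13 — the
hydrolytic-defluorination product and headline biomarker — localizes to
the side chain with the core acylium unshifted at 145.0396; M19's shifted
core ion (161.0346) places its hydroxyl on the indazole core instead. The
8 ambiguous records are formula-degenerate reaction multisets (e.g. amide
hydrolysis vs deamination), which MS1+MS2 evidence genuinely cannot
separate.

End-to-end on a seeded synthetic study:

```r
fr <- run_fullrun(default_config(seed = 1))
fr$recall                      # 1  (every planted metabolite re-identified at 5 ppm)
fr$profile$nomination$ranking[, c("metabolite_id", "category", "score")]
#>           metabolite_id         category     score
#> 1            m_defluoro  dominant_stable 0.9226503
#> 2 m_defluoro_oh_dehydro     core_cluster 0.7045030
#> 3                parent rapidly_decaying 0.2104779
#> 4                  m_oh rapidly_decaying 0.2000221
#> 5         m_defluoro_oh rapidly_decaying 0.1154495
```

The planted defluorination sink is nominated top biomarker; the
early-peaking monohydroxy intermediate is classified rapidly decaying —
the same qualitative verdicts the method reaches on real incubations.

There is also a CLI (`inst/cli/biotransformr`) with subcommands
`simulate | annotate | profile | fullrun`, driven by a JSON config whose
hash is echoed into every report.

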