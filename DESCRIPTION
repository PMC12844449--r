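Package: biotransformr
Title: Phase I Biotransformation Enumeration, Accurate-Mass Metabolite
    Annotation and Temporal Metabolic Profiling
Version: 0.1.0
Authors@R:
    person("biotransformr", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for in vitro drug-metabolism studies of synthetic
    cannabinoids and related small molecules. Provides elemental-formula
    algebra with exact monoisotopic masses, enumeration of phase I
    biotransformation products (hydroxylation, dehydrogenation, amide
    hydrolysis, deamination, defluorination routes, N-dealkylation) to a
    bounded reaction depth, ppm-tolerance matching of MS1 peak lists to
    candidate metabolites, diagnostic-fragment based localization of
    modifications to structural moieties from MS2 spectra, temporal
    profiling of metabolite time courses (trend classification, Pearson
    correlation clustering, biomarker nomination), and a ground-truthed
    first-order kinetic simulator for end-to-end validation without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
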