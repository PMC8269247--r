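Package: dielMetab
Title: Diel Particulate Metabolite Quantification, Rhythm Detection, and
    Flux Budgeting
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for targeted particulate-metabolite time
    series sampled over day-night (diel) cycles in marine surface waters.
    Converts raw LC-MS peak areas to molar concentrations via best-matched
    internal standard (BMIS) normalization, isotopologue ratios, standard
    additions and matrix-matched external calibration; detects 24-h
    periodicity per compound with a nonparametric umbrella rank test and
    Benjamini-Hochberg FDR control; estimates peak clock hour and amplitude
    by cosinor regression and mean daily fold change from triplicate
    medians; converts oscillations into carbon and nitrogen composition
    fractions and net turnover fluxes; attributes metabolite pools to taxa
    via cell quotas, including a diazotroph trehalose-to-nitrogen-fixation
    energy budget; links metabolites to taxon-by-KEGG-ortholog transcript
    series with circular phase-lag analysis; and tests time-of-day
    structure in the community metabolome with ANOSIM. A seeded synthetic
    study generator reproduces the statistical structure of the field
    design (triplicates every 4 h over two multi-day periods) so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
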