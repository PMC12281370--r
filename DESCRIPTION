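Package: immunotriad
Title: Immune-Correlate Analysis for Therapeutic Cancer Vaccine Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Response calling and immune-correlate statistics for vaccine
    immunomonitoring: ex vivo IFN-gamma ELISpot specific-spot computation and
    positivity calling, intracellular cytokine staining (ICS) Boolean-combination
    analysis with single/double/triple polyfunctional Th1 immunotyping,
    anti-peptide IgG titer extrapolation from ELISA standard curves,
    epitope-spreading classification across non-vaccine antigen panels,
    patient harmonic-mean best-rank (PHBR) HLA-DR presentation scores,
    TCR-beta clonotype repertoire statistics (richness, Shannon entropy,
    clonality, D50, clone-size bins, overlap, clonotype tracking), and
    integration into an immune-triad classifier with Kaplan-Meier / log-rank
    survival association. Includes a seeded synthetic-cohort generator that
    emulates the assay battery of a ~60-patient two-peptide telomerase
    (UCP2/UCP4) vaccine study so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
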