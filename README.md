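# immunotriad

Immune-correlate analysis for helper-peptide cancer-vaccine
immunomonitoring, built around the *immune triad*: the conjunction, in one
patient, of a polyfunctional triple-positive (IFN-γ⁺TNF-α⁺IL-2⁺) Th1
response, an anti-peptide IgG response, and epitope spreading.

The package is for immunologists and biostatisticians analysing
vaccine-trial assay tables. It implements:

- **ELISpot calling** — specific spots = mean(stimulated) − mean(background),
  floored at 0; positive iff stimulated mean ≥ 2× background mean **and**
  specific spots > 10; responder/durability/intensity summaries
  (low/high split at the per-peptide responder median).
- **ICS polyfunctionality** — the 7 Boolean IFN-γ/TNF-α/IL-2 combinations,
  background-subtracted; positive iff post ≥ 2× baseline and > 0.05% of
  CD4⁺ T cells; immunotype hierarchy
  `polyF_triple > polyF_double > singleF > none`.
- **Antibody titers** — degree-2 polynomial standard-curve calibration
  (OD → ng/mL, range-restricted), 2-fold positivity over ovalbumin
  background, baseline-positive rise rule, high titer > 1000 ng/mL.
- **Epitope spreading** — de novo vs pre-existing antigen reactivity after
  in vitro stimulation; breadth; intermolecular (class II tumor antigens)
  vs intramolecular (class I hTERT) tags.
- **PHBR** — patient harmonic-mean best rank over the two HLA-DRB1
  alleles, `PHBR = 2/(1/BR₁ + 1/BR₂)` (lower = better presentation).
- **TCR-β repertoire statistics** — richness, Shannon entropy
  (−Σ Fᵢ log₂ Fᵢ), clonality (1 − Pielou evenness), D50, clone-size
  homeostasis bins, sample overlap, top-clonotype tracking; AIRR-style TSV
  and CSV clonotype tables.
- **Outcome integration** — the triad classifier, Kaplan–Meier estimation
  with log-rank comparison (via the `survival` package), PCA + k-means
  immune grouping, Mann–Whitney/Fisher/chi-square group comparisons.
- **A seeded synthetic-cohort generator** (`synth_config()` /
  `generate_cohort()`) emulating a 60-patient two-peptide (UCP2/UCP4)
  trial: Poisson spot counts, Dirichlet cytokine-combination splits,
  log-normal titers, power-law repertoires, exponential survival with
  triad-dependent hazards.

## Worked example

```r
library(immunotriad)

co <- generate_cohort(synth_config(seed = 1))
ta <- triad_analysis(co)
summary(ta)
```

```
Immune-correlate analysis
  60 patients; immune triad in 8/60 evaluable
  UCP2       response rate: 68% (41/60)
  UCP4       response rate: 77% (46/60)
  pooled     response rate: 93% (56/60)
  antibody   response rate: 50% (30/60)
  spreading  response rate: 48% (29/60)
  OS triad vs rest: log-rank chi-sq 0.00, p = 0.953 (exploratory)
  immunotypes: none=4, singleF=5, polyF_double=15, polyF_triple=36
  median OS (no_triad): 8.99 months; 12-month rate 0.381
  median OS (triad): 10.78 months; 12-month rate 0.438
  Th1 response by Ab status (Fisher exact): p = 0.612; proportions 0.967 vs 0.900
```

Reading this: each rate line is positives/evaluable from the corresponding
caller (UCP2 lands on its configured 68%; UCP4 drew high at this seed —
single-cohort rates carry binomial noise of several points). Eight
patients satisfy all three triad components. The per-group Kaplan–Meier
medians are reported with the 12-month survival rate; with only 8 triad
patients the log-rank comparison is underpowered and exploratory, even
though the generating hazards differ twofold — exactly the uncertainty a
real 60-patient cohort would face. `plot(ta)` draws the two survival
curves; individual callers (`call_elispot()`, `call_ics()`, `call_ab()`,
`call_spreading()`, `cohort_phbr()`, `repertoire_metrics()`) can be used
on your own delimited-text tables in the schemas documented on each
function.

A thin command-line wrapper with `simulate`, `call-*`, `phbr`,
`repertoire` and `triad` subcommands is installed at
`system.file("cli/immunotriad.R", package = "immunotriad")`.

## Vignette

`vignettes/immune-correlates.Rmd` documents the calling rules and their
parameters, the design decisions taken where the rules are underspecified,
what the synthetic cohort does and does not emulate, and the problem sizes
used in validation.
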