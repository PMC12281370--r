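---
title: "Immune-correlate analysis for helper-peptide cancer vaccines: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-correlate analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunotriad)
```

# The problem

Therapeutic cancer vaccines built on pan-HLA-DR-binding helper peptides —
here the telomerase (hTERT)-derived UCP2 and UCP4 peptides given as weekly
priming followed by repeated boosts — are monitored with a battery of
blood-based assays: ex vivo IFN-γ ELISpot for vaccine-specific CD4+ T
cells, intracellular cytokine staining (ICS) for the quality
(polyfunctionality) of the Th1 response, ELISA for the anti-peptide IgG
response, a post-IVS ELISpot panel of non-vaccine tumor antigens for
epitope spreading, HLA-DRB1 genotyping for peptide-presentation capacity,
and TCR-β sequencing of vaccine-specific cells. The scientific question is
which combination of these readouts marks patients whose immune response
translates into tumor control, and the headline construct is the *immune
triad*: a polyfunctional triple-positive (IFN-γ+TNF-α+IL-2+) Th1 response
**and** an anti-peptide IgG response **and** epitope spreading in the same
patient.

`immunotriad` implements each assay's response-calling rule, the
repertoire and presentation-score analytics, and the integration into the
triad classifier with Kaplan–Meier/log-rank survival association. A seeded
synthetic-cohort generator produces the whole assay bundle with the
statistical structure the callers assume, so the pipeline is testable end
to end without any patient-level data.

# Calling rules and their parameters

## ELISpot

Specific spots are `mean(stimulated wells) − mean(background wells)`,
floored at zero (negative specific counts are non-physical), reported on
the acquisition cell basis (3×10^5 PBMC/well ex vivo, 1×10^5 after IVS). A
response is positive when the stimulated mean is at least **2×** the
background mean *and* the specific count is **strictly greater than 10**.
Two clauses, read literally: the fold criterion applies to the stimulated
mean, the count criterion to the specific count. When the background mean
is exactly 0 the fold clause is satisfied by any non-zero signal
(avoiding a division by zero while preserving the intent of the rule).

Derived per-patient summaries: a *responder* is positive at ≥1
post-vaccination timepoint; *pooled immunogenicity* is a response to ≥1 of
the two peptides; *durability* is ≥1 positive boost-phase timepoint (the
most permissive reading of "still detected", recorded as a deliberate
choice); *intensity* splits responders at the per-peptide cohort median of
peak specific spots (84 spots for UCP2, 63 for UCP4 in the reference
cohort), ties going to "high" for determinism.

## ICS polyfunctionality

The 7 non-null Boolean combinations of IFN-γ/TNF-α/IL-2 partition the
cytokine-positive CD4+ compartment, so their frequencies add up to the
total — the generator enforces this by construction and
`combo_composition()` checks it. Each combination is background-subtracted
(stimulated − unstimulated, floored at 0) and called positive when the
post-vaccination frequency is ≥2× baseline *and* >0.05% of CD4+ T cells; a
baseline of exactly zero passes the fold clause. The patient immunotype is
the highest-order positive combination across post timepoints
(`polyF_triple` > `polyF_double` > `singleF` > `none`); the hierarchy is a
design choice — the classes are mutually exclusive in the source material
but no precedence is stated, and triple+ is the headline subset.

Absolute counts are `freq/100 × CD4 count per mm³`. Note a unit oddity in
the source material: triple+ cells "exceeding 0.2% of circulating CD4+ T
cells" is glossed there as "100 cells/mm³", yet 0.2% of a typical ~719
CD4/mm³ is ~1.4 cells/mm³. The package computes frequency × CD4 count and
does not attempt to guess the intended denominator.

## Antibody response

Titers are extrapolated from a degree-2 least-squares polynomial mapping
OD to concentration fitted on the IgG standard series (0.31–20 ng/mL);
degree 2 is the lowest capturing ELISA curvature on 7 points and is
configurable. Prediction is restricted to the calibration OD range —
out-of-range ODs are flagged, never extrapolated. Plasma dilutions (1/125,
1/1000) multiply back into ng/mL; the least-diluted in-range well wins.
Positivity is OD(UCP-coated) ≥ 2× OD(ovalbumin); a patient already
positive at baseline must additionally show a ≥2-fold rise of titer *or*
OD. High titer is strict: >1000 ng/mL, and only among positives.

`ab_response_rate()` reports the computed fraction. On the reference
counts 31/50 this is 62%, whereas the source text prints "59% (31/50)";
the package reports the arithmetic and documents the mismatch rather than
reproducing the printed figure by construction.

## Epitope spreading

Per antigen: *de novo* = negative pre, positive post; any baseline-positive
response is *pre-existing* and excluded from spreading even if it expands.
Patient-level spreading is ≥1 de novo antigen; breadth counts them; de
novo reactivity against class II tumor-antigen epitopes is intermolecular,
against class I hTERT epitopes intramolecular. Antigens are treated
independently (a pre-existing response to one does not block a de novo
call on another), and a missing baseline makes that antigen ineligible for
de novo (conservative). Both choices are configurable at the data level.

## PHBR

The patient harmonic-mean best rank over the two HLA-DRB1 alleles,
`PHBR = 2 / (1/BR₁ + 1/BR₂)`, lower = better presentation. The external
binding predictor is deliberately *not* invoked — best ranks arrive as a
table, keeping the package self-contained and predictor-version-agnostic;
any positive lower-is-better scale works. Useful identities exercised in
the tests: symmetry, homozygote identity, scale equivariance, and
`min ≤ PHBR ≤ min(2·min, max)` — the score is dominated by the
best-presenting allele.

## TCR-β repertoire

Clonotype identity is the (CDR3 amino-acid, V gene) pair; duplicate rows
merge with counts summed, frequencies sum to 1 (tolerance 1e-9). Metrics:
richness (unique clonotypes); Shannon entropy −Σ Fᵢ log₂ Fᵢ (bits, with
0·log 0 = 0); clonality 1 − H/log n (base-invariant; defined as 1 at
n = 1, a monoclonal repertoire being maximally clonal); D50 (minimal
number of top clones reaching 50% cumulative frequency, stable ties);
clone-size bins small (0,1e-4], medium (1e-4,1e-3], large (1e-3,1e-2],
hyperexpanded (1e-2,1] — the conventional homeostasis edges collapsed to
four categories, configurable; shared-clonotype overlap with Jaccard as
auxiliary; and top-k clonotype tracking across ordered samples (absent
clones read 0).

## Survival and group statistics

Kaplan–Meier estimation and the two-group log-rank test are delegated to
the `survival` package behind the module interface; the median is
extracted from the step function by the explicit convention *smallest
observed time with S(t) ≤ 0.5* (undefined when the curve never reaches
0.5), so the contract is pinned independently of `survfit`'s printed
summary. Zero events in both groups combined return a log-rank statistic
of 0. Continuous two-group comparisons use Wilcoxon–Mann–Whitney;
2×2 proportions use Fisher's exact test when any observed or expected
cell is below 5, chi-square otherwise. Following the exploratory stance of
the source analysis, no multiplicity correction is applied and all
p-values are labelled exploratory.

The immune grouping z-scores the per-patient feature table (peak specific
spots, triple+ frequency, titer, spreading breadth — continuous encodings
where available, per the stated default for the ambiguous feature set),
projects by PCA and clusters by k-means with a fixed seed; k defaults
to 4 (a small number of groups, with z-scoring preventing the titer scale
from dominating). Constant columns are dropped with a warning; rows with
missing assays are excluded (complete-case), mirroring the per-figure
varying denominators of real cohorts. The same complete-case rule applies
to the triad: a patient missing any of the three component calls is
undetermined, not negative.

# The synthetic cohort

`synth_config()` fixes the study conditions; they are chosen once and are
not tuning knobs:

* 60 patients, peptides UCP2/UCP4, timepoints baseline, priming, and three
  boosts; per-peptide responder rates 0.68/0.57 (the printed per-peptide
  response frequencies). Per-peptide responses are drawn independently, so
  the pooled rate exceeds either (real responses are correlated; the
  pooled rate is not a calibration target).
* Spot counts are Poisson per replicate well (3 wells/arm): background
  mean 5 spots/well; responders add 84 (UCP2) or 63 (UCP4) spots, matching
  the printed responder medians — only cohort medians, not variances, are
  available to constrain these.
* ICS: responders draw a total cytokine-positive frequency
  ~ lognormal(log 0.35, 0.35) (percent of CD4) split over the 7 combos by
  a Dirichlet with concentration (1,1,1,1,1,2,2) — the TNF-α+IL-2 double
  and the triple weighted up, as doubles are predominantly TNF-α+IL-2 in
  the source data. The generated table realizes these latent frequencies
  without replicate-level measurement noise, so the decomposition identity
  holds by construction and the realized immunotype is the one the latent
  draw implies.
* Antibody: rate 0.62 (= 31/50); positive titers
  ~ lognormal(meanlog 7.3, sdlog 1.5) ng/mL truncated to [50, 20000],
  putting ~60% of positives above 1000 ng/mL (the printed 19/31). ODs are
  generated through a mildly saturating standard curve at both plasma
  dilutions; very low titers can fall below the 2-fold OD criterion, a
  realistic measurement limit.
* Spreading: probability 0.45 *given* a vaccine response (≈15 spreaders
  per ~41 responders), zero otherwise — making the observed exclusivity of
  spreading among responders structural; breadth 1–3 antigens; a 5%
  per-antigen chance of a pre-existing response that must be excluded.
* Repertoires: 300 clonotypes per sample, ranked frequencies ∝ rank^(−1)
  (Zipf), 20,000 multinomial reads — qualitatively reproducing a
  hyperexpanded head and long tail.
* Survival: exponential in months with hazards log(2)/15 for triad
  patients and log(2)/8.3 otherwise (the printed group medians);
  independent uniform early censoring with probability 0.15 and
  administrative censoring at 36 months (`follow_up_months = Inf` disables
  the latter for parameter-recovery studies).

One master seed fans out through fixed per-table substreams, so identical
configurations are byte-identical and generating a subset of tables does
not perturb the rest.

What the generator does **not** emulate: correlated per-peptide responses,
assay dropout/missingness, batch effects, replicate-level ICS noise, raw
reads or FCS events, and any tumor-response (RECIST) structure. Passing
tests therefore demonstrate the correctness and calibration of the calling
rules and statistics under the stated model — not robustness to the messiness
of real trial data.

# Numerical choices and degenerate inputs

Threshold clauses are read literally: "twice" as ≥2×, ">10" and ">0.05%"
strict, ">1000 ng/mL" strict. Zero backgrounds/baselines satisfy fold
clauses as described above. Median ties classify "high"; D50 ties resolve
by stable input order; a monoclonal repertoire has clonality 1; KM medians
are undefined (NA) when S never reaches 0.5; empty replicate lists, empty
repertoires, negative counts/ODs/times and invalid generator
configurations are rejected with messages naming the offending field.

# Problem sizes used in validation

The validation suite exercises: exhaustive 51×51 integer grids for the
ELISpot rule and ~10^4-point fine grids for the ICS rule; 1,000 random
repertoires against independent brute-force entropy/D50 oracles; KM
median recovery on n = 1,000 exponential samples (15% tolerance at the
analytic median ln 2/λ); log-rank type-I error over 1,000 null replicates
at 200 patients/arm (expected rejection 0.05 ± 0.02); and the full
simulate → call → join → triad → survival pipeline on a 60-patient seeded
cohort, checked for determinism and for agreement of the triad count with
the brute-force conjunction. A separate 2,000-patient single-arm
exponential cohort at hazard log(2)/15 with censoring disabled is used to
recompute the triple+ group's median overall survival (`scripts/acceptance.R`).

# Known limitations

* The ELISA inverse-calibration fits concentration as a polynomial in OD;
  when the truth is polynomial in the other direction the inverse is
  approximated, contributing a small titer error near the range edges.
* Cohort-scale survival contrasts at n = 60 with ~10 triad patients are
  dominated by sampling noise; the log-rank association in a single
  synthetic cohort of that size is frequently non-significant even though
  the generating hazards differ twofold. This mirrors the width of the
  confidence statements possible at trial scale.
* No Cox modelling, no multiplicity correction, no RECIST endpoints —
  deliberately out of scope.
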