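---
title: "Cumulative mixture-risk screening: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative mixture-risk screening: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixriskscreen)
```

## The problem

Drinking-water surveys — bottled water in particular — routinely detect
many inorganic and organic contaminants simultaneously at individually
low concentrations. Single-contaminant comparisons against regulatory
limits miss the question that matters for public health: what is the
*cumulative* burden of the detected mixture? This package implements a
screening-level answer built from two complementary lines of evidence,
both under the non-interactive concentration-addition model (component
risk ratios add; no synergy or antagonism):

* **Hazard index / cumulative toxicity quotient.** For each detection,
  the toxicity quotient is the concentration divided by the most
  protective human-health benchmark,
  $TQ_i = C_i / B_i$, and the sample-level hazard index is
  $\Sigma_{TQ} = \sum_i TQ_i$ over detections. Screening thresholds are
  $TQ = 0.1$ for a single contaminant of potential concern and
  $\Sigma_{TQ} = 1$ for the mixture.
* **Cumulative exposure-activity ratio.** For organic contaminants with
  high-throughput in vitro bioactivity data, the exposure-activity ratio
  is the concentration divided by the activity concentration at cutoff
  (ACC) of an assay endpoint, $EAR_{ij} = C_i / ACC_{ij}$, aggregated
  per sample to $\Sigma_{EAR}$. The precautionary screening level is
  $\Sigma_{EAR} = 0.001$; $\Sigma_{EAR} = 1$ marks the level expected to
  modulate molecular targets in vitro.

The two screens are linked by an approximate contaminant-specific
equivalency: when a chemical's ACC sits two orders of magnitude above
its margin-of-safety health benchmark ($ACC = 100 B$), $TQ = 0.1$ and
$EAR = 0.001$ coincide exactly — the package's equivalence fixture tests
this identity. (Note the orientation: bioactivity cutoffs lie *above*
health benchmarks, which embed a margin of exposure; the equivalence
fails in the stated direction if the ratio is inverted.)

## Detection and censoring QA

Every result is classified against its long-term method detection limit
(MDL) and limit of quantitation (LOQ): `quantitative` at or above the
LOQ, `semiquantitative` in `[MDL, LOQ)`, `nondetect` below the MDL or
absent. Both detection classes count as detections everywhere
downstream. Two boundary conventions were genuinely open and are fixed
as follows:

* a concentration exactly at the MDL is a (semiquantitative) detection
  — the closed lower bound is the precautionary reading;
* nondetects carry **no** imputed value (no ½-MDL substitution),
  because every downstream sum runs over detections only.

Blank-based censoring applies deterministic rules, not statistical
blank modelling: any analyte detected in a field/laboratory blank has
its sample detections at or below the analyte-specific maximum blank
concentration re-flagged as `censored`; analytes whose blank levels
fall within the sample range can be placed on a *doubled* rule
(threshold $2\times$ the maximum blank) or removed from the
interpretive dataset entirely. Membership of the doubled/removal sets
is configuration (`censor_policy()`), not hard-coded chemistry, because
the rule is a judgement about specific blank observations rather than a
property of the analyte. Censoring at `<=` the threshold (inclusive) is
again the precautionary choice. Censored records are retained with
audit notes rather than deleted, so the censoring report is fully
reproducible; censoring is idempotent and, with empty blanks, the
identity.

## Benchmark resolution

The hazard-index denominator is resolved per analyte as the *minimum*
among the health-based candidates: MCLG, WHO guideline and provisional
guideline values, USGS health-based screening levels, state MCLs, and
drinking-water health advisories. Enforceable SOQ/MCL values never
enter this resolution (they embed treatment cost and feasibility, not
just health) — they drive the separate exceedance report. An MCLG of
zero means "no identified safe exposure level" and cannot be a divisor;
it is substituted by the analyte's method reporting limit, except where
an explicit override is configured — the package ships the lead
override of 1 µg/L (the American Academy of Pediatrics recommendation).
When two benchmark types tie at the minimum, provenance is made
deterministic by the fixed precedence MCLG > WHO GV > WHO pGV > HBSL >
state MCL > DWHA; the choice affects only the recorded source, never
the value. Detected analytes with no health benchmark are reported as
*uncovered* rather than silently dropped or guessed at.

Exceedance reporting is three-tiered: (1) strict exceedance of the
lowest enforceable SOQ/MCL ("shall not contain in excess of", hence
strict `>`); (2) de facto exceedances — any detection of an MCLG-zero
analyte, independent of concentration; (3) near-benchmark detections
above a configurable fraction of the enforceable value, defaulting to
0.5 since "near" has no agreed definition.

## EAR aggregation policies

Summing EARs has an ambiguous axis: a chemical usually hits several
correlated endpoints, and an endpoint aggregates several chemicals. All
three readings are first-class and reported side by side:

* `sum_of_chem_max` (default): per chemical take the maximum EAR over
  endpoints, sum over chemicals. This is the precautionary
  *per-chemical* reading that avoids double-counting one chemical
  across correlated endpoints.
* `per_endpoint_sum_max`: per endpoint sum over chemicals, report the
  maximum endpoint and its family — identifies which endpoint family
  (e.g. DNA binding) drives the mixture signal.
* `grand_sum`: sum over every pair; an upper bound on both.

`grand_sum >= ` each of the others on every input, a property tested on
random synthetic studies. Whether semiquantitative detections enter the
sums is a toggle defaulting to *include* (they are detections).

## Permutation statistics

Group comparisons use one-way PERMANOVA on Euclidean distances,
implemented from first principles via the standard partitioning of
squared interpoint distances:
$SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2$,
$SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$,
$F = \frac{(SS_{total} - SS_{within})/(a-1)}{SS_{within}/(N-a)}$,
with the probability from label permutations. The observed
configuration is counted once, $p = (\#\{F^\pi \ge F\} + 1)/(B + 1)$,
so $p$ can never be 0 and the attainable floor is $1/(B+1)$; with this
convention the test is exactly sized (rejection probability at nominal
0.05 is exactly 50/1000 with 999 permutations under exchangeability).
One-way label permutation of raw observations and of distance-matrix
rows are equivalent, so only the former is implemented. A constant data
matrix has nothing to partition: $F$ is defined as 0 with $p = 1$.
Pairwise group comparisons are optional wrapper calls with no
multiplicity adjustment (reported as-is, as is conventional for
figure-annotation probabilities). Concentrations enter the distance
matrix as $\log_{10}(1 + C)$ with nondetects as 0 in the pipeline's
group test; treating nondetects as 0 is the default because imputation
below the MDL would manufacture distance where the data contain none.

Spearman correlation uses average ranks (ties shared) with a two-sided
permutation probability under the same +1 convention; a constant vector
leaves rho undefined and is returned flagged with $p = 1$ rather than
erroring mid-pipeline.

## The synthetic study generator

The generator emulates the *structure* of a 30-brand bottled-water
survey so that the whole pipeline is testable without any data
download: 7 purified-tapwater (domestic), 16 spring domestic and 7
spring imported samples; a 28-analyte panel with real CAS numbers
spanning trace inorganics, mg/L-carried major ions, trihalomethane
disinfection byproducts (DBP), volatile organics and pesticides;
per-analyte × source-type Bernoulli detection probabilities (DBP
enriched in purified-tapwater samples, geogenic As/U confined to spring
samples); and sporadic low-level blank contamination. Defaults encode
the survey conditions: e.g. arsenic detection probability 0 in
purified-tapwater and 20/23 in spring samples, uranium 17/23 in spring,
lead 1/7 and 4/23.

Design choices worth recording:

* **Concentrations are log-normal** (geometric median and GSD per
  analyte), truncated below at the MDL by inverse-CDF sampling — the
  standard distributional model for environmental trace concentrations;
  no distributional form is implied by the survey itself.
* **As–U co-occurrence** is induced by drawing the 2×2 joint detection
  cells exactly (joint probability 16/23 in spring samples with the
  configured marginals). A latent shared-factor OR-construction was
  considered and rejected: it cannot hit the marginals and the joint
  simultaneously (it overshoots the joint by construction). The joint
  must respect the Fréchet bounds of its marginals; the constructor
  validates this.
* **All randomness flows from a single seed** through a fixed draw
  order (samples outer, co-occurring pairs first, then remaining
  analytes in panel order, blanks last), so a configuration is
  byte-reproducible.
* `calibrate_to_frequencies()` maps printed detection counts (e.g.
  5 of 30) to Bernoulli probabilities so expected subgroup frequencies
  equal the targets exactly; recovery is then a law-of-large-numbers
  statement checked over replicate studies.

The benchmark and ACC fixture tables are *synthetic plausible-scale*
registries, not agency or ToxCast extracts: they embed the qualitative
regulatory facts that matter for screening (which analytes carry an
MCLG of zero, the 10 mg/L nitrate-N MCLG, enforceable SOQ values, a
DNA-binding endpoint family on the DBPs, sub-µg/L cutoffs for
1-butanol) while keeping the package free of third-party data. A real
benchmark or `invitroDB` extract with the documented columns can be
dropped in unchanged.

What passing tests therefore show — and what they do not: the pipeline
arithmetic, rounding, censoring and calibration are exact, and the
qualitative attribution pattern (DBP-dominated hazard in
purified-tapwater samples; As/U contributions in spring samples)
emerges for the reasons it does in real surveys (MCLG-zero analytes
resolve to reporting-limit-scale benchmarks, so any detection carries a
large TQ). They do not validate the fixture magnitudes against any
laboratory dataset; absolute ΣEAR/ΣTQ levels on synthetic studies are
illustrative.

## Numerical conventions and problem sizes

* Detection percentages are $100k/n$ rounded half-up to integer
  percent, matching survey reporting style, so printed values like
  91 % (48 of 53) reproduce exactly.
* Units are carried as explicit tags (`ug/L`, `mg/L`) and converted
  (mg/L × 1000) only where ratios are formed; nothing is rescaled
  silently at I/O time.
* Permutation comparisons use a $10^{-12}$ slack when counting
  $F^\pi \ge F$ to avoid floating-point ties biasing $p$ downward.
* Validation problem sizes: the permutation-test calibration uses 1000
  simulated null datasets × 999 permutations (12 samples, 3
  variables) and 200 datasets for power; concentration-addition
  properties run over 200 replicate 9-sample studies; calibrated
  recovery pools 500 replicate 30-sample studies in the test suite and
  200 in the acceptance script. These sizes give binomial Monte-Carlo
  error comfortably inside the asserted tolerances.

## Limitations

* Screening-level only: no toxicokinetics, no internal-dose modelling,
  no dose-response refitting, no relative-source contribution — the
  ratios use measured concentrations directly.
* ACC coverage of detected organics is structurally incomplete (the
  fixture mirrors the roughly 58 % coverage typical of exact-CAS
  matching), and inorganics have no bioactivity coverage at all, so ΣEAR is a
  lower bound on the organic mixture signal and silent on inorganics.
* The hazard index inherits every benchmark's vintage and derivation;
  mixing MCLG, WHO and state values in one minimum is deliberately
  precautionary, not toxicologically harmonized.
* Microbial metrics and estrogen-receptor bioactivity are carried as
  plain variables only; no growth or receptor modelling.
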