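---
title: "Phenotype-level severity from EHR event data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-level severity from EHR event data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Severity indices in clinical informatics almost always grade *patients*: how
bad is this patient's asthma? `phenosev` addresses the complementary,
phenotype-level question: how severe is a condition *as a condition*,
relative to other conditions — myocardial infarction versus acne —
independently of any individual presentation. A ranking of phenotypes by
intrinsic severity lets comparative-effectiveness and phenome-wide studies
concentrate on the conditions that matter most, shrinking a phenotype
selection space of thousands of codes to its severe core.

The input is a minimal OMOP-CDM-style extract: condition occurrences
(patient, phenotype code, date), drug exposures, procedure occurrences
(HCPCS or ICD9PROC), a procedure fee schedule (rate per minute and typical
minutes per HCPCS code), and optionally a curated reference standard
labelling a subset of phenotypes mild or severe. Phenotype codes are opaque
strings; in practice they are SNOMED-CT concepts, each distinct code
treated as a distinct phenotype.

## The five measures and E-PSI

For each phenotype with prevalence at least a threshold (default 0.0001,
inclusive; prevalence = distinct carriers / distinct patients in the
condition table), five patient-level quantities are averaged over all
carriers of the code:

* **treatment time** — days between the carrier's first and last event of
  the code (single event = 0);
* **comorbidities** — distinct other condition codes on the carrier's
  record;
* **medications** — distinct drug codes on the record;
* **procedures** — procedure *events* on the record (repeats count: the
  number of procedures performed carries signal, not just their variety);
* **cost** — the summed billable amount of the carrier's HCPCS events,
  each priced as rate × minutes from the fee schedule. ICD9PROC events
  carry no fee data and contribute zero, so cost deliberately tracks
  procedure burden only partially.

Each measure $m$ is then expressed as a proportion of its maximum over the
profiled phenotypes, and the index is their mean:

$$\mathrm{E\text{-}PSI}(x) = \frac{1}{5}\left(
\frac{x_{\mathrm{cost}}}{\max(\mathrm{cost})} +
\frac{x_{\mathrm{treat}}}{\max(\mathrm{treat})} +
\frac{x_{\mathrm{comorb}}}{\max(\mathrm{comorb})} +
\frac{x_{\mathrm{med}}}{\max(\mathrm{med})} +
\frac{x_{\mathrm{proc}}}{\max(\mathrm{proc})}\right) \in [0, 1].$$

`compute_epsi(average = FALSE)` returns the raw sum of ratios instead. If a
measure is zero everywhere its proportion is defined as 0 rather than
dividing by zero. E-PSI is scale-invariant per measure (rescaling any one
column changes nothing) and monotone (raising a measure below its maximum
cannot lower the index) — both properties are enforced by tests.

No single measure suffices. Chronic but mild conditions (the classic
example is acne) accrue *long treatment times* without being severe;
cosmetic procedures are expensive without marking severity. The design
assumption throughout is that severity is the factor the five measures
share, while each measure's idiosyncratic bias is its own.

## Unsupervised forest, proximity, and anchored calling

The classifier input is the six-column feature matrix (five measures +
E-PSI, in the fixed order cost, treatment_time, n_comorbidities,
n_medications, n_procedures, epsi). Severity classes are learned without
using the labels for training:

1. **Contrast sample.** Each feature column is independently resampled
   with replacement — the product of the empirical marginals. The
   synthetic class has the data's marginals but none of its dependence.
2. **Forest.** 1000 classification trees (via `randomForest`) discriminate
   observed from synthetic rows. Only dependence structure can be learned,
   so terminal nodes align with the data's joint density modes.
3. **Proximity.** proximity(i, j) = fraction of *all* trees in which
   observed rows i and j share a terminal node. A common variant counts
   only trees where both rows are out of bag; the all-trees form is used
   here because it is simpler and exactly reproducible from the seed, and
   the OOB restriction changes proximities by a roughly uniform shrinkage
   at these sample sizes. The matrix is symmetric with unit diagonal by
   construction, asserted on every fit.
4. **Embedding.** Classical (Torgerson) scaling of $D = 1 - \mathrm{proximity}$:
   double-center $-\tfrac12 D^2$, eigendecompose, scale the top two
   eigenvectors by the square roots of their eigenvalues. $1-$proximity
   need not be Euclidean, so negative eigenvalues are clipped at zero and
   their mass logged; a requested dimension beyond the configuration's
   rank yields a zero column. Each axis's largest-magnitude coordinate is
   made positive so embeddings are sign-deterministic.
5. **Calling.** The published approach drew mild/severe demarcation lines
   on the embedding by eye; a reproducible rule is needed instead. Each
   phenotype takes its `k = 15` highest-proximity reference-standard
   anchors (excluding itself — anchors are therefore scored leave-one-out
   for free) and receives the proximity-weighted majority label. Exact
   ties, including the all-zero-proximity corner case, resolve to
   *severe*: over-calling severity is the safer error for a screening
   instrument whose output feeds phenotype prioritization.
   `neighbor_support` records the winning share of summed proximity.

Variable importance is the forest's mean decrease in Gini. Note a subtlety
of the unsupervised setting: because the contrast sample preserves
marginals, a feature separating classes *in isolation* earns no impurity
decrease — importance flows through the dependence between features. The
importance tests therefore use designs where the dominant feature sits on
a backdrop of weakly co-varying ones, which is also the regime real
severity data occupy.

Per-class error curves (`error_curves()`) come from a supervised forest on
the reference-labelled rows only, reported as OOB, mild-class and
severe-class error against the number of trees.

## Evaluation statistics

`classification_performance()` reports sensitivity and specificity in both
positive-class orientations, because published severity evaluations are
often ambiguous about which class was "positive". Cohen's and Fleiss'
kappa are implemented directly (the degenerate chance-agreement-1 case is
defined as κ = 1 so unanimous raters score perfect agreement rather than
NaN); both are verified against independent brute-force oracles to 1e-10.
The Wilcoxon rank-sum test is two-sided throughout; with both samples at
most 10 and tie-free the p-value is computed by full enumeration over
midranks (feasible to n + m = 22), otherwise by the normal approximation
with tie and continuity corrections. No multiple-testing correction is
applied across the six per-measure class contrasts; the six p-values are
reported as-is.

## The synthetic cohort generator

No public patient-level data accompany this method, so validation rests on
a generator that emulates the structure the method assumes, with every
parameter exposed:

* Each phenotype draws a latent class (severe with probability 0.3) and a
  log-normal random effect (sdlog 0.1). Carrier counts are binomial around
  a log-normal prevalence with mean 10 carriers per phenotype (minimum 2),
  times an enrichment factor 1.5 for severe phenotypes — hospital-style
  selection in which sicker conditions are over-represented; toggleable.
* Per carrier–phenotype pair, medication, comorbidity-filler and procedure
  counts are negative binomial (size 8) with mild-class means 3, 2 and 3,
  multiplied by the per-measure effect size (default 3) for severe
  phenotypes. Counts are overdispersed because real utilization data are.
* Treatment spans are log-normal (sdlog 0.4) with mild median 45 days,
  scaled by the effect size for severe phenotypes **and** for a 10%
  "chronic mild" subgroup that receives severe-scale spans while staying
  mild on every other measure — the acne-style confounder the multi-measure
  design exists to defeat. A generator test verifies the confounder is
  real: chronic-mild treatment times are statistically indistinguishable
  from severe ones while their medication burden is not.
* Procedure events are 20% ICD9PROC (no cost) and 80% HCPCS drawn from
  two fee tiers — severe phenotypes sample the high-fee tier (rates scaled
  by the cost effect size) with 20% crossover — and 15% of HCPCS codes are
  withheld from the emitted fee schedule. Cost therefore correlates with
  procedure count imperfectly, as it does when fee data cover only part of
  the coding system.
* Comorbidity fillers come from a shared 300-code pool, so they are
  themselves legitimate high-prevalence phenotypes; a patient's distinct
  condition codes, not a per-phenotype dial, determine the comorbidity
  measure.
* The reference standard covers 25% of phenotypes at a 372:144
  mild:severe ratio with labels equal to the latent truth — an idealized
  curated standard.

What the generator does **not** emulate: real clinical vocabularies, visit
structure, coding drift, care-process feedback between phenotypes, or
label noise in the reference standard. Passing the simulation benchmarks
therefore shows the pipeline recovers planted structure under realistic
noise and confounding — not that any particular hospital's data would
separate as cleanly.

## Problem sizes, numerics, determinism

The standard validation cohort is 2000 patients × 500 phenotypes (about
55k condition, 26k drug and 26k procedure events), profiled in about a
second; the 1000-tree forest over the ~800 retained phenotypes (500 index
codes plus the filler pool) fits in a few seconds. Unit tests use smaller
cohorts (≈ 300–600 patients, 60–150 phenotypes, 100–300 trees), chosen as
the smallest sizes at which the class structure is statistically stable.

Everything stochastic — cohort generation, contrast sampling, tree
training — is driven by explicit integer seeds, and regeneration under a
fixed seed is byte-identical, tested as such. Ranking ties break
lexicographically by phenotype code; scaling signs are fixed as described;
classification with the same seed and inputs reproduces
`classification.csv` exactly.

## Known limitations

* The k-NN-on-proximity calling rule is one reproducible formalization of
  a visual demarcation; other rules (e.g. density-based clustering on the
  embedding) could be substituted behind the same interface.
* Treatment-time aggregation across carriers defaults to the mean (the
  same averaging the other measures use); published phenotype-level
  treatment times may reflect maxima. The aggregation is a parameter
  (`aggregate` in `build_profiles()`).
* Comorbidity and medication counts use whole-record distinct codes with
  no time window; windowing is an explicit extension point.
* Currency is unit-agnostic: fee schedules are used as supplied, with no
  inflation adjustment.
* Binary calls only; `neighbor_support` and the embedding carry the
  graded information if finer severity levels are wanted.
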