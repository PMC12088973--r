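---
title: "Methods: energy landscape analysis of checkup cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy landscape analysis of checkup cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elacohort)
```

## The model

Energy landscape analysis summarizes a multivariate longitudinal dataset
as movement on a discrete potential surface. Six biomarkers per visit are
binarized at their medians, so a visit is a pattern $\sigma \in \{0,1\}^6$
(64 patterns, indexed with the first feature as the most significant
bit). The pattern distribution is modelled by the pairwise
maximum-entropy (Ising) family

$$P(\sigma) = \frac{e^{-E(\sigma)}}{Z}, \qquad
E(\sigma) = -\sum_i h_i \sigma_i - \sum_{i<j} J_{ij}\sigma_i\sigma_j ,$$

the least-structured distribution reproducing the data's single-feature
means and pairwise co-activations. Low energy means a frequent pattern.
Local minima of $E$ over the Hamming-1 neighbourhood define stable
states; the minimax barrier between two minima (the lowest maximum
energy any one-bit-step path must cross) quantifies how hard the
transition is.

Assumptions worth keeping in mind: (i) binarization at the median throws
away within-half quantitative variation deliberately, trading resolution
for noise tolerance and a tractable state space; (ii) the pairwise model
captures second-order structure only — third-order interactions are
invisible to it; (iii) visits are treated as exchangeable draws when
fitting (the temporal structure re-enters only through transition
counting); (iv) six features is a practical ceiling, since the number of
patterns grows as $2^m$ while the records stay fixed, so reliability
degrades rapidly for larger panels.

### State coding

The energy above uses the raw $\{0,1\}$ bits. A $\{-1,+1\}$ spin coding
is also available (`coding = "pm1"`); the two parameterize the same
64-pattern exponential family, so fitted probabilities — and everything
downstream: energies up to an affine shift, basins, barriers — agree.
Tests compare probabilities across codings rather than $h, J$, which are
coding-dependent. `"01"` is the default because the patterns themselves
are 0/1 and the worked encoding example reads directly off the bits.

## Fitting: exact gradients, moment-matching certificate

With 64 states the log-likelihood and its gradient are exact:

* gradient in $h_i$: empirical mean of $\sigma_i$ minus the model mean;
* gradient in $J_{ij}$: empirical co-activation minus the model's.

`fit_pairwise_maxent()` runs plain gradient ascent (learning rate 0.1)
until the largest absolute moment mismatch falls below `tol` (default
$10^{-6}$), capped at $10^5$ iterations; non-convergence is an error
carrying the last gradient norm, never a silent return. The stopping rule
doubles as an implementation-independent certificate: at convergence the
model reproduces every empirical first and second moment to `tol`,
whatever path the optimizer took. The likelihood is concave, so the
fixed point is the global maximum-likelihood solution.

Degenerate inputs: a feature column that is all 0 or all 1 makes the
corresponding $h_i$ diverge; the fit refuses such columns and suggests
regularizing (in practice median binarization of a continuous feature
cannot produce them). Row weights are supported; passing the 64 exact
probabilities of a known model as weights fits in the infinite-sample
limit, which the tests use to verify recovery to $10^{-6}$.

## Basins, tie-breaking, and barriers

Descent edges point from each pattern to its lowest-energy Hamming-1
neighbour. Ties are resolved by the lexicographic order (energy, pattern
index): a pattern is a local minimum iff no neighbour lies strictly below
it in that order. This makes plateaus deterministic — exactly one member
of an energy-tied plateau becomes the minimum, and descent from every
pattern terminates (at most 63 steps). States are numbered by increasing
local-minimum index, so "state 1" always contains pattern 0 when 0 is a
minimum.

Barriers are computed by a threshold sweep: activate patterns in
increasing (energy, index) order, union-find-merge each with its active
neighbours, and record the activation energy at which two minima first
share a component. This equals the minimax path value (the sweep is the
standard Kruskal-style argument on the node-weighted Hamming graph) and
costs $O(64 \log 64)$; the tests certify it against an independent
Floyd–Warshall minimax recomputation on 100 random landscapes. The
*modified* variant restricts the sweep to the patterns of the two states
being compared. Restriction can only raise a barrier (nested allowed
sets give monotone barriers); a strict rise means the unrestricted
saddle path detoured through a third state. Minima disconnected within
an allowed set get an `Inf` barrier rather than an error. Reported
barrier matrices carry absolute energies, with the climb relative to
each state's minimum provided alongside, so either convention can be
read off.

## Cohort pipeline choices

* **Diagnosis.** Onset is the earliest year in which any of: fasting
  PG ≥ 126 mg/dL with HbA1c ≥ 6.5 %; non-fasting PG ≥ 200 mg/dL with
  HbA1c ≥ 6.5 %; a questionnaire history of diabetes; or questionnaire
  diabetes treatment. For the questionnaire conditions the onset year is
  the first year the flag is reported true. Missing labs and
  questionnaires throughout yield "no onset", not an error.
* **Obesity.** BMI ≥ 25 kg/m² at the first measurement, fixed for life
  of the record series; the first *available* BMI is used if the
  earliest visit lacks one.
* **Filtering.** Feature-level missingness in step 1 is computed over
  the records present at that step; HbA1c is exempt from the 30 % rule
  as clinically indispensable. Step-3 record criteria (non-fasting,
  at/after onset, incomplete) are counted sequentially in that order, so
  the per-criterion counts sum exactly to the records removed — the
  report is conservation-checked and filtering is idempotent.
* **Feature ranking.** Records are labelled positive when onset occurs
  within the following three years (onset year − record year ∈ [1, 3];
  the record's own year is excluded because pipeline records are
  strictly pre-onset). A 500-tree random forest with Gini importance
  ranks the 17 candidates (HbA1c is held out and then forced into the
  selected six). Forest hyperparameters are not critical: ranking
  stability is asserted by majority vote over seeds, not per-seed.
* **Transitions.** Only calendar-year gaps of exactly 1 count;
  self-transitions count; at most one record per individual-year is
  guaranteed upstream. The pathway-preference chi-squared test applies
  the Yates continuity correction by default: on 2×2 tables of the size
  this analysis produces the corrected test is the conservative standard
  choice, and it is the variant whose p-values the package's acceptance
  checks pin down.
* **Pre-transition comparisons.** Mean ± sample SD (n − 1) per
  transition type, Mann–Whitney U two-sided (exact for small untied
  samples, normal approximation with continuity correction otherwise),
  missing values dropped per feature, and no multiple-testing
  adjustment — the table is descriptive, one feature at a time, and is
  documented as such.

## The synthetic cohort generator

Real checkup data of this kind are access-restricted, so the generator
is a first-class module: it emulates the *schema and failure modes* of
checkup data — yearly visits 2012–2020 with ~85 % attendance, an obese
subgroup (30 %, BMI/WC means shifted up), females (40 %, later excluded
by the pipeline), fasting on ~60 % of visits, per-cell
missing-completely-at-random deletion with HbA1c missing at 37 % (its
dominant real-world pattern) and 2–10 % elsewhere, and diabetes onset as
a per-state annual hazard (0 / 0.01 / 0.05 for healthy / intermediate /
unhealthy) that, once fired, sets the questionnaire treatment flag
permanently.

Dynamics are a latent three-state Markov chain per individual. Default
biomarker means/SDs per state are set to clinically realistic values for
middle-aged men (healthy ≈ normal panel; intermediate ≈ raised BMI, WC,
TG, ALT, UA with lowered HDL-C but near-normal glycaemia; unhealthy ≈
raised PG and HbA1c), and obese individuals use a transition matrix
tilted toward the intermediate state so that group-stratified pathway
analyses have something to find. Features are conditionally independent
Gaussians given the latent state — the simplest mechanism that induces
the cross-feature correlation ELA feeds on, with values floored just
above zero.

What the generator does *not* emulate: physiological feedback (treatment
effects, weight-glycaemia coupling within an individual), measurement
drift, seasonal effects, informative missingness, or within-individual
autocorrelation beyond the latent chain — the latent-Markov choice is a
pragmatic stand-in, not an inference about real dynamics. Passing tests
on synthetic cohorts therefore certify the *computation* (labelling,
filtering, fitting, basins, barriers, counting) and not any clinical
claim about real populations.

A companion exact sampler, `sample_ising()`, draws categorically from
the enumerated 64-pattern distribution of a known model, giving the fit
a round-trip oracle with known ground truth.

## Numerical conventions and problem sizes

Medians use the standard midpoint-of-central-order-statistics convention
for even counts; the boundary rule "≤ threshold → 0" makes the exact
threshold value unambiguous either way. Probability normalization is
exact up to floating point (checked at $10^{-12}$). Energy ties anywhere
in the basin/barrier machinery resolve by pattern index, as above.

The test and reproduction scripts size their simulations for
completeness of coverage rather than asymptotics: moment checks use
cohorts of 2,000 individuals, fit round-trips use $10^5$ exact samples
(deviations measured in Monte-Carlo standard errors), brute-force
certification uses 100 random 64-point landscapes, and the end-to-end
reproduction run analyzes a 2,000-individual synthetic cohort (~15,000
records before filtering). These sizes were chosen so each property is
measured well inside its tolerance.

## Limitations

The package stratifies pathways; it does not model time-to-event or
adjust for covariates, estimate Markov transition probabilities on the
landscape, or handle multi-year lags. The second-order model, the
six-feature ceiling, and median binarization are inherited limits of the
method itself, discussed above. Female-specific analysis is excluded by
the pipeline's design (step 2), mirroring the male-cohort setting the
pipeline implements; the generator produces females solely so that step
is exercised.
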