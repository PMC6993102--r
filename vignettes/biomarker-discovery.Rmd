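---
title: "Random-Forest biomarker discovery from MALDI-MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-Forest biomarker discovery from MALDI-MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldimarkers)
```

## The problem

Untargeted plasma MALDI-MS produces, per subject, a handful of replicate
spectra binned to nominal m/z channels (here 1,752 unit-width channels over
m/z 250–2,001). Given two patient groups — cases with weight gain (WHO
overweight or obese, BMI ≥ 25 kg/m²) and eutrophic controls — the goal is to
(i) train a *diagnosis classifier* that predicts the class from a spectrum
and (ii) shortlist the m/z channels ("ions") that drive the prediction, as
candidates for metabolite identification. `maldimarkers` implements this
workflow end to end, together with a synthetic-cohort generator that plants
known markers and known linear dependencies so every stage can be validated
against ground truth.

## The pipeline, stage by stage

### Normalization

Every replicate spectrum is divided by its own maximum intensity
(`normalize_rows()`), so the largest channel of each vector is exactly 1.
All-zero vectors are kept (with a warning), because dropping them would
silently unbalance replicate counts per patient. The operation is idempotent
and invariant to positive rescaling of a vector.

### Patient-grouped partitioning

All of a patient's replicate vectors travel together: `split_fit_test()`
reserves `floor(0.2 n)` patients per class as an untouched final test set,
and `make_experiments()` reshuffles the remaining fit patients into 10
train/validation experiments (80/20 by patient, per class). With 90 patients
per class this gives 18 test, 72 fit, and 57/15 train/validation patients
per class per experiment; an 82-patient fit class yields the 65/17 split.
`assert_no_leakage()` re-verifies pairwise disjointness on every run.
Partition sizes always derive from the fractions and the supplied cohort;
they are never hard-coded.

### Dependency reduction

Linearly dependent channels carry no additional information for the
classifier, so `find_dependent_groups()` runs Gauss-Jordan elimination over
the channels in ascending m/z order with partial pivoting on rows. A column
whose entries after elimination all fall below `pivot_tolerance`
(relative to the column's maximum absolute value; default 1e-8) is declared
dependent, and — because the pivot block is reduced to the identity — its
entries in the pivot rows are exactly its expansion coefficients. Each
dependent channel joins the group of its lowest-m/z supporting pivot; each
group is then represented by its member with the maximum median intensity
across all vectors (ties to the lower m/z), and `reduce_channels()` keeps
only representatives. `expand_to_group()` recovers the full group later,
when matching ions to molecules at the annotation stage.

Two deliberate choices matter here. First, the elimination by default uses
only fit-partition rows, so held-out test spectra never influence the
feature space; `reduction_rows = "all"` reproduces the alternative
convention of feeding every vector to the elimination, as one would when
re-running a deposited dataset. Second, and importantly for tables with more
channels than spectra: the column rank is bounded by the number of rows, so
with 1,752 channels over 820 fit vectors the reduction necessarily retains at
most 820 representatives. Channels beyond the rank bound are genuine linear
combinations of earlier channels *in the observed data*, even though they
carry independent noise in the generative sense. The planted dependent
members are always among the eliminated channels, but they are never the
only ones in this regime — a structural property of rank, not a tolerance
artifact. The assignment of densely-dependent incidental channels to their
lowest-m/z supporting pivot keeps the planted groups (whose dependence is
sparse and exact) cleanly separated.

### Tree-count grid search

`grid_search_trees()` evaluates a (vector length × tree count) grid: a pilot
full-length forest per experiment fixes an importance ranking, each cell
trains one forest per experiment on the top-`length` channels, and the cell
means of validation f1 and balanced accuracy are recorded. Per length, the
tree count maximising mean f1 wins; ties resolve to higher accuracy, then to
*fewer* trees. Lengths the ranking loop visits but the grid did not are
mapped to the nearest visited length (ties toward the smaller length) —
nearest-neighbour extension avoids inventing a functional form for the
trees-versus-length curve.

### Iterative importance ranking

`iterate_ranking()` trains one forest per experiment at the current channel
set, averages the per-forest impurity importances (each normalized to sum 1,
so forests contribute on a common scale), records the validation metrics,
and keeps the top `max(1, floor(0.9 L))` channels. The floor/max rule
guarantees termination at length 1 regardless of the factor. Ranking ties
break toward higher mean importance, then lower m/z. `select_optimal()`
returns the surviving set at the iteration with the maximum mean validation
f1, ties toward the *smaller* length.

Validation metrics during model selection are computed per replicate vector
(the unit the classifier actually predicts). The alternative — majority
voting to patient level already at validation time — leaves only ~30
evaluation units per experiment, and with five replicates per patient the
vote is so strong that f1 saturates at 1.0 over long stretches of the
ranking trace, at which point the tie rule collapses the optimal set to a
minimal subset of the informative channels. Vector-level scoring has about
five times the granularity and preserves a usable f1 gradient; the final
diagnosis test is still aggregated to patient level by majority vote (ties
to the positive class — the defensible bias for a screening tool), which is
also the only level at which an 18+18-patient test can produce the integer
confusion tables a final report prints.

### Metrics

From a confusion table, `compute_metrics()` returns sensitivity
`Tp/(Tp+Fn)`, specificity `Tn/(Tn+Fp)`, precision `Tp/(Tp+Fp)`, f1 (the
harmonic mean of precision and sensitivity) and *balanced* accuracy
`(sensitivity + specificity)/2` — note this is not `(Tp+Tn)/total`. Zero
denominators yield `NA` sentinels, never a silent 0. Values are proportions;
`metrics_percent()` applies the 1-decimal percentage rounding only at report
time.

### The CDF marker criterion

A discriminant channel is promoted to *marker* when the ion is
systematically more intense in cases. With `P` the empirical CDF of the
positive-class values of channel `j`, `Q` the negative-class CDF and `m_j`
the positive-class median, the criterion is

$$\Delta_j = Q(m_j) - P(m_j) > \beta,
\qquad Q(x) \ge P(x)\ \forall x > m_j,$$

with `beta` restricted to (0, 0.5), default 0.4. For continuous samples
`P(m_j) ≈ 0.5`, so `Δ_j > 0.4` demands that over 90% of control values lie
below the case median; the dominance condition rejects channels whose upper
tails cross. Dominance is checked at every observed sample value above
`m_j`, which is exact for step functions — no discretization grid is
involved. Values are pooled across replicate vectors, and by default only
fit-partition vectors enter the decision. Since empirical CDFs step only at
sample values, `Δ_j ∈ [−1, 1]` always, the statistic is monotone in an
upward location shift of the positive sample, and the marker set shrinks
monotonically as `beta` rises.

### Annotation

`monoisotopic_mass()` sums most-abundant-isotope atomic masses over a parsed
formula; `adduct_mz()` adds the cation delta of `[M+H]+`, `[M+Na]+`,
`[M+K]+`, `[M+NH4]+` or `[M+H−2H2O]+` — each delta includes the loss of one
electron, which matters at ppm accuracy. `ppm_error()` is signed,
`(measured − theoretical)/theoretical × 1e6`, and the display convention
truncates toward zero at two decimals (the convention under which the
bundled table's printed ppm column is reproduced exactly; rounding would
not). `match_candidates()` screens a local compound table at a 2 ppm default
tolerance, computing ppm against the 4-decimal display-precision theoretical
mass as printed annotation tables do. One bundled compound (PGB2) carries a
reported theoretical mass that plain monoisotopic arithmetic on its usual
formula does not reproduce (3.8 ppm off); it is flagged
`mass_derivable = FALSE` and excluded from derivation checks.

## The synthetic cohort: what it emulates, and what it does not

`synthetic_spec()` describes a balanced two-class cohort (default 90+90
patients × 5 replicates × 1,752 channels). Channel log-intensities follow
`mu_c + a_ic + e_icr`: a channel-specific baseline mean (gentle decay with
m/z plus heterogeneity, sd 0.8), a patient-level effect (log-sd 0.40,
roughly the ~40% inter-individual CV typical of plasma metabolites) and
replicate noise (log-sd 0.15, a typical technical CV for MALDI
quintuplicates). Exponentiation makes intensities positive and
heavy-tailed, as MALDI intensities are. One channel (m/z 251) is a stable
high-intensity base peak, giving the row-max normalization a steady anchor
the way a matrix peak does in real spectra.

Markers are planted as upward location shifts of the case patients' channel
mean, in units of the channel's total log-scale sd (default: five markers at
3 sigma, at the low-m/z positions where plasma metabolite ions concentrate).
Dependency groups are planted by overwriting member columns with
`coefficient × generator` after noise, so their linear dependence is exact;
coefficients below 1 keep the generator as its group's max-median
representative. Subject covariates (height, BMI by class, weight
back-computed) are drawn so that the WHO cut points reproduce the class
labels exactly.

Not emulated: isotope envelopes, peak shape, baseline drift, m/z
calibration error, batch effects, class imbalance, or correlated marker
panels — channels are independent given the planted structure. Passing the
planted-recovery tests therefore demonstrates that the pipeline's selection
and inference machinery works when its assumptions hold; it does not
certify performance against matrix effects or confounded designs.

## Numerical choices and degenerate inputs

* Pivot tolerance 1e-8 (relative, per column); supporting-coefficient cutoff
  1e-6 relative to the largest coefficient. All-zero columns attach to the
  first pivot group; an entirely zero matrix collapses to one group.
* Tie-breaks are fixed everywhere (fewer trees, smaller length, lower m/z,
  positive class on vote ties) so reruns at a seed are bit-identical. All
  randomness descends from one master seed through named stage substreams,
  recorded in the run log.
* Forest hyperparameters other than the tree count stay at ranger defaults
  (`mtry = sqrt(p)`, unlimited depth) and are recorded via the run log;
  forests train single-threaded for reproducibility.
* Majority votes with an even replicate count resolve ties to "case".
* `marker_delta()` requires non-empty samples; `compute_metrics()` returns
  `NA` for undefined ratios; all-zero spectra normalize to themselves with a
  warning.

## Problem sizes used in the validation studies

The packaged studies run the full emulated scale — 90+90 patients, 5
replicates, 1,752 channels — with a compact grid (lengths {64, 16} × trees
{25, 50}) for the 20-seed planted-recovery study, and 50 single-experiment
seeds for the null control. The analysis scripts under `analysis/` use a
slightly wider default grid on a single seed. These sizes were chosen so a
complete validation cycle runs comfortably on a laptop-class single core;
the statistics they estimate (median recovered markers, mean null accuracy)
are stable at these replication counts.

## Known limitations

* With more channels than spectra, "linear dependence" is rank-limited: the
  reduction cannot distinguish planted from incidental dependence, only
  eliminate both (see above). Interpreting *which* channels were eliminated
  is only meaningful when spectra outnumber channels.
* The marker criterion is a fixed threshold rule; no multiplicity control
  is applied, by design.
* The SVM comparison uses two independent R implementations (e1071/libsvm
  and kernlab) of sequential-minimal-style optimisation with a linear
  kernel; they are solver variants, not a reproduction of any specific
  proprietary optimiser.
* Annotation is plain mass arithmetic against a local table; no isotope
  pattern scoring or MS/MS evidence is considered.

## A worked miniature

```{r mini, eval = FALSE}
spec <- synthetic_spec(n_per_class = 20, replicates_per_patient = 3,
                       n_channels = 80,
                       marker_channels = data.frame(mz = c(255, 270, 300),
                                                    shift = 3),
                       dependent_groups = data.frame(
                         generator_mz = c(260, 265),
                         member_mz = c(310, 320),
                         coefficient = c(0.5, 0.6)))
coh <- generate_cohort(spec, seed = 7)
res <- run_discovery_pipeline(coh$matrix, seed = 11,
                              lengths_grid = c(32, 8), trees_grid = c(25, 50))
res
res$markers
```
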