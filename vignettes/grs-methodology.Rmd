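---
title: "Genetic risk scores for the triglyceride response to fish oil: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores for the triglyceride response to fish oil: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omega3grs)
```

## The scientific problem

Fish-oil (omega-3 fatty-acid, *n*-3 FA) supplementation lowers plasma
triglycerides (TG) in most — but not all — people. In controlled
supplementation protocols roughly 30–40% of participants keep stable or
even rising TG. A genetic risk score (GRS) summarising TG-response-associated
variants can separate likely *responders* from *nonresponders* before
treatment, which is the premise of the decision-aid workflow this package
implements: genotype quality control, odds-ratio-based scoring,
GRS summation, covariate-adjusted prediction models, cross-validated
discrimination metrics, and cutoff selection.

Because individual-level cohort data of this kind are not publicly
released, the package ships a synthetic-cohort generator that emulates the
statistical structure of such a study (below), plus the published
17-variant panel — per-group allele frequencies, odds ratios and the
published score column — as packaged fixtures that serve as the worked
validation surface.

## Response classification

A subject is a **responder** when plasma TG fell over the supplementation:
change `tg_post − tg_baseline ≤ −0.01` mmol/L. A **nonresponder** has
stable or rising TG: change `≥ 0.00` mmol/L. Changes in the open interval
between the bounds are `unclassified`. Both bounds are exposed as
arguments of `classify_response()`; the defaults make the two rules
disjoint (a literal reading of the published pair of inequalities overlaps,
which cannot be intended). Responders whose *relative* decrease is at
least 10% carry an `extreme` flag — cohorts of this design are typically
selected for extreme response, and the generator reproduces that
selection.

## Quality control

Per variant, the package computes the minor-allele frequency (MAF, pooled
and per response group, missing genotypes excluded pairwise), an exact
Hardy–Weinberg equilibrium (HWE) test, a monomorphism flag, and the call
count. Two policies deserve comment:

* **Exact rather than χ² HWE.** `hwe_exact_test()` implements the
  two-sided conditional exact test (Wigginton-style recurrence over
  heterozygote counts, summing all configurations no more probable than
  the observed one) — the default of standard genotype-QC software; the χ²
  version is available (`hwe_chisq_test()`) as the asymptotic cross-check.
  The standard (not mid-p) variant is the default because published
  per-variant HWE p-values of the kind reproduced here are consistent with
  it; a `midp` flag covers the alternative.
* **HWE failure flags, monomorphism excludes.** `qc_filter()` removes only
  monomorphic variants (no carrier of the rare allele — such variants
  cannot carry information and break odds-ratio estimation); HWE
  departures below `hwe_alpha = 0.05` are reported but retained, since
  exclusion is an analyst's judgement, not an automatic rule.

## Odds ratios and the ±1 score rule

For each variant the allele-based odds ratio between the response groups
is
$$ OR = \frac{p_R/(1-p_R)}{p_{NR}/(1-p_{NR})}, $$
with $p_R$, $p_{NR}$ the minor-allele frequencies among responders and
nonresponders. The 95% CI uses the normal approximation on
$\log OR$ from the four allele counts, so it requires group sizes.

**Orientation.** Published tables of this design describe the OR verbally
as "nonresponders over responders", yet the printed values are only
consistent with responder-odds over nonresponder-odds (e.g. MAFs
0.18/0.23 give 0.73, and 0.12/0.88 ÷ 0.14/0.86 = 0.84). The package
implements the value-consistent orientation and exposes a `flip` flag for
the opposite convention.

**Scores.** `assign_score()` gives +1 when OR < 1 (minor allele enriched
in nonresponders, i.e. associated with higher post-supplementation
lipids), −1 when OR > 1, and excludes a variant when the responder MAF is
0 (its OR is undefined in this orientation) or the OR is exactly 1 (the
rule defines no sign there). Excluded entries contribute nothing to any
GRS.

**Printed tables vs rounded frequencies.** `score_table()` recomputes ORs
from group MAFs but lets a supplied `odds_ratio` column take precedence.
This matters for the packaged panel: frequencies printed to two decimals
make several rare-variant ORs collapse to exactly 1, while the original
analysts' ORs — computed from unrounded allele counts — do not. With the
published ORs supplied, the packaged panel reproduces its published score
column exactly (14 scored, 1 excluded).

## GRS summation

The unweighted GRS of subject $i$ over score set $S$ is
$$ GRS_i = \sum_{j \in S} s_j \, g_{ij}, $$
with $s_j \in \{+1, -1\}$ and $g_{ij} \in \{0,1,2\}$ the minor-allele
dosage; the weighted version scales each term by $|w_j|$, with weights
(e.g. externally estimated interaction effect sizes) supplied by the
user — they are not derivable from the data at hand. Dosage (allele-count)
coding is the default reading of "summing the score of risk alleles";
higher GRS means more nonresponse-associated alleles. Missing dosages at
scored variants are mean-imputed per variant by default (`missing =
"zero"` is the alternative); score sets are nested supersets built by
`build_score_sets()` (the GRS31 → GRS32/GRS38/GRS46 construction, at
default sizes).

## Models and statistics

* `fit_logistic()` — binomial-logit ML fit (IRLS via `glm`), with
  separation detected and resolved by a tiny ridge penalty (1e-6) so
  coefficients stay finite; the condition is reported, not hidden.
* `mcfadden_r2()` — $1 - \ell_{model}/\ell_{null}$.
* `delta_r2()` — explained-variance contribution of the GRS: the
  R² increase of `outcome ~ covariates + GRS` over
  `outcome ~ covariates` (age, sex, BMI), nonnegative by nesting. The
  outcome can be the post-supplementation TG or the TG change; the change
  is the default because it is what the response label is defined on.
* `group_ttest()` — Welch's two-sided unpaired t-test (the unequal-variance
  form is the safer default when the pooled-variance choice is unstated).
* `snp_visit_interaction()` — the genotype-by-visit interaction of a
  two-visit random-intercept mixed model, implemented as its exact
  balanced-design equivalent: the dosage coefficient of the change-score
  regression `ΔTG ~ dosage + covariates`. The equivalence (estimate,
  t statistic and Satterthwaite p) is asserted in the test suite against
  an explicit REML random-intercept fit; implementing it as a change-score
  regression avoids a bespoke mixed-model engine for a two-period design
  where none is needed.

Sex enters models as a single male indicator (reference female).

## Evaluation protocol

`stratified_split()` halves the labelled cohort (default fraction 0.5)
preserving the responder:nonresponder ratio to within one subject, and
pre-assigns stratified tenfold cross-validation folds within the training
half; everything is deterministic given the seed. `cross_validate()` fits
the logistic model on 9/10 folds, evaluates each held-out fold
(fold-mean aggregation, the common default), then refits on the full
training half and evaluates once on the untouched test half. Metrics:
accuracy (Clopper–Pearson exact CI), AUC-ROC (Mann–Whitney rank formula,
ties ½; DeLong CI), sensitivity and specificity with *responder* as the
positive class, and McFadden's pseudo-R². The classification threshold on
the predicted responder probability is 0.5 (exposed as an argument — the
underlying convention is rarely printed).

`evaluate_pipeline()` adds the leakage-free variant used for calibration
experiments: the score table is estimated from the *training* subjects
only before any GRS reaches the test half. Estimating scores in-sample
(as original-study protocols effectively do) inflates held-out metrics;
the package supports both, and the calibration tests use the clean one.

## Cutoff selection and the decision aid

`cutoff_sweep()` evaluates "predict responder iff GRS ≤ c" at every
distinct GRS value. Following the clinical reading, responders *at or
below* the cutoff count as captured while nonresponders *at or above* it
count to the other side — ties at the cutoff deliberately count toward
both quoted proportions. `summary_points()` reports the rows at the
nearest-rank (type-1) tertile and median quantiles; nearest-rank is chosen
because the candidate cutoffs must be attainable GRS values.
`decision_aid()` applies a calibrated cutoff, siding with treating on
ties: mislabelling a nonresponder as responder costs little (an
ineffective supplement), whereas the reverse withholds a beneficial
treatment — hence cutoffs favouring sensitivity/capture.

## The synthetic-cohort generator

`generate_cohort()` draws, per subject: group membership by fixed counts
(default 80 responders / 60 nonresponders, the size of the motivating
cohort after one genotyping failure; which group lost the failed subject
is unknowable, so the split is configurable); genotypes independently per
variant as Binomial(2, group MAF) — Hardy–Weinberg within group, no
linkage disequilibrium (the score treats variants independently, and LD
simulation is out of scope); TG change from the group's normal
distribution (−0.50 ± 0.36 responders, +0.18 ± 0.17 nonresponders,
mmol/L) by rejection sampling (10,000-attempt cap, then an explicit
error) so every subject satisfies the classification rule, including the
≥10% relative-decrease selection for responders; baseline TG log-normal
with a higher median for responders (1.70 vs 1.20 mmol/L, sdlog 0.30 —
responders in such cohorts start higher; the exact medians are a
realistic choice, not published values); age uniform 18–50 y and BMI
uniform 25–40 kg/m² (the study's inclusion windows; uniformity is the
least-assumptive choice within them); sex Bernoulli(0.5).

The default 31-variant base panel (group MAFs 0.25 vs 0.40, all variants)
stands in for the original 31-SNP score whose true frequencies are not
printed anywhere reproducible; that separation gives a population GRS
AUC ≈ 0.95, matching the discrimination reported for such scores. Setting
the two base MAFs equal yields a null panel for calibration.

What the generator does **not** emulate: linkage disequilibrium, allele
frequency spectra beyond the configured panel, genotype–covariate
correlation, measurement error in TG, or any direct genotype→TG effect —
the GRS–response association arises purely through the group-wise
frequency differences. Passing tests therefore demonstrate the
correctness and calibration of the *procedures*, not the real-world
predictive value of any particular score.

## Numerical choices and degenerate inputs

* HWE exact p-values are computed by a normalized recurrence (no
  factorial overflow); p is clamped into (0, 1].
* Odds ratios at $p_{NR}=0$ signal `infinite`; at $p_R=0$, `excluded`.
* Constant prediction scores give AUC 0.5 with a degenerate-CI warning;
  single-class folds are skipped with a warning and reported.
* Constant-GRS threshold sweeps collapse to a single row with a warning.
* All randomness flows through explicit integer seeds; RNG state is
  restored after each call, so library calls never perturb a user's
  session RNG.

## Problem sizes used by the test suite

The suite validates the HWE test exhaustively over all genotype triples
up to 40 subjects plus 300 random triples up to 200 subjects against a
log-factorial enumeration oracle (tolerance 1e-12); AUC against a
pairwise-count oracle at n ≤ 50 with heavy ties; type-I error of the
interaction test over 1000 null simulations at n = 140 (acceptance band
3–7% at α = 0.05); odds-ratio recovery on a 7000-subject cohort (joint
z-band, since a per-variant 2-SE band over 14 variants has only ~52%
joint coverage); and parameter recovery over 20 generator seeds per arm
(strong separation: mean held-out AUC > 0.8; null: within 0.45–0.55).
These sizes were chosen to make each statistical check decisive at a
desk-scale runtime.

## Known limitations

* PLINK *text* and single-allelic VCF only; no `.bed`, phasing, or
  multi-allelic handling.
* The mixed-model interaction test covers the balanced two-visit design
  only — by construction, not as an approximation.
* Weighted GRS weights must be supplied; the package does not re-estimate
  interaction effect sizes.
* Scores estimated and evaluated in the same small cohort are optimistic;
  use `evaluate_pipeline()` (train-only estimation) when the goal is an
  honest generalisation estimate.
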