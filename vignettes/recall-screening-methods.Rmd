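---
title: "Methods: story-recall screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: story-recall screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallscreen)
```

## The problem

Story recall — listening to a short narrative and retelling it immediately
and again after a delay — is one of the most sensitive bedside probes of
episodic memory, the domain affected earliest in Alzheimer's disease. A
fully automated version of this task scores the *relationship between the
retelling and the source text* rather than a simple accuracy count, and uses
that representation to screen for two targets: mild cognitive impairment
(MCI, including mild Alzheimer's dementia) and amyloid beta (Aβ) positivity,
the biomarker that defines Alzheimer pathology and gates recruitment into
disease-modifying trials.

`recallscreen` implements that analysis end to end on synthetic data: a
cohort generator emulating the 2×2 amyloid-by-diagnosis case-control design,
a deterministic text-pair feature extractor over story-recall triplets,
tournament leave-pair-out cross-validated classification, the ROC inference
stack (DeLong variance, Youden operating points, Cohen's kappa, power), and
two deterministic screening simulations.

## The synthetic cohort generator

`group_design()` fixes the study conditions. The four groups cross amyloid
status with clinical status, with sizes 46 / 54 / 47 / 46
(Aβ+ MCI, Aβ− MCI, Aβ+ CU, Aβ− CU) and per-group normal distributions for
age (means 72.7 / 68.7 / 71.4 / 69.4 years, truncated to the 50–85
eligibility window), years of education, and MMSE (truncated to the
eligibility windows 23–30 for MCI/mild AD and 26–30 for CU, then rounded).
CDR-G is drawn from a categorical distribution over {0, 0.5, 1} with
per-group probabilities chosen to match the group means (0.57 / 0.54 /
0.12 / 0.09); only means and SDs are published for these variables, and
normality is an assumption of the generator, not a reported fact.
Missingness is missing-completely-at-random: education with probability
0.015 per participant, and with probability 0.115 a participant loses one or
two randomly chosen PACC5 subtests — the participant-level formulation is
used so the *fraction of participants with at least one missing subtest*
matches the motivating cohort's 11.5%, which a per-subtest rate of 0.115
would badly overshoot (≈46% of participants).

### Recall degradation model

Synthetic recalls are produced from the source story by token-level
operations at per-group rates: omission (a token is dropped), substitution
(replaced by a random story-vocabulary token), filler insertion (*um*, *uh*,
…), and an extra omission pass for the delayed recall. This is deliberately
the simplest process that yields recall transcripts whose distance from the
source is group-dependent; it does not emulate paraphrase, semantic
clustering, word-finding pauses with repairs, or ASR noise, so passing tests
demonstrate correctness of the *pipeline*, not clinical validity of the
surrogate features on real speech.

The defaults define a strongly separable regime in which the two label axes
act through distinct channels: clinical status drives recall completeness
(omission 0.40 / 0.35 / 0.12 / 0.08; delayed extra omission 0.15 / 0.12 /
0.05 / 0.03) while amyloid status drives disfluency and accuracy (filler
insertion 0.28 / 0.06 / 0.22 / 0.04; substitution 0.10 / 0.06 / 0.05 /
0.02). The separation of channels is structural, not cosmetic: if a single
severity axis drove all rates, the full-sample amyloid contrast would be
confounded with diagnosis (the Aβ− MCI group would sit *above* the Aβ+ CU
group on every feature) and no classifier could learn it. The design
validator enforces that omission, substitution and delayed extra-omission
rates are at least as high in the impaired groups as in the CU groups.

PACC5 subtest z-scores are group-shifted normals (shifts −1.3 / −1.1 /
−0.25 / 0 SD), making the composite a strong MCI discriminator and a weak
amyloid discriminator, the qualitative pattern expected of cognitive
composites.

### Numerical conventions

Truncated normals are drawn by inversion, so a zero SD degenerates cleanly
to the mean. The even-count median used by `impute_education()` is the mean
of the two central values. The PACC5 composite is the mean of *available*
subtest z-scores; all five missing yields `NA`, never zero.

## Text-pair features

`normalize_transcript()` lower-cases, deletes apostrophes inside words,
treats hyphens and em-dashes as separators, strips remaining punctuation and
tokenises on whitespace. A trailing plain hyphen marks a partial word (a
manual-transcription convention); partial words and a configurable filler
lexicon (*um, uh, er, …*) are flagged and optionally removed.
`word_error_rate()` is the token-level minimum-edit-distance error count per
reference word, with corpus-level and mean-over-recordings aggregations in
`wer_summary()` (mean over recordings is the default report).

The neural text-pair encoder whose vectors drive the original analysis is
pre-trained at GPU scale and is not re-implemented here. The pipeline
defines an *encoder interface* — any function mapping an ordered pair of
token sequences to a fixed-length named numeric vector — and ships a
deterministic 16-feature surrogate (`pair_features()`): unigram/bigram
clipped precision and recall, longest-common-subsequence ratios, length
ratio, Jaccard type overlap, content-word precision/recall, ordering
concordance of shared tokens, and per-side filler and repetition rates. All
features are bounded in [0, 1], which also means no feature can explode in a
fold's standardisation. Direction matters: precision-type features differ
between (a, b) and (b, a).

Each story-recall triplet yields six directed pairs — source→immediate,
immediate→source, source→delayed, delayed→source, immediate→delayed,
delayed→immediate — and `story_vector()` averages the six vectors
element-wise into one vector per story. Feature vectors are not standardised
globally; standardisation happens inside each training fold.

## Tournament leave-pair-out evaluation

The hold-out unit is the **participant**: all of a participant's story
vectors leave the training set together, which is the structural guard
against leakage (asserted in the tests by instrumenting the classifier).
For every pair of participants (`all_pairs` mode; `cross_label_pairs`
restricts to opposite-label pairs, the classical leave-pair-out AUC
estimator), the model is refit on the remaining participants' story vectors
— each carrying its participant's label — and both held-out participants are
scored by averaging their per-story predicted probabilities.

The fold classifier is a ridge-penalised logistic regression with the
configuration fixed once: training-fold mean/SD standardisation, unit
inverse-regularisation strength (penalty λ = 1 on standardised
coefficients), unpenalised intercept, Newton iterations with step halving,
convergence at gradient sup-norm 1e-8. Nothing is tuned per fold; the fit is
deterministic, so the whole TLPO estimate is deterministic given the data.
Fold outcomes are keyed by the held-out pair, so aggregation is invariant to
execution order.

Pairwise outcomes (higher participant score wins; exact ties half a win
each) aggregate into win counts; the final ranking sorts by descending win
count, breaking ties by descending mean cross-validated score and then by
participant id. The AUC is the fraction of opposite-label participant pairs
ordered correctly by (win count, mean score), ties on both keys counted 1/2.
Win-count aggregation is used; a staged-knockout aggregation would be an
alternative reading of "tournament" and the ranking function is isolated so
it can be swapped. In `all_pairs` mode at least 3 participants per class are
required — with only 2, holding out both members of a class would leave a
single-class training fold.

The demographic comparison model (age, sex as a binary indicator, years of
education, after group-median imputation) runs through the identical TLPO
loop, as does the PACC5 model with the single composite score as its only
feature.

## ROC inference

`auc_mw()` is the Mann–Whitney estimator with half-ties. `delong_ci()`
computes the nonparametric DeLong variance from per-class structural
components — algebraically identical to the per-class leave-one-out
jackknife, which is how the tests cross-check it to 1e-6 alongside the pROC
reference implementation — with a Wald interval and a two-sided z test
against 0.5. Degenerate variance (e.g. perfect separation) collapses the CI
to a point and is flagged rather than raising; the paired test
(`delong_test_paired()`) uses the convention z = 0, p = 1 when the variance
of the difference vanishes (identical scores). Two-sided tests are used
throughout.

`youden_metrics()` scans midpoints between adjacent distinct scores (plus
sentinels outside the range) for the threshold maximising J = Sn + Sp − 1;
among maximisers the one with the **higher specificity** wins, because in a
screening context fewer false positives is the preferred trade-off at equal
J. Cohen's kappa is computed from the 2×2 table at the chosen threshold,
pooled over all cross-validated participant scores (not per fold).

`auc_power()` uses Hanley–McNeil exponential-model variances under the null
(AUC 0.5) and the alternative in a two-sided normal approximation; both
rejection regions are counted, so power tends to α as the alternative
approaches chance. At the design anchor — AUC 0.75, 50 per group, α = 0.05 —
the power is 99.7%.

## Screening simulations

All screening outputs are expectations — deterministic functions of
prevalence and operating characteristics — because the published quantities
they mirror are exactly that; a binomial-draw mode exists behind a flag for
uncertainty bands. `build_population()` accepts age strata (weights summing
to 1, per-stratum prevalence) and pools by expected counts; with operating
characteristics constant across strata the stratified result equals the
pooled-prevalence result, a property the tests exercise.

*Primary-care MCI screening.* In a population of 1000 aged 65+ at aggregate
MCI prevalence 15.4%, the MMSE reference operating point (meta-analytic
pooled sensitivity 62.7%, specificity 63.3%) gives PPV 23.7% and NPV 90.3%.
The speech comparator is expressed through its *relative* changes — +8.5%
detection, −59.1% false positives — applied to the MMSE point
(`apply_relative_deltas()`), which raises NPV to 93.6% and PPV to 45.2%.
The relative reading is verified internally: only it reproduces the 93.6%
NPV from the MMSE operating point.

*PET pre-screening enrichment.* To confirm `N` Aβ+ participants at
prevalence `p`, routine scanning needs `N/p` scans. Pre-screening scans only
screen-positives: `N/(Sn·p)` recruits and `N/PPV` scans, so the scan
reduction is `1 − p/PPV` and the recruitment increase `1/Sn − 1` (a function
of sensitivity alone). Default prevalence presets: Aβ+ 0.559 within MCI and
0.249 within CU (65–85). Note the reduction identity can go below −1 for a
worse-than-useless pre-screen (PPV < p/2); the invariant worth having — an
enriching pre-screen never adds scans — holds whenever PPV ≥ p.

In `run_experiment()` both simulations are fed by the Youden operating
points the pipeline itself estimated on the synthetic cohort, so the
reported enrichment numbers are computed, never copied.

## Problem sizes and determinism

The packaged default experiment uses the full 193-participant design
(18 528 TLPO folds per full-sample task). The test suite and the
acceptance script run a proportionally scaled 60-participant cohort
(1 770 folds per full-sample task, ≈20 s per full run on one CPU), which is
ample for the strongly separable regime the defaults define. Every stochastic
step is seeded; identical configuration and seed give byte-identical report
JSON. Properties checked by simulation (null behaviour, CI coverage,
recovery against the single-feature theory AUC Φ(δ/√2)) use fixed seeds and
replicate counts stated in the tests.

## Known limitations

* The surrogate encoder measures lexical/sequential overlap, not meaning; a
  perfect paraphrase scores as poorly as an omission. Real-data AUCs from
  the neural encoder are out of scope and not reproduced here.
* The recall generator's degradation channels are stylised; group
  separability on synthetic data says nothing about effect sizes in real
  speech.
* Wald-type DeLong intervals undercover slightly at small n; no bootstrap
  alternative is provided.
* Age-stratified prevalence tables for the screening simulations are config
  slots the user must fill from the relevant meta-analyses; only the
  aggregate presets ship with the package.
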