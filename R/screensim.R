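# Deterministic screening simulations: primary-care MCI screening against
# the MMSE, and amyloid-PET pre-screening enrichment. All quantities are
# expectations (infinite-population arithmetic); a binomial-draw mode gives
# stochastic counts for uncertainty bands.

#' A screening test's operating characteristics
#'
#' @param name label.
#' @param sensitivity,specificity both in \[0, 1\].
#' @return A `screening_test` list.
#' @export
screening_test <- function(name, sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity), class = "screening_test")
}

#' Derive a comparator test from relative deltas
#'
#' Builds a test whose sensitivity is scaled by `1 + detection_delta`
#' relative to `base`, and whose false-positive rate `1 - Sp` is scaled by
#' `1 + fp_delta`. Used to express a comparator reported only through its
#' relative detection/false-positive changes against a reference test.
#'
#' @param base a [screening_test()].
#' @param detection_delta relative change in sensitivity (e.g. +0.085).
#' @param fp_delta relative change in the false-positive rate (e.g. -0.591).
#' @param name label for the derived test.
#' @return A [screening_test()].
#' @export
apply_relative_deltas <- function(base, detection_delta, fp_delta,
                                  name = paste0(base$name, "+deltas")) {
  screening_test(name,
                 sensitivity = base$sensitivity * (1 + detection_delta),
                 specificity = 1 - (1 - base$specificity) * (1 + fp_delta))
}

#' Build an age-stratified screening population
#'
#' @param strata data frame with columns `weight` (population proportions,
#'   summing to 1 within 1e-9) and `prevalence` (condition prevalence per
#'   stratum); optionally `age_band` labels. A single-stratum population is
#'   the degenerate case.
#' @param n population size.
#' @return A `screen_population`: the strata plus expected cases per stratum
#'   and the overall prevalence (weighted mean).
#' @export
build_population <- function(strata, n = 1000) {
  stopifnot(is.data.frame(strata), all(c("weight", "prevalence") %in% names(strata)))
  if (abs(sum(strata$weight) - 1) > 1e-9)
    stop("stratum weights must sum to 1")
  stopifnot(all(strata$prevalence >= 0 & strata$prevalence <= 1))
  strata$n <- n * strata$weight
  strata$expected_cases <- strata$n * strata$prevalence
  structure(list(strata = strata, n = n,
                 prevalence = sum(strata$weight * strata$prevalence)),
            class = "screen_population")
}

#' Expected screening outcomes of a test in a population
#'
#' Expectation arithmetic per stratum — TP = n p Sn, FP = n (1-p)(1-Sp),
#' FN = n p (1-Sn), TN = n (1-p) Sp — aggregated by pooled counts; PPV and
#' NPV by their definitions on the pooled 2x2 table. With
#' `stochastic = TRUE`, counts are single binomial draws instead of
#' expectations (for uncertainty bands).
#'
#' @param population a [build_population()].
#' @param test a [screening_test()].
#' @param stochastic draw binomial counts instead of expectations.
#' @return A `screen_outcome` list: `test`, `tp`, `fp`, `fn`, `tn`, `ppv`,
#'   `npv`, `detected`, `false_positives`.
#' @export
screen_outcomes <- function(population, test, stochastic = FALSE) {
  st <- population$strata
  sn <- test$sensitivity; sp <- test$specificity
  if (stochastic) {
    cases <- stats::rbinom(nrow(st), round(st$n), st$prevalence)
    tp <- stats::rbinom(nrow(st), cases, sn)
    fp <- stats::rbinom(nrow(st), round(st$n) - cases, 1 - sp)
    fn <- cases - tp
    tn <- round(st$n) - cases - fp
  } else {
    cases <- st$n * st$prevalence
    tp <- cases * sn
    fp <- (st$n - cases) * (1 - sp)
    fn <- cases * (1 - sn)
    tn <- (st$n - cases) * sp
  }
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn); TN <- sum(tn)
  structure(list(test = test$name, tp = TP, fp = FP, fn = FN, tn = TN,
                 ppv = TP / (TP + FP), npv = TN / (TN + FN),
                 detected = TP, false_positives = FP),
            class = "screen_outcome")
}

#' Compare two screening tests in the same population
#'
#' Relative change in detected cases (`Sn_A / Sn_B - 1`), relative change in
#' false positives (`(1 - Sp_A) / (1 - Sp_B) - 1`), and PPV/NPV under each
#' test. When `Sp_B = 1` and `Sp_A < 1` the relative false-positive change
#' is undefined and reported as `NA` with the absolute change only.
#'
#' @param test_a,test_b [screening_test()]s (A is the candidate, B the
#'   reference).
#' @param population a [build_population()].
#' @return List with `detection_delta`, `fp_delta`, `fp_delta_absolute`,
#'   `outcome_a`, `outcome_b`.
#' @export
compare_tests <- function(test_a, test_b, population) {
  oa <- screen_outcomes(population, test_a)
  ob <- screen_outcomes(population, test_b)
  fp_rate_a <- 1 - test_a$specificity
  fp_rate_b <- 1 - test_b$specificity
  fp_delta <- if (fp_rate_b == 0) {
    if (fp_rate_a == 0) 0 else NA_real_
  } else fp_rate_a / fp_rate_b - 1
  list(detection_delta = test_a$sensitivity / test_b$sensitivity - 1,
       fp_delta = fp_delta,
       fp_delta_absolute = oa$fp - ob$fp,
       outcome_a = oa, outcome_b = ob)
}

#' Amyloid-PET pre-screening enrichment
#'
#' To recruit a target number `n_target` of biomarker-positive participants:
#' without pre-screening, `n_target / p` PET scans are needed at prevalence
#' `p`. With a pre-screen of sensitivity Sn and specificity Sp, only
#' screen-positives are scanned: `n_target / (Sn p)` participants must be
#' recruited, and `n_target / PPV` scans performed, where
#' `PPV = Sn p / (Sn p + (1 - Sp)(1 - p))`. The scan reduction is
#' `1 - p / PPV` and the recruitment increase `1 / Sn - 1` (a function of
#' sensitivity only).
#'
#' @param prevalence biomarker-positive prevalence, in (0, 1).
#' @param prescreen a [screening_test()] with sensitivity > 0.
#' @param n_target required number of confirmed positives.
#' @return An `enrichment_result` list: `n_target`, `ppv`,
#'   `scans_without`, `scans_with`, `recruited_with`, `scan_reduction`,
#'   `recruitment_increase`.
#' @export
pet_enrichment <- function(prevalence, prescreen, n_target = 100) {
  stopifnot(prevalence > 0, prevalence < 1)
  sn <- prescreen$sensitivity; sp <- prescreen$specificity
  if (sn <= 0) stop("pre-screen sensitivity must be > 0 to reach the target")
  ppv <- sn * prevalence / (sn * prevalence + (1 - sp) * (1 - prevalence))
  structure(list(n_target = n_target, ppv = ppv,
                 scans_without = n_target / prevalence,
                 scans_with = n_target / ppv,
                 recruited_with = n_target / (sn * prevalence),
                 scan_reduction = 1 - prevalence / ppv,
                 recruitment_increase = 1 / sn - 1),
            class = "enrichment_result")
}

#' Shipped prevalence presets
#'
#' Aggregate prevalences used by the default screening scenarios: MCI in the
#' 65+ population (0.154), amyloid positivity within MCI (0.559) and within
#' cognitively unimpaired individuals aged 65-85 (0.249). Age-stratified
#' prevalence tables are scenario-config slots the user fills from the
#' relevant meta-analyses.
#'
#' @return Named numeric vector.
#' @export
prevalence_presets <- function() {
  c(mci_65plus = 0.154, abeta_in_mci = 0.559, abeta_in_cu = 0.249)
}

#' Reference MMSE operating point for MCI screening
#'
#' Meta-analytic pooled sensitivity 62.7% and specificity 63.3% of the MMSE
#' for detecting MCI, used as the comparator in the primary-care screening
#' scenario.
#'
#' @return A [screening_test()].
#' @export
mmse_reference_test <- function() screening_test("MMSE", 0.627, 0.633)
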