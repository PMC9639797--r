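# End-to-end experiment orchestration: simulate -> featurize -> TLPO
# evaluation -> ROC statistics -> screening simulations.

TASKS <- c("amyloid_full", "mci_full", "amyloid_in_mci", "amyloid_in_cu")

#' Experiment configuration
#'
#' Validated configuration for [run_experiment()]. Defaults run the full
#' synthetic study: the 2x2 cohort design, the three built-in stories, the
#' surrogate encoder, all four classification tasks, the demographic and
#' PACC5 comparison models, and both screening simulations.
#'
#' @param design a [group_design()].
#' @param stories character vector of source stories.
#' @param tasks subset of `"amyloid_full"`, `"mci_full"`, `"amyloid_in_mci"`,
#'   `"amyloid_in_cu"`.
#' @param encoder `"surrogate"` or a function `(a, b) -> named numeric
#'   vector` (see [story_vector()]).
#' @param tlpo_mode `"all_pairs"` or `"cross_label_pairs"`.
#' @param comparisons evaluate demographic and PACC5 comparison models and
#'   paired DeLong tests?
#' @param screening run the screening simulations (fed by the evaluated
#'   Youden operating points)?
#' @param remove_fillers drop fillers before encoding.
#' @param max_participants optional cap on total cohort size; group sizes
#'   are scaled proportionally (at least 2 per group) for scaled-down runs.
#' @param seed integer seed for cohort and recall generation.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(design = group_design(),
                              stories = asrt_stories(),
                              tasks = TASKS,
                              encoder = "surrogate",
                              tlpo_mode = "all_pairs",
                              comparisons = TRUE,
                              screening = TRUE,
                              remove_fillers = FALSE,
                              max_participants = NULL,
                              seed = 1L) {
  problems <- character()
  if (!length(tasks)) problems <- c(problems, "tasks: must be non-empty")
  if (!all(tasks %in% TASKS))
    problems <- c(problems, paste0("tasks: unknown task(s) ",
                                   paste(setdiff(tasks, TASKS), collapse = ", ")))
  if (!length(stories) || any(!nzchar(trimws(stories))))
    problems <- c(problems, "stories: need >= 1 non-empty story")
  if (!tlpo_mode %in% c("all_pairs", "cross_label_pairs"))
    problems <- c(problems, "tlpo_mode: must be all_pairs or cross_label_pairs")
  if (!(identical(encoder, "surrogate") || is.function(encoder)))
    problems <- c(problems, "encoder: must be \"surrogate\" or a function")
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    problems <- c(problems, "seed: must be an integer")
  if (length(problems))
    stop("invalid experiment config:\n  ", paste(problems, collapse = "\n  "))
  validate_group_design(design)
  if (!is.null(max_participants)) {
    scale <- max_participants / sum(design$sizes)
    design$sizes <- pmax(2L, as.integer(round(design$sizes * scale)))
  }
  structure(list(design = design, stories = stories, tasks = tasks,
                 encoder = encoder, tlpo_mode = tlpo_mode,
                 comparisons = comparisons, screening = screening,
                 remove_fillers = remove_fillers,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the
#' `design` section holds [group_design()] arguments.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  design <- if (is.null(raw$design)) group_design() else {
    if (!is.null(raw$design$cdr_probs))
      raw$design$cdr_probs <- matrix(unlist(raw$design$cdr_probs),
                                     nrow = 4L, byrow = TRUE)
    do.call(group_design, raw$design)
  }
  raw$design <- design
  do.call(experiment_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(serializable_config(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  if (is.function(cfg$encoder)) cfg$encoder <- "<custom function>"
  cfg$design <- unclass(cfg$design)
  cfg$design$cdr_probs <- apply(cfg$design$cdr_probs, 1L, identity,
                                simplify = FALSE)
  cfg
}

subset_for_task <- function(cohort, task) {
  switch(task,
         amyloid_full = list(cohort = cohort, label_task = "amyloid"),
         mci_full = list(cohort = cohort, label_task = "MCI"),
         amyloid_in_mci = list(cohort = cohort[cohort$diagnosis == "MCI", ],
                               label_task = "amyloid"),
         amyloid_in_cu = list(cohort = cohort[cohort$diagnosis == "CU", ],
                              label_task = "amyloid"),
         stop("unknown task: ", task))
}

evaluate_task <- function(task, cohort, vectors, config) {
  sel <- subset_for_task(cohort, task)
  sub <- sel$cohort
  models <- list()
  ds <- story_dataset(vectors, sub, sel$label_task)
  models$asrt <- tlpo_model_stats(ds, config$tlpo_mode)
  if (isTRUE(config$comparisons)) {
    models$demographics <- tlpo_model_stats(
      demographic_dataset(sub, sel$label_task), config$tlpo_mode)
    models$pacc5 <- tlpo_model_stats(
      pacc5_dataset(sub, sel$label_task), config$tlpo_mode)
    lab <- task_labels(sub, sel$label_task)
    models$asrt_vs_demographics <- delong_test_paired(
      models$asrt$cv_score[names(lab)],
      models$demographics$cv_score[names(lab)], lab)
    models$asrt_vs_pacc5 <- delong_test_paired(
      models$asrt$cv_score[names(lab)],
      models$pacc5$cv_score[names(lab)], lab)
  }
  models
}

tlpo_model_stats <- function(ds, mode) {
  res <- tlpo_auc(ds, mode = mode)
  labels <- ds$label[names(res$cv_score)]
  list(tlpo = res, auc = res$auc,
       cv_score = res$cv_score,
       delong = delong_ci(res$cv_score, labels),
       youden = youden_metrics(res$cv_score, labels))
}

#' Run the full synthetic screening experiment
#'
#' Generates the synthetic cohort and recalls, builds story vectors with the
#' configured encoder, evaluates each requested task with TLPO
#' cross-validation (story model plus optional demographic and PACC5
#' comparison models with paired DeLong tests), computes DeLong CIs and
#' Youden operating points on the cross-validated participant scores, and
#' (optionally) runs the two screening simulations fed by the evaluated
#' operating points. Identical config and seed give an identical report.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_report` list: `tasks` (per-task model stats),
#'   `screening`, `cohort`, `provenance` (config hash, seed, package
#'   version).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  encoder <- if (is.function(config$encoder)) config$encoder else pair_features
  cohort <- generate_cohort(config$design, seed = config$seed)
  records <- generate_recalls(cohort, config$stories, config$design,
                              seed = config$seed + 1L)
  vectors <- featurize_records(records, encoder, config$remove_fillers)
  cohort <- add_pacc5(cohort)
  tasks <- stats::setNames(
    lapply(config$tasks, evaluate_task, cohort = cohort, vectors = vectors,
           config = config),
    config$tasks)
  screening <- NULL
  if (isTRUE(config$screening)) {
    screening <- run_screening(screening_scenarios_from(tasks))
  }
  structure(list(tasks = tasks, screening = screening, cohort = cohort,
                 provenance = list(config_hash = config_hash(config),
                                   seed = config$seed,
                                   package_version =
                                     as.character(utils::packageVersion("recallscreen")))),
            class = "experiment_report")
}

# Build the screening scenario block from evaluated task operating points;
# tasks not evaluated fall back to the printed reference deltas only.
screening_scenarios_from <- function(tasks) {
  sc <- list()
  if (!is.null(tasks$mci_full)) {
    y <- tasks$mci_full$asrt$youden
    sc$mci_candidate <- screening_test("speech", y$sensitivity, y$specificity)
  }
  if (!is.null(tasks$amyloid_in_mci)) {
    y <- tasks$amyloid_in_mci$asrt$youden
    sc$pet_mci_prescreen <- screening_test("speech", y$sensitivity, y$specificity)
  }
  if (!is.null(tasks$amyloid_in_cu)) {
    y <- tasks$amyloid_in_cu$asrt$youden
    sc$pet_cu_prescreen <- screening_test("speech", y$sensitivity, y$specificity)
  }
  sc
}

#' Run the screening simulations
#'
#' Two deterministic simulations: (i) primary-care MCI screening in an age
#' 65+ population of 1000, comparing a candidate test against the pooled
#' MMSE reference operating point; (ii) amyloid-PET pre-screening
#' enrichment within MCI and within CU populations.
#'
#' @param scenario list with optional elements `mci_candidate`,
#'   `pet_mci_prescreen`, `pet_cu_prescreen` (each a [screening_test()]),
#'   and optional overrides `mci_prevalence`, `abeta_mci_prevalence`,
#'   `abeta_cu_prevalence`, `n`, `n_target`. Missing prevalences use
#'   [prevalence_presets()].
#' @return List with `mci` (a [compare_tests()] result plus the population)
#'   and `pet` (per-subgroup [pet_enrichment()] results).
#' @export
run_screening <- function(scenario = list()) {
  presets <- prevalence_presets()
  grab <- function(key, preset) {
    if (!is.null(scenario[[key]])) return(scenario[[key]])
    if (is.na(presets[preset])) stop("missing prevalence preset: ", preset)
    presets[[preset]]
  }
  out <- list()
  if (!is.null(scenario$mci_candidate)) {
    pop <- build_population(
      data.frame(weight = 1, prevalence = grab("mci_prevalence", "mci_65plus")),
      n = if (is.null(scenario$n)) 1000 else scenario$n)
    out$mci <- c(compare_tests(scenario$mci_candidate, mmse_reference_test(), pop),
                 list(population = pop))
  }
  nt <- if (is.null(scenario$n_target)) 100 else scenario$n_target
  pet <- list()
  if (!is.null(scenario$pet_mci_prescreen)) {
    pet$mci <- pet_enrichment(grab("abeta_mci_prevalence", "abeta_in_mci"),
                              scenario$pet_mci_prescreen, nt)
  }
  if (!is.null(scenario$pet_cu_prescreen)) {
    pet$cu <- pet_enrichment(grab("abeta_cu_prevalence", "abeta_in_cu"),
                             scenario$pet_cu_prescreen, nt)
  }
  if (length(pet)) out$pet <- pet
  out
}

#' Reference MCI screening comparison at the printed operating points
#'
#' The deterministic primary-care comparison that needs no model fit: the
#' MMSE reference operating point at the aggregate 65+ MCI prevalence, and a
#' comparator derived from relative deltas to detection and false positives.
#'
#' @param detection_delta,fp_delta relative deltas defining the comparator
#'   (defaults +8.5% detection, -59.1% false positives).
#' @param prevalence MCI prevalence (default preset 0.154).
#' @param n population size.
#' @return A [compare_tests()] result.
#' @export
reference_mci_screening <- function(detection_delta = 0.085,
                                    fp_delta = -0.591,
                                    prevalence = prevalence_presets()[["mci_65plus"]],
                                    n = 1000) {
  pop <- build_population(data.frame(weight = 1, prevalence = prevalence), n)
  mmse <- mmse_reference_test()
  speech <- apply_relative_deltas(mmse, detection_delta, fp_delta, "speech")
  compare_tests(speech, mmse, pop)
}

#' Flatten an experiment report to JSON
#'
#' @param report an `experiment_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "tlpo_result"))
      return(list(auc = x$auc, n_folds = x$n_folds, mode = x$mode))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- list(tasks = strip(report$tasks),
              screening = strip(report$screening),
              provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
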