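# Group labels for the 2x2 amyloid-by-diagnosis design.
# Group 1: amyloid-positive MCI/mild AD; Group 2: amyloid-negative MCI/mild AD;
# Group 3: amyloid-positive CU; Group 4: amyloid-negative CU.
GROUP_DIAGNOSIS <- c("MCI", "MCI", "CU", "CU")
GROUP_AMYLOID   <- c("positive", "negative", "positive", "negative")

PACC5_SUBTESTS <- c("mmse_z", "lmdr_z", "dsc_z", "fcsrt_z", "fluency_z")

#' Study design for the synthetic 2x2 amyloid-by-diagnosis cohort
#'
#' Defines group sizes, per-group demographic distributions and per-group
#' recall-degradation parameters for the synthetic cohort generator. Defaults
#' reproduce the recruited sample of the motivating case-control study: four
#' groups crossing amyloid status (positive/negative, by PET or CSF) with
#' clinical status (MCI/mild AD vs cognitively unimpaired, CU), sizes
#' 46/54/47/46, with group-specific age, education, MMSE and CDR-G
#' distributions. Ages are truncated to the eligibility window 50-85 years
#' and MMSE to its eligibility window (23-30 for MCI/mild AD, 26-30 for CU).
#'
#' The recall-degradation block parameterises the synthetic story-recall
#' generator: per-group token omission, substitution and filler-insertion
#' rates, plus an extra omission rate applied to delayed recall on top of
#' immediate recall. The defaults define a strongly separable regime in
#' which the two label axes of the 2x2 design act through distinct
#' channels: clinical status (MCI/mild AD vs CU) chiefly drives recall
#' completeness (omission and delayed-recall extra omission), while amyloid
#' status chiefly drives disfluency and accuracy (filler insertion and word
#' substitution). Without distinct channels the full-sample amyloid
#' contrast would be confounded with diagnosis severity and unlearnable by
#' construction. Omission, substitution and delayed extra-omission rates
#' must be at least as high in the MCI/mild-AD groups as in the CU groups.
#'
#' @param sizes integer vector of 4 group sizes (Groups 1-4).
#' @param age_mean,age_sd numeric vectors of 4 per-group age parameters (years).
#' @param edu_mean,edu_sd numeric vectors of 4 per-group education parameters
#'   (years).
#' @param female_frac numeric vector of 4 per-group probabilities of female sex.
#' @param mmse_mean,mmse_sd numeric vectors of 4 per-group MMSE parameters.
#' @param cdr_probs 4x3 matrix of per-group probabilities over CDR-G values
#'   0, 0.5, 1 (rows sum to 1).
#' @param omission_rate,substitution_rate,filler_rate,delayed_extra_omission
#'   numeric vectors of 4 per-group token-degradation rates in \[0, 1\].
#' @param pacc5_shift numeric vector of 4 per-group mean shifts of the PACC5
#'   subtest z-scores (CU amyloid-negative is the reference at 0).
#' @param edu_missing_rate probability a participant's education is missing
#'   (missing completely at random).
#' @param pacc5_missing_rate probability a participant has one or more PACC5
#'   subtests missing (missing completely at random).
#'
#' @return An object of class `group_design` (a validated list).
#' @export
group_design <- function(sizes = c(46L, 54L, 47L, 46L),
                         age_mean = c(72.72, 68.65, 71.43, 69.41),
                         age_sd = c(5.95, 7.45, 4.77, 4.10),
                         edu_mean = c(15.22, 14.92, 15.06, 15.75),
                         edu_sd = c(3.09, 2.81, 3.53, 3.08),
                         female_frac = c(21 / 46, 34 / 54, 27 / 47, 28 / 46),
                         mmse_mean = c(26.64, 26.89, 28.77, 28.78),
                         mmse_sd = c(2.18, 2.16, 1.43, 1.07),
                         cdr_probs = rbind(c(0.00, 0.86, 0.14),
                                           c(0.00, 0.92, 0.08),
                                           c(0.76, 0.24, 0.00),
                                           c(0.82, 0.18, 0.00)),
                         omission_rate = c(0.40, 0.35, 0.12, 0.08),
                         substitution_rate = c(0.10, 0.06, 0.05, 0.02),
                         filler_rate = c(0.28, 0.06, 0.22, 0.04),
                         delayed_extra_omission = c(0.15, 0.12, 0.05, 0.03),
                         pacc5_shift = c(-1.3, -1.1, -0.25, 0),
                         edu_missing_rate = 0.015,
                         pacc5_missing_rate = 0.115) {
  d <- list(sizes = as.integer(sizes), age_mean = age_mean, age_sd = age_sd,
            edu_mean = edu_mean, edu_sd = edu_sd, female_frac = female_frac,
            mmse_mean = mmse_mean, mmse_sd = mmse_sd, cdr_probs = cdr_probs,
            omission_rate = omission_rate,
            substitution_rate = substitution_rate,
            filler_rate = filler_rate,
            delayed_extra_omission = delayed_extra_omission,
            pacc5_shift = pacc5_shift,
            edu_missing_rate = edu_missing_rate,
            pacc5_missing_rate = pacc5_missing_rate)
  class(d) <- "group_design"
  validate_group_design(d)
  d
}

validate_group_design <- function(d) {
  stopifnot(inherits(d, "group_design"))
  len4 <- c("sizes", "age_mean", "age_sd", "edu_mean", "edu_sd",
            "female_frac", "mmse_mean", "mmse_sd", "omission_rate",
            "substitution_rate", "filler_rate", "delayed_extra_omission",
            "pacc5_shift")
  for (f in len4) {
    if (length(d[[f]]) != 4L) stop("invalid design: '", f, "' must have length 4")
  }
  if (any(d$sizes <= 0L)) stop("invalid design: group sizes must be positive")
  rates <- c(d$omission_rate, d$substitution_rate, d$filler_rate,
             d$delayed_extra_omission, d$female_frac,
             d$edu_missing_rate, d$pacc5_missing_rate)
  if (any(rates < 0 | rates > 1)) stop("invalid design: rates must lie in [0, 1]")
  # impaired groups must degrade at least as much as CU groups
  for (f in c("omission_rate", "substitution_rate", "delayed_extra_omission")) {
    if (min(d[[f]][1:2]) < max(d[[f]][3:4]) - 1e-12)
      stop("invalid design: MCI/mild-AD degradation rates must be >= CU rates ('", f, "')")
  }
  if (!is.matrix(d$cdr_probs) || any(dim(d$cdr_probs) != c(4L, 3L)) ||
      any(abs(rowSums(d$cdr_probs) - 1) > 1e-9))
    stop("invalid design: cdr_probs must be a 4x3 matrix with rows summing to 1")
  invisible(d)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  # inverse-CDF truncated normal: deterministic given the RNG stream
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic 2x2 amyloid-by-diagnosis cohort
#'
#' Draws one participant table from a [group_design()]: demographics
#' (age, sex, years of education), diagnosis (CU vs MCI/mild AD), amyloid
#' status, MMSE, CDR-G, and the five PACC5 subtest z-scores, with
#' missing-completely-at-random education and PACC5 values at the design's
#' rates. Group counts match the design exactly and output is deterministic
#' given `seed`.
#'
#' @param design a [group_design()].
#' @param seed integer seed.
#' @return A data frame with one row per participant: `id`, `site`, `group`
#'   (1-4), `diagnosis` ("CU"/"MCI"), `amyloid` ("positive"/"negative"),
#'   `age`, `sex` ("female"/"male"), `education`, `mmse`, `cdr_g`, and the
#'   five PACC5 subtest columns `mmse_z`, `lmdr_z`, `dsc_z`, `fcsrt_z`,
#'   `fluency_z`. Missing values are `NA`.
#' @export
generate_cohort <- function(design = group_design(), seed = 1L) {
  validate_group_design(design)
  set.seed(as.integer(seed))
  rows <- vector("list", 4L)
  offset <- 0L
  for (g in 1:4) {
    n <- design$sizes[g]
    age <- rnorm_trunc(n, design$age_mean[g], design$age_sd[g], 50, 85)
    edu <- round(pmax(6, stats::rnorm(n, design$edu_mean[g], design$edu_sd[g])))
    sex <- ifelse(stats::runif(n) < design$female_frac[g], "female", "male")
    mmse_lo <- if (GROUP_DIAGNOSIS[g] == "CU") 26L else 23L
    mmse <- as.integer(round(rnorm_trunc(n, design$mmse_mean[g],
                                         design$mmse_sd[g], mmse_lo - 0.49, 30.49)))
    mmse <- pmin(30L, pmax(mmse_lo, mmse))
    cdr <- c(0, 0.5, 1)[1L + findInterval(stats::runif(n),
                                          cumsum(design$cdr_probs[g, ])[1:2] + 1e-15)]
    pacc <- matrix(stats::rnorm(n * 5L, design$pacc5_shift[g], 1), nrow = n)
    colnames(pacc) <- PACC5_SUBTESTS
    # MCAR missingness: participant-level for PACC5 (one or two subtests lost)
    edu[stats::runif(n) < design$edu_missing_rate] <- NA
    hit <- which(stats::runif(n) < design$pacc5_missing_rate)
    for (i in hit) {
      k <- sample.int(2L, 1L)
      pacc[i, sample.int(5L, k)] <- NA
    }
    rows[[g]] <- data.frame(
      id = sprintf("P%03d", offset + seq_len(n)),
      site = ifelse(stats::runif(n) < 0.5, "UK", "US"),
      group = g,
      diagnosis = GROUP_DIAGNOSIS[g],
      amyloid = GROUP_AMYLOID[g],
      age = age,
      sex = sex,
      education = edu,
      mmse = mmse,
      cdr_g = cdr,
      stringsAsFactors = FALSE
    )
    rows[[g]] <- cbind(rows[[g]], as.data.frame(pacc))
    offset <- offset + n
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort
}

#' Built-in synthetic source stories
#'
#' Three short narrative texts standing in for the long story stimuli of an
#' automatic story recall task. They are synthetic compositions written for
#' this package (not the copyrighted study stimuli) with everyday episodic
#' content of roughly matched length.
#'
#' @return Named character vector of 3 stories.
#' @export
asrt_stories <- function() {
  c(story1 = paste(
      "On a bright Tuesday morning Margaret Wilson took the early bus from",
      "her house on Elm Street to the central market in town. She bought",
      "fresh bread, a dozen brown eggs, two bags of apples and a small jar",
      "of honey from the stall near the fountain. On her way home she met",
      "her neighbour Thomas, who told her that the library would open a new",
      "reading room on Friday. Margaret promised to visit the reading room",
      "with her granddaughter Lucy after school. When she finally reached",
      "home she realised she had left the honey on the bus, so she wrote a",
      "note to remind herself to buy another jar next week."),
    story2 = paste(
      "Last summer David Carter and his brother drove along the coast road",
      "to the small fishing village of Port Annan. They rented a blue",
      "wooden boat from an old fisherman called Joseph and spent the",
      "afternoon on the calm water near the lighthouse. David caught three",
      "silver mackerel while his brother read a newspaper under a wide",
      "straw hat. In the evening they cooked the fish on the beach over a",
      "driftwood fire and watched the ferry cross the bay towards the",
      "islands. Before leaving they thanked Joseph and bought two postcards",
      "of the lighthouse to send to their parents in the city."),
    story3 = paste(
      "The school in Mill Lane held its spring fair on the last Saturday",
      "of April. Teachers set up long tables in the playground with cakes,",
      "books and painted flower pots made by the children. Anna Brooks,",
      "the head teacher, opened the fair at ten o'clock and announced that",
      "the money raised would pay for new instruments for the school band.",
      "A sudden shower at noon sent everyone into the hall, where the choir",
      "sang while parents drank tea. By four o'clock the sun had returned,",
      "the stalls were nearly empty, and the fair had raised six hundred",
      "and forty pounds for the band."))
}

degrade_tokens <- function(tokens, omission, substitution, filler, vocab) {
  keep <- stats::runif(length(tokens)) >= omission
  out <- tokens[keep]
  if (length(out)) {
    sub <- stats::runif(length(out)) < substitution
    if (any(sub)) out[sub] <- vocab[sample.int(length(vocab), sum(sub), replace = TRUE)]
  }
  fill <- c("um", "uh", "er", "you", "know", "well")
  nfill <- stats::rbinom(1L, max(length(tokens), 1L), filler)
  if (nfill > 0L && length(out)) {
    fills <- fill[sample.int(length(fill), nfill, replace = TRUE)]
    slots <- sample.int(length(out) + 1L, nfill, replace = TRUE) - 1L
    ord <- order(c(seq_along(out), slots + 0.5))
    out <- c(out, fills)[ord]
  }
  if (!length(out)) out <- fill[sample.int(length(fill), 1L)]
  out
}

#' Generate synthetic story-recall transcripts for a cohort
#'
#' Produces one record per participant and story. Immediate recall is derived
#' from the source text by token-level omission, substitution and
#' filler-insertion at the participant's group rates; delayed recall applies
#' the group's extra omission rate on top of the immediate recall. This is a
#' deliberately simple degradation model standing in for recorded and
#' transcribed human recalls.
#'
#' @param cohort data frame from [generate_cohort()].
#' @param source_stories character vector of >= 1 non-empty story texts
#'   (default [asrt_stories()]).
#' @param design the [group_design()] providing per-group degradation rates.
#' @param seed integer seed.
#' @return A data frame of records: `participant_id`, `story_id`,
#'   `source_text`, `immediate_recall`, `delayed_recall`, `transcript_kind`
#'   (always "synthetic").
#' @export
generate_recalls <- function(cohort, source_stories = asrt_stories(),
                             design = group_design(), seed = 1L) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  if (length(source_stories) < 1L) stop("need at least one source story")
  if (any(!nzchar(trimws(source_stories)))) stop("empty source story")
  validate_group_design(design)
  set.seed(as.integer(seed))
  story_tokens <- lapply(source_stories, function(s) normalize_transcript(s)$tokens)
  vocab <- unique(unlist(story_tokens))
  out <- vector("list", nrow(cohort) * length(source_stories))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    g <- cohort$group[i]
    for (s in seq_along(source_stories)) {
      imm <- degrade_tokens(story_tokens[[s]], design$omission_rate[g],
                            design$substitution_rate[g], design$filler_rate[g],
                            vocab)
      extra <- design$delayed_extra_omission[g]
      keep <- stats::runif(length(imm)) >= extra
      del <- imm[keep]
      if (!length(del)) del <- imm[1L]
      k <- k + 1L
      out[[k]] <- data.frame(participant_id = cohort$id[i], story_id = s,
                             source_text = source_stories[[s]],
                             immediate_recall = paste(imm, collapse = " "),
                             delayed_recall = paste(del, collapse = " "),
                             transcript_kind = "synthetic",
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' PACC5 composite z-score
#'
#' The preclinical Alzheimer cognitive composite is the arithmetic mean of
#' the five subtest z-scores. When subtests are missing the composite is the
#' mean of the available z-scores; if all five are missing the result is
#' `NA` (a missing-output marker, never zero).
#'
#' @param subtest_z numeric vector of up to five z-scores (`NA` = missing).
#' @return The composite z-score, or `NA_real_` if nothing is available.
#' @export
pacc5_composite <- function(subtest_z) {
  z <- as.numeric(subtest_z)
  if (all(is.na(z))) return(NA_real_)
  mean(z, na.rm = TRUE)
}

#' Add the PACC5 composite column to a cohort
#'
#' @param cohort data frame with the five PACC5 subtest columns.
#' @return The cohort with a `pacc5` column ([pacc5_composite()] per row).
#' @export
add_pacc5 <- function(cohort) {
  m <- as.matrix(cohort[, PACC5_SUBTESTS, drop = FALSE])
  cohort$pacc5 <- apply(m, 1L, pacc5_composite)
  cohort
}

#' Impute missing years of education with the sample median
#'
#' Missing education values are replaced with the median over the non-missing
#' values of the analysis sample. An even count uses the mean-of-the-two-middle
#' values convention.
#'
#' @param cohort data frame with an `education` column.
#' @return The cohort with missing education imputed; all else unchanged.
#' @export
impute_education <- function(cohort) {
  edu <- cohort$education
  if (all(is.na(edu))) stop("cannot impute: all education values are missing")
  edu[is.na(edu)] <- stats::median(edu, na.rm = TRUE)
  cohort$education <- edu
  cohort
}

#' Read/write cohort tables and transcript records
#'
#' Cohorts are plain CSV, one row per participant, missing values as empty
#' fields. Transcript records are JSON-lines, one object per record (UTF-8).
#'
#' @param cohort,records data frames as produced by [generate_cohort()] and
#'   [generate_recalls()].
#' @param path file path.
#' @return The written path (writers, invisibly) or the read data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}

#' @rdname write_cohort_csv
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l),
                                                  stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Read transcripts from a directory of text files
#'
#' Expects files named `<participant_id>_story<k>_<slot>.txt` with slot one of
#' `source`, `immediate`, `delayed`; a complete record needs all three slots.
#'
#' @param dir directory path.
#' @param transcript_kind tag stored on each record.
#' @return A records data frame as from [generate_recalls()].
#' @export
read_records_dir <- function(dir, transcript_kind = "manual") {
  files <- list.files(dir, pattern = "_story[0-9]+_(source|immediate|delayed)\\.txt$")
  if (!length(files)) stop("no transcript files found in ", dir)
  m <- regmatches(files, regexec("^(.*)_story([0-9]+)_(source|immediate|delayed)\\.txt$", files))
  info <- do.call(rbind, lapply(m, function(x) x[2:4]))
  keys <- unique(info[, 1:2, drop = FALSE])
  out <- apply(keys, 1L, function(k) {
    slot <- function(s) {
      f <- files[info[, 1] == k[1] & info[, 2] == k[2] & info[, 3] == s]
      if (length(f) != 1L) stop("missing or duplicated '", s, "' for ", k[1],
                                " story ", k[2])
      paste(readLines(file.path(dir, f), encoding = "UTF-8", warn = FALSE),
            collapse = " ")
    }
    data.frame(participant_id = k[1], story_id = as.integer(k[2]),
               source_text = slot("source"), immediate_recall = slot("immediate"),
               delayed_recall = slot("delayed"), transcript_kind = transcript_kind,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant_id, res$story_id), ]
}
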