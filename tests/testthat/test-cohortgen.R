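test_that("default design reproduces the 2x2 group structure exactly", {
  cohort <- generate_cohort(group_design(), seed = 3)
  counts <- table(cohort$diagnosis, cohort$amyloid)
  expect_equal(unname(counts["CU", "positive"]), 47)
  expect_equal(unname(counts["CU", "negative"]), 46)
  expect_equal(unname(counts["MCI", "positive"]), 46)
  expect_equal(unname(counts["MCI", "negative"]), 54)
  expect_equal(as.vector(table(cohort$group)), c(46, 54, 47, 46))
})

test_that("cohort generation is deterministic and respects eligibility windows", {
  d <- tiny_design()
  a <- generate_cohort(d, seed = 11)
  b <- generate_cohort(d, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(d, seed = 12)))
  big <- generate_cohort(group_design(), seed = 5)
  expect_true(all(big$age >= 50 & big$age <= 85))
  mci <- big$diagnosis == "MCI"
  expect_true(all(big$mmse[mci] >= 23 & big$mmse[mci] <= 30))
  expect_true(all(big$mmse[!mci] >= 26 & big$mmse[!mci] <= 30))
  expect_true(all(big$cdr_g %in% c(0, 0.5, 1)))
})

test_that("degenerate age SD collapses a group to its mean", {
  d <- tiny_design(age_sd = c(0, 0, 0, 0))
  cohort <- generate_cohort(d, seed = 1)
  for (g in 1:4) {
    expect_true(all(cohort$age[cohort$group == g] == d$age_mean[g]))
  }
})

test_that("invalid designs are rejected", {
  expect_error(group_design(sizes = c(0, 5, 5, 5)), "positive")
  expect_error(group_design(omission_rate = c(0.1, 0.1, 0.1, 1.2)), "\\[0, 1\\]")
  # impaired groups must degrade at least as much as CU groups
  expect_error(group_design(omission_rate = c(0.05, 0.05, 0.3, 0.3)), ">=")
})

test_that("recall generation is seeded, complete and identity at zero rates", {
  d <- tiny_design(omission_rate = rep(0, 4), substitution_rate = rep(0, 4),
                   filler_rate = rep(0, 4), delayed_extra_omission = rep(0, 4))
  cohort <- generate_cohort(d, seed = 2)
  rec <- generate_recalls(cohort, asrt_stories(), d, seed = 2)
  expect_equal(nrow(rec), nrow(cohort) * 3L)
  expect_identical(rec, generate_recalls(cohort, asrt_stories(), d, seed = 2))
  src <- normalize_transcript(rec$source_text[1])$tokens
  expect_identical(normalize_transcript(rec$immediate_recall[1])$tokens, src)
  expect_identical(normalize_transcript(rec$delayed_recall[1])$tokens, src)
  expect_error(generate_recalls(cohort, "  ", d, seed = 1), "empty")
  expect_error(generate_recalls(cohort[0, ], asrt_stories(), d), "empty")
})

test_that("retained-token fraction decreases in the omission rate", {
  rates <- c(0.1, 0.3, 0.5)
  retained <- vapply(seq_along(rates), function(k) {
    r <- rates[k]
    d <- group_design(sizes = rep(12L, 4L), omission_rate = rep(r, 4),
                      substitution_rate = rep(0, 4), filler_rate = rep(0, 4),
                      delayed_extra_omission = rep(0, 4))
    cohort <- generate_cohort(d, seed = 40 + k)
    rec <- generate_recalls(cohort, asrt_stories(), d, seed = 40 + k)
    expect_gte(nrow(rec), 100)  # >= 100 simulated recalls per rate
    mean(vapply(seq_len(nrow(rec)), function(i) {
      length(normalize_transcript(rec$immediate_recall[i])$tokens) /
        length(normalize_transcript(rec$source_text[i])$tokens)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(retained) < 0))
  expect_lt(retained[3], retained[1])
})

test_that("PACC5 composite averages available subtests only", {
  expect_equal(pacc5_composite(c(0, 0, 0, 0, 0)), 0)
  expect_equal(pacc5_composite(c(1, 1, 1, 1, 1)), 1)
  expect_equal(pacc5_composite(c(1.0, 0.5, NA, NA, 0.0)), 0.5)
  expect_true(is.na(pacc5_composite(rep(NA_real_, 5))))
  # order invariance, and full mean when complete
  z <- c(0.3, -0.2, 1.1, 0.4, -0.9)
  expect_equal(pacc5_composite(z), mean(z))
  expect_equal(pacc5_composite(rev(z)), pacc5_composite(z))
})

test_that("education imputation uses the analysis-sample median", {
  co <- data.frame(id = letters[1:4], education = c(12, 16, 20, NA))
  expect_equal(impute_education(co)$education, c(12, 16, 20, 16))
  co2 <- data.frame(id = letters[1:3], education = c(12, 16, NA))
  expect_equal(impute_education(co2)$education[3], 14)  # mean-of-middle
  co3 <- data.frame(id = letters[1:3], education = c(12, 16, 18))
  expect_identical(impute_education(co3), co3)
  expect_error(impute_education(data.frame(education = c(NA_real_, NA_real_))),
               "all education")
})

test_that("cohort CSV and records JSON-lines round-trip", {
  d <- tiny_design()
  cohort <- generate_cohort(d, seed = 9)
  rec <- generate_recalls(cohort[1:3, ], asrt_stories()[1:2], d, seed = 9)
  csv <- tempfile(fileext = ".csv"); jl <- tempfile(fileext = ".jsonl")
  write_cohort_csv(cohort, csv)
  back <- read_cohort_csv(csv)
  expect_equal(back$id, cohort$id)
  expect_equal(back$education, cohort$education)
  expect_equal(back$mmse_z, cohort$mmse_z, tolerance = 1e-12)
  write_records_jsonl(rec, jl)
  back2 <- read_records_jsonl(jl)
  expect_equal(back2$immediate_recall, rec$immediate_recall)
  expect_equal(back2$story_id, rec$story_id)
})

test_that("directory-of-text-files reader assembles complete records", {
  dir <- tempfile(); dir.create(dir)
  writeLines("A story about a market.", file.path(dir, "P001_story1_source.txt"))
  writeLines("a story about market", file.path(dir, "P001_story1_immediate.txt"))
  writeLines("story market", file.path(dir, "P001_story1_delayed.txt"))
  rec <- read_records_dir(dir)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$participant_id, "P001")
  expect_equal(rec$delayed_recall, "story market")
  unlink(file.path(dir, "P001_story1_delayed.txt"))
  expect_error(read_records_dir(dir), "delayed")
})
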