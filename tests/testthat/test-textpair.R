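test_that("normalisation lower-cases, strips punctuation and handles fillers", {
  expect_identical(normalize_transcript("Um, the— the cat.",
                                        remove_fillers = TRUE)$tokens,
                   c("the", "the", "cat"))
  expect_identical(normalize_transcript("")$tokens, character(0))
  expect_identical(normalize_transcript("The Cat")$tokens, c("the", "cat"))
  # fillers retained but masked when not removed
  s <- normalize_transcript("um the cat")
  expect_identical(s$tokens, c("um", "the", "cat"))
  expect_identical(s$filler_mask, c(TRUE, FALSE, FALSE))
  # partial words: trailing plain hyphen marks, em-dash is punctuation
  p <- normalize_transcript("a wor- here")
  expect_identical(p$filler_mask, c(FALSE, TRUE, FALSE))
  expect_identical(normalize_transcript("a wor- here",
                                        remove_fillers = TRUE)$tokens,
                   c("a", "here"))
  expect_false(any(grepl("[[:upper:][:punct:]]",
                         normalize_transcript("It's a well-lit ROOM!")$tokens)))
})

test_that("word error rate matches hand counts and edge conventions", {
  expect_equal(word_error_rate("the quick brown fox", "the quick brown fox"), 0)
  expect_equal(word_error_rate("the quick brown fox", ""), 1)
  expect_equal(word_error_rate("the quick brown fox", "the brown fox"), 0.25)
  expect_error(word_error_rate("", "anything"), "empty")
  # invariant to fillers when removal is on
  expect_equal(word_error_rate("the cat sat", "um the uh cat er sat",
                               remove_fillers = TRUE), 0)
})

test_that("word error rate agrees with a character-level edit-distance oracle", {
  set.seed(101)
  vocab <- c("the", "cat", "sat", "on", "mat", "dog", "ran", "far", "big", "red")
  for (rep in 1:40) {
    ref <- sample(vocab, sample(3:12, 1), replace = TRUE)
    hyp <- sample(vocab, sample(0:14, 1), replace = TRUE)
    expect_equal(word_error_rate(ref, hyp, remove_fillers = FALSE),
                 oracle_wer(ref, hyp))
  }
})

test_that("corpus-level and mean-over-recordings WER aggregate as defined", {
  refs <- list(c("a", "b", "c", "d"), c("a", "b"))
  hyps <- list(c("a", "b", "c"), c("x", "b"))
  expect_equal(wer_summary(refs, hyps, "mean"), mean(c(1 / 4, 1 / 2)))
  expect_equal(wer_summary(refs, hyps, "corpus"), 2 / 6)
})

test_that("pair features satisfy their defining identities", {
  a <- c("the", "cat", "sat")
  id <- pair_features(a, a)
  expect_equal(unname(id["unigram_precision"]), 1)
  expect_equal(unname(id["unigram_recall"]), 1)
  expect_equal(unname(id["length_ratio"]), 1)
  expect_equal(unname(pair_features(a, c("dog", "ran"))["unigram_precision"]), 0)
  expect_equal(unname(pair_features(a, c("the", "dog", "sat"))["unigram_precision"]),
               2 / 3)
  # direction sensitivity
  b <- c("the", "cat")
  expect_equal(unname(pair_features(a, b)["unigram_precision"]), 2 / 3)
  expect_equal(unname(pair_features(b, a)["unigram_precision"]), 1)
  # purity / determinism
  expect_identical(pair_features(a, b), pair_features(a, b))
  expect_warning(v0 <- pair_features(character(0), character(0)), "empty")
  expect_true(all(v0 == 0))
})

test_that("all bounded features stay in [0, 1] under fuzzed inputs", {
  set.seed(77)
  vocab <- c(letters[1:8], "um", "uh")
  for (rep in 1:60) {
    a <- sample(vocab, sample(0:15, 1), replace = TRUE)
    b <- sample(vocab, sample(0:15, 1), replace = TRUE)
    if (!length(a) && !length(b)) next
    v <- pair_features(a, b)
    expect_equal(length(v), length(pair_feature_schema()))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("story vector is the mean of the six directed pair vectors", {
  rec <- list(source_text = "The cat sat on the mat near the door.",
              immediate_recall = "um the cat sat on a mat",
              delayed_recall = "the cat was on the mat")
  sv <- story_vector(rec)
  src <- normalize_transcript(rec$source_text)
  ir <- normalize_transcript(rec$immediate_recall)
  dr <- normalize_transcript(rec$delayed_recall)
  manual <- (pair_features(src, ir) + pair_features(ir, src) +
             pair_features(src, dr) + pair_features(dr, src) +
             pair_features(ir, dr) + pair_features(dr, ir)) / 6
  expect_equal(sv, manual)
  # self-identical triplet collapses to pair_features of a text with itself
  same <- list(source_text = "a b c", immediate_recall = "a b c",
               delayed_recall = "a b c")
  expect_equal(story_vector(same), pair_features(c("a", "b", "c"), c("a", "b", "c")))
  expect_error(story_vector(list(source_text = "a", immediate_recall = "",
                                 delayed_recall = "b")), "immediate_recall")
})

test_that("any encoder honouring the contract can be swapped in", {
  mock <- function(a, b) c(f1 = 0.25, f2 = 0.5)
  rec <- list(source_text = "a b", immediate_recall = "a", delayed_recall = "b")
  expect_equal(story_vector(rec, encoder = mock), c(f1 = 0.25, f2 = 0.5))
  recs <- data.frame(participant_id = c("p1", "p1"), story_id = 1:2,
                     source_text = "a b", immediate_recall = "a",
                     delayed_recall = "b", stringsAsFactors = FALSE)
  out <- featurize_records(recs, encoder = mock)
  expect_identical(names(out), c("participant_id", "story_id", "f1", "f2"))
  expect_true(all(out$f1 == 0.25))
})

test_that("story-vector CSV writer emits the sidecar schema", {
  recs <- data.frame(participant_id = "p1", story_id = 1L,
                     source_text = "the cat sat", immediate_recall = "the cat",
                     delayed_recall = "cat", stringsAsFactors = FALSE)
  v <- featurize_records(recs)
  path <- tempfile(fileext = ".csv")
  write_story_vectors(v, path)
  expect_true(file.exists(paste0(path, ".schema.json")))
  schema <- jsonlite::fromJSON(paste0(path, ".schema.json"))
  expect_identical(schema$features, pair_feature_schema())
})
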