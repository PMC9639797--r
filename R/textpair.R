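# Transcript normalisation, word error rate and the directed text-pair
# feature surrogate. The feature extractor stands behind a small encoder
# interface so that any text-pair model producing a fixed-length numeric
# vector can be swapped in.

DEFAULT_FILLERS <- c("um", "uh", "er", "erm", "uhm", "mm", "hmm", "mhm", "ah", "eh")

STOPWORDS <- c("the", "a", "an", "and", "or", "but", "of", "to", "in", "on",
               "at", "by", "for", "with", "from", "that", "this", "it", "its",
               "was", "were", "is", "are", "be", "been", "had", "has", "have",
               "he", "she", "they", "his", "her", "their", "i", "we", "you",
               "so", "as", "while", "when", "where", "who", "which", "would")

#' Normalise a transcript into a token sequence
#'
#' Lower-cases the text, strips punctuation (hyphens and em-dashes become
#' separators), and tokenises on whitespace. Partial words are identified by
#' a trailing dash in the raw text (a manual-transcription convention) and
#' treated as fillers. With `remove_fillers = TRUE` tokens in the filler
#' lexicon and partial words are dropped; otherwise they are retained and
#' flagged in `filler_mask`.
#'
#' @param text a character string (may be empty).
#' @param remove_fillers drop filled pauses and partial words?
#' @param filler_lexicon filler word list (default `um, uh, er, ...`).
#' @return A `token_seq`: list with `tokens` (lowercase words, no
#'   punctuation) and `filler_mask` (logical, same length).
#' @export
normalize_transcript <- function(text, remove_fillers = FALSE,
                                 filler_lexicon = DEFAULT_FILLERS) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- gsub("'", "", x)              # apostrophes deleted, not separators
  # tag partial words (trailing plain hyphen, a manual-transcription
  # convention) with a sentinel that survives punctuation stripping;
  # em/en dashes are interruption punctuation, not partial-word markers
  x <- gsub("([\\p{L}\\p{N}']+)-+(?=\\s|$)", "\\1\001", x, perl = TRUE)
  x <- gsub("[-—–]+", " ", x)        # remaining dashes separate
  x <- gsub("[^\\p{L}\\p{N}'\001]+", " ", x, perl = TRUE)
  x <- gsub("(^|\\s)'+|'+(\\s|$)", " ", x)               # stray quote marks
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  partial <- grepl("\001$", tokens)
  tokens <- sub("\001$", "", tokens)
  mask <- partial | tokens %in% filler_lexicon
  if (remove_fillers) {
    tokens <- tokens[!mask]
    mask <- rep(FALSE, length(tokens))
  }
  structure(list(tokens = tokens, filler_mask = mask), class = "token_seq")
}

as_token_seq <- function(x) {
  if (inherits(x, "token_seq")) return(x)
  if (is.character(x) && length(x) == 1L) return(normalize_transcript(x))
  if (is.character(x)) {
    return(structure(list(tokens = x, filler_mask = rep(FALSE, length(x))),
                     class = "token_seq"))
  }
  stop("cannot interpret input as a token sequence")
}

token_edit_distance <- function(ref, hyp) {
  n <- length(ref); m <- length(hyp)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    sub_cost <- prev[1:m] + (ref[i] != hyp)
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(sub_cost[j], prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Word error rate between a reference and a hypothesis transcript
#'
#' The number of substitutions, insertions and deletions in a minimum
#' edit-distance alignment of the two token sequences, divided by the
#' reference length: the average number of errors per reference word.
#' Inputs may be raw strings (normalised internally) or `token_seq` objects.
#'
#' @param reference,hypothesis transcripts (string or `token_seq`);
#'   reference must be non-empty.
#' @param remove_fillers drop fillers/partial words before comparison
#'   (applied when inputs are raw strings or carry a filler mask).
#' @return WER, a non-negative number (can exceed 1 for long hypotheses).
#' @seealso [wer_summary()] for corpus-level and mean-over-recordings
#'   aggregation.
#' @export
word_error_rate <- function(reference, hypothesis, remove_fillers = TRUE) {
  ref <- wer_tokens(reference, remove_fillers)
  hyp <- wer_tokens(hypothesis, remove_fillers)
  if (length(ref) == 0L) stop("reference transcript is empty")
  token_edit_distance(ref, hyp) / length(ref)
}

wer_tokens <- function(x, remove_fillers) {
  if (is.character(x) && length(x) == 1L) {
    return(normalize_transcript(x, remove_fillers = remove_fillers)$tokens)
  }
  s <- as_token_seq(x)
  if (remove_fillers) s$tokens[!s$filler_mask] else s$tokens
}

#' Aggregate word error rates over a set of recordings
#'
#' @param references,hypotheses parallel lists/vectors of transcripts.
#' @param method `"mean"` (default): mean of per-recording WERs (average WER
#'   across recordings); `"corpus"`: total errors over total reference words.
#' @param remove_fillers see [word_error_rate()].
#' @return A single aggregated WER.
#' @export
wer_summary <- function(references, hypotheses, method = c("mean", "corpus"),
                        remove_fillers = TRUE) {
  method <- match.arg(method)
  stopifnot(length(references) == length(hypotheses), length(references) > 0L)
  refs <- lapply(references, wer_tokens, remove_fillers = remove_fillers)
  hyps <- lapply(hypotheses, wer_tokens, remove_fillers = remove_fillers)
  if (any(lengths(refs) == 0L)) stop("reference transcript is empty")
  errs <- mapply(token_edit_distance, refs, hyps)
  switch(method,
         mean = mean(errs / lengths(refs)),
         corpus = sum(errs) / sum(lengths(refs)))
}

#' Names of the surrogate text-pair features
#'
#' The deterministic surrogate encoder emits 16 named features for a directed
#' pair (a, b); all are bounded in \[0, 1\]. Direction-sensitive features
#' (n-gram precision/recall, LCS precision/recall) differ between (a, b) and
#' (b, a).
#'
#' @return Character vector of 16 feature names.
#' @export
pair_feature_schema <- function() {
  c("unigram_precision", "unigram_recall",
    "bigram_precision", "bigram_recall",
    "lcs_ratio", "lcs_precision", "lcs_recall",
    "length_ratio", "jaccard",
    "content_precision", "content_recall",
    "order_concordance",
    "filler_rate_a", "filler_rate_b",
    "repetition_a", "repetition_b")
}

ngrams <- function(tokens, n) {
  k <- length(tokens) - n + 1L
  if (k <= 0L) return(character())
  if (n == 1L) return(tokens)
  vapply(seq_len(k), function(i) paste(tokens[i:(i + n - 1L)], collapse = ""),
         character(1))
}

clipped_overlap <- function(a, b) {
  # sum over types of min(count in a, count in b)
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    match_score <- prev[1:m] + (a[i] == b)
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(match_score[j], prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

order_concordance <- function(a, b) {
  # concordance of first-occurrence order of shared types, mapped to [0, 1]
  shared <- intersect(unique(a), unique(b))
  k <- length(shared)
  if (k < 2L) return(if (k == 1L) 1 else 0)
  pa <- vapply(shared, function(t) match(t, a), integer(1))
  pb <- vapply(shared, function(t) match(t, b), integer(1))
  ord <- order(pa)
  pb <- pb[ord]
  conc <- 0L
  for (i in seq_len(k - 1L)) conc <- conc + sum(pb[(i + 1L):k] > pb[i])
  conc / (k * (k - 1L) / 2)
}

safe_ratio <- function(num, den) if (den > 0) num / den else 0

#' Surrogate text-pair feature vector for a directed pair
#'
#' Computes the 16-feature surrogate representation of the differences
#' between two token sequences: unigram/bigram clipped precision and recall,
#' longest-common-subsequence ratios, length ratio, Jaccard type overlap,
#' content-word (non-stopword) precision/recall, ordering concordance of
#' shared tokens, and per-side filler and repetition rates. Deterministic
#' and pure; all features lie in \[0, 1\].
#'
#' @param a,b token sequences (or raw strings, normalised internally with
#'   fillers retained and masked).
#' @return Named numeric vector following [pair_feature_schema()].
#' @export
pair_features <- function(a, b) {
  a <- as_token_seq(a); b <- as_token_seq(b)
  fa <- safe_ratio(sum(a$filler_mask), length(a$tokens))
  fb <- safe_ratio(sum(b$filler_mask), length(b$tokens))
  ta <- a$tokens[!a$filler_mask]
  tb <- b$tokens[!b$filler_mask]
  la <- length(ta); lb <- length(tb)
  if (la == 0L && lb == 0L) {
    warning("both sequences empty; returning all-zero feature vector")
    return(stats::setNames(numeric(16L), pair_feature_schema()))
  }
  uni <- clipped_overlap(ta, tb)
  bga <- ngrams(ta, 2L); bgb <- ngrams(tb, 2L)
  bi <- clipped_overlap(bga, bgb)
  lcs <- lcs_length(ta, tb)
  ca <- ta[!ta %in% STOPWORDS]; cb <- tb[!tb %in% STOPWORDS]
  cov <- clipped_overlap(ca, cb)
  v <- c(
    unigram_precision = safe_ratio(uni, la),
    unigram_recall = safe_ratio(uni, lb),
    bigram_precision = safe_ratio(bi, length(bga)),
    bigram_recall = safe_ratio(bi, length(bgb)),
    lcs_ratio = safe_ratio(lcs, max(la, lb)),
    lcs_precision = safe_ratio(lcs, la),
    lcs_recall = safe_ratio(lcs, lb),
    length_ratio = safe_ratio(min(la, lb), max(la, lb)),
    jaccard = safe_ratio(length(intersect(unique(ta), unique(tb))),
                         length(union(unique(ta), unique(tb)))),
    content_precision = safe_ratio(cov, length(ca)),
    content_recall = safe_ratio(cov, length(cb)),
    order_concordance = order_concordance(ta, tb),
    filler_rate_a = fa,
    filler_rate_b = fb,
    repetition_a = if (la > 0L) 1 - length(unique(ta)) / la else 0,
    repetition_b = if (lb > 0L) 1 - length(unique(tb)) / lb else 0
  )
  v
}

#' Per-story feature vector: mean over the six directed pairs
#'
#' A story-recall triplet (source text, immediate recall IR, delayed recall
#' DR) yields six directed pairs — source/IR, IR/source, source/DR, DR/source,
#' IR/DR, DR/IR — each encoded by the text-pair encoder; the story vector is
#' their element-wise arithmetic mean.
#'
#' @param record one transcript record (a list/row with `source_text`,
#'   `immediate_recall`, `delayed_recall`).
#' @param encoder a function `(a, b) -> named numeric vector` (default
#'   [pair_features()]); any encoder with this contract can be swapped in.
#' @param remove_fillers drop fillers before encoding.
#' @return Named numeric feature vector (the encoder's schema).
#' @export
story_vector <- function(record, encoder = pair_features, remove_fillers = FALSE) {
  for (slot in c("source_text", "immediate_recall", "delayed_recall")) {
    txt <- record[[slot]]
    if (is.null(txt) || is.na(txt) || !nzchar(trimws(txt)))
      stop("record is missing text for slot '", slot, "'")
  }
  src <- normalize_transcript(record$source_text, remove_fillers)
  ir <- normalize_transcript(record$immediate_recall, remove_fillers)
  dr <- normalize_transcript(record$delayed_recall, remove_fillers)
  pairs <- list(list(src, ir), list(ir, src), list(src, dr),
                list(dr, src), list(ir, dr), list(dr, ir))
  vecs <- lapply(pairs, function(p) encoder(p[[1]], p[[2]]))
  Reduce(`+`, vecs) / length(vecs)
}

#' Build the story-vector matrix for a set of transcript records
#'
#' @param records data frame from [generate_recalls()] (or the readers).
#' @param encoder,remove_fillers see [story_vector()].
#' @return Data frame: `participant_id`, `story_id`, then one column per
#'   feature.
#' @export
featurize_records <- function(records, encoder = pair_features,
                              remove_fillers = FALSE) {
  vecs <- lapply(seq_len(nrow(records)), function(i)
    story_vector(records[i, , drop = FALSE], encoder, remove_fillers))
  mat <- do.call(rbind, vecs)
  out <- data.frame(participant_id = records$participant_id,
                    story_id = records$story_id, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat))
}

#' Write a story-vector matrix as CSV with a sidecar schema
#'
#' @param vectors data frame from [featurize_records()].
#' @param path CSV path; the schema JSON is written alongside as
#'   `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_story_vectors <- function(vectors, path) {
  utils::write.csv(vectors, path, row.names = FALSE)
  feature_cols <- setdiff(names(vectors), c("participant_id", "story_id"))
  jsonlite::write_json(list(features = feature_cols),
                       paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}
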