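# Tournament leave-pair-out (TLPO) cross-validation.
#
# Every possible pair of participants is held out in turn; a
# ridge-penalised logistic regression is trained on the story vectors of
# all remaining participants (each story vector carries its participant's
# label), both held-out participants are scored by averaging their
# per-story predicted probabilities, and the pairwise outcomes are
# aggregated into a tournament ranking from which the AUC is computed.

#' Assemble a labelled dataset for TLPO evaluation
#'
#' Groups story vectors by participant and attaches a binary label per
#' participant. The same container also carries covariate-only designs
#' (demographics) or single-score designs (PACC5): any numeric matrix with
#' >= 1 row per participant works.
#'
#' @param x numeric matrix or data frame of features, one row per instance
#'   (story vector, or a single covariate row per participant).
#' @param participant character/int vector mapping rows of `x` to
#'   participants.
#' @param label named logical/0-1 vector of participant labels (names =
#'   participant ids), or an unnamed vector parallel to `unique(participant)`.
#' @return A `labeled_dataset`: list with `x` (matrix), `participant`,
#'   `ids` (unique participants) and `label` (0/1 per id).
#' @export
labeled_dataset <- function(x, participant, label) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(participant))
  ids <- unique(as.character(participant))
  if (!is.null(names(label))) {
    lab <- label[ids]
  } else {
    stopifnot(length(label) == length(ids))
    lab <- stats::setNames(label, ids)
  }
  lab <- as.integer(lab)
  if (any(is.na(lab)) || !all(lab %in% c(0L, 1L)))
    stop("labels must be binary (0/1) and available for every participant")
  if (any(tapply(seq_along(participant), participant, length) < 1L))
    stop("every participant needs at least one feature row")
  structure(list(x = x, participant = as.character(participant),
                 ids = ids, label = stats::setNames(lab, ids)),
            class = "labeled_dataset")
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

#' Ridge-penalised logistic regression (deterministic Newton solver)
#'
#' Minimises the penalised negative log-likelihood
#' `-sum(y*log(p) + (1-y)*log(1-p)) + (lambda/2) * ||beta||^2`
#' with an unpenalised intercept, after standardising each feature by the
#' training mean and SD. `lambda = 1` corresponds to unit
#' inverse-regularisation strength. Convergence at gradient sup-norm 1e-8;
#' the fit is deterministic.
#'
#' @param x numeric training matrix (instances x features).
#' @param y 0/1 instance labels (both classes must be present).
#' @param lambda ridge penalty on non-intercept coefficients.
#' @param tol gradient convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return A `ridge_logit` scorer: use [predict_prob()] or `fit$score(x)`.
#' @export
fit_ridge_logit <- function(x, y, lambda = 1, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("training fold contains a single class")
  std <- standardize_fit(x)
  xs <- sweep(sweep(x, 2L, std$mu), 2L, std$sd, `/`)
  X <- cbind(1, xs)
  p1 <- ncol(X)
  pen <- c(0, rep(lambda, p1 - 1L))
  beta <- numeric(p1)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    if (max(abs(grad)) < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    # halving safeguard: penalised log-likelihood must not decrease
    obj <- function(b) {
      e <- drop(X %*% b)
      lse <- ifelse(e > 30, e, log1p(exp(pmin(e, 30))))
      sum(y * e - lse) - sum(pen * b^2) / 2
    }
    f0 <- obj(beta)
    s <- 1
    repeat {
      cand <- beta + s * step
      if (obj(cand) >= f0 - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- cand
  }
  structure(list(beta = beta, mu = std$mu, sd = std$sd, lambda = lambda),
            class = "ridge_logit")
}

#' Predicted probabilities from a ridge logistic fit
#'
#' @param fit a `ridge_logit` from [fit_ridge_logit()].
#' @param x numeric matrix of instances.
#' @return Vector of probabilities in \[0, 1\].
#' @export
predict_prob <- function(fit, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2L, fit$mu), 2L, fit$sd, `/`)
  drop(stats::plogis(cbind(1, xs) %*% fit$beta))
}

#' Fit one TLPO training fold
#'
#' Trains the fold scorer on all story vectors of the training participants
#' (each instance labelled with its participant's label).
#'
#' @param data a [labeled_dataset()].
#' @param train_ids participant ids in the training fold.
#' @param classifier a function `(x, y) -> scorer` where `scorer(x)` (or
#'   [predict_prob()]) returns probabilities; default [fit_ridge_logit()].
#' @return The fitted scorer.
#' @export
fit_fold <- function(data, train_ids = data$ids,
                     classifier = fit_ridge_logit) {
  rows <- data$participant %in% train_ids
  y <- data$label[data$participant[rows]]
  classifier(data$x[rows, , drop = FALSE], y)
}

#' Participant-level score: average of per-story predictions
#'
#' @param fit a fitted scorer.
#' @param data a [labeled_dataset()].
#' @param id one participant id.
#' @return The arithmetic mean of the participant's story-level predicted
#'   probabilities.
#' @export
participant_score <- function(fit, data, id) {
  rows <- data$participant == id
  mean(predict_prob(fit, data$x[rows, , drop = FALSE]))
}

#' Tournament ranking from pairwise outcomes
#'
#' Participants are ordered by descending tournament win count; ties are
#' broken by descending mean cross-validated score, remaining ties by
#' participant id. Deterministic.
#'
#' @param wins named numeric vector of win counts.
#' @param mean_score named numeric vector of fallback scores (same ids).
#' @return Character vector of ids, best first.
#' @export
tournament_ranking <- function(wins, mean_score) {
  ids <- names(wins)
  ids[order(-wins, -mean_score[ids], ids)]
}

ranking_auc <- function(wins, mean_score, label) {
  # AUC = fraction of opposite-label pairs ordered correctly by
  # (win count, mean score); exact ties on both keys count 1/2
  ids <- names(wins)
  pos <- ids[label[ids] == 1L]
  neg <- ids[label[ids] == 0L]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      dw <- wins[[p]] - wins[[q]]
      ds <- mean_score[[p]] - mean_score[[q]]
      total <- total + if (dw > 0 || (dw == 0 && ds > 0)) 1
        else if (dw == 0 && ds == 0) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

#' Tournament leave-pair-out cross-validated AUC
#'
#' For each held-out pair of participants the classifier is refit on the
#' story vectors of all remaining participants and both held-out
#' participants are scored ([participant_score()]). Pairwise outcomes
#' (higher score wins; equal scores give half a win each) are aggregated
#' into a tournament ranking, and the AUC is the fraction of opposite-label
#' participant pairs ordered correctly by that ranking, ties counted 1/2.
#'
#' @param data a [labeled_dataset()] with >= 3 participants per class in
#'   `all_pairs` mode (>= 2 in `cross_label_pairs` mode).
#' @param classifier see [fit_fold()].
#' @param mode `"all_pairs"` (default; every possible pair is held out) or
#'   `"cross_label_pairs"` (only opposite-label pairs, the classical
#'   leave-pair-out AUC).
#' @return A `tlpo_result`: list with `auc`, `cv_score` (per-participant
#'   mean cross-validated score), `wins`, `ranking`, `n_folds`, `mode`.
#' @export
tlpo_auc <- function(data, classifier = fit_ridge_logit,
                     mode = c("all_pairs", "cross_label_pairs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "labeled_dataset"))
  n_min <- min(sum(data$label == 1L), sum(data$label == 0L))
  if (n_min < 2L)
    stop("need at least 2 participants per class")
  if (mode == "all_pairs" && n_min < 3L)
    stop("all_pairs mode needs at least 3 participants per class ",
         "(holding out both members of a 2-participant class would leave ",
         "a single-class training fold)")
  ids <- data$ids
  n <- length(ids)
  pairs <- utils::combn(n, 2L)
  if (mode == "cross_label_pairs") {
    keep <- data$label[ids[pairs[1L, ]]] != data$label[ids[pairs[2L, ]]]
    pairs <- pairs[, keep, drop = FALSE]
  }
  wins <- stats::setNames(numeric(n), ids)
  score_sum <- stats::setNames(numeric(n), ids)
  score_cnt <- stats::setNames(numeric(n), ids)
  # row indices per participant, precomputed once
  row_idx <- split(seq_along(data$participant), data$participant)[ids]
  for (k in seq_len(ncol(pairs))) {
    i <- ids[pairs[1L, k]]; j <- ids[pairs[2L, k]]
    train_rows <- -c(row_idx[[i]], row_idx[[j]])
    y <- data$label[data$participant[train_rows]]
    fit <- classifier(data$x[train_rows, , drop = FALSE], y)
    si <- mean(predict_prob(fit, data$x[row_idx[[i]], , drop = FALSE]))
    sj <- mean(predict_prob(fit, data$x[row_idx[[j]], , drop = FALSE]))
    if (si > sj) wins[i] <- wins[i] + 1
    else if (sj > si) wins[j] <- wins[j] + 1
    else { wins[i] <- wins[i] + 0.5; wins[j] <- wins[j] + 0.5 }
    score_sum[i] <- score_sum[i] + si; score_cnt[i] <- score_cnt[i] + 1
    score_sum[j] <- score_sum[j] + sj; score_cnt[j] <- score_cnt[j] + 1
  }
  mean_score <- ifelse(score_cnt > 0, score_sum / score_cnt, NA_real_)
  names(mean_score) <- ids
  structure(list(auc = ranking_auc(wins, mean_score, data$label),
                 cv_score = mean_score, wins = wins,
                 ranking = tournament_ranking(wins, mean_score),
                 n_folds = ncol(pairs), mode = mode),
            class = "tlpo_result")
}

#' @export
print.tlpo_result <- function(x, ...) {
  cat("Tournament leave-pair-out result\n",
      "  participants: ", length(x$wins), "   folds: ", x$n_folds,
      "   mode: ", x$mode, "\n",
      "  AUC: ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Build TLPO datasets for the standard model specifications
#'
#' Convenience constructors for the three model families evaluated against
#' each other: story-vector features, a demographic covariate model
#' (age, sex, years of education), and a single-score PACC5 model.
#'
#' @param vectors story-vector data frame from [featurize_records()].
#' @param cohort cohort data frame; education is median-imputed and the
#'   PACC5 composite computed if absent.
#' @param task `"amyloid"` (positive = 1) or `"MCI"` (MCI/mild AD = 1).
#' @return A [labeled_dataset()].
#' @export
story_dataset <- function(vectors, cohort, task = c("amyloid", "MCI")) {
  lab <- task_labels(cohort, match.arg(task))
  keep <- vectors$participant_id %in% names(lab)
  v <- vectors[keep, , drop = FALSE]
  feats <- setdiff(names(v), c("participant_id", "story_id"))
  labeled_dataset(v[, feats, drop = FALSE], v$participant_id, lab)
}

#' @rdname story_dataset
#' @export
demographic_dataset <- function(cohort, task = c("amyloid", "MCI")) {
  lab <- task_labels(cohort, match.arg(task))
  cohort <- impute_education(cohort)
  x <- cbind(age = cohort$age,
             sex = as.integer(cohort$sex == "female"),
             education = cohort$education)
  labeled_dataset(x, cohort$id, lab)
}

#' @rdname story_dataset
#' @export
pacc5_dataset <- function(cohort, task = c("amyloid", "MCI")) {
  lab <- task_labels(cohort, match.arg(task))
  if (is.null(cohort$pacc5)) cohort <- add_pacc5(cohort)
  if (any(is.na(cohort$pacc5)))
    stop("PACC5 composite missing for some participants")
  labeled_dataset(matrix(cohort$pacc5, ncol = 1L,
                         dimnames = list(NULL, "pacc5")),
                  cohort$id, lab)
}

task_labels <- function(cohort, task) {
  lab <- switch(task,
                amyloid = as.integer(cohort$amyloid == "positive"),
                MCI = as.integer(cohort$diagnosis == "MCI"))
  stats::setNames(lab, cohort$id)
}
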