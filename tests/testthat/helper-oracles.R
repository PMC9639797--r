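# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct likelihood maximisation via optim(),
# double-loop AUC counting, character-level edit distance via utils::adist,
# and exhaustive threshold search.

# --- logistic regression oracle: penalised likelihood via optim/BFGS -------
oracle_fit_logit <- function(x, y, lambda = 1) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sd, `/`)
  X <- cbind(1, xs)
  pen <- c(0, rep(lambda, ncol(X) - 1L))
  nll <- function(b) {
    e <- drop(X %*% b)
    lse <- ifelse(e > 30, e, log1p(exp(pmin(e, 30))))
    -sum(y * e - lse) + sum(pen * b^2) / 2
  }
  gr <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(crossprod(X, y - p)) + pen * b
  }
  fit <- stats::optim(numeric(ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  list(beta = fit$par, mu = mu, sd = sd)
}

oracle_predict_logit <- function(fit, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2L, fit$mu), 2L, fit$sd, `/`)
  drop(stats::plogis(cbind(1, xs) %*% fit$beta))
}

# --- brute-force TLPO: enumerate every pair, refit with the optim oracle ---
oracle_tlpo_auc <- function(x, participant, label, mode = "all_pairs") {
  x <- as.matrix(x)
  participant <- as.character(participant)
  ids <- unique(participant)
  lab <- label[ids]
  wins <- stats::setNames(numeric(length(ids)), ids)
  ssum <- wins; scnt <- wins
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      if (mode == "cross_label_pairs" && lab[a] == lab[b]) next
      i <- ids[a]; j <- ids[b]
      tr <- !(participant %in% c(i, j))
      fit <- oracle_fit_logit(x[tr, , drop = FALSE], lab[participant[tr]])
      si <- mean(oracle_predict_logit(fit, x[participant == i, , drop = FALSE]))
      sj <- mean(oracle_predict_logit(fit, x[participant == j, , drop = FALSE]))
      if (si > sj) wins[i] <- wins[i] + 1
      else if (sj > si) wins[j] <- wins[j] + 1
      else { wins[i] <- wins[i] + 0.5; wins[j] <- wins[j] + 0.5 }
      ssum[i] <- ssum[i] + si; scnt[i] <- scnt[i] + 1
      ssum[j] <- ssum[j] + sj; scnt[j] <- scnt[j] + 1
    }
  }
  ms <- ssum / pmax(scnt, 1)
  pos <- ids[lab == 1]; neg <- ids[lab == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    dw <- wins[[p]] - wins[[q]]; ds <- ms[[p]] - ms[[q]]
    tot <- tot + if (dw > 0 || (dw == 0 && ds > 0)) 1
      else if (dw == 0 && ds == 0) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# --- double-loop AUC (no ranks) --------------------------------------------
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# --- per-class leave-one-out jackknife variance of the AUC -----------------
oracle_jackknife_var <- function(scores, labels) {
  jack_class <- function(cls) {
    idx <- which(labels == cls)
    loo <- vapply(idx, function(i)
      oracle_auc(scores[-i], labels[-i]), numeric(1))
    (length(idx) - 1) / length(idx) * sum((loo - mean(loo))^2)
  }
  jack_class(1) + jack_class(0)
}

# --- exhaustive Youden search over a fine threshold grid -------------------
oracle_youden_j <- function(scores, labels) {
  grid <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  best <- -Inf
  for (tau in grid) {
    pred <- scores > tau
    sn <- sum(pred & labels == 1) / sum(labels == 1)
    sp <- sum(!pred & labels == 0) / sum(labels == 0)
    best <- max(best, sn + sp - 1)
  }
  best
}

# --- WER oracle: utils::adist on a token-to-character encoding -------------
oracle_wer <- function(ref_tokens, hyp_tokens) {
  vocab <- unique(c(ref_tokens, hyp_tokens))
  enc <- function(t) if (length(t)) intToUtf8(match(t, vocab) + 160L) else ""
  drop(utils::adist(enc(ref_tokens), enc(hyp_tokens))) / length(ref_tokens)
}

# --- small fixtures --------------------------------------------------------
tiny_design <- function(...) {
  group_design(sizes = c(6L, 6L, 6L, 6L), ...)
}

single_feature_dataset <- function(n_pos, n_neg, delta, seed) {
  set.seed(seed)
  x <- matrix(c(stats::rnorm(n_pos, delta), stats::rnorm(n_neg, 0)), ncol = 1)
  ids <- sprintf("s%03d", seq_len(n_pos + n_neg))
  labeled_dataset(x, ids, stats::setNames(rep(c(1L, 0L), c(n_pos, n_neg)), ids))
}
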