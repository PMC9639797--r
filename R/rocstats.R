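# ROC/AUC inference: Mann-Whitney AUC, DeLong variance and tests,
# Youden-index operating points with Cohen's kappa, and AUC-detection power.

check_labels <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  labels
}

#' Mann-Whitney AUC estimate
#'
#' Fraction of (positive, negative) score pairs correctly ordered, ties
#' counted 1/2.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (per positive), V01 (per negative)
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

delong_var <- function(comp) {
  m <- length(comp$v10); n <- length(comp$v01)
  s10 <- if (m > 1L) stats::var(comp$v10) else 0
  s01 <- if (n > 1L) stats::var(comp$v01) else 0
  s10 / m + s01 / n
}

#' DeLong confidence interval and against-chance test for one AUC
#'
#' Nonparametric (DeLong) variance of the Mann-Whitney AUC with a Wald
#' confidence interval, and a two-sided z test of AUC = 0.5. A zero-variance
#' (degenerate) case — e.g. perfect separation — collapses the CI to a point
#' and is flagged; the against-chance z is then `Inf` for AUC != 0.5 and 0
#' otherwise.
#'
#' @param scores,labels see [auc_mw()]; >= 2 per class.
#' @param level confidence level (default 0.95).
#' @return A `roc_result`: list with `auc`, `se`, `ci` (lower/upper), `z`,
#'   `p_value`, `level`, `degenerate`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_labels(scores, labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("need >= 2 observations per class")
  comp <- delong_components(scores, labels)
  v <- delong_var(comp)
  se <- sqrt(max(v, 0))
  degenerate <- se < .Machine$double.eps
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(1, pmax(0, comp$auc + c(-1, 1) * zq * se))
  if (degenerate) {
    z <- if (abs(comp$auc - 0.5) < .Machine$double.eps) 0 else Inf * sign(comp$auc - 0.5)
    p <- if (z == 0) 1 else 0
    ci <- c(comp$auc, comp$auc)
  } else {
    z <- (comp$auc - 0.5) / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc = comp$auc, se = se, ci = ci, z = z, p_value = p,
                 level = level, degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (SE %.4f), %g%% CI [%.4f, %.4f], z = %.3f, p = %.4g%s\n",
              x$auc, x$se, 100 * x$level, x$ci[1], x$ci[2], x$z, x$p_value,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' DeLong test for two correlated (paired) AUCs
#'
#' Compares AUCs of two score vectors computed on the same subjects, using
#' the covariance of their DeLong structural components. If the variance of
#' the difference is degenerate (e.g. identical scores) the convention
#' z = 0, p = 1 applies.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels common 0/1 labels.
#' @return List with `auc_a`, `auc_b`, `diff`, `se`, `z`, `p_value`.
#' @export
delong_test_paired <- function(scores_a, scores_b, labels) {
  labels <- check_labels(scores_a, labels)
  stopifnot(length(scores_a) == length(scores_b))
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff < .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, diff = d,
       se = sqrt(max(var_diff, 0)), z = z, p_value = p)
}

cohen_kappa_2x2 <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) return(0)
  (po - pe) / (1 - pe)
}

#' Operating point at Youden's index
#'
#' Scans candidate thresholds (midpoints between adjacent distinct scores,
#' plus sentinels below/above the score range) and returns the threshold
#' maximising Youden's J = sensitivity + specificity - 1. When several
#' thresholds attain the maximum J, the one with the higher specificity is
#' chosen (fewer false positives, the preferred trade-off in screening).
#' Cohen's kappa is computed from the binarisation at the chosen threshold.
#'
#' @param scores,labels see [auc_mw()].
#' @return A `threshold_metrics` list: `threshold`, `sensitivity`,
#'   `specificity`, `youden_j`, `kappa`.
#' @export
youden_metrics <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- NULL
  for (tau in cand) {
    pred <- scores > tau
    tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
    fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
    sn <- tp / (tp + fn); sp <- tn / (tn + fp)
    j <- sn + sp - 1
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 && sp > best$specificity)) {
      best <- list(threshold = tau, sensitivity = sn, specificity = sp,
                   youden_j = j,
                   kappa = cohen_kappa_2x2(tp, fp, fn, tn))
    }
  }
  structure(best, class = "threshold_metrics")
}

#' ROC curve points
#'
#' Sensitivity/specificity pairs over all candidate thresholds, for plotting
#' or export as CSV.
#'
#' @param scores,labels see [auc_mw()].
#' @return Data frame: `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_labels(scores, labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  do.call(rbind, lapply(cand, function(tau) {
    pred <- scores > tau
    data.frame(threshold = tau,
               sensitivity = sum(pred & labels == 1L) / sum(labels == 1L),
               specificity = sum(!pred & labels == 0L) / sum(labels == 0L))
  }))
}

# Hanley-McNeil AUC variance under the exponential model
hanley_mcneil_var <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
     (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Power to detect an AUC above chance
#'
#' Two-sided normal-approximation power for testing AUC = 0.5 against a
#' superior alternative, using Hanley-McNeil exponential-model variances
#' under the null and the alternative.
#'
#' @param n_pos,n_neg group sizes (>= 2).
#' @param auc_alt alternative AUC, in (0.5, 1).
#' @param alpha two-sided significance level.
#' @return Power in (0, 1).
#' @export
auc_power <- function(n_pos, n_neg, auc_alt, alpha = 0.05) {
  stopifnot(n_pos >= 2L, n_neg >= 2L, alpha > 0, alpha < 1)
  if (auc_alt <= 0.5 || auc_alt >= 1)
    stop("auc_alt must lie in (0.5, 1): superiority framing only")
  se0 <- sqrt(hanley_mcneil_var(0.5, n_pos, n_neg))
  se1 <- sqrt(hanley_mcneil_var(auc_alt, n_pos, n_neg))
  za <- stats::qnorm(1 - alpha / 2)
  d <- auc_alt - 0.5
  # both rejection regions of the two-sided test
  stats::pnorm((d - za * se0) / se1) + stats::pnorm((-d - za * se0) / se1)
}
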