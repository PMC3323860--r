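# Gaussian naive Bayes and the four accuracy criteria (AUC, 1-RMSE, SAR,
# F), plus the paired significance machinery used by the validation
# protocols.

#' Gaussian naive Bayes: fit on training data, predict probabilities
#'
#' Class-conditional univariate Gaussians per feature (variance floored at
#' `1e-9`), empirical class priors, posterior computed in log space and
#' normalized per sample.
#'
#' @param train_X,test_X Numeric matrices / data frames of continuous
#'   features (same columns).
#' @param train_y Binary training labels, both classes present.
#' @param threshold Posterior cutoff for the hard label (default 0.5).
#' @return A tibble with `prob` (posterior of class 1) and `label`
#'   (hard 0/1 call), one row per test sample.
#' @export
nb_fit_predict <- function(train_X, train_y, test_X, threshold = 0.5) {
  train_X <- as_feature_matrix(train_X)
  test_X <- as_feature_matrix(test_X)
  y <- as_binary(train_y)
  if (length(unique(y)) < 2) stop("single-class training target")
  stopifnot(ncol(train_X) == ncol(test_X))

  log_post <- vapply(c(0L, 1L), function(cls) {
    Xc <- train_X[y == cls, , drop = FALSE]
    mu <- colMeans(Xc)
    # unbiased per-class variance, floored so constant features stay finite
    s2 <- apply(Xc, 2, stats::var)
    s2 <- pmax(ifelse(is.finite(s2), s2, 0), 1e-9)
    ll <- -0.5 * sweep(sweep(test_X, 2, mu)^2, 2, s2, "/") -
      matrix(0.5 * log(2 * pi * s2), nrow(test_X), ncol(test_X), byrow = TRUE)
    rowSums(ll) + log(mean(y == cls))
  }, numeric(nrow(test_X)))
  log_post <- matrix(log_post, ncol = 2)
  mx <- pmax(log_post[, 1], log_post[, 2])
  p1 <- exp(log_post[, 2] - mx) /
    (exp(log_post[, 1] - mx) + exp(log_post[, 2] - mx))
  tibble::tibble(prob = p1, label = as.integer(p1 > threshold))
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation; tied scores count one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Root mean squared error of probabilistic predictions
#'
#' @param probs Predicted probabilities of class 1.
#' @param labels Binary 0/1 labels.
#' @return `sqrt(mean((probs - labels)^2))`.
#' @export
rmse <- function(probs, labels) {
  y <- as_binary(labels)
  sqrt(mean((probs - y)^2))
}

#' SAR composite score
#'
#' Arithmetic mean of accuracy, AUC and `1 - RMSE`.
#'
#' @param accuracy,auc,rmse The three component criteria.
#' @return SAR in `[0, 1]` when its inputs are.
#' @export
sar <- function(accuracy, auc, rmse) {
  (accuracy + auc + (1 - rmse)) / 3
}

#' Precision-recall F score for the positive class
#'
#' `2PR/(P+R)`; returns 0 when precision + recall is 0 (e.g. no positive
#' predictions).
#'
#' @param pred_labels Predicted 0/1 labels.
#' @param labels True 0/1 labels.
#' @return F score in `[0, 1]`.
#' @export
f_score <- function(pred_labels, labels) {
  yp <- as_binary(pred_labels)
  y <- as_binary(labels)
  tp <- sum(yp == 1L & y == 1L)
  fp <- sum(yp == 1L & y == 0L)
  fn <- sum(yp == 0L & y == 1L)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' All four accuracy criteria at once
#'
#' @param probs Posterior probabilities of class 1.
#' @param labels True 0/1 labels.
#' @param threshold Hard-label cutoff (default 0.5).
#' @return One-row tibble: `auc`, `one_minus_rmse`, `sar`, `f`, `n_test`.
#' @export
classification_metrics <- function(probs, labels, threshold = 0.5) {
  y <- as_binary(labels)
  hard <- as.integer(probs > threshold)
  a <- auc(probs, y)
  r <- rmse(probs, y)
  acc <- mean(hard == y)
  tibble::tibble(
    auc = a,
    one_minus_rmse = 1 - r,
    sar = sar(acc, a, r),
    f = f_score(hard, y),
    n_test = length(y)
  )
}

#' Paired comparison of two classifiers
#'
#' McNemar test on the discordant misclassifications (exact binomial;
#' p = 1 when there are no discordant pairs) and the Wilcoxon signed-rank
#' test on paired squared errors (zero differences dropped; p = 1 when all
#' differences are zero).
#'
#' @param err_a,err_b Logical/0-1 vectors: was each test sample
#'   misclassified by classifier A / B?
#' @param sq_err_a,sq_err_b Paired squared errors of the probabilistic
#'   predictions.
#' @return One-row tibble with `mcnemar_p` and `wilcoxon_p`.
#' @export
compare_classifiers <- function(err_a, err_b, sq_err_a, sq_err_b) {
  err_a <- as.logical(err_a)
  err_b <- as.logical(err_b)
  b <- sum(err_a & !err_b)
  c_ <- sum(!err_a & err_b)
  mcnemar_p <- if (b + c_ == 0) 1 else
    stats::binom.test(b, b + c_, p = 0.5)$p.value
  d <- sq_err_a - sq_err_b
  d <- d[d != 0]
  wilcoxon_p <- if (length(d) == 0) 1 else
    suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
  tibble::tibble(mcnemar_p = mcnemar_p, wilcoxon_p = wilcoxon_p)
}

#' Holm step-down multiple-testing adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")`: order-preserving,
#' never below the raw p-values, capped at 1.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "holm")
}
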