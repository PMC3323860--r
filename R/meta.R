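# Multi-study orchestration: survival binarization, correlation-level
# meta-analysis, and the holdout / leave-one-dataset-out validation
# protocols.

#' Binarize survival at a fixed horizon
#'
#' High risk (1) if the event occurred at or before the horizon; low risk
#' (0) if follow-up extends beyond it (with or without a later event).
#' Patients censored before the horizon are uninformative for the binary
#' outcome and are excluded via the mask.
#'
#' @param time Follow-up times (same unit as `horizon`, conventionally
#'   years), non-negative.
#' @param event 0/1 event indicators (1 = event observed at `time`).
#' @param horizon Classification horizon (default 5).
#' @return A tibble with `label` (0/1, `NA` when excluded) and `included`
#'   (logical mask).
#' @export
#' @examples
#' binarize_survival(c(3, 7, 2), c(1, 0, 0))
binarize_survival <- function(time, event, horizon = 5) {
  if (any(time < 0)) stop("negative survival time")
  event <- as_binary(event)
  label <- dplyr::case_when(
    event == 1L & time <= horizon ~ 1L,
    time > horizon ~ 0L,
    TRUE ~ NA_integer_
  )
  tibble::tibble(label = label, included = !is.na(label))
}

#' Meta-analytic pooled correlation
#'
#' Fisher z-transforms each study correlation, combines with
#' inverse-variance weights `n - 3`, and back-transforms. Studies with
#' `n < 4` carry no information at this weighting and are dropped with a
#' warning. With a single study the input correlation is returned.
#'
#' @param rho Per-study correlations, `|rho| < 1`.
#' @param n Per-study sample sizes.
#' @return The pooled correlation (scalar).
#' @export
#' @examples
#' pooled_correlation(c(0.3, 0.6), c(53, 103))
pooled_correlation <- function(rho, n) {
  if (length(rho) != length(n)) stop("`rho` and `n` must have equal length")
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  keep <- n >= 4
  if (!all(keep)) {
    warning(sum(!keep), " study(ies) with n < 4 dropped from the pool")
  }
  if (!any(keep)) stop("no study with n >= 4")
  if (sum(keep) == 1) return(rho[keep]) # single study: exact identity
  w <- n[keep] - 3
  tanh(sum(w * atanh(rho[keep])) / sum(w))
}

# ---- protocol internals ----------------------------------------------------

# Stratified half/half split on the primary target; retried until both
# halves contain both classes of every target (bounded attempts).
stratified_half_split <- function(Y, max_tries = 100) {
  n <- nrow(Y)
  y1 <- Y[, 1L]
  for (i in seq_len(max_tries)) {
    idx1 <- which(y1 == 1L)
    idx0 <- which(y1 == 0L)
    tr <- sort(c(sample(idx1, floor(length(idx1) / 2)),
                 sample(idx0, ceiling(length(idx0) / 2))))
    te <- setdiff(seq_len(n), tr)
    ok <- all(apply(Y[tr, , drop = FALSE], 2, function(y) length(unique(y)) == 2)) &&
      all(apply(Y[te, , drop = FALSE], 2, function(y) length(unique(y)) == 2))
    if (ok) return(list(train = tr, test = te))
  }
  stop("could not stratify a half/half split with both classes in both halves")
}

# Fit/evaluate naive Bayes on the pooled training halves for each (v,
# lambda), given a per-lambda ranking. Returns per-(v, lambda) metrics and
# the per-sample errors needed for win-loss testing.
evaluate_cells <- function(rankings, v_values, train_X, train_y, test_X, test_y) {
  purrr::map_dfr(names(rankings), function(lam_chr) {
    feats_all <- rankings[[lam_chr]]
    purrr::map_dfr(v_values, function(v) {
      feats <- feats_all[seq_len(v)]
      pred <- nb_fit_predict(train_X[, feats, drop = FALSE], train_y,
                             test_X[, feats, drop = FALSE])
      met <- classification_metrics(pred$prob, test_y)
      met$lambda <- as.numeric(lam_chr)
      met$v <- v
      met$errors <- list(pred$label != test_y)
      met$sq_errors <- list((pred$prob - test_y)^2)
      met$probs <- list(pred$prob)
      met
    })
  })
}

# Win-loss table: for each (v, lambda > 0), compare against lambda = 0
# per dataset on test predictions concatenated across repetitions; both
# the exact McNemar and the Wilcoxon-on-squared-errors test must be
# significant after Holm adjustment across datasets, and a win requires
# strictly fewer misclassifications.
win_loss_table <- function(errs, alpha = 0.05) {
  lambdas <- sort(unique(errs$lambda))
  if (!0 %in% lambdas) return(tibble::tibble())
  purrr::map_dfr(sort(unique(errs$v)), function(v) {
    purrr::map_dfr(setdiff(lambdas, 0), function(lam) {
      per_ds <- purrr::map_dfr(unique(errs$dataset), function(ds) {
        base <- dplyr::filter(errs, .data$dataset == ds, .data$v == !!v,
                              .data$lambda == 0)
        cand <- dplyr::filter(errs, .data$dataset == ds, .data$v == !!v,
                              .data$lambda == !!lam)
        e0 <- unlist(base$errors); ec <- unlist(cand$errors)
        s0 <- unlist(base$sq_errors); sc <- unlist(cand$sq_errors)
        cmp <- compare_classifiers(ec, e0, sc, s0)
        cmp$dataset <- ds
        cmp$better <- sum(ec) < sum(e0)
        cmp$worse <- sum(ec) > sum(e0)
        cmp
      })
      mc <- holm_adjust(per_ds$mcnemar_p)
      wx <- holm_adjust(per_ds$wilcoxon_p)
      sig <- mc < alpha & wx < alpha
      tibble::tibble(v = v, lambda = lam,
                     wins = sum(sig & per_ds$better),
                     losses = sum(sig & per_ds$worse))
    })
  })
}

new_mimo_protocol <- function(metrics, wl, mode, config) {
  out <- list(metrics = metrics, win_loss = wl, mode = mode, config = config)
  class(out) <- "mimo_protocol"
  out
}

#' @export
print.mimo_protocol <- function(x, ...) {
  cat("mimo_protocol (", x$mode, "): ", x$config$reps, " repetitions, v in {",
      paste(x$config$v, collapse = ", "), "}, lambda in {",
      paste(x$config$lambdas, collapse = ", "), "}\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @method tidy mimo_protocol
#' @export
tidy.mimo_protocol <- function(x, ...) x$metrics

#' @method glance mimo_protocol
#' @export
glance.mimo_protocol <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$v, .data$lambda) |>
    dplyr::summarise(
      auc = mean(.data$auc),
      one_minus_rmse = mean(.data$one_minus_rmse),
      sar = mean(.data$sar),
      f = mean(.data$f),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}

#' Plot protocol accuracy against the degree of causality
#'
#' @param object A `mimo_protocol`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mimo_protocol
#' @export
autoplot.mimo_protocol <- function(object, ...) {
  long <- tidyr::pivot_longer(glance(object),
                              c("auc", "one_minus_rmse", "sar", "f"),
                              names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$lambda, .data$value,
                                     colour = factor(.data$v))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "lambda (degree of causality)", y = NULL,
                  colour = "signature size v") +
    ggplot2::theme_minimal()
}

# ---- protocols -------------------------------------------------------------

#' Multi-study holdout validation protocol
#'
#' For each repetition: every study is split in half (stratified on the
#' primary target); the causal filter runs on the pooled training halves
#' (correlation-level meta-analysis); a Gaussian naive Bayes is trained on
#' the pooled training halves restricted to the top `v` features and
#' evaluated on the pooled test halves, for every (v, lambda) cell. Test
#' halves never influence selection or fitting within a repetition.
#'
#' @param studies Named list of studies (each with `features` and
#'   `targets`; see [pooled_forward_rank()]).
#' @param v Signature sizes to evaluate.
#' @param lambdas Degrees of causality to compare (include 0 to enable the
#'   win-loss comparison).
#' @param reps Number of training-and-test repetitions (default 100).
#' @param seed Integer seed.
#' @param primary Primary target column (name or index).
#' @return A `mimo_protocol`: per-repetition metrics (`tidy()`), aggregate
#'   means per (v, lambda) (`glance()`), and a `win_loss` table comparing
#'   each lambda > 0 against lambda = 0 per study.
#' @export
holdout_protocol <- function(studies, v = 10, lambdas = c(0, 1), reps = 100,
                             seed = NULL, primary = 1L) {
  std <- align_studies(studies)
  ds_names <- names(studies) %||% paste0("study", seq_along(studies))
  if (!is.null(seed)) set.seed(seed)
  v_max <- max(v)
  prim <- resolve_primary(primary, colnames(std$Ys[[1]]))

  metrics <- purrr::map_dfr(seq_len(reps), function(rep) {
    splits <- lapply(std$Ys, stratified_half_split)
    Xtr <- purrr::map2(std$Xs, splits, ~ .x[.y$train, , drop = FALSE])
    Ytr <- purrr::map2(std$Ys, splits, ~ .x[.y$train, , drop = FALSE])
    Xte <- purrr::map2(std$Xs, splits, ~ .x[.y$test, , drop = FALSE])
    Yte <- purrr::map2(std$Ys, splits, ~ .x[.y$test, , drop = FALSE])

    engine <- new_mi_engine(Xtr, Ytr, primary = prim)
    rankings <- lapply(stats::setNames(lambdas, lambdas), function(lam) {
      forward_rank_engine(engine, lam, v_max)$order
    })

    train_X <- do.call(rbind, Xtr)
    train_y <- unlist(lapply(Ytr, function(Y) Y[, prim]))
    test_X <- do.call(rbind, Xte)
    test_y <- unlist(lapply(Yte, function(Y) Y[, prim]))
    ds_of <- rep(ds_names, times = vapply(Xte, nrow, integer(1)))

    # one classifier per (v, lambda), evaluated on the pooled test halves
    cells <- evaluate_cells(rankings, v, train_X, train_y, test_X, test_y)
    cells$dataset <- list(ds_of)
    cells$rep <- rep
    cells
  })

  # win-loss needs per-dataset error vectors; slice the pooled predictions
  errs_ds <- metrics |>
    tidyr::unnest(c("errors", "sq_errors", "dataset")) |>
    dplyr::group_by(.data$dataset, .data$v, .data$lambda) |>
    dplyr::summarise(errors = list(.data$errors),
                     sq_errors = list(.data$sq_errors), .groups = "drop")
  wl <- win_loss_table(errs_ds)
  metrics$errors <- metrics$sq_errors <- metrics$probs <- metrics$dataset <- NULL
  new_mimo_protocol(metrics, wl, "holdout",
                    list(v = v, lambdas = lambdas, reps = reps))
}

#' Leave-one-dataset-out validation protocol
#'
#' For each held-out study, the causal filter runs once on the pooled
#' remaining studies, freezing one feature set per (v, lambda). Then
#' `reps` stratified half/half holdout repetitions *within* the held-out
#' study assess the frozen signature with a Gaussian naive Bayes. The
#' held-out study never influences feature selection.
#'
#' @inheritParams holdout_protocol
#' @return A `mimo_protocol` with per-(dataset, repetition) metrics and the
#'   per-dataset win-loss table (lambda > 0 vs lambda = 0, both McNemar and
#'   Wilcoxon significant after Holm adjustment).
#' @export
lodo_protocol <- function(studies, v = 10, lambdas = c(0, 1), reps = 100,
                          seed = NULL, primary = 1L) {
  if (length(studies) < 2) stop("leave-one-dataset-out needs >= 2 studies")
  std <- align_studies(studies)
  ds_names <- names(studies) %||% paste0("study", seq_along(studies))
  if (!is.null(seed)) set.seed(seed)
  v_max <- max(v)
  prim <- resolve_primary(primary, colnames(std$Ys[[1]]))

  metrics <- purrr::map_dfr(seq_along(std$Xs), function(hold) {
    engine <- new_mi_engine(std$Xs[-hold], std$Ys[-hold], primary = prim)
    rankings <- lapply(stats::setNames(lambdas, lambdas), function(lam) {
      forward_rank_engine(engine, lam, v_max)$order
    })
    Xh <- std$Xs[[hold]]
    Yh <- std$Ys[[hold]]
    purrr::map_dfr(seq_len(reps), function(rep) {
      split <- stratified_half_split(Yh)
      cells <- evaluate_cells(rankings, v,
                              Xh[split$train, , drop = FALSE],
                              Yh[split$train, prim],
                              Xh[split$test, , drop = FALSE],
                              Yh[split$test, prim])
      cells$dataset <- ds_names[hold]
      cells$rep <- rep
      cells
    })
  })

  wl <- win_loss_table(metrics)
  metrics$errors <- metrics$sq_errors <- metrics$probs <- NULL
  new_mimo_protocol(metrics, wl, "lodo",
                    list(v = v, lambdas = lambdas, reps = reps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
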