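# Cause-prioritization metrics and the synthetic benchmark loop.

#' Average rank of the known causes in a ranking
#'
#' Mean 1-based position of the cause features within a full ranking.
#' Lower is better; 3.0 means the causes occupy the top five positions
#' (when there are five of them).
#'
#' @param ranking A `mimo_ranking` (or any tibble with a `feature` column
#'   giving the ranked order).
#' @param cause_ids Character vector of cause feature identifiers.
#' @return Mean position (numeric scalar).
#' @export
average_cause_rank <- function(ranking, cause_ids) {
  pos <- match(cause_ids, ranking$feature)
  if (anyNA(pos)) {
    stop("cause(s) absent from the ranking: ",
         paste(cause_ids[is.na(pos)], collapse = ", "))
  }
  mean(pos)
}

#' Fraction of top-k positions held by known causes
#'
#' By default the fraction of the first `k` ranked features that are true
#' causes (so with 5 causes and `k = 5` the value lives on
#' `{0, 0.2, ..., 1}`). With `strict = TRUE` the value is 1 only when
#' *all* causes sit inside the top `k`, 0 otherwise — the conservative
#' reading of "causes ranked among the first k variables".
#'
#' @inheritParams average_cause_rank
#' @param k Number of leading positions to inspect (default 5).
#' @param strict All-causes-in-top-k indicator instead of the fraction.
#' @return A value in `[0, 1]`.
#' @export
top_k_cause_rate <- function(ranking, cause_ids, k = 5, strict = FALSE) {
  if (k <= 0) stop("`k` must be positive")
  if (k > nrow(ranking)) stop("`k` exceeds the ranking length")
  top <- ranking$feature[seq_len(k)]
  if (strict) {
    return(as.numeric(all(cause_ids %in% top)))
  }
  mean(top %in% cause_ids)
}

#' Mean and normal-approximation confidence interval over trials
#'
#' @param values Numeric vector of per-trial metric values (length >= 2).
#' @param level Confidence level (default 0.90).
#' @return A tibble with `mean`, `ci_halfwidth`
#'   (`z * sd / sqrt(n_trials)`), and `n_trials`.
#' @export
summarize_trials <- function(values, level = 0.90) {
  if (length(values) < 2) stop("need at least 2 trials")
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    mean = mean(values),
    ci_halfwidth = z * stats::sd(values) / sqrt(length(values)),
    n_trials = length(values)
  )
}

#' Synthetic cause-prioritization benchmark
#'
#' For each noise level and each trial, draws a fresh benchmark network
#' (new random edge weights), simulates a dataset, runs the full causal
#' forward ranking at every `lambda`, and scores how well the direct
#' causes are prioritized: their average rank and the top-5 cause rate.
#'
#' @param trials Number of simulated datasets per noise level.
#' @param sigmas Noise standard deviations to sweep.
#' @param lambdas Causality degrees to compare (0 = plain MI ranking).
#' @param n_samples Samples per simulated dataset.
#' @param seed Integer seed; per-trial sub-seeds are derived from it so
#'   every lambda sees the same datasets (paired design).
#' @param keep_trials Return per-trial values instead of summaries.
#' @return With `keep_trials = FALSE` (default) a `mimo_synthetic_eval`
#'   tibble with one row per (sigma, lambda): `mean_rank`, `rank_ci`,
#'   `top5_rate`, `top5_ci`, `n_trials`. Otherwise the per-trial tibble
#'   (sigma, lambda, trial, mean_rank, top5_rate).
#' @export
eval_synthetic <- function(trials = 150, sigmas = 0.1,
                           lambdas = c(0, 0.5, 1, 2, 5),
                           n_samples = 100, seed = NULL,
                           keep_trials = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(2147483645L, trials * length(sigmas))
  dim(sub_seeds) <- c(trials, length(sigmas))

  per_trial <- purrr::map_dfr(seq_along(sigmas), function(si) {
    purrr::map_dfr(seq_len(trials), function(t) {
      s <- sub_seeds[t, si]
      net <- default_network(seed = s, sigma = sigmas[si])
      d <- simulate_network(net, n_samples = n_samples, seed = s + 1L)
      causes <- d$truth$feature[d$truth$role == "direct_cause"]
      X <- as_feature_matrix(d$features)
      Y <- as_target_matrix(d$targets, nrow(X))
      # one engine per dataset: the structural-score cache is shared across
      # lambdas, so each interaction term is estimated once per trial
      engine <- new_mi_engine(list(X), list(Y), primary = 1L)
      purrr::map_dfr(lambdas, function(lam) {
        res <- forward_rank_engine(engine, lam, v = ncol(X))
        rk <- new_mimo_ranking(res, colnames(X), lambda = lam, v = ncol(X),
                               primary = "y1", n_targets = ncol(Y),
                               n_features = ncol(X), pooled = FALSE)
        tibble::tibble(
          sigma = sigmas[si], lambda = lam, trial = t,
          mean_rank = average_cause_rank(rk, causes),
          top5_rate = top_k_cause_rate(rk, causes, k = 5)
        )
      })
    })
  })
  if (keep_trials) return(per_trial)

  out <- per_trial |>
    dplyr::group_by(.data$sigma, .data$lambda) |>
    dplyr::summarise(
      rank_sum = summarize_trials(.data$mean_rank),
      top5_sum = summarize_trials(.data$top5_rate),
      .groups = "drop"
    ) |>
    tidyr::unpack("rank_sum", names_sep = "_") |>
    tidyr::unpack("top5_sum", names_sep = "_") |>
    dplyr::transmute(
      sigma = .data$sigma, lambda = .data$lambda,
      mean_rank = .data$rank_sum_mean, rank_ci = .data$rank_sum_ci_halfwidth,
      top5_rate = .data$top5_sum_mean, top5_ci = .data$top5_sum_ci_halfwidth,
      n_trials = .data$rank_sum_n_trials
    )
  class(out) <- c("mimo_synthetic_eval", class(out))
  out
}

#' Plot synthetic benchmark curves
#'
#' Average direct-cause rank (left) and top-5 cause rate (right) against
#' the noise standard deviation, one line per lambda, with the
#' trial-based confidence band.
#'
#' @param object A `mimo_synthetic_eval` from [eval_synthetic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mimo_synthetic_eval
#' @export
autoplot.mimo_synthetic_eval <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, .data$sigma, .data$lambda,
                     metric = "average rank of direct causes",
                     value = .data$mean_rank, ci = .data$rank_ci),
    dplyr::transmute(object, .data$sigma, .data$lambda,
                     metric = "top-5 cause rate",
                     value = .data$top5_rate, ci = .data$top5_ci)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$sigma, .data$value,
                                     colour = factor(.data$lambda))) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$ci,
                                      ymax = .data$value + .data$ci,
                                      fill = factor(.data$lambda)),
                         alpha = 0.15, colour = NA) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "noise standard deviation", colour = "lambda",
                  fill = "lambda", y = NULL) +
    ggplot2::theme_minimal()
}
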