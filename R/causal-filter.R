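# User surface of the MIMO causal filter: univariate relevance ranking and
# the interaction-information forward selection.

#' Univariate relevance of each feature to the primary target
#'
#' Gaussian-approximation mutual information between every feature column
#' and the primary binary target — the conventional filter ranking
#' criterion, and what the causal filter reduces to at `lambda = 0`.
#'
#' @param features A data frame or matrix of numeric feature columns
#'   (rows = samples).
#' @param primary_target Binary class vector, one entry per row.
#' @return A tibble with columns `feature` and `relevance` (nats), one row
#'   per feature in input column order.
#' @export
relevance_scores <- function(features, primary_target) {
  X <- as_feature_matrix(features)
  y <- as_binary(primary_target)
  if (length(y) != nrow(X)) stop("target length must equal the number of rows")
  if (length(unique(y)) < 2) stop("target has one class")
  r <- safe_cor_vec(y, X)
  tibble::tibble(feature = colnames(X), relevance = gaussian_mi(r))
}

#' Structural (causal) score of a feature pair
#'
#' Minus the average, over all targets, of the three-way interaction
#' information of the pair with each target:
#' `C(x_i, x_k) = -(1/m) * sum_j I(x_i; x_k; y_j)`.
#' Both parents of a collider interact negatively with it, so a high score
#' is evidence that the pair plays a joint causal role for the targets;
#' two effects of a target (common-cause pattern) score negatively.
#'
#' @param xi,xk Numeric feature vectors.
#' @param targets A binary vector, or a data frame / list of binary vectors
#'   (primary and secondaries all participate).
#' @return A single real score; symmetric in `xi` and `xk`.
#' @export
structural_score <- function(xi, xk, targets) {
  ys <- as_target_list(targets)
  -mean(vapply(ys, function(y) interaction_information(xi, xk, y), numeric(1)))
}

#' Causal forward-selection feature ranking
#'
#' Forward selection that scores each candidate feature by its relevance to
#' the primary target plus `lambda / d` times the summed structural scores
#' against the `d` features already selected:
#' `x* = argmax_k I(x_k; y_1) + (lambda/d) * sum_{i in S} C(x_i, x_k)`.
#' The first step is pure relevance (empty causal sum). `lambda = 0`
#' reproduces the plain mutual-information ranking; larger `lambda`
#' increasingly prioritizes features that look like joint causes of the
#' targets over mere effects. All interaction terms are computed once per
#' selected feature and cached as a running sum.
#'
#' @inheritParams relevance_scores
#' @param targets A data frame (or matrix) of binary target columns; the
#'   primary target drives relevance, every column enters the causal term.
#' @param primary Name or index of the primary target column (default: the
#'   first).
#' @param lambda Degree of causality, `>= 0`.
#' @param v Number of features to select; defaults to all (a full ranking).
#' @param rank_all If `TRUE`, run the forward pass to completion regardless
#'   of `v`.
#' @return A `mimo_ranking`: a tibble with one row per selection step and
#'   columns `step`, `feature`, `relevance`, `causal_term` (the
#'   lambda-weighted causal increment at selection time) and `score`, with
#'   the configuration stored in attributes.
#' @seealso [relevance_scores()], [pooled_forward_rank()]
#' @export
#' @examples
#' set.seed(7)
#' net <- default_network(seed = 7, sigma = 0.1)
#' d <- simulate_network(net, n_samples = 100, seed = 7)
#' causal_forward_rank(d$features, d$targets, lambda = 2)
causal_forward_rank <- function(features, targets, primary = 1L,
                                lambda = 1, v = NULL, rank_all = FALSE) {
  X <- as_feature_matrix(features)
  Y <- as_target_matrix(targets, nrow(X))
  primary <- resolve_primary(primary, colnames(Y))
  if (lambda < 0) stop("`lambda` must be >= 0")
  validate_classes(Y, min_per_class = 3L)
  n_feat <- ncol(X)
  if (is.null(v) || rank_all) v <- n_feat
  if (v < 1 || v > n_feat) stop("`v` must be between 1 and the number of features")

  engine <- new_mi_engine(list(X), list(Y), primary = primary)
  res <- forward_rank_engine(engine, lambda, v)
  new_mimo_ranking(res, colnames(X), lambda = lambda, v = v,
                   primary = colnames(Y)[primary], n_targets = ncol(Y),
                   n_features = n_feat, pooled = FALSE)
}

#' Causal forward ranking pooled across several studies
#'
#' Same selection rule as [causal_forward_rank()], but every correlation —
#' marginal, point-biserial, and within-class — is estimated per study and
#' combined on the Fisher z scale with weights `n - 3` before entering the
#' Gaussian mutual-information form. This is the meta-analytic integration
#' at the correlation level used by the multi-study validation protocols.
#'
#' @param studies A list of studies, each a list with elements `features`
#'   (numeric data frame/matrix, shared column set) and `targets` (binary
#'   columns, shared layout). Features are aligned on the intersection of
#'   column names across studies.
#' @inheritParams causal_forward_rank
#' @return A `mimo_ranking` tibble (see [causal_forward_rank()]).
#' @export
pooled_forward_rank <- function(studies, primary = 1L, lambda = 1,
                                v = NULL, rank_all = FALSE) {
  std <- align_studies(studies)
  if (lambda < 0) stop("`lambda` must be >= 0")
  n_feat <- ncol(std$Xs[[1]])
  if (is.null(v) || rank_all) v <- n_feat
  if (v < 1 || v > n_feat) stop("`v` must be between 1 and the number of features")
  primary <- resolve_primary(primary, colnames(std$Ys[[1]]))
  engine <- new_mi_engine(std$Xs, std$Ys, primary = primary)
  res <- forward_rank_engine(engine, lambda, v)
  new_mimo_ranking(res, colnames(std$Xs[[1]]), lambda = lambda, v = v,
                   primary = colnames(std$Ys[[1]])[primary],
                   n_targets = ncol(std$Ys[[1]]),
                   n_features = n_feat, pooled = TRUE)
}

new_mimo_ranking <- function(res, feature_names, ...) {
  out <- tibble::tibble(
    step = seq_along(res$order),
    feature = feature_names[res$order],
    relevance = res$relevance,
    causal_term = res$causal_term,
    score = res$score
  )
  config <- list(...)
  attr(out, "mimo_config") <- config
  class(out) <- c("mimo_ranking", class(out))
  out
}

#' @export
print.mimo_ranking <- function(x, ...) {
  cfg <- attr(x, "mimo_config")
  cat("MIMO causal ranking: lambda = ", cfg$lambda, ", ", nrow(x), " of ",
      cfg$n_features, " features, ", cfg$n_targets, " targets (primary ",
      cfg$primary, ")", if (isTRUE(cfg$pooled)) ", pooled across studies",
      "\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy mimo_ranking
#' @export
tidy.mimo_ranking <- function(x, ...) {
  out <- x
  attr(out, "mimo_config") <- NULL
  class(out) <- setdiff(class(out), "mimo_ranking")
  out
}

#' @method glance mimo_ranking
#' @export
glance.mimo_ranking <- function(x, ...) {
  cfg <- attr(x, "mimo_config")
  tibble::tibble(
    lambda = cfg$lambda, v = cfg$v, n_features = cfg$n_features,
    n_targets = cfg$n_targets, primary = cfg$primary,
    pooled = isTRUE(cfg$pooled)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the score decomposition of a ranking
#'
#' Relevance and causal contributions of each selected feature by
#' selection step.
#'
#' @param object A `mimo_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mimo_ranking
#' @export
autoplot.mimo_ranking <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("relevance", "causal_term"),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "selection step", y = "score contribution (nats)",
                  title = paste0("Causal forward ranking (lambda = ",
                                 attr(object, "mimo_config")$lambda, ")")) +
    ggplot2::theme_minimal()
}

# ---- input coercion helpers ------------------------------------------------

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    non_num <- !vapply(features, is.numeric, logical(1))
    if (any(non_num)) {
      stop("non-numeric feature columns: ",
           paste(names(features)[non_num], collapse = ", "))
    }
    features <- as.matrix(features)
  }
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature matrix contains missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

as_target_matrix <- function(targets, n_rows) {
  if (is.atomic(targets) && is.null(dim(targets))) targets <- list(y1 = targets)
  if (is.list(targets) && !is.data.frame(targets)) {
    targets <- tibble::as_tibble(targets, .name_repair = "minimal")
  }
  Y <- vapply(as.data.frame(targets), as_binary, integer(nrow(targets)))
  Y <- matrix(as.integer(Y), nrow = nrow(targets),
              dimnames = list(NULL, colnames(targets)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  if (nrow(Y) != n_rows) stop("targets and features disagree on sample count")
  Y
}

as_target_list <- function(targets) {
  if (is.atomic(targets) && is.null(dim(targets))) return(list(as_binary(targets)))
  lapply(as.data.frame(targets), as_binary)
}

resolve_primary <- function(primary, target_names) {
  if (is.character(primary)) {
    idx <- match(primary, target_names)
    if (is.na(idx)) stop("primary target '", primary, "' not found")
    return(idx)
  }
  primary <- as.integer(primary)
  if (primary < 1 || primary > length(target_names)) stop("invalid primary target index")
  primary
}

validate_classes <- function(Y, min_per_class = 3L) {
  for (j in seq_len(ncol(Y))) {
    counts <- tabulate(Y[, j] + 1L, nbins = 2L)
    if (any(counts == 0L)) stop("target ", colnames(Y)[j], " has one class")
    if (any(counts < min_per_class)) {
      stop("target ", colnames(Y)[j], " has a class with fewer than ",
           min_per_class, " observations")
    }
  }
  invisible(TRUE)
}

align_studies <- function(studies) {
  if (length(studies) < 1) stop("need at least one study")
  Xs <- lapply(studies, function(s) as_feature_matrix(s$features))
  common <- Reduce(intersect, lapply(Xs, colnames))
  if (length(common) == 0) stop("studies share no feature identifiers")
  dropped <- unique(unlist(lapply(Xs, function(X) setdiff(colnames(X), common))))
  if (length(dropped) > 0) {
    message("dropping ", length(dropped),
            " feature(s) absent from some studies")
  }
  Xs <- lapply(Xs, function(X) X[, common, drop = FALSE])
  Ys <- lapply(studies, function(s) {
    as_target_matrix(s$targets, nrow(as_feature_matrix(s$features)))
  })
  m <- unique(vapply(Ys, ncol, integer(1)))
  if (length(m) != 1) stop("studies disagree on the number of targets")
  for (Y in Ys) validate_classes(Y, min_per_class = 3L)
  list(Xs = Xs, Ys = Ys)
}
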