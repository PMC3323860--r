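# Gaussian-approximation mutual-information estimators.
#
# All mutual-information quantities in this package are computed through the
# closed form for bivariate Gaussians, I = -1/2 log(1 - rho^2), applied to
# sample Pearson correlations. Binary targets enter through their 0/1
# encoding (point-biserial correlation); this is an approximation, since a
# 0/1 variable is not Gaussian, but it keeps every term estimable from
# correlations alone, which is what makes cross-study pooling at the
# correlation level possible. Units are nats (natural logarithm).

# |rho| is kept strictly below 1 so MI stays finite on collinear inputs.
RHO_EPS <- 1e-12

clamp_rho <- function(rho) {
  lim <- 1 - RHO_EPS
  rho[rho > lim] <- lim
  rho[rho < -lim] <- -lim
  rho
}

#' Pearson correlation with zero-variance guard
#'
#' Standard sample Pearson correlation. A constant vector carries no
#' information, so zero-variance input yields 0 with a warning instead of
#' `NA`, which keeps genome-scale matrices with constant probes from
#' aborting a run.
#'
#' @param x1,x2 Numeric vectors of equal length (>= 2), all entries finite.
#' @return A single correlation in `[-1, 1]`.
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
pearson_correlation <- function(x1, x2) {
  x1 <- as.numeric(x1)
  x2 <- as.numeric(x2)
  if (length(x1) != length(x2)) {
    stop("`x1` and `x2` must have the same length (", length(x1), " vs ",
         length(x2), ")")
  }
  if (length(x1) < 2) stop("need at least 2 observations")
  if (!all(is.finite(x1)) || !all(is.finite(x2))) {
    stop("inputs must be finite and free of missing values")
  }
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
    warning("zero-variance input: correlation set to 0")
    return(0)
  }
  stats::cor(x1, x2)
}

#' Mutual information of a bivariate Gaussian from its correlation
#'
#' Computes `-1/2 * log(1 - rho^2)` in nats, with `rho` clamped to
#' `|rho| <= 1 - 1e-12` so the result is finite even for collinear inputs.
#' The function is even in `rho` and strictly increasing in `|rho|`.
#'
#' @param rho Correlation(s) in `[-1, 1]`; vectorized.
#' @return Mutual information in nats, same length as `rho`.
#' @export
#' @examples
#' gaussian_mi(0.9) # -0.5 * log(1 - 0.81)
gaussian_mi <- function(rho) {
  if (any(abs(rho) > 1 + 1e-9, na.rm = TRUE)) {
    stop("|rho| must not exceed 1")
  }
  -0.5 * log1p(-clamp_rho(rho)^2)
}

#' Mutual information between two continuous variables
#'
#' `gaussian_mi(pearson_correlation(x1, x2))`; symmetric in its arguments.
#'
#' @inheritParams pearson_correlation
#' @return Mutual information in nats.
#' @export
mi_cc <- function(x1, x2) {
  gaussian_mi(pearson_correlation(x1, x2))
}

#' Mutual information between a continuous variable and a binary class
#'
#' The class is encoded 0/1 and the point-biserial correlation is pushed
#' through the Gaussian closed form. Approximate by construction (the class
#' is not Gaussian) but consistent with the correlation-level estimation
#' used everywhere else in the package.
#'
#' @param x Numeric vector.
#' @param y Binary class vector (0/1, logical, or two-level factor), both
#'   classes present.
#' @return Mutual information in nats.
#' @export
mi_cd <- function(x, y) {
  y <- as_binary(y)
  if (length(unique(y)) < 2) stop("target has one class")
  gaussian_mi(pearson_correlation(x, y))
}

#' Class-conditional mutual information between two continuous variables
#'
#' Weighted average, over the classes of `y`, of the Gaussian MI of the
#' within-class Pearson correlations; weights are the empirical class
#' frequencies (maximum-likelihood plug-in, no shrinkage). Symmetric in
#' `x1`, `x2` and non-negative.
#'
#' @inheritParams pearson_correlation
#' @param y Binary class vector; each class needs at least 3 observations
#'   for the within-class correlation to be defined.
#' @return Conditional mutual information in nats.
#' @export
conditional_mi_cc <- function(x1, x2, y) {
  y <- as_binary(y)
  counts <- table(y)
  if (length(counts) < 2) stop("target has one class")
  if (any(counts < 3)) {
    stop("each class needs >= 3 observations for a within-class correlation")
  }
  n <- length(y)
  value <- 0
  for (cls in names(counts)) {
    idx <- y == as.integer(cls)
    value <- value + (sum(idx) / n) * mi_cc(x1[idx], x2[idx])
  }
  value
}

#' Three-way interaction information with a binary target
#'
#' `mi_cc(x1, x2) - conditional_mi_cc(x1, x2, y)`. Negative values denote
#' synergy/complementarity (conditioning on the target creates dependence,
#' the collider signature); positive values denote redundancy (a common
#' cause or chain explains the marginal dependence). Symmetric in `x1`
#' and `x2`.
#'
#' @inheritParams conditional_mi_cc
#' @return Interaction information in nats (any sign).
#' @export
#' @examples
#' set.seed(1)
#' x1 <- rnorm(2000); x2 <- rnorm(2000)
#' y <- as.integer(x1 + x2 > 0)
#' interaction_information(x1, x2, y) # negative: collider pattern
interaction_information <- function(x1, x2, y) {
  mi_cc(x1, x2) - conditional_mi_cc(x1, x2, y)
}

# Coerce a class vector to integer 0/1, preserving two-level factors and
# logicals; errors on anything not reducible to two known levels.
as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (anyNA(y)) stop("class vector contains missing values")
  if (!all(y %in% c(0L, 1L))) {
    stop("class vector must be binary (0/1, logical, or a two-level factor)")
  }
  y
}
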