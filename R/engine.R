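# Internal correlation engine behind the forward-selection filter.
#
# The filter only ever needs two kinds of quantities: the relevance of each
# feature to the primary target, and structural scores C(x_i, x_k) between a
# selected feature and every candidate. Both reduce, under the Gaussian
# approximation, to (possibly class-conditional) Pearson correlations, so
# the engine exposes them as vectorized column-vs-matrix operations. With
# several studies the correlations are pooled on the Fisher z scale with
# weights n - 3 before being mapped to mutual information, which is how the
# meta-analytic protocols share one code path with the single-dataset case.
#
# Caching contract: `structural_vec(i)` is called once per *selected*
# feature, and the forward pass accumulates its running sum, so every
# (pair, target) interaction term is estimated exactly once per run
# (O(v * n_features * m) work and memory).

# Correlation of one column against every column of X; zero-variance
# columns (either side) contribute 0 rather than NA.
safe_cor_vec <- function(x, X) {
  r <- suppressWarnings(as.vector(stats::cor(x, X)))
  r[!is.finite(r)] <- 0
  r
}

# Fisher-z pool of a p x S matrix of per-study correlations with weights w.
# With a single study this is the identity, bit-for-bit.
pool_cor <- function(rmat, w) {
  if (ncol(rmat) == 1L) return(rmat[, 1L])
  keep <- w > 0
  if (!any(keep)) stop("no study carries positive pooling weight")
  z <- atanh(clamp_rho(rmat[, keep, drop = FALSE]))
  tanh(as.vector(z %*% w[keep]) / sum(w[keep]))
}

# Xs: list of numeric matrices (same columns, same order); Ys: list of
# integer 0/1 matrices (same m columns); primary: column index into Ys.
new_mi_engine <- function(Xs, Ys, primary = 1L) {
  S <- length(Xs)
  p <- ncol(Xs[[1L]])
  m <- ncol(Ys[[1L]])
  ns <- vapply(Xs, nrow, integer(1))
  w_all <- pmax(ns - 3, 0)
  if (S == 1L) w_all <- 1

  # per (study, target): row indices of class 0 / class 1
  class_idx <- lapply(seq_len(S), function(s) {
    lapply(seq_len(m), function(j) {
      y <- Ys[[s]][, j]
      list(which(y == 0L), which(y == 1L))
    })
  })
  # pooled class priors per target
  priors <- lapply(seq_len(m), function(j) {
    n1 <- sum(vapply(seq_len(S), function(s) length(class_idx[[s]][[j]][[2L]]), integer(1)))
    n0 <- sum(ns) - n1
    c(n0, n1) / sum(ns)
  })
  for (j in seq_len(m)) {
    if (any(priors[[j]] == 0)) stop("target ", j, " has one class")
  }

  pooled_vec <- function(fetch, weights) {
    rmat <- vapply(seq_len(S), function(s) fetch(s), numeric(p))
    pool_cor(matrix(rmat, nrow = p), weights)
  }

  relevance <- local({
    r <- pooled_vec(function(s) {
      safe_cor_vec(Ys[[s]][, primary], Xs[[s]])
    }, w_all)
    gaussian_mi(r)
  })

  # C(x_i, .) = -(1/m) * sum_j [ I(x_i; x_k) - I(x_i; x_k | y_j) ] over all k.
  # Memoized per selected feature so repeated passes (e.g. several lambdas
  # over the same data) never re-estimate a (pair, target) term.
  cache <- vector("list", p)
  structural_vec_raw <- function(i) {
    mi_marg <- gaussian_mi(pooled_vec(function(s) {
      safe_cor_vec(Xs[[s]][, i], Xs[[s]])
    }, w_all))
    inter_sum <- numeric(p)
    for (j in seq_len(m)) {
      mi_cond <- numeric(p)
      for (cls in 1:2) {
        w_c <- vapply(seq_len(S), function(s) {
          max(length(class_idx[[s]][[j]][[cls]]) - 3, 0)
        }, numeric(1))
        if (S == 1L) w_c <- 1
        r_c <- pooled_vec(function(s) {
          idx <- class_idx[[s]][[j]][[cls]]
          if (length(idx) < 3) return(numeric(p))
          safe_cor_vec(Xs[[s]][idx, i], Xs[[s]][idx, , drop = FALSE])
        }, w_c)
        mi_cond <- mi_cond + priors[[j]][cls] * gaussian_mi(r_c)
      }
      inter_sum <- inter_sum + (mi_marg - mi_cond)
    }
    -inter_sum / m
  }
  structural_vec <- function(i) {
    if (is.null(cache[[i]])) cache[[i]] <<- structural_vec_raw(i)
    cache[[i]]
  }

  list(p = p, m = m, relevance = relevance, structural_vec = structural_vec)
}

# Forward pass of the causal filter. Step 1 is pure relevance (empty causal
# sum); step d+1 maximizes relevance + (lambda/d) * sum of structural scores
# against the d already-selected features. Ties break to the lowest column
# index (which.max), making runs reproducible.
forward_rank_engine <- function(engine, lambda, v) {
  p <- engine$p
  rel <- engine$relevance
  selected <- integer(v)
  rel_out <- causal_out <- score_out <- numeric(v)
  csum <- numeric(p)
  taken <- rep(FALSE, p)
  for (d in seq_len(v)) {
    causal <- if (d == 1L) numeric(p) else (lambda / (d - 1)) * csum
    total <- rel + causal
    total[taken] <- -Inf
    k <- which.max(total)
    selected[d] <- k
    rel_out[d] <- rel[k]
    causal_out[d] <- causal[k]
    score_out[d] <- rel[k] + causal[k]
    taken[k] <- TRUE
    if (d < v) csum <- csum + engine$structural_vec(k)
  }
  list(order = selected, relevance = rel_out, causal_term = causal_out,
       score = score_out)
}
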