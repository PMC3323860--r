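# Generators shared across tests. Everything is built in code at test time;
# seeds are always explicit.

# Two independent parents and their binarized common child (collider):
# conditioning on y induces negative within-class correlation.
collider_data <- function(n, seed) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  list(x1 = x1, x2 = x2, y = as.integer(x1 + x2 > 0))
}

# Two noisy copies of a latent z and the binarized z (common cause):
# conditioning on y absorbs part of the shared dependence.
common_cause_data <- function(n, seed) {
  set.seed(seed)
  z <- rnorm(n)
  list(x1 = z + rnorm(n), x2 = z + rnorm(n), y = as.integer(z > 0))
}

# Random continuous features with random binary targets guaranteed to have
# several observations per class.
random_instance <- function(n_feat, n_samp, m = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n_samp * n_feat), n_samp, n_feat,
              dimnames = list(NULL, paste0("f", seq_len(n_feat))))
  Y <- replicate(m, {
    y <- rbinom(n_samp, 1, 0.5)
    # force at least 4 observations per class
    y[sample(n_samp, 4)] <- 0L
    y[sample(which(y == 0L), 4)] <- 1L
    y
  })
  colnames(Y) <- paste0("y", seq_len(m))
  list(X = X, Y = Y)
}

# Recompute-everything reference for the forward rule: at every step each
# remaining candidate is rescored from scratch with the package's scalar
# estimators; no caching, no incremental sums.
naive_forward_rank <- function(X, Y, lambda, v) {
  n_feat <- ncol(X)
  rel <- vapply(seq_len(n_feat), function(k) mi_cd(X[, k], Y[, 1]), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(n_feat)
  for (d in seq_len(v)) {
    cand_scores <- vapply(remaining, function(k) {
      if (length(selected) == 0) return(rel[k])
      cs <- sum(vapply(selected, function(i) {
        structural_score(X[, i], X[, k], as.data.frame(Y))
      }, numeric(1)))
      rel[k] + lambda / length(selected) * cs
    }, numeric(1))
    best <- remaining[which.max(cand_scores)]
    scores <- c(scores, max(cand_scores))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  list(order = selected, score = scores)
}

# A small collection of studies simulated from one shared network (same
# edge weights, independent samples), emulating cohorts that measure the
# same biology.
make_study_collection <- function(n_studies = 3, n = 120, sigma = 0.05,
                                  seed = 11) {
  net <- default_network(seed = seed, sigma = sigma)
  studies <- lapply(seq_len(n_studies), function(s) {
    simulate_network(net, n_samples = n, seed = seed + s)
  })
  names(studies) <- paste0("study", seq_len(n_studies))
  studies
}
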