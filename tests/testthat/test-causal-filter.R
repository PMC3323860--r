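test_that("relevance scores are mi_cd per column and duplicate columns tie", {
  inst <- random_instance(5, 200, m = 1, seed = 3)
  X <- cbind(inst$X, dup = inst$X[, 1])
  rel <- relevance_scores(X, inst$Y[, 1])
  expect_equal(rel$relevance[1], rel$relevance[6])
  expect_equal(rel$relevance[2], mi_cd(X[, 2], inst$Y[, 1]))
  expect_lt(rel$relevance[3], 0.05) # noise column
})

test_that("structural score averages interactions over targets with a sign flip", {
  d <- collider_data(5000, 21)
  # both targets are binarizations of noisy copies of x1 + x2: the pair is
  # a joint parent of both, so both interactions are negative and C > 0
  s <- d$x1 + d$x2
  y1 <- as.integer(s + rnorm(5000, sd = 0.3) > 0)
  y2 <- as.integer(s + rnorm(5000, sd = 0.3) > 0)
  targets <- data.frame(y1 = y1, y2 = y2)
  expect_gt(structural_score(d$x1, d$x2, targets), 0)
  manual <- -(interaction_information(d$x1, d$x2, y1) +
                interaction_information(d$x1, d$x2, y2)) / 2
  expect_equal(structural_score(d$x1, d$x2, targets), manual)
  # two effects of one cause: common-cause pattern, C < 0
  cc <- common_cause_data(5000, 22)
  expect_lt(structural_score(cc$x1, cc$x2, data.frame(y1 = cc$y)), 0)
  # independent targets: C ~ 0
  set.seed(23)
  noise_y <- data.frame(y1 = rbinom(5000, 1, 0.5))
  expect_lt(abs(structural_score(d$x1, d$x2, noise_y)), 0.02)
})

test_that("lambda = 0 forward pass equals the descending relevance ranking", {
  for (seed in 1:10) {
    inst <- random_instance(12, 80, m = 2, seed = seed)
    rk <- causal_forward_rank(inst$X, inst$Y, lambda = 0, rank_all = TRUE)
    rel <- relevance_scores(inst$X, inst$Y[, 1])
    expect_identical(rk$feature, rel$feature[order(-rel$relevance)])
  }
})

test_that("full ranking is a permutation and runs are deterministic", {
  inst <- random_instance(10, 100, m = 2, seed = 8)
  rk1 <- causal_forward_rank(inst$X, inst$Y, lambda = 1.5, rank_all = TRUE)
  rk2 <- causal_forward_rank(inst$X, inst$Y, lambda = 1.5, rank_all = TRUE)
  expect_identical(rk1, rk2)
  expect_setequal(rk1$feature, colnames(inst$X))
  expect_identical(anyDuplicated(rk1$feature), 0L)
})

test_that("incremental cached pass agrees with the recompute-everything reference", {
  for (seed in 1:20) {
    n_feat <- sample(3:8, 1)
    inst <- random_instance(n_feat, 60, m = 2, seed = 100 + seed)
    lambda <- runif(1, 0, 3)
    rk <- causal_forward_rank(inst$X, inst$Y, lambda = lambda, rank_all = TRUE)
    ref <- naive_forward_rank(inst$X, inst$Y, lambda, n_feat)
    expect_identical(match(rk$feature, colnames(inst$X)), ref$order)
    expect_equal(rk$score, ref$score, tolerance = 1e-12)
  }
})

test_that("small lambda converges to the lambda = 0 ranking", {
  inst <- random_instance(10, 150, m = 2, seed = 77)
  rk0 <- causal_forward_rank(inst$X, inst$Y, lambda = 0, rank_all = TRUE)
  rk_eps <- causal_forward_rank(inst$X, inst$Y, lambda = 1e-10, rank_all = TRUE)
  expect_identical(rk0$feature, rk_eps$feature)
})

test_that("the toy parents/effect/noise example promotes the causal pair", {
  set.seed(9)
  n <- 5000
  p1 <- rnorm(n)
  p2 <- rnorm(n)
  s <- p1 + p2
  y1 <- as.integer(s + rnorm(n, sd = 0.8) > 0)
  y2 <- as.integer(s + rnorm(n, sd = 0.8) > 0)
  effect <- (2 * y1 - 1) + rnorm(n, sd = 1.6) # child of the primary target
  noise <- rnorm(n)
  X <- cbind(parent1 = p1, parent2 = p2, effect = effect, noise = noise)
  Y <- data.frame(y1 = y1, y2 = y2)
  rk0 <- causal_forward_rank(X, Y, lambda = 0, rank_all = TRUE)
  rk2 <- causal_forward_rank(X, Y, lambda = 2, rank_all = TRUE)
  pos <- function(rk, f) match(f, rk$feature)
  expect_identical(pos(rk0, "effect"), 1L) # relevance alone favors the effect
  expect_lt(pos(rk2, "parent1"), pos(rk2, "noise"))
  expect_lt(pos(rk2, "parent2"), pos(rk2, "noise"))
  parents <- c("parent1", "parent2")
  expect_lte(average_cause_rank(rk2, parents), average_cause_rank(rk0, parents))
})

test_that("rankings expose tidy, glance and autoplot views", {
  inst <- random_instance(6, 80, m = 2, seed = 4)
  rk <- causal_forward_rank(inst$X, inst$Y, lambda = 1, v = 4)
  td <- tidy(rk)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("step", "feature", "relevance", "causal_term", "score"))
  gl <- glance(rk)
  expect_identical(gl$lambda, 1)
  expect_identical(gl$v, 4)
  expect_s3_class(autoplot(rk), "ggplot")
})

test_that("invalid configurations are rejected", {
  inst <- random_instance(5, 50, m = 1, seed = 2)
  expect_error(causal_forward_rank(inst$X, inst$Y, v = 6), "between 1")
  expect_error(causal_forward_rank(inst$X, inst$Y, lambda = -1), ">= 0")
  expect_error(causal_forward_rank(inst$X, rep(1L, 50)), "one class")
})
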