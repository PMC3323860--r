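test_that("naive Bayes separates well-separated clusters and normalizes posteriors", {
  set.seed(1)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3) + 6 * y
  te <- sample(n, 60)
  pred <- nb_fit_predict(X[-te, ], y[-te], X[te, ])
  expect_gt(auc(pred$prob, y[te]), 0.99)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
})

test_that("naive Bayes matches a hand Bayes-rule evaluation on 4 samples", {
  train_X <- matrix(c(0, 1, 10, 11), ncol = 1)
  train_y <- c(0L, 0L, 1L, 1L)
  test_X <- matrix(c(0.5, 10.5, 5.25), ncol = 1)
  pred <- nb_fit_predict(train_X, train_y, test_X)
  # per class: mean 0.5 / 10.5, var 0.5 (unbiased), priors 1/2
  lik <- function(x, mu) dnorm(x, mu, sqrt(0.5))
  manual <- lik(test_X[, 1], 10.5) / (lik(test_X[, 1], 0.5) + lik(test_X[, 1], 10.5))
  expect_equal(pred$prob, manual, tolerance = 1e-12)
  # duplicating a feature sharpens the posterior (naive independence)
  pred2 <- nb_fit_predict(cbind(train_X, train_X), train_y,
                          cbind(test_X, test_X))
  manual2 <- lik(test_X[, 1], 10.5)^2 /
    (lik(test_X[, 1], 0.5)^2 + lik(test_X[, 1], 10.5)^2)
  expect_equal(pred2$prob, manual2, tolerance = 1e-12)
})

test_that("naive Bayes agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(2)
  n <- 150
  y <- rbinom(n, 1, 0.4)
  X <- matrix(rnorm(n * 4), n, 4) + 1.5 * y
  colnames(X) <- paste0("f", 1:4)
  te <- 101:150
  pred <- nb_fit_predict(X[1:100, ], y[1:100], X[te, ])
  fit <- e1071::naiveBayes(X[1:100, ], factor(y[1:100]))
  ref <- predict(fit, X[te, ], type = "raw", threshold = 0, eps = 0)[, "1"]
  expect_equal(pred$prob, unname(ref), tolerance = 1e-6)
})

test_that("labels independent of features give chance-level AUC", {
  set.seed(3)
  aucs <- replicate(30, {
    y <- rbinom(120, 1, 0.5)
    X <- matrix(rnorm(120 * 5), 120, 5)
    pred <- nb_fit_predict(X[1:60, ], y[1:60], X[61:120, ])
    auc(pred$prob, y[61:120])
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("AUC follows the rank formulation with half-credit ties", {
  expect_identical(auc(1:10, rep(c(0L, 1L), each = 5)), 1)
  expect_identical(auc(10:1, rep(c(0L, 1L), each = 5)), 0)
  expect_identical(auc(rep(1, 10), rep(c(0L, 1L), each = 5)), 0.5)
  set.seed(4)
  for (i in 1:20) {
    s <- round(rnorm(30), 1) # induces ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- outer(s[y == 1], s[y == 0], function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(s, y), mean(pairs))
    expect_equal(auc(s, y) + auc(-s, y), 1)
  }
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("rmse, sar and f follow their definitions", {
  expect_identical(rmse(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_identical(rmse(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(rmse(c(0.8, 0.3), c(1, 0)), sqrt((0.04 + 0.09) / 2))
  expect_identical(sar(1, 1, 0), 1)
  expect_identical(sar(0.5, 0.5, 0.5), 0.5)
  expect_equal(sar(0.8, 0.7, 0.4), 0.7)
  # sar is exactly the mean of its three inputs
  set.seed(5)
  a <- runif(50); b <- runif(50); r <- runif(50)
  expect_equal(sar(a, b, r), (a + b + (1 - r)) / 3)
  expect_identical(f_score(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_identical(f_score(rep(0L, 6), c(1, 1, 0, 0, 1, 0)), 0)
  # TP=2 FP=1 FN=1
  expect_equal(f_score(c(1, 1, 1, 0), c(1, 1, 0, 1)), 2 / 3)
})

test_that("classifier comparison handles degenerate and asymmetric errors", {
  same <- c(TRUE, FALSE, TRUE, FALSE)
  out <- compare_classifiers(same, same, c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_identical(out$mcnemar_p, 1)
  expect_identical(out$wilcoxon_p, 1)
  # A always right, B wrong on 20 of 40: exact binomial with k=0, n=20
  err_a <- rep(FALSE, 40)
  err_b <- c(rep(TRUE, 20), rep(FALSE, 20))
  out <- compare_classifiers(err_a, err_b, rep(0, 40), as.numeric(err_b))
  expect_equal(out$mcnemar_p, 2 * (0.5^20))
  # symmetric discordance
  out <- compare_classifiers(c(rep(TRUE, 10), rep(FALSE, 10)),
                             c(rep(FALSE, 10), rep(TRUE, 10)),
                             runif(20), runif(20))
  expect_gt(out$mcnemar_p, 0.99)
})

test_that("Holm adjustment is step-down, monotone and capped", {
  expect_identical(holm_adjust(0.03), 0.03)
  # step-down by hand: 3*0.01 = 0.03; 2*0.03 = 0.06; max(0.06, 1*0.04) = 0.06
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(0.2, 4)), rep(0.8, 4))
  set.seed(6)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_identical(order(adj[order(p)]), 1:20)
})
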