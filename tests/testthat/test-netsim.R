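test_that("the default network has the documented structure", {
  net <- default_network(seed = 1, sigma = 0.1)
  expect_identical(nrow(net$nodes), 40L)
  counts <- table(net$nodes$role)
  expect_identical(as.integer(counts[c("indirect_cause", "direct_cause",
                                       "latent", "primary_target",
                                       "secondary_target", "effect",
                                       "irrelevant")]),
                   c(3L, 5L, 1L, 1L, 2L, 17L, 11L))
  # every direct cause has all three indirect causes as parents
  for (ch in 4:8) {
    expect_setequal(net$edges$parent[net$edges$child == ch], 1:3)
  }
  expect_setequal(net$edges$parent[net$edges$child == 9], 4:8)
  expect_setequal(net$edges$child[net$edges$parent == 9], 10:12)
  # effects are children of exactly one target, round-robin
  eff <- net$edges[net$edges$child %in% 13:29, ]
  eff <- eff[order(eff$child), ]
  expect_identical(eff$parent, rep(10:12, length.out = 17))
  # irrelevant nodes carry no edges
  expect_false(any(c(net$edges$parent, net$edges$child) %in% 30:40))
  expect_true(all(net$edges$weight >= -2 & net$edges$weight <= 2))
})

test_that("weight draws are seed-reproducible", {
  expect_identical(default_network(seed = 5)$edges$weight,
                   default_network(seed = 5)$edges$weight)
  expect_false(identical(default_network(seed = 5)$edges$weight,
                         default_network(seed = 6)$edges$weight))
})

test_that("simulation emits 36 standardized features, 3 balanced targets and truth", {
  net <- default_network(seed = 2, sigma = 0.1)
  d <- simulate_network(net, n_samples = 100, seed = 3)
  expect_identical(dim(d$features), c(100L, 36L))
  expect_false("x9" %in% names(d$features)) # latent never observed
  expect_named(d$targets, c("y1", "y2", "y3"))
  for (j in 1:3) {
    expect_lte(abs(sum(d$targets[[j]]) - 50), 1)
  }
  mus <- vapply(d$features, mean, numeric(1))
  sds <- vapply(d$features, sd, numeric(1))
  expect_true(all(abs(mus) < 1e-8))
  expect_true(all(abs(sds - 1) < 1e-6))
  expect_identical(sum(d$truth$role == "direct_cause"), 5L)
  # seed contract
  d2 <- simulate_network(net, n_samples = 100, seed = 3)
  expect_identical(d, d2)
})

test_that("at tiny noise an effect tracks its continuous target parent", {
  ok <- 0
  for (seed in 1:20) {
    net <- default_network(seed = seed, sigma = 0.01)
    d <- simulate_network(net, n_samples = 200, seed = seed + 1000)
    # x13 is a child of the continuous primary target (node 10); its
    # point-biserial correlation with the binarized y1 is bounded, so
    # check against the continuous signal via the class separation
    r <- abs(cor(d$features$x13, d$targets$y1))
    if (r > 0.7) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("zero weights give a globally independent dataset", {
  net <- default_network(seed = 4, sigma = 0.1)
  net$edges$weight <- 0
  net <- new_mimo_network(net$nodes, net$edges, noise_sd = net$noise_sd)
  d <- simulate_network(net, n_samples = 2000, seed = 5)
  rel <- relevance_scores(d$features, d$targets$y1)
  expect_lt(max(rel$relevance), 0.01)
})

test_that("cyclic specifications are rejected", {
  nodes <- tibble::tibble(id = 1:2, role = c("effect", "effect"))
  edges <- tibble::tibble(parent = c(1L, 2L), child = c(2L, 1L),
                          weight = c(1, 1))
  expect_error(new_mimo_network(nodes, edges, noise_sd = 0.1), "cycle")
})

test_that("median binarization splits and is affine-equivariant", {
  expect_identical(discretize_binary(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  set.seed(10)
  v <- rnorm(101)
  b <- discretize_binary(v)
  expect_lte(abs(sum(b) - (101 - sum(b))), 1)
  expect_identical(discretize_binary(3 * v + 7), b)
  expect_error(discretize_binary(rep(2, 5)), "constant")
})

test_that("network JSON round-trips", {
  net <- default_network(seed = 12, sigma = 0.2)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$edges$weight, net$edges$weight)
  expect_identical(back$nodes$role, net$nodes$role)
  expect_equal(back$noise_sd, net$noise_sd)
})
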