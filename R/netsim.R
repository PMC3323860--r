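# Linear-Gaussian causal-network simulator.
#
# The default benchmark is a 40-node DAG mimicking a disease study: a layer
# of indirect causes feeds a layer of direct causes, which feed a latent
# (unobserved) disease node; the latent node drives three observable
# targets (think survival, tumor size, grade), each target has downstream
# effect nodes, and a block of isolated nodes plays the role of irrelevant
# genes. Every structural equation is linear with Gaussian noise; targets
# are median-binarized for classification.

NODE_ROLES <- c("indirect_cause", "direct_cause", "latent", "primary_target",
                "secondary_target", "effect", "irrelevant")

#' Default 40-node benchmark network
#'
#' Builds the benchmark topology: nodes 1-3 (indirect causes) are each a
#' parent of every node 4-8 (direct causes); nodes 4-8 are parents of the
#' latent node 9; node 9 is the sole parent of the targets 10-12; each
#' effect node 13-29 is the child of exactly one continuous target,
#' assigned round-robin (10, 11, 12, 10, ...); nodes 30-40 are isolated.
#' Edge weights are drawn uniformly from `weight_range`.
#'
#' @param seed Integer seed making the weight draw reproducible.
#' @param sigma Structural-equation noise standard deviation (> 0).
#' @param weight_range Length-2 numeric, the uniform support of the edge
#'   weights (default `c(-2, 2)`).
#' @return A `mimo_network`: list with tibbles `nodes` (id, role) and
#'   `edges` (parent, child, weight), plus `noise_sd` and `weight_range`.
#' @export
#' @examples
#' net <- default_network(seed = 1, sigma = 0.1)
#' dplyr::count(net$nodes, role)
default_network <- function(seed = NULL, sigma = 0.1,
                            weight_range = c(-2, 2)) {
  if (sigma <= 0) stop("`sigma` must be positive")
  nodes <- tibble::tibble(
    id = 1:40,
    role = c(rep("indirect_cause", 3), rep("direct_cause", 5), "latent",
             "primary_target", rep("secondary_target", 2),
             rep("effect", 17), rep("irrelevant", 11))
  )
  edges <- dplyr::bind_rows(
    tidyr::expand_grid(parent = 1:3, child = 4:8),
    tibble::tibble(parent = 4:8, child = 9L),
    tibble::tibble(parent = 9L, child = 10:12),
    tibble::tibble(parent = rep(10:12, length.out = 17), child = 13:29)
  )
  if (!is.null(seed)) set.seed(seed)
  edges$weight <- stats::runif(nrow(edges), weight_range[1], weight_range[2])
  new_mimo_network(nodes, edges, noise_sd = sigma, weight_range = weight_range)
}

#' Construct a network specification
#'
#' @param nodes Tibble/data frame with columns `id` and `role` (one of
#'   indirect_cause, direct_cause, latent, primary_target,
#'   secondary_target, effect, irrelevant).
#' @param edges Tibble/data frame with columns `parent`, `child`, `weight`.
#' @param noise_sd Noise standard deviation.
#' @param weight_range Length-2 numeric (documentation of the draw support).
#' @return A `mimo_network` object. The graph is validated to be acyclic.
#' @export
new_mimo_network <- function(nodes, edges, noise_sd,
                             weight_range = c(-2, 2)) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "role") %in% names(nodes)),
            all(c("parent", "child", "weight") %in% names(edges)))
  if (!all(nodes$role %in% NODE_ROLES)) {
    stop("unknown node role(s): ",
         paste(setdiff(nodes$role, NODE_ROLES), collapse = ", "))
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  g <- igraph::graph_from_data_frame(
    edges[, c("parent", "child")], directed = TRUE,
    vertices = data.frame(name = nodes$id)
  )
  if (!igraph::is_dag(g)) stop("network specification contains a cycle")
  out <- list(nodes = nodes, edges = edges, noise_sd = noise_sd,
              weight_range = weight_range, graph = g)
  class(out) <- "mimo_network"
  out
}

#' @export
print.mimo_network <- function(x, ...) {
  cat("mimo_network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, noise sd ", x$noise_sd, "\n", sep = "")
  print(dplyr::count(x$nodes, .data$role))
  invisible(x)
}

#' Simulate a classification dataset from a network
#'
#' Samples the structural equations in topological order: root nodes are
#' standard normal, every other node is the weighted sum of its parents
#' plus `N(0, noise_sd^2)` noise. Observed features (everything except the
#' latent node and the raw targets) are centered and scaled; the three
#' target nodes are median-binarized into classes via
#' [discretize_binary()]. Effect nodes are children of the *continuous*
#' target variables; discretization applies only to the emitted classes.
#'
#' @param spec A `mimo_network`.
#' @param n_samples Number of samples (>= 20).
#' @param seed Integer seed for the noise draws.
#' @return A `mimo_dataset`: list with `features` (tibble, standardized),
#'   `targets` (tibble of 0/1 columns `y1`, `y2`, ...; primary first) and
#'   `truth` (tibble mapping `feature` to its causal `role`).
#' @export
simulate_network <- function(spec, n_samples = 100, seed = NULL) {
  stopifnot(inherits(spec, "mimo_network"))
  if (n_samples < 20) stop("`n_samples` must be at least 20")
  if (!is.null(seed)) set.seed(seed)

  ord <- as.integer(names(igraph::topo_sort(spec$graph)))
  V <- matrix(NA_real_, n_samples, nrow(spec$nodes),
              dimnames = list(NULL, paste0("x", spec$nodes$id)))
  for (node in ord) {
    par_edges <- spec$edges[spec$edges$child == node, ]
    j <- match(node, spec$nodes$id)
    if (nrow(par_edges) == 0) {
      V[, j] <- stats::rnorm(n_samples)
    } else {
      pj <- match(par_edges$parent, spec$nodes$id)
      V[, j] <- as.vector(V[, pj, drop = FALSE] %*% par_edges$weight) +
        stats::rnorm(n_samples, 0, spec$noise_sd)
    }
  }

  roles <- spec$nodes$role
  target_idx <- which(roles %in% c("primary_target", "secondary_target"))
  target_idx <- target_idx[order(match(roles[target_idx],
                                       c("primary_target", "secondary_target")))]
  feat_idx <- which(!roles %in% c("latent", "primary_target", "secondary_target"))

  targets <- lapply(target_idx, function(j) discretize_binary(V[, j]))
  names(targets) <- paste0("y", seq_along(targets))

  feats <- scale(V[, feat_idx, drop = FALSE])
  const <- attr(feats, "scaled:scale") == 0 | !is.finite(colSums(feats))
  if (any(const)) {
    warning("constant feature column(s) left at 0: ",
            paste(colnames(feats)[const], collapse = ", "))
    feats[, const] <- 0
  }

  out <- list(
    features = tibble::as_tibble(feats),
    targets = tibble::as_tibble(targets),
    truth = tibble::tibble(feature = colnames(feats), role = roles[feat_idx])
  )
  class(out) <- c("mimo_dataset", class(out))
  out
}

#' @export
print.mimo_dataset <- function(x, ...) {
  cat("mimo_dataset: ", nrow(x$features), " samples, ", ncol(x$features),
      " features, ", ncol(x$targets), " binary targets\n", sep = "")
  invisible(x)
}

#' Median binarization of a continuous variable
#'
#' Label 1 iff the value exceeds the sample median, 0 otherwise. For
#' continuous data this yields classes balanced within one sample.
#' Invariant under increasing affine transforms of the input.
#'
#' @param values Numeric vector, length >= 2, not constant.
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' discretize_binary(c(1, 2, 3, 4)) # 0 0 1 1
discretize_binary <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("cannot binarize a constant vector")
  as.integer(values > stats::median(values))
}

#' Read / write a network specification as JSON
#'
#' The on-disk schema is
#' `{"nodes":[{"id","role"}], "edges":[{"parent","child","weight"}],
#'  "noise_sd", "weight_range"}`.
#'
#' @param path File path.
#' @return `read_network_json()` returns a `mimo_network`;
#'   `write_network_json()` returns `path` invisibly.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_mimo_network(obj$nodes, obj$edges, noise_sd = obj$noise_sd,
                   weight_range = obj$weight_range)
}

#' @rdname read_network_json
#' @param spec A `mimo_network` to serialize.
#' @export
write_network_json <- function(spec, path) {
  jsonlite::write_json(
    list(nodes = spec$nodes, edges = spec$edges, noise_sd = spec$noise_sd,
         weight_range = spec$weight_range),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
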