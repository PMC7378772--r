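# Shared toy corpora and random-graph builders used across test files.

corpus_from_codes <- function(code_lists) {
  filter_valid(lapply(seq_along(code_lists), function(i) {
    accident_chain(code_lists[[i]], paste0("c", i))
  }))
}

# Three sample chains whose L-space graph is small enough to check by hand.
fig1_corpus <- function() {
  corpus_from_codes(list(c(1, 2, 3, 4, 5, 6),
                         c(7, 3, 4, 8, 5, 6),
                         c(8, 7, 3, 4, 9)))
}

# {[1,2,3],[1,2,4],[2,3,4]}: node 2 has k = 3, s_out = 3, s_in = 2; the
# 2-3-4 triangle with max weight 2 gives node 3 a weighted CC of 0.25.
toy4_corpus <- function() {
  corpus_from_codes(list(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4)))
}

network_from_adjacency <- function(A, weights = NULL) {
  # Builds a hazard_network directly from a 0/1 adjacency (codes 1..n),
  # bypassing chain ingestion, for graph-level property tests.
  n <- nrow(A)
  W <- matrix(0L, n, n, dimnames = list(1:n, 1:n))
  W[A > 0] <- if (is.null(weights)) 1L else as.integer(weights[A > 0])
  structure(list(codes = 1:n, W = W, codebook = NULL),
            class = "hazard_network")
}

random_digraph <- function(n, p) {
  A <- matrix(stats::rbinom(n * n, 1L, p), n, n)
  diag(A) <- 0L
  network_from_adjacency(A)
}

random_weighted_network <- function(n, p, max_w = 9L) {
  A <- matrix(stats::rbinom(n * n, 1L, p), n, n)
  diag(A) <- 0L
  w <- matrix(sample.int(max_w, n * n, replace = TRUE), n, n)
  network_from_adjacency(A, weights = w * A)
}

# igraph twin of a hazard_network (unweighted, directed), for cross-checks.
as_igraph <- function(network) {
  A <- (network$W > 0L) * 1
  diag(A) <- 0
  igraph::graph_from_adjacency_matrix(A, mode = "directed")
}

# two-node metric table assembled by hand (betweenness needs >= 3 nodes)
compute_node_metrics_small <- function(net) {
  ds <- degrees_and_strengths(net)
  ds$label <- as.character(ds$code)
  ds$c_unw <- NA_real_; ds$c_w <- NA_real_; ds$betweenness <- 0
  ds
}
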