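test_that("degrees and strengths on hand-checked toys", {
  ds <- degrees_and_strengths(build_network(toy4_corpus()))
  n2 <- ds[ds$code == 2, ]
  expect_equal(n2$k, 3L)
  expect_equal(n2$s_out, 3L)
  expect_equal(n2$s_in, 2L)
  expect_equal(n2$s, 5L)
  tri <- degrees_and_strengths(build_network(corpus_from_codes(
    list(c(1, 2, 3, 1)))))
  expect_equal(tri$k_in, rep(1L, 3))
  expect_equal(tri$k_out, rep(1L, 3))
  expect_equal(tri$s, rep(2L, 3))
})

test_that("strength totals conserve the transition count", {
  set.seed(5)
  corpora <- list(beijing_chains(), toy4_corpus())
  corpora <- c(corpora, list(generate_chains(default_generator_model(), 200)))
  for (corpus in corpora) {
    ds <- degrees_and_strengths(build_network(corpus))
    lens <- vapply(corpus$chains, length, integer(1))
    expect_equal(sum(ds$s_in), sum(lens - 1L))
    expect_equal(sum(ds$s_out), sum(lens - 1L))
  }
})

test_that("un-weighted clustering: triangles, stars, and the fixture", {
  tri <- undirected_projection(build_network(corpus_from_codes(list(c(1, 2, 3, 1)))))
  expect_equal(unname(unweighted_cc(tri)), rep(1, 3))
  star <- undirected_projection(build_network(corpus_from_codes(
    list(c(1, 2), c(1, 3), c(1, 4)))))
  expect_equal(unweighted_cc(star, node = 1), 0)
  expect_true(is.na(unweighted_cc(star, node = 2)))
  g <- global_cc(tri)
  expect_equal(g$C_unw, 1)
  expect_equal(g$defined_cc_count, 3L)
})

test_that("un-weighted clustering agrees with igraph local transitivity", {
  skip_if_not_installed("igraph")
  net <- build_network(beijing_chains(), beijing_codebook())
  view <- undirected_projection(net)
  g <- igraph::graph_from_adjacency_matrix((view$U > 0) * 1, mode = "undirected")
  ref <- igraph::transitivity(g, type = "local", isolates = "NaN")
  ours <- unweighted_cc(view)
  expect_equal(unname(ours[!is.na(ours)]), unname(ref[!is.nan(ref)]),
               tolerance = 1e-12)
  expect_equal(which(is.na(ours)), which(is.nan(ref)))
})

test_that("weighted clustering: derived toy value and boundary behaviour", {
  view <- undirected_projection(build_network(toy4_corpus()))
  norm <- normalized_weights(view)
  expect_equal(norm$max_w, 2L)
  expect_equal(weighted_cc(view, norm, node = 3), 0.25)
  # k >= 2 but no closed triangle -> 0
  path <- undirected_projection(build_network(corpus_from_codes(list(c(1, 2, 3)))))
  expect_equal(weighted_cc(path, node = 2), 0)
  # triangle with all weights at the maximum: weighted equals un-weighted
  tri <- undirected_projection(build_network(corpus_from_codes(list(c(1, 2, 3, 1)))))
  expect_equal(unname(weighted_cc(tri)), unname(unweighted_cc(tri)))
})

test_that("weighted CC never exceeds un-weighted, and equals it at equal weights", {
  set.seed(9)
  for (rep in 1:20) {
    net <- random_weighted_network(sample(5:10, 1), 0.4)
    view <- undirected_projection(net)
    cu <- unweighted_cc(view)
    cw <- weighted_cc(view)
    ok <- !is.na(cu)
    expect_true(all(cw[ok] <= cu[ok] + 1e-12))
    # flatten the combined weights: every triangle term becomes 1
    vflat <- view
    vflat$U[vflat$U > 0L] <- 1L
    expect_equal(weighted_cc(vflat), unweighted_cc(vflat))
  }
  fix <- undirected_projection(build_network(beijing_chains(), beijing_codebook()))
  cu <- unweighted_cc(fix); cw <- weighted_cc(fix)
  expect_true(all(cw[!is.na(cu)] <= cu[!is.na(cu)] + 1e-12))
})

test_that("shortest-path counts on elementary digraphs", {
  path <- build_network(corpus_from_codes(list(c(1, 2, 3))))
  pc <- shortest_path_counts(path)
  expect_equal(pc$D["1", "3"], 2)
  expect_equal(pc$S["1", "3"], 1)
  diamond <- build_network(corpus_from_codes(list(c(1, 2, 4), c(1, 3, 4))))
  pd <- shortest_path_counts(diamond)
  expect_equal(pd$S["1", "4"], 2)
  expect_equal(pd$D["4", "1"], Inf)
  expect_equal(pd$S["4", "1"], 0)
})

test_that("betweenness on elementary digraphs matches hand enumeration", {
  path <- build_network(corpus_from_codes(list(c(1, 2, 3))))
  pc <- shortest_path_counts(path)
  b <- node_betweenness(pc)
  expect_equal(unname(b), c(0, 0.5, 0))
  expect_equal(unname(node_betweenness(pc, norm = "unordered")["2"]), 1)
  eb <- edge_betweenness(pc, path)
  expect_equal(eb$betweenness[eb$src == 1 & eb$dst == 2], 2 / 6)
  expect_error(node_betweenness(shortest_path_counts(
    build_network(corpus_from_codes(list(c(1, 2)))))), "at least 3")
})

test_that("pure sources and sinks have zero node betweenness", {
  ds <- degrees_and_strengths(build_network(beijing_chains()))
  b <- node_betweenness(shortest_path_counts(build_network(beijing_chains())))
  ends <- as.character(ds$code[ds$s_in == 0 | ds$s_out == 0])
  expect_true(all(b[ends] == 0))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("betweenness equals the exhaustive enumeration oracle on random digraphs", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    net <- random_digraph(n, stats::runif(1, 0.15, 0.45))
    ours_n <- node_betweenness(shortest_path_counts(net))
    ref <- oracle_betweenness(net$W)
    expect_equal(unname(ours_n), ref$node, tolerance = 1e-12)
    ours_e <- edge_betweenness(shortest_path_counts(net), net)
    if (nrow(ours_e)) {
      ref_e <- ref$edge[order(ref$edge$src, ref$edge$dst), ]
      expect_equal(ours_e$betweenness, ref_e$betweenness, tolerance = 1e-12)
    }
  }
})

test_that("betweenness agrees with igraph on the fixture network", {
  skip_if_not_installed("igraph")
  net <- build_network(beijing_chains(), beijing_codebook())
  n <- length(net$codes)
  g <- as_igraph(net)
  ref <- igraph::betweenness(g, directed = TRUE) / ((n - 1) * (n - 2))
  ours <- node_betweenness(shortest_path_counts(net))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
  ref_e <- igraph::edge_betweenness(g, directed = TRUE) / (n * (n - 1))
  el <- igraph::as_edgelist(g, names = TRUE)
  ours_e <- edge_betweenness(shortest_path_counts(net), net)
  key <- paste(ours_e$src, ours_e$dst)
  expect_equal(ours_e$betweenness,
               ref_e[match(key, paste(el[, 1], el[, 2]))], tolerance = 1e-10)
})

test_that("metrics are invariant to relabeling hazard codes", {
  set.seed(13)
  corpus <- toy4_corpus()
  perm <- c(`1` = 40L, `2` = 7L, `3` = 19L, `4` = 2L)
  relabeled <- corpus_from_codes(lapply(corpus$chains, function(ch) {
    unname(perm[as.character(as.integer(ch))])
  }))
  m1 <- compute_node_metrics(build_network(corpus))
  m2 <- compute_node_metrics(build_network(relabeled))
  m2r <- m2[match(unname(perm[as.character(m1$code)]), m2$code), ]
  for (col in c("k_in", "k_out", "k", "s_in", "s_out", "s", "c_unw", "c_w",
                "betweenness")) {
    expect_equal(unname(m2r[[col]]), unname(m1[[col]]), info = col)
  }
})

test_that("undirected betweenness option symmetrizes the graph", {
  net <- build_network(corpus_from_codes(list(c(1, 2, 3))))
  pc <- shortest_path_counts(net, direction = "undirected")
  expect_equal(pc$D["3", "1"], 2)
  expect_equal(unname(node_betweenness(pc)["2"]), 1)
})
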