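test_that("L-space construction accumulates consecutive-pair weights", {
  net <- build_network(fig1_corpus())
  expect_equal(length(net$codes), 9L)
  expect_equal(net$W["3", "4"], 3L)
  expect_equal(net$W["5", "6"], 2L)
  expect_equal(net$W["1", "2"], 1L)
  one <- build_network(corpus_from_codes(list(c(1, 2))))
  expect_equal(length(one$codes), 2L)
  expect_equal(one$W["1", "2"], 1L)
  expect_equal(sum(one$W), 1L)
})

test_that("node set is the chain support, or the full codebook when given", {
  cb <- beijing_codebook()
  corpus <- beijing_chains(cb)
  expect_equal(length(build_network(corpus)$codes), 49L)
  net <- build_network(corpus, codebook = cb)
  expect_equal(length(net$codes), 61L)
  # hazards identified in the sample but absent from every printed chain
  # stay as isolated nodes
  iso <- net$codes[rowSums(net$W) + colSums(net$W) == 0]
  expect_equal(length(iso), 12L)
  expect_true(all(c(2, 11, 59) %in% iso))
})

test_that("total edge instances conserve the per-chain transition counts", {
  for (corpus in list(fig1_corpus(), toy4_corpus(), beijing_chains())) {
    net <- build_network(corpus)
    lens <- vapply(corpus$chains, length, integer(1))
    expect_equal(sum(net$W), sum(lens - 1L))
  }
})

test_that("network is invariant to the order of chains in the corpus", {
  set.seed(11)
  corpus <- beijing_chains()
  shuffled <- structure(list(chains = sample(corpus$chains),
                             excluded_count = 0L), class = "chain_corpus")
  expect_equal(build_network(shuffled)$W, build_network(corpus)$W)
})

test_that("empty corpus yields an empty network, not an error", {
  net <- build_network(filter_valid(list()))
  expect_equal(length(net$codes), 0L)
  s <- summarize_network(net)
  expect_equal(unlist(s), c(node_count = 0L, edge_instance_count = 0L,
                            unique_edge_count = 0L, max_weight = 0L))
})

test_that("fixture summary counts match independent recomputation", {
  # frozen values cross-checked against an independent graph library on the
  # packaged 327 chains
  s <- summarize_network(build_network(beijing_chains(), beijing_codebook()))
  expect_equal(s$node_count, 61L)
  expect_equal(s$edge_instance_count, 886L)
  expect_equal(s$unique_edge_count, 134L)
  expect_equal(s$max_weight, 108L)
})

test_that("undirected projection combines reciprocal weights by sum or max", {
  net <- build_network(corpus_from_codes(list(c(1, 2, 1, 2))))  # 1→2 w2, 2→1 w1
  vs <- undirected_projection(net, rule = "sum")
  expect_equal(vs$U["1", "2"], 3L)
  vm <- undirected_projection(net, rule = "max")
  expect_equal(vm$U["1", "2"], 2L)
  one_way <- build_network(corpus_from_codes(list(c(1, 2), c(1, 2))))
  expect_equal(undirected_projection(one_way)$U["1", "2"], 2L)
})

test_that("projection is symmetric and conserves total weight under the sum rule", {
  set.seed(3)
  for (rep in 1:10) {
    net <- random_weighted_network(sample(4:9, 1), 0.4)
    v <- undirected_projection(net, rule = "sum")
    expect_equal(v$U, t(v$U))
    expect_equal(sum(v$U[upper.tri(v$U)]) + sum(diag(v$U)) / 1,
                 sum(net$W) + sum(diag(net$W)))
    expect_false(any(mapply(function(code, nb) code %in% nb,
                            v$codes, v$neighbors)))
  }
})

test_that("self-loops stay in the weight map but out of neighbour sets", {
  net <- build_network(corpus_from_codes(list(c(1, 1, 2))))
  expect_equal(net$W["1", "1"], 1L)
  v <- undirected_projection(net)
  expect_equal(v$neighbors[["1"]], 2L)
  ds <- degrees_and_strengths(net)
  expect_equal(ds$k[ds$code == 1], 1L)       # loop excluded from degree
  expect_equal(ds$s_out[ds$code == 1], 2L)   # loop event still counted
})

test_that("Pajek export writes the arcs dialect and round-trips", {
  net <- build_network(corpus_from_codes(list(c(1, 2), c(1, 2), c(1, 2))))
  f <- withr::local_tempfile(fileext = ".net")
  write_pajek(net, f)
  lines <- readLines(f)
  expect_equal(lines[1], "*Vertices 2")
  expect_true("*Arcs" %in% lines)
  expect_equal(lines[length(lines)], "1 2 3")
  fix <- build_network(beijing_chains(), beijing_codebook())
  f2 <- withr::local_tempfile(fileext = ".net")
  write_pajek(fix, f2)
  back <- read_pajek(f2)
  expect_equal(back$W, fix$W)
  empty <- build_network(filter_valid(list()))
  f3 <- withr::local_tempfile(fileext = ".net")
  write_pajek(empty, f3)
  expect_equal(readLines(f3)[1], "*Vertices 0")
})

test_that("edge-list export matches the weight map", {
  net <- build_network(toy4_corpus())
  f <- withr::local_tempfile(fileext = ".csv")
  write_edgelist(net, f)
  tab <- utils::read.csv(f)
  expect_equal(nrow(tab), sum(net$W > 0))
  expect_equal(tab$weight[tab$src == 1 & tab$dst == 2], 2L)
})
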