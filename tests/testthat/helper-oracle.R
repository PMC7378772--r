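# Exhaustive shortest-path oracle: enumerates every simple path between
# every ordered node pair by depth-first search, keeps the minimum-length
# ones, and derives betweenness by literal counting. Deliberately naive and
# independent of the package's BFS/multiplicity machinery; only usable on
# small graphs (<= 8 nodes or so).

enumerate_simple_paths <- function(A, from, to) {
  n <- nrow(A)
  paths <- list()
  visit <- function(path) {
    cur <- path[length(path)]
    if (cur == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in which(A[cur, ] > 0)) {
      if (!(nxt %in% path)) visit(c(path, nxt))
    }
  }
  if (from == to) return(list())
  visit(from)
  paths
}

oracle_shortest_paths <- function(A) {
  # list indexed [[j]][[k]] of the minimal-length simple paths j -> k
  n <- nrow(A)
  out <- vector("list", n)
  for (j in 1:n) {
    out[[j]] <- vector("list", n)
    for (k in 1:n) {
      if (j == k) next
      ps <- enumerate_simple_paths(A, j, k)
      if (length(ps)) {
        lens <- vapply(ps, length, integer(1))
        out[[j]][[k]] <- ps[lens == min(lens)]
      }
    }
  }
  out
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  sp <- oracle_shortest_paths(A)
  node_raw <- numeric(n)
  edges <- which(A > 0, arr.ind = TRUE)
  edge_raw <- numeric(nrow(edges))
  for (j in 1:n) for (k in 1:n) {
    ps <- sp[[j]][[k]]
    if (j == k || is.null(ps)) next
    p_jk <- length(ps)
    for (i in setdiff(1:n, c(j, k))) {
      through <- sum(vapply(ps, function(p) i %in% p[-c(1, length(p))],
                            logical(1)))
      node_raw[i] <- node_raw[i] + through / p_jk
    }
    for (r in seq_len(nrow(edges))) {
      u <- edges[r, 1]; v <- edges[r, 2]
      uses <- sum(vapply(ps, function(p) {
        any(p[-length(p)] == u & p[-1] == v)
      }, logical(1)))
      edge_raw[r] <- edge_raw[r] + uses / p_jk
    }
  }
  list(node = node_raw / ((n - 1) * (n - 2)),
       edge = data.frame(src = edges[, 1], dst = edges[, 2],
                         betweenness = edge_raw / (n * (n - 1))))
}
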