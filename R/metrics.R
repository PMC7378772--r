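#' Degrees and strengths of every hazard
#'
#' Degree counts distinct neighbours; strength sums event frequencies
#' (edge weights). Both split into in/out components on the directed
#' network; `k` is the neighbour count in the undirected projection.
#' Self-loops are excluded from degrees and neighbour counts but their
#' events still count toward strength.
#'
#' @param network a `hazard_network`.
#' @return data.frame with columns `code`, `k_in`, `k_out`, `k`, `s_in`,
#'   `s_out`, `s`.
#' @export
degrees_and_strengths <- function(network) {
  stopifnot(inherits(network, "hazard_network"))
  W <- network$W
  A <- W > 0L
  diag(A) <- FALSE
  und <- A | t(A)
  data.frame(code = network$codes,
             k_in = as.integer(colSums(A)),
             k_out = as.integer(rowSums(A)),
             k = as.integer(rowSums(und)),
             s_in = as.integer(colSums(W)),
             s_out = as.integer(rowSums(W)),
             s = as.integer(colSums(W) + rowSums(W)))
}

#' Max-normalized edge weights of an undirected view
#'
#' Weights are rescaled by the maximum combined weight in the network so
#' every normalized weight lies in (0, 1] and the weighted clustering
#' coefficient is bounded by the un-weighted one.
#'
#' @param view an `undirected_view`.
#' @return list with `max_w` and the normalized symmetric matrix `Wn`
#'   (diagonal zeroed).
#' @export
normalized_weights <- function(view) {
  stopifnot(inherits(view, "undirected_view"))
  U <- view$U
  diag(U) <- 0L
  max_w <- if (length(U)) max(U) else 0L
  Wn <- if (max_w > 0L) U / max_w else U * 0
  list(max_w = as.integer(max_w), Wn = Wn)
}

#' Un-weighted local clustering coefficient
#'
#' Fraction of a hazard's neighbour pairs that are themselves adjacent:
#' `2 e(i) / (k (k - 1))` with `e(i)` the number of edges inside the
#' neighbourhood. Undefined (`NA`) for nodes with fewer than two
#' neighbours.
#'
#' @param view an `undirected_view`.
#' @param node a hazard code, or `NULL` (default) for all nodes.
#' @return named numeric vector (or scalar when `node` given); `NA` where
#'   undefined.
#' @export
unweighted_cc <- function(view, node = NULL) {
  stopifnot(inherits(view, "undirected_view"))
  A <- view$U > 0L
  diag(A) <- FALSE
  k <- rowSums(A)
  # e(i): edges among neighbours = half the count of ordered adjacent pairs
  e2 <- vapply(seq_along(view$codes), function(i) {
    nb <- A[i, ]
    sum(A[nb, nb, drop = FALSE])
  }, numeric(1))
  cc <- ifelse(k >= 2, e2 / (k * (k - 1)), NA_real_)
  names(cc) <- view$codes
  if (is.null(node)) cc else unname(cc[as.character(node)])
}

#' Weighted local clustering coefficient
#'
#' Extends the un-weighted coefficient by crediting each closed triangle
#' with the product of its three max-normalized weights, so frequently
#' co-occurring hazard triangles dominate:
#' `c_w(i) = 2/(k(k-1)) * sum over unordered neighbour pairs {j,l} closing
#' a triangle with i of wn(i,j) wn(j,l) wn(i,l)`.
#' Undefined (`NA`) when `k < 2`; always `<=` the un-weighted value.
#'
#' @param view an `undirected_view`.
#' @param norm output of [normalized_weights()]; computed when `NULL`.
#' @param node a hazard code, or `NULL` for all nodes.
#' @return named numeric vector (or scalar); `NA` where undefined.
#' @export
weighted_cc <- function(view, norm = NULL, node = NULL) {
  stopifnot(inherits(view, "undirected_view"))
  if (is.null(norm)) norm <- normalized_weights(view)
  Wn <- norm$Wn
  A <- view$U > 0L
  diag(A) <- FALSE
  k <- rowSums(A)
  # (Wn^3)[i,i] sums wn(i,j) wn(j,l) wn(l,i) over ordered pairs (j,l):
  # twice the unordered triangle sum
  tri2 <- diag(Wn %*% Wn %*% Wn)
  cc <- ifelse(k >= 2, tri2 / (k * (k - 1)), NA_real_)
  names(cc) <- view$codes
  if (is.null(node)) cc else unname(cc[as.character(node)])
}

#' Network-average clustering coefficients
#'
#' Averages the local coefficients over the nodes for which they are
#' defined (at least two neighbours); nodes without a defined coefficient
#' are excluded from the mean by default, or counted as zero over all `n`
#' nodes with `undefined = "zero"` for sensitivity checks.
#'
#' @param view an `undirected_view`.
#' @param undefined `"exclude"` (default) or `"zero"`.
#' @return list with `C_unw`, `C_w` and `defined_cc_count`.
#' @export
global_cc <- function(view, undefined = c("exclude", "zero")) {
  undefined <- match.arg(undefined)
  cu <- unweighted_cc(view)
  cw <- weighted_cc(view)
  defined <- !is.na(cu)
  if (undefined == "exclude") {
    list(C_unw = mean(cu[defined]), C_w = mean(cw[defined]),
         defined_cc_count = sum(defined))
  } else {
    n <- length(cu)
    list(C_unw = sum(cu[defined]) / n, C_w = sum(cw[defined]) / n,
         defined_cc_count = sum(defined))
  }
}

#' All-pairs shortest-path distances and multiplicities
#'
#' Breadth-first search from every node of the unweighted graph (hop-count
#' path length: edge weights carry event frequency, never distance).
#' Direction is respected by default; `direction = "undirected"` symmetrizes
#' the adjacency first. Self-loops are ignored.
#'
#' @param network a `hazard_network`.
#' @param direction `"directed"` (default) or `"undirected"`.
#' @return a `path_counts`: list with `codes`, integer distance matrix `D`
#'   (`Inf` when unreachable) and path-multiplicity matrix `S`
#'   (`S[j, k]` = number of distinct shortest directed paths j -> k;
#'   0 when unreachable, 1 on the diagonal).
#' @export
shortest_path_counts <- function(network, direction = c("directed", "undirected")) {
  direction <- match.arg(direction)
  stopifnot(inherits(network, "hazard_network"))
  A <- network$W > 0L
  diag(A) <- FALSE
  if (direction == "undirected") A <- A | t(A)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (src in seq_len(n)) {
    dist <- rep(Inf, n)
    sigma <- numeric(n)
    dist[src] <- 0
    sigma[src] <- 1
    frontier <- src
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) {
        vs <- which(A[u, ])
        for (v in vs) {
          if (is.infinite(dist[v])) {
            dist[v] <- d
            nxt <- c(nxt, v)
            sigma[v] <- sigma[v] + sigma[u]
          } else if (dist[v] == d) {
            sigma[v] <- sigma[v] + sigma[u]
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[src, ] <- dist
    S[src, ] <- sigma
  }
  structure(list(codes = network$codes, D = D, S = S, direction = direction),
            class = "path_counts")
}

#' Normalized node betweenness centrality
#'
#' For each hazard `i`, the sum over ordered origin-destination pairs
#' `(j, k)`, `j != k != i`, of the fraction of shortest `j -> k` paths
#' passing through `i` (unreachable pairs contribute zero), divided by the
#' number of such pairs `(n-1)(n-2)` so values lie in `[0, 1]`. The halved
#' (unordered-pair) constant is available via `norm = "unordered"`.
#'
#' @param counts a `path_counts`.
#' @param norm `"ordered"` (default) or `"unordered"`.
#' @return named numeric vector of betweenness values per hazard code.
#' @export
node_betweenness <- function(counts, norm = c("ordered", "unordered")) {
  norm <- match.arg(norm)
  stopifnot(inherits(counts, "path_counts"))
  D <- counts$D; S <- counts$S
  n <- nrow(D)
  if (n < 3L) stop("node betweenness needs at least 3 nodes", call. = FALSE)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    through <- is.finite(D) & (outer(D[, i], D[i, ], "+") == D)
    contrib <- outer(S[, i], S[i, ])
    ok <- through & S > 0
    ok[i, ] <- FALSE; ok[, i] <- FALSE; diag(ok) <- FALSE
    raw[i] <- sum(contrib[ok] / S[ok])
  }
  denom <- (n - 1) * (n - 2)
  if (norm == "unordered") denom <- denom / 2
  stats::setNames(raw / denom, counts$codes)
}

#' Normalized edge betweenness centrality
#'
#' For each directed edge `(u, v)` of the network, the sum over ordered
#' pairs `(j, k)` of the fraction of shortest `j -> k` paths traversing the
#' edge, divided by `n(n-1)` (or its half with `norm = "unordered"`).
#'
#' @param counts a `path_counts`.
#' @param network the `hazard_network` the counts were computed from
#'   (supplies the edge set).
#' @param norm `"ordered"` (default) or `"unordered"`.
#' @return data.frame with columns `src`, `dst`, `weight`, `betweenness`.
#' @export
edge_betweenness <- function(counts, network,
                             norm = c("ordered", "unordered")) {
  norm <- match.arg(norm)
  stopifnot(inherits(counts, "path_counts"),
            inherits(network, "hazard_network"))
  D <- counts$D; S <- counts$S
  n <- nrow(D)
  if (n < 2L) stop("edge betweenness needs at least 2 nodes", call. = FALSE)
  A <- network$W > 0L
  diag(A) <- FALSE
  if (counts$direction == "undirected") A <- A | t(A)
  idx <- which(A, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  raw <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    u <- idx[r, 1L]; v <- idx[r, 2L]
    through <- is.finite(D) & (outer(D[, u], D[v, ], "+") + 1 == D)
    contrib <- outer(S[, u], S[v, ])
    ok <- through & S > 0
    raw[r] <- sum(contrib[ok] / S[ok])
  }
  denom <- n * (n - 1)
  if (norm == "unordered") denom <- denom / 2
  data.frame(src = network$codes[idx[, 1L]],
             dst = network$codes[idx[, 2L]],
             weight = network$W[idx],
             betweenness = raw / denom)
}

#' Full per-hazard metric table
#'
#' Convenience wrapper assembling degrees, strengths, both clustering
#' coefficients and node betweenness into one table, with labels resolved
#' from the network's codebook when present.
#'
#' @param network a `hazard_network`.
#' @param projection_rule passed to [undirected_projection()].
#' @param direction,norm passed to the betweenness computations.
#' @return data.frame, one row per hazard: `code`, `label`, `k_in`,
#'   `k_out`, `k`, `s_in`, `s_out`, `s`, `c_unw`, `c_w`, `betweenness`.
#' @export
compute_node_metrics <- function(network, projection_rule = "sum",
                                 direction = "directed", norm = "ordered") {
  ds <- degrees_and_strengths(network)
  view <- undirected_projection(network, rule = projection_rule)
  cu <- unweighted_cc(view)
  cw <- weighted_cc(view)
  b <- node_betweenness(shortest_path_counts(network, direction = direction),
                        norm = norm)
  label <- if (!is.null(network$codebook)) {
    codebook_label(network$codebook, ds$code)
  } else as.character(ds$code)
  cbind(ds[, "code", drop = FALSE], label = label,
        ds[, c("k_in", "k_out", "k", "s_in", "s_out", "s")],
        c_unw = unname(cu), c_w = unname(cw), betweenness = unname(b))
}
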