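#' Build the cascading-hazard network from a chain corpus
#'
#' L-space construction: every hazard is a node and each consecutive ordered
#' pair in a chain contributes one event to the weight of the directed edge
#' between the two hazards. No multiple edges are kept — repeated transitions
#' accumulate as integer weights.
#'
#' @param corpus a `chain_corpus` (see [filter_valid()]) or list of chains,
#'   each of length >= 2.
#' @param codebook optional `hazard_codebook`. When supplied, every codebook
#'   hazard becomes a node even if it appears in no retained chain (hazards
#'   identified in the accident sample but detached from the cascade
#'   network stay visible as isolated nodes); without it the node set is the
#'   union of chain supports.
#' @return a `hazard_network`: list with `codes` (sorted node codes), `W`
#'   (dense integer weight matrix, dimnames = codes) and `codebook`.
#' @examples
#' corpus <- filter_valid(list(parse_chain("1→2→3"), parse_chain("2→3")))
#' net <- build_network(corpus)
#' net$W["2", "3"]
#' @export
build_network <- function(corpus, codebook = NULL) {
  chains <- if (inherits(corpus, "chain_corpus")) corpus$chains else corpus
  lens <- vapply(chains, length, integer(1))
  if (any(lens < 2L)) {
    stop("build_network: all chains must have length >= 2 (run filter_valid first)",
         call. = FALSE)
  }
  support <- sort(unique(unlist(lapply(chains, as.integer))))
  codes <- if (is.null(codebook)) support else sort(unique(c(codebook$code, support)))
  n <- length(codes)
  W <- matrix(0L, n, n, dimnames = list(codes, codes))
  for (ch in chains) {
    v <- as.integer(ch)
    from <- match(v[-length(v)], codes)
    to <- match(v[-1L], codes)
    for (t in seq_along(from)) W[from[t], to[t]] <- W[from[t], to[t]] + 1L
  }
  structure(list(codes = codes, W = W, codebook = codebook),
            class = "hazard_network")
}

#' @export
print.hazard_network <- function(x, ...) {
  s <- summarize_network(x)
  cat(sprintf("<hazard_network> %d nodes, %d directed edges (%d event instances), max weight %d\n",
              s$node_count, s$unique_edge_count, s$edge_instance_count,
              s$max_weight))
  invisible(x)
}

#' Summary counts of a hazard network
#'
#' @param network a `hazard_network`.
#' @return list with `node_count`, `edge_instance_count` (sum of all
#'   weights, i.e. total observed transitions), `unique_edge_count`
#'   (ordered pairs with positive weight) and `max_weight`.
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "hazard_network"))
  W <- network$W
  list(node_count = length(network$codes),
       edge_instance_count = as.integer(sum(W)),
       unique_edge_count = as.integer(sum(W > 0L)),
       max_weight = if (length(W)) as.integer(max(W)) else 0L)
}

#' Undirected projection of a hazard network
#'
#' Clustering is a property of neighbourhood structure, not of cascade
#' direction, so edge direction is discarded. Reciprocal directed weights
#' are combined per unordered pair, by default summed (the weight is an
#' event frequency, so the total interaction count is the natural
#' symmetrization); `rule = "max"` keeps the larger of the two instead.
#' Self-loops are retained in the weight matrix but never enter neighbour
#' sets.
#'
#' @param network a `hazard_network`.
#' @param rule `"sum"` (default) or `"max"`.
#' @return an `undirected_view`: list with `codes`, symmetric weight matrix
#'   `U`, and `neighbors` (list of neighbour codes per node, self excluded).
#' @export
undirected_projection <- function(network, rule = c("sum", "max")) {
  rule <- match.arg(rule)
  stopifnot(inherits(network, "hazard_network"))
  W <- network$W
  U <- if (rule == "sum") W + t(W) else pmax(W, t(W))
  adj <- U > 0L
  diag(adj) <- FALSE
  neighbors <- lapply(seq_along(network$codes),
                      function(i) network$codes[adj[i, ]])
  names(neighbors) <- network$codes
  structure(list(codes = network$codes, U = U, neighbors = neighbors,
                 rule = rule),
            class = "undirected_view")
}

#' Write a network as a Pajek .net arcs file
#'
#' Vertices are numbered 1..n by ascending hazard code (codes are
#' identifiers, never indices); labels are quoted; each arc line is
#' `src dst weight`.
#'
#' @param network a `hazard_network`.
#' @param path output file path or connection.
#' @export
write_pajek <- function(network, path) {
  stopifnot(inherits(network, "hazard_network"))
  codes <- network$codes
  labels <- if (!is.null(network$codebook)) {
    lab <- codebook_label(network$codebook, codes)
    ifelse(is.na(lab), as.character(codes), lab)
  } else as.character(codes)
  lines <- c(sprintf("*Vertices %d", length(codes)),
             sprintf("%d \"%s\"", seq_along(codes), labels),
             "*Arcs")
  idx <- which(network$W > 0L, arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    lines <- c(lines, sprintf("%d %d %d", idx[, 1L], idx[, 2L],
                              network$W[idx]))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a Pajek .net arcs file back into a hazard network
#'
#' Paired reader for [write_pajek()]. Vertex labels that are plain integers
#' are taken as hazard codes; otherwise codes are assigned positionally and
#' a label lookup is kept.
#'
#' @param path Pajek file path.
#' @return a `hazard_network`.
#' @export
read_pajek <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  vhead <- grep("^\\*[Vv]ertices", lines)
  ahead <- grep("^\\*[Aa]rcs", lines)
  if (!length(vhead) || !length(ahead)) {
    stop("not a Pajek arcs file: missing *Vertices or *Arcs section",
         call. = FALSE)
  }
  nv <- as.integer(sub("^\\*[Vv]ertices\\s+", "", lines[[vhead[1L]]]))
  vlines <- lines[seq(vhead[1L] + 1L, length.out = max(0L, ahead[1L] - vhead[1L] - 1L))]
  vlines <- vlines[nzchar(trimws(vlines))]
  labels <- sub('^\\s*\\d+\\s+"(.*)"\\s*$', "\\1", vlines)
  codes <- suppressWarnings(as.integer(labels))
  if (anyNA(codes)) codes <- seq_len(nv)
  W <- matrix(0L, nv, nv, dimnames = list(codes, codes))
  alines <- lines[seq(ahead[1L] + 1L, length.out = length(lines) - ahead[1L])]
  alines <- alines[nzchar(trimws(alines))]
  for (al in alines) {
    f <- as.numeric(strsplit(trimws(al), "\\s+")[[1L]])
    W[f[[1L]], f[[2L]]] <- as.integer(if (length(f) >= 3L) f[[3L]] else 1L)
  }
  structure(list(codes = codes, W = W, codebook = NULL),
            class = "hazard_network")
}

#' Write the network as an edge-list CSV (src, dst, weight)
#'
#' @param network a `hazard_network`.
#' @param path output file path.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "hazard_network"))
  idx <- which(network$W > 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tab <- data.frame(src = network$codes[idx[, 1L]],
                    dst = network$codes[idx[, 2L]],
                    weight = network$W[idx])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
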