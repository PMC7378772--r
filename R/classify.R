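#' Classify hazards as trigger, transitional or consequence
#'
#' A hazard that mostly starts cascades has out-strength well above
#' in-strength; one that mostly ends them has the reverse; one that passes
#' cascades along has the two roughly balanced. The comparison is made on
#' the relative strength asymmetry `(s_out - s_in) / s`, which lies in
#' `[-1, 1]`: above `tau` the hazard is a trigger, below `-tau` a
#' consequence, otherwise transitional. Hazards with no events at all
#' (`s = 0`) are isolated.
#'
#' @param metrics per-hazard metric table from [degrees_and_strengths()] or
#'   [compute_node_metrics()] (needs columns `code`, `s_in`, `s_out`, `s`).
#' @param tau relative asymmetry threshold in (0, 1); default 0.2.
#' @return data.frame with columns `code`, `asymmetry` (`NA` when
#'   isolated) and `role` (factor: trigger / transitional / consequence /
#'   isolated).
#' @examples
#' net <- build_network(filter_valid(list(parse_chain("1→2→3"))))
#' classify_roles(degrees_and_strengths(net))
#' @export
classify_roles <- function(metrics, tau = 0.2) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("tau must be a single number strictly between 0 and 1", call. = FALSE)
  }
  asym <- ifelse(metrics$s > 0, (metrics$s_out - metrics$s_in) / metrics$s,
                 NA_real_)
  role <- ifelse(metrics$s == 0, "isolated",
                 ifelse(asym > tau, "trigger",
                        ifelse(asym < -tau, "consequence", "transitional")))
  data.frame(code = metrics$code, asymmetry = asym,
             role = factor(role, levels = c("trigger", "transitional",
                                            "consequence", "isolated")))
}

rank_table <- function(metrics, column, k, label_col = "label") {
  ok <- !is.na(metrics[[column]])
  tab <- metrics[ok, , drop = FALSE]
  ord <- order(-tab[[column]], tab$code)
  tab <- tab[ord, , drop = FALSE][seq_len(min(k, nrow(tab))), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(tab)), code = tab$code)
  if (label_col %in% names(tab)) out$label <- tab[[label_col]]
  out$value <- tab[[column]]
  rownames(out) <- NULL
  out
}

#' Ranked critical-hazard report
#'
#' Top-k tables by total/in/out strength, both clustering coefficients and
#' node betweenness, a top-k edge-betweenness table, and the role of every
#' hazard. All tables are sorted descending with ties broken by ascending
#' hazard code, so reports are deterministic.
#'
#' @param metrics per-hazard table from [compute_node_metrics()].
#' @param roles output of [classify_roles()].
#' @param edge_b edge-betweenness table from [edge_betweenness()]
#'   (optional; omit to skip the edge table).
#' @param k table depth (default 10).
#' @param codebook optional codebook used to label the edge table.
#' @return a `criticality_report`: list of ranked data.frames
#'   (`by_s`, `by_s_in`, `by_s_out`, `by_c_unw`, `by_c_w`,
#'   `by_betweenness`, `by_edge_betweenness`) plus `roles`.
#' @export
build_report <- function(metrics, roles, edge_b = NULL, k = 10,
                         codebook = NULL) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  rep <- list(
    by_s = rank_table(metrics, "s", k),
    by_s_in = rank_table(metrics, "s_in", k),
    by_s_out = rank_table(metrics, "s_out", k),
    by_c_unw = rank_table(metrics, "c_unw", k),
    by_c_w = rank_table(metrics, "c_w", k),
    by_betweenness = rank_table(metrics, "betweenness", k)
  )
  if (!is.null(edge_b)) {
    ord <- order(-edge_b$betweenness, edge_b$src, edge_b$dst)
    tab <- edge_b[ord, , drop = FALSE][seq_len(min(k, nrow(edge_b))), ,
                                       drop = FALSE]
    tab <- cbind(rank = seq_len(nrow(tab)), tab)
    if (!is.null(codebook)) {
      tab$src_label <- codebook_label(codebook, tab$src)
      tab$dst_label <- codebook_label(codebook, tab$dst)
    }
    rownames(tab) <- NULL
    rep$by_edge_betweenness <- tab
  }
  rep$roles <- merge(roles, metrics[, intersect(c("code", "label"),
                                                names(metrics))],
                     by = "code", sort = TRUE)
  class(rep) <- "criticality_report"
  rep
}

#' @export
print.criticality_report <- function(x, ...) {
  cat("<criticality_report>\n")
  cat("Top hazards by node betweenness:\n")
  print.data.frame(x$by_betweenness)
  cat("\nRole counts:\n")
  print(table(x$roles$role))
  invisible(x)
}
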