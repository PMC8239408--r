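# Hub and bottleneck diagnostics on the functional layer.

.ranked_table <- function(id, value, top_n, metric, convention = NULL) {
  ord <- order(-value, id)
  df <- data.frame(node_id = id[ord], value = value[ord],
                   rank = seq_along(id), stringsAsFactors = FALSE)
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  rownames(df) <- NULL
  attr(df, "metric") <- metric
  if (!is.null(convention)) attr(df, "convention") <- convention
  class(df) <- c("ranked_node_table", "data.frame")
  df
}

#' Hub table: nodes ranked by total degree
#'
#' Value is the total incident edge count (in + out); parallel edges —
#' including retained conflicting-sign pairs — are counted separately, as
#' each carries its own evidence. Ties are broken lexicographically by node
#' id; ranks start at 1.
#'
#' @param net a \code{causal_network}.
#' @param top_n number of rows to return.
#' @return data.frame (\code{ranked_node_table}) with columns
#'   \code{node_id}, \code{value}, \code{rank}.
#' @export
degree_table <- function(net, top_n = 10L) {
  stopifnot(inherits(net, "causal_network"))
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  ends <- c(net$edges$source, net$edges$target)
  deg <- table(factor(ends, levels = net$nodes$id))
  .ranked_table(net$nodes$id, as.numeric(deg), top_n, metric = "degree")
}

#' Bottleneck table: nodes ranked by normalized betweenness centrality
#'
#' Computed on the simple graph obtained by merging parallel edges.
#' Normalization divides by the number of ordered (\code{directed = TRUE}) or
#' unordered node pairs excluding the focal node, so values lie in [0, 1].
#' The convention used is recorded in the table's \code{"convention"}
#' attribute. Because the convention behind published tables is often
#' unstated, \code{both_conventions = TRUE} returns both variants so the
#' matching one can be identified empirically.
#'
#' @param net a \code{causal_network}.
#' @param top_n number of rows (\code{NULL} for all).
#' @param directed treat edges as directed (default \code{FALSE}).
#' @param both_conventions return \code{list(undirected = , directed = )}.
#' @return a \code{ranked_node_table}, or a list of two when
#'   \code{both_conventions}.
#' @export
betweenness_table <- function(net, top_n = 10L, directed = FALSE,
                              both_conventions = FALSE) {
  stopifnot(inherits(net, "causal_network"))
  if (both_conventions) {
    return(list(
      undirected = betweenness_table(net, top_n, directed = FALSE),
      directed = betweenness_table(net, top_n, directed = TRUE)
    ))
  }
  g <- as_igraph(net, directed = TRUE, merge_parallel = TRUE)
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  n <- igraph::vcount(g)
  # weights = NA: hop-count shortest paths (edge weights are evidence
  # bookkeeping, not distances)
  bw <- igraph::betweenness(g, directed = directed, weights = NA,
                            normalized = FALSE)
  denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  bw <- if (denom > 0) bw / denom else bw * 0
  conv <- sprintf(
    "%s; parallel edges merged; normalized by %s node pairs excluding focal node",
    if (directed) "directed" else "undirected",
    if (directed) "ordered" else "unordered")
  .ranked_table(names(bw), unname(bw), top_n,
                metric = "betweenness", convention = conv)
}

#' Write a ranked node table to TSV
#'
#' Mirrors published hub/bottleneck tables (columns \code{node_id},
#' \code{value}); the metric and normalization convention are written as
#' \code{#}-comment header lines.
#'
#' @param tbl a \code{ranked_node_table}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ranked_table <- function(tbl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", attr(tbl, "metric")), con)
  if (!is.null(attr(tbl, "convention")))
    writeLines(sprintf("# convention: %s", attr(tbl, "convention")), con)
  utils::write.table(as.data.frame(tbl)[, c("node_id", "value")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
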