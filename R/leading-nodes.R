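# Leading-node decomposition and reporting subnetwork extraction.

#' Leading nodes of an NPA fit
#'
#' Ranks nodes by contribution fraction (ties broken lexicographically by
#' node id) and returns the smallest prefix whose cumulative contribution
#' reaches the threshold (inclusive: a prefix summing exactly to the
#' threshold stops). Each row carries the node's inferred direction —
#' activated (positive coefficient), inactivated (negative), or neutral.
#'
#' @param result an \code{\link{npa}} fit with \code{npa > 0}.
#' @param threshold cumulative contribution target in (0, 1]; default 0.8
#'   (the leading nodes are the major drivers responsible for 80\% of the
#'   score).
#' @return data.frame of class \code{leading_node_report} with columns
#'   \code{node_id}, \code{contribution}, \code{cumulative},
#'   \code{direction}; attribute \code{"threshold"}.
#' @export
leading_nodes <- function(result, threshold = 0.8) {
  stopifnot(inherits(result, "npa"))
  if (!isTRUE(result$npa > 0))
    stop("no perturbation to decompose (NPA = 0)", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  contrib <- result$contributions
  coeff <- result$coefficients
  ord <- order(-contrib, names(contrib))
  contrib <- contrib[ord]
  coeff <- coeff[ord]
  cum <- cumsum(contrib)
  # inclusive threshold, with float fuzz so exact sums (e.g. 8 x 0.1) count
  n_keep <- which(cum >= threshold - 1e-9)[1]
  if (is.na(n_keep)) n_keep <- length(contrib)
  idx <- seq_len(n_keep)
  if (threshold >= 1) idx <- which(contrib > 0)   # all nonzero contributors
  dir <- ifelse(coeff[idx] > 0, "activated",
                ifelse(coeff[idx] < 0, "inactivated", "neutral"))
  df <- data.frame(node_id = names(contrib)[idx],
                   contribution = unname(contrib[idx]),
                   cumulative = unname(cum[idx]),
                   direction = unname(dir),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "threshold") <- threshold
  class(df) <- c("leading_node_report", "data.frame")
  df
}

#' Write a leading-node report to TSV
#'
#' @param report a \code{\link{leading_nodes}} report.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_leading_nodes <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract a reporting subnetwork around a node set
#'
#' Induced subgraph on \code{nodes} plus \code{extras} (e.g. downstream
#' adverse outcomes added for context regardless of leading-node status).
#' For ordered pairs in the set with no direct edge but a directed path of
#' length at most \code{max_path} in the full causal network, an
#' \emph{indirect} edge is added (flagged in the \code{indirect} edge
#' column), with sign equal to the product of edge signs along one shortest
#' path; pairs whose equal-length shortest paths disagree on the sign are
#' reported in the network log.
#'
#' @param net a \code{causal_network}.
#' @param nodes character vector of node ids (e.g. leading nodes).
#' @param extras additional ids to include.
#' @param max_path indirect-connection path-length cap (default 4).
#' @return a \code{causal_network} whose node set is exactly
#'   \code{union(nodes, extras)}.
#' @export
extract_subnetwork <- function(net, nodes, extras = character(),
                               max_path = 4L) {
  stopifnot(inherits(net, "causal_network"))
  want <- unique(c(nodes, extras))
  unknown <- setdiff(want, net$nodes$id)
  if (length(unknown))
    stop("unknown node id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sub_nodes <- net$nodes[net$nodes$id %in% want, , drop = FALSE]
  keep <- net$edges$source %in% want & net$edges$target %in% want
  edges <- net$edges[keep, , drop = FALSE]
  evidence <- net$evidence[keep]
  log <- character()

  if (length(want) >= 2) {
    causal <- net$edges[net$edges$sign != 0, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      causal[, c("source", "target")], directed = TRUE,
      vertices = net$nodes)
    gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    dist <- igraph::distances(gs, v = want, to = want, mode = "out")
    sign_lookup <- stats::setNames(
      causal$sign, paste(causal$source, causal$target, sep = "\r"))
    conflict_pair <- unique(paste(causal$source, causal$target,
                                  sep = "\r")[duplicated(
      paste(causal$source, causal$target, sep = "\r"))])
    ind <- list()
    for (u in want) for (v in setdiff(want, u)) {
      d <- dist[u, v]
      if (!is.finite(d) || d < 2 || d > max_path) next
      if (any(edges$source == u & edges$target == v)) next
      paths <- igraph::all_shortest_paths(gs, from = u, to = v,
                                          mode = "out")$vpaths
      prods <- vapply(paths, function(p) {
        nm <- igraph::V(gs)$name[as.integer(p)]
        steps <- paste(nm[-length(nm)], nm[-1], sep = "\r")
        prod(sign_lookup[steps])
      }, 0)
      if (length(unique(prods)) > 1L)
        log <- c(log, sprintf(
          "ambiguous indirect sign between %s and %s (equal-length paths disagree)",
          u, v))
      if (any(vapply(paths, function(p) {
        nm <- igraph::V(gs)$name[as.integer(p)]
        any(paste(nm[-length(nm)], nm[-1], sep = "\r") %in% conflict_pair)
      }, TRUE)))
        log <- c(log, sprintf(
          "indirect path between %s and %s crosses a conflicting-sign pair",
          u, v))
      ind <- c(ind, list(data.frame(
        source = u, target = v, sign = as.integer(prods[1]), weight = 1,
        indirect = TRUE, stringsAsFactors = FALSE)))
    }
    if (length(ind)) {
      ind_df <- do.call(rbind, ind)
      edges <- rbind(edges[, c("source", "target", "sign", "weight",
                               "indirect")], ind_df)
      evidence <- c(evidence, rep(list(list()), nrow(ind_df)))
    }
  }
  new_causal_network(sub_nodes, edges, evidence,
                     provenance = c(net$provenance,
                                    list(subnetwork_of = nrow(net$nodes))),
                     log = c(net$log, log))
}

#' Annotate a subnetwork with coefficient directions
#'
#' Adds a \code{direction} column to the node table from the signs of the
#' fitted coefficients (for GraphML color-coding: activated / inactivated /
#' neutral; nodes without a coefficient are neutral).
#'
#' @param net a \code{causal_network} (typically from
#'   \code{\link{extract_subnetwork}}).
#' @param fit an \code{\link{npa}} fit.
#' @return the network with an annotated node table.
#' @export
annotate_directions <- function(net, fit) {
  stopifnot(inherits(net, "causal_network"), inherits(fit, "npa"))
  cc <- fit$coefficients[net$nodes$id]
  cc[is.na(cc)] <- 0
  net$nodes$direction <- ifelse(cc > 0, "activated",
                                ifelse(cc < 0, "inactivated", "neutral"))
  net
}
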