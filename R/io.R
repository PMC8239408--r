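# File formats: expression TSV, SIF/GraphML/JSON network exchange, reports.

#' Construct an expression profile
#'
#' A per-gene log2 fold-change table for one treatment-vs-control contrast,
#' with an optional variance used by the parametric confidence interval.
#'
#' @param gene_id character vector.
#' @param log2fc finite numeric log2 fold-changes.
#' @param se optional standard errors (variance = se^2).
#' @param variance optional variances (mutually exclusive with \code{se}).
#' @return data.frame of class \code{expression_profile} with columns
#'   \code{gene_id}, \code{log2fc}, \code{variance}.
#' @export
expression_profile <- function(gene_id, log2fc, se = NULL, variance = NULL) {
  if (!is.null(se) && !is.null(variance))
    stop("give either se or variance, not both", call. = FALSE)
  if (!is.null(se)) variance <- se^2
  if (is.null(variance)) variance <- rep(0, length(log2fc))
  gene_id <- as.character(gene_id)
  if (anyDuplicated(toupper(gene_id)))
    stop("duplicate gene ids in expression profile", call. = FALSE)
  if (!all(is.finite(log2fc)))
    stop("log2 fold-changes must be finite", call. = FALSE)
  if (any(variance < 0 | !is.finite(variance)))
    stop("variances must be finite and non-negative", call. = FALSE)
  df <- data.frame(gene_id = gene_id, log2fc = as.numeric(log2fc),
                   variance = as.numeric(variance), stringsAsFactors = FALSE)
  class(df) <- c("expression_profile", "data.frame")
  df
}

#' Read an expression profile from TSV
#'
#' Expected header: \code{gene_id<TAB>log2fc} with an optional \code{se}
#' column (variance = se squared).
#'
#' @param path TSV path.
#' @return an \code{\link{expression_profile}}.
#' @export
read_expression_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene_id", "log2fc") %in% names(df)))
    stop("expression TSV must have columns gene_id, log2fc [, se]",
         call. = FALSE)
  expression_profile(df$gene_id, df$log2fc,
                     se = if ("se" %in% names(df)) df$se else NULL)
}

#' Write an expression profile to TSV
#'
#' @param profile an \code{expression_profile}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_expression_profile <- function(profile, path) {
  out <- data.frame(gene_id = profile$gene_id,
                    log2fc = format(profile$log2fc, digits = 17, trim = TRUE),
                    se = format(sqrt(profile$variance), digits = 17,
                                trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- network exchange -------------------------------------------------------

.sign_relation <- function(sign)
  c("decreases", "association", "increases")[sign + 2L]

#' Write a network as SIF
#'
#' Cytoscape-compatible simple interaction format; the relation column is
#' \code{increases}/\code{decreases}/\code{association} from the edge sign.
#'
#' @param net a \code{causal_network}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sif <- function(net, path) {
  lines <- sprintf("%s\t%s\t%s", net$edges$source,
                   .sign_relation(net$edges$sign), net$edges$target)
  iso <- setdiff(net$nodes$id, c(net$edges$source, net$edges$target))
  writeLines(c(lines, iso), path, useBytes = TRUE)
  invisible(path)
}

#' Read a network from SIF
#'
#' @param path SIF path (source, relation, target; bare lines are isolated
#'   nodes).
#' @return a \code{causal_network} (node kinds inferred by re-parsing ids
#'   where possible, otherwise \code{"unknown"}; no evidence).
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- lengths(parts) >= 3L
  src <- vapply(parts[is_edge], `[[`, "", 1L)
  rel <- vapply(parts[is_edge], `[[`, "", 2L)
  tgt <- vapply(parts[is_edge], `[[`, "", 3L)
  sign <- unname(.relation_sign[rel])
  if (anyNA(sign)) stop("unknown SIF relation token", call. = FALSE)
  iso <- vapply(parts[!is_edge], `[[`, "", 1L)
  ids <- unique(c(src, tgt, iso))
  kind <- vapply(ids, function(id) {
    tryCatch(parse_term(id)$fn, error = function(e) "unknown")
  }, "")
  new_causal_network(
    nodes = data.frame(id = ids, kind = unname(kind),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = src, target = tgt, sign = as.integer(sign),
                       weight = 1, stringsAsFactors = FALSE),
    provenance = list(source = path)
  )
}

#' Write a network as GraphML
#'
#' Node attributes \code{kind}; edge attributes \code{sign}, \code{weight},
#' \code{indirect} (used by subnetwork extraction) and, when present in the
#' \code{direction} node column, a signed direction attribute for
#' color-coding.
#'
#' @param net a \code{causal_network}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "sign", "weight", "indirect")],
    directed = TRUE, vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network from GraphML
#'
#' @param path GraphML path written by \code{\link{write_graphml}}.
#' @return a \code{causal_network} (no evidence).
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  id <- if (!is.null(va$name)) va$name else as.character(seq_len(igraph::vcount(g)))
  kind <- if (!is.null(va$kind)) va$kind else rep("unknown", length(id))
  el <- igraph::as_edgelist(g, names = TRUE)
  ea <- igraph::edge_attr(g)
  edges <- data.frame(
    source = el[, 1], target = el[, 2],
    sign = if (!is.null(ea$sign)) as.integer(ea$sign) else
      rep(1L, nrow(el)),
    weight = if (!is.null(ea$weight)) as.numeric(ea$weight) else
      rep(1, nrow(el)),
    indirect = if (!is.null(ea$indirect)) as.logical(ea$indirect) else
      rep(FALSE, nrow(el)),
    stringsAsFactors = FALSE)
  new_causal_network(
    nodes = data.frame(id = id, kind = kind, stringsAsFactors = FALSE),
    edges = edges, provenance = list(source = path))
}

#' Write a JSON graph dump with evidence
#'
#' @param net a \code{causal_network}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    nodes = net$nodes,
    edges = net$edges,
    evidence = net$evidence,
    provenance = net$provenance,
    log = net$log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a score report (JSON + per-node TSV)
#'
#' The JSON report carries the NPA, its confidence interval, the o/k
#' permutation p-values, the configuration and all substream seeds; the TSV
#' lists per-node coefficients and contribution fractions.
#'
#' @param fit an \code{\link{npa}} fit.
#' @param json_path output JSON path (\code{NULL} to skip).
#' @param tsv_path output TSV path (\code{NULL} to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_score_report <- function(fit, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(fit, "npa"))
  if (!is.null(json_path)) {
    obj <- list(
      npa = fit$npa,
      ci = list(lo = fit$ci[[1]], hi = fit$ci[[2]]),
      p_o = fit$p_o, p_k = fit$p_k,
      n_nodes = length(fit$coefficients),
      n_inodes = length(fit$activities),
      config = unclass(fit$control),
      seeds = fit$seeds
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(node_id = names(fit$coefficients),
                     coefficient = unname(fit$coefficients),
                     contribution = unname(fit$contributions),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$contribution, df$node_id), ]
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}
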