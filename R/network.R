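# Two-layer causal model: signed functional layer + transcript layer.

.relation_sign <- c(
  increases = 1L, directlyIncreases = 1L,
  decreases = -1L, directlyDecreases = -1L,
  association = 0L
)

new_causal_network <- function(nodes, edges, evidence = NULL,
                               provenance = list(), log = character()) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (is.null(evidence)) evidence <- rep(list(list()), nrow(edges))
  stopifnot(length(evidence) == nrow(edges))
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (is.null(edges$indirect)) edges$indirect <- rep(FALSE, nrow(edges))
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, evidence = evidence,
         provenance = provenance, log = log),
    class = "causal_network"
  )
}

#' Compile BEL statements into a signed functional-layer network
#'
#' One node per distinct canonical term. Relations map to edge signs:
#' \code{increases}/\code{directlyIncreases} to +1,
#' \code{decreases}/\code{directlyDecreases} to -1, \code{association} to 0.
#' Duplicate (source, target, sign) edges are merged with concatenated
#' evidence; pairs connected with both signs are retained as two parallel
#' edges and reported in the compile log. Only sign-carrying edges
#' participate in scoring; association edges are kept for topology and
#' visualization.
#'
#' @param statements list of \code{\link{parse_statement}} results.
#' @param merge_duplicates merge identical (source, target, sign) edges
#'   (default \code{TRUE}).
#' @return a \code{causal_network}: list with \code{nodes}
#'   (data.frame \code{id}, \code{kind}), \code{edges} (data.frame
#'   \code{source}, \code{target}, \code{sign}, \code{weight}),
#'   \code{evidence} (list of evidence records per edge), \code{provenance}
#'   and \code{log}.
#' @export
compile_network <- function(statements, merge_duplicates = TRUE) {
  if (length(statements) == 0L) {
    warning("empty statement list: returning an empty network", call. = FALSE)
    return(new_causal_network(
      nodes = data.frame(id = character(), kind = character(),
                         stringsAsFactors = FALSE),
      edges = data.frame(source = character(), target = character(),
                         sign = integer(), weight = numeric(),
                         stringsAsFactors = FALSE)
    ))
  }
  subj_id <- vapply(statements, function(s) s$subject$canonical_id, "")
  obj_id <- vapply(statements, function(s) s$object$canonical_id, "")
  subj_kind <- vapply(statements, function(s) s$subject$fn, "")
  obj_kind <- vapply(statements, function(s) s$object$fn, "")
  rel <- vapply(statements, function(s) s$relation, "")

  ids <- c(subj_id, obj_id)
  kinds <- c(subj_kind, obj_kind)
  keep <- !duplicated(ids)
  nodes <- data.frame(id = ids[keep], kind = kinds[keep],
                      stringsAsFactors = FALSE)

  sign <- unname(.relation_sign[rel])
  # evidence is a list (per edge) of records; one record per source statement
  evidence <- lapply(statements, function(s)
    list(list(citation = s$citation, annotations = s$annotations,
              relation = s$relation)))

  edges <- data.frame(source = subj_id, target = obj_id, sign = sign,
                      weight = 1, stringsAsFactors = FALSE)
  log <- character()
  if (merge_duplicates) {
    key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
    first <- !duplicated(key)
    grp <- match(key, key[first])
    merged_ev <- lapply(seq_len(sum(first)), function(g)
      do.call(c, unname(evidence[grp == g])))
    edges <- edges[first, , drop = FALSE]
    evidence <- merged_ev
  }
  pair <- paste(edges$source, edges$target, sep = "\r")
  for (p in unique(pair[duplicated(pair)])) {
    signs <- edges$sign[pair == p]
    if (any(signs > 0) && any(signs < 0)) {
      uv <- strsplit(p, "\r", fixed = TRUE)[[1]]
      log <- c(log, sprintf(
        "conflicting signs retained as parallel edges: %s / %s",
        uv[1], uv[2]))
    }
  }
  new_causal_network(nodes, edges, evidence,
                     provenance = list(n_statements = length(statements)),
                     log = log)
}

#' @export
print.causal_network <- function(x, ...) {
  n_causal <- sum(x$edges$sign != 0)
  cat(sprintf("<causal_network> %d nodes, %d edges (%d causal, %d association)\n",
              nrow(x$nodes), nrow(x$edges), n_causal,
              nrow(x$edges) - n_causal))
  if (length(x$log)) cat(sprintf("  %d compile log entries\n", length(x$log)))
  invisible(x)
}

#' Node-type census of a compiled network
#'
#' Counts nodes by their outermost term function; counts partition the node
#' set. Kinds not present report zero. Also reports causal vs. association
#' edge counts in the \code{"edges"} attribute so either edge-count
#' convention can be compared against an external tally.
#'
#' @param net a \code{causal_network}.
#' @return named integer vector over the nine term functions (plus any
#'   non-standard kinds present, e.g. after variant collapsing).
#' @export
node_type_census <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  levels <- names(.bel_short)
  extra <- setdiff(unique(net$nodes$kind), levels)
  census <- table(factor(net$nodes$kind, levels = c(levels, extra)))
  out <- stats::setNames(as.integer(census), names(census))
  attr(out, "edges") <- c(causal = sum(net$edges$sign != 0),
                          association = sum(net$edges$sign == 0))
  out
}

# gene-level label used by variant collapsing; NA when the rule does not apply
.variant_core <- function(term) {
  if (term$fn %in% c("protein", "rna") && !is.na(term$namespace))
    return(paste0(term$namespace, ":", term$value))
  if (term$fn == "activity" && length(term$inner) == 1L) {
    inner <- term$inner[[1]]
    if (inner$fn %in% c("protein", "rna") && !is.na(inner$namespace))
      return(paste0(inner$namespace, ":", inner$value))
  }
  NA_character_
}

#' Collapse molecular variants to gene-level nodes
#'
#' \code{r(X)}, \code{p(X)}, \code{p(X, pmod(...))} and \code{act(p(X))} map
#' to a single node labeled \code{X}; edges are re-attached, resulting
#' duplicates merged, and self-loops created by collapsing dropped and
#' logged. Collapsed nodes get kind \code{"gene"}; other nodes are untouched.
#'
#' @param net a \code{causal_network}.
#' @return a \code{causal_network}.
#' @export
collapse_molecular_variants <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  terms <- lapply(net$nodes$id, parse_term)
  core <- vapply(terms, .variant_core, "")
  new_id <- ifelse(is.na(core), net$nodes$id, core)
  new_kind <- ifelse(is.na(core), net$nodes$kind, "gene")
  keep <- !duplicated(new_id)
  nodes <- data.frame(id = new_id[keep], kind = new_kind[keep],
                      stringsAsFactors = FALSE)
  map <- stats::setNames(new_id, net$nodes$id)

  edges <- net$edges
  evidence <- net$evidence
  edges$source <- unname(map[edges$source])
  edges$target <- unname(map[edges$target])
  log <- net$log
  loop <- edges$source == edges$target
  if (any(loop)) {
    log <- c(log, sprintf("dropped self-loop created by collapsing: %s",
                          edges$source[loop]))
    evidence <- evidence[!loop]
    edges <- edges[!loop, , drop = FALSE]
  }
  key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  evidence <- lapply(seq_len(sum(first)), function(g)
    do.call(c, unname(evidence[grp == g])))
  edges <- edges[first, , drop = FALSE]
  new_causal_network(nodes, edges, evidence,
                     provenance = c(net$provenance, list(collapsed = TRUE)),
                     log = log)
}

# ---- transcript layer -------------------------------------------------------

#' Construct a transcript layer
#'
#' The transcript layer attaches a signed gene signature to inferable nodes
#' (iNodes) of the functional layer: gene \code{g} under iNode \code{x}
#' carries sign \eqn{s_{xg} \in \{+1, -1\}}, the expected direction of its
#' differential expression when \code{x} is active.
#'
#' @param inode_id,gene_id,sign equal-length vectors; sign coerced from
#'   \code{"+1"/"-1"/1/-1}.
#' @return data.frame of class \code{transcript_layer} with columns
#'   \code{inode_id}, \code{gene_id}, \code{sign}.
#' @export
transcript_layer <- function(inode_id, gene_id, sign) {
  sign <- as.integer(gsub("^\\+", "", as.character(sign)))
  if (!all(sign %in% c(1L, -1L)))
    stop("transcript-layer signs must be +1 or -1", call. = FALSE)
  df <- data.frame(inode_id = as.character(inode_id),
                   gene_id = as.character(gene_id),
                   sign = sign, stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("inode_id", "gene_id")]) |
    duplicated(data.frame(df$inode_id, toupper(df$gene_id)))
  if (any(dup))
    stop("duplicate gene within one iNode signature: ",
         paste(unique(df$gene_id[dup]), collapse = ", "), call. = FALSE)
  class(df) <- c("transcript_layer", "data.frame")
  df
}

#' Read a transcript layer from TSV
#'
#' Expected header: \code{inode_id<TAB>gene_id<TAB>sign}.
#'
#' @param path TSV file path.
#' @return a \code{\link{transcript_layer}}.
#' @export
read_transcript_layer <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  req <- c("inode_id", "gene_id", "sign")
  if (!all(req %in% names(df)))
    stop("transcript layer TSV must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  transcript_layer(df$inode_id, df$gene_id, df$sign)
}

#' Write a transcript layer to TSV
#'
#' @param layer a \code{transcript_layer}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_transcript_layer <- function(layer, path) {
  utils::write.table(as.data.frame(layer)[, c("inode_id", "gene_id", "sign")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a transcript layer to a functional network
#'
#' Pairs the signed functional layer with the transcript layer into the
#' two-layer model consumed by \code{\link{npa}}. Layer rows naming nodes
#' absent from the network are an error in strict mode, otherwise dropped
#' with a warning listing them.
#'
#' @param net a \code{causal_network}.
#' @param layer a \code{transcript_layer}.
#' @param strict error (rather than warn) on unknown iNode ids.
#' @return an object of class \code{npa_model}: list with \code{network},
#'   \code{layer}, and \code{dropped} (ids removed in non-strict mode).
#' @export
attach_transcript_layer <- function(net, layer, strict = FALSE) {
  stopifnot(inherits(net, "causal_network"),
            inherits(layer, "transcript_layer"))
  unknown <- setdiff(unique(layer$inode_id), net$nodes$id)
  if (length(unknown)) {
    if (strict)
      stop("transcript layer names unknown nodes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    warning("dropping transcript-layer rows for unknown nodes: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    layer <- layer[!layer$inode_id %in% unknown, , drop = FALSE]
    class(layer) <- c("transcript_layer", "data.frame")
  }
  if (nrow(layer) == 0L || length(unique(layer$inode_id)) == 0L)
    stop("model unscoreable: no usable iNodes after attachment",
         call. = FALSE)
  structure(list(network = net, layer = layer, dropped = unknown),
            class = "npa_model")
}

#' @export
print.npa_model <- function(x, ...) {
  cat(sprintf(
    "<npa_model> %d nodes / %d edges; %d iNodes, %d signature genes\n",
    nrow(x$network$nodes), nrow(x$network$edges),
    length(unique(x$layer$inode_id)), nrow(x$layer)))
  invisible(x)
}

# ---- igraph bridge ----------------------------------------------------------

# igraph view of a network; merge_parallel collapses multi-edges (keeping the
# first sign), causal_only drops association edges
as_igraph <- function(net, directed = TRUE, causal_only = FALSE,
                      merge_parallel = FALSE) {
  stopifnot(inherits(net, "causal_network"))
  edges <- net$edges
  if (causal_only) edges <- edges[edges$sign != 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "sign", "weight")],
    directed = directed,
    vertices = net$nodes
  )
  if (merge_parallel)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE,
                          edge.attr.comb = list(sign = "first",
                                                weight = "sum"))
  g
}
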