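# Shared fixtures and independent oracles, all built in code.

worked_example_statements <- function() {
  lapply(c("a(CHEBI:ethanol) -> path(MESHD:Microcephaly)",
           "act(p(ZFIN:agrn)) -| path(MESHD:Microcephaly)",
           "act(p(ZFIN:shha)) -| path(MESHD:Microcephaly)"),
         parse_statement)
}

# chain/star builders from statement text
net_from <- function(...) compile_network(lapply(c(...), parse_statement))

# model with n isolated anchored iNodes whose activities are `a`
isolated_model <- function(a) {
  n <- length(a)
  net <- generate_network(n, 0, seed = 1)
  layer <- transcript_layer(net$nodes$id, paste0("iso_g", seq_len(n)),
                            rep(1, n))
  model <- attach_transcript_layer(net, layer)
  profile <- expression_profile(paste0("iso_g", seq_len(n)), a)
  list(model = model, profile = profile)
}

# a small scoreable synthetic model
toy_model <- function(seed = 5, n_nodes = 12, n_edges = 14,
                      frac_inodes = 0.5, genes_per_inode = 6) {
  net <- generate_network(n_nodes, n_edges, p_negative = 0.3, seed = seed)
  layer <- generate_transcript_layer(net, frac_inodes, genes_per_inode,
                                     seed = seed)
  attach_transcript_layer(net, layer)
}

fast_control <- function(seed = 42, permutations = 100, ci_draws = 100)
  npa_control(permutations = permutations, ci_draws = ci_draws, seed = seed)

# ---- independent oracles -----------------------------------------------------

# J(c): the quadratic objective, written directly from its definition
oracle_objective <- function(cvec, nodes, edges, anchors, lambda) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  jj <- 0
  if (nrow(edges))
    jj <- sum(edges$weight *
                (cvec[idx[edges$target]] -
                   edges$sign * cvec[idx[edges$source]])^2)
  jj + lambda * sum((cvec[idx[names(anchors)]] - anchors)^2)
}

# brute-force numeric minimization of J via quasi-Newton from several starts
oracle_fit <- function(model, act, lambda = 1) {
  edges <- model$network$edges[model$network$edges$sign != 0, , drop = FALSE]
  causal_ids <- unique(c(edges$source, edges$target,
                         unique(model$layer$inode_id)))
  nodes <- model$network$nodes$id[model$network$nodes$id %in% causal_ids]
  anchors <- act$a[names(act$a) %in% nodes]
  best <- NULL
  for (start in list(rep(0, length(nodes)), rep(0.5, length(nodes)))) {
    res <- stats::optim(start, oracle_objective, nodes = nodes,
                        edges = edges, anchors = anchors, lambda = lambda,
                        method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || res$value < best$value) best <- res
  }
  stats::setNames(best$par, nodes)
}

# brute-force normalized betweenness by enumerating all shortest paths (DFS)
oracle_betweenness <- function(net, directed = FALSE) {
  edges <- unique(net$edges[, c("source", "target")])
  ids <- net$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (e in seq_len(nrow(edges))) {
    adj[[edges$source[e]]] <- c(adj[[edges$source[e]]], edges$target[e])
    if (!directed)
      adj[[edges$target[e]]] <- c(adj[[edges$target[e]]], edges$source[e])
  }
  adj <- lapply(adj, unique)
  all_paths <- function(u, v, maxlen) {
    found <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (length(path) - 1 > maxlen) return()
      if (last == v) { found[[length(found) + 1]] <<- path; return() }
      for (w in adj[[last]]) if (!w %in% path) walk(c(path, w))
    }
    walk(u)
    found
  }
  score <- stats::setNames(rep(0, length(ids)), ids)
  pairs <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  if (!directed) pairs <- pairs[pairs$s < pairs$t, ]
  for (r in seq_len(nrow(pairs))) {
    paths <- all_paths(pairs$s[r], pairs$t[r], maxlen = length(ids))
    if (!length(paths)) next
    lens <- lengths(paths)
    paths <- paths[lens == min(lens)]
    for (v in ids) {
      if (v %in% c(pairs$s[r], pairs$t[r])) next
      onpath <- sum(vapply(paths, function(p) v %in% p, TRUE))
      score[v] <- score[v] + onpath / length(paths)
    }
  }
  n <- length(ids)
  denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  score / denom
}

# random BEL term / statement generators for round-trip property tests
random_term <- function(depth = 0) {
  ns <- sample(c("ZFIN", "GOBP", "MESHD", "CHEBI", "HGNC"), 1)
  val <- sample(c("gbx2", "shha", "lef1", "cell proliferation",
                  "mir9-2", "Microcephaly", "apical junction assembly"), 1)
  leaf_fns <- c("abundance", "protein", "rna", "microRNA",
                "biologicalProcess", "pathology", "complexAbundance")
  fn <- if (depth == 0 && stats::runif(1) < 0.4) "activity" else
    sample(leaf_fns, 1)
  if (fn == "activity") {
    inner_fn <- sample(c("protein", "rna", "abundance"), 1)
    base <- parse_term(sprintf("%s(%s:%s)",
                               c(protein = "p", rna = "r",
                                 abundance = "a")[inner_fn], ns,
                               if (grepl("[ ,:()-]", val))
                                 sprintf('"%s"', val) else val))
    return(parse_term(sprintf("act(%s)", base$canonical_id)))
  }
  tok <- c(abundance = "a", protein = "p", rna = "r", microRNA = "m",
           biologicalProcess = "bp", pathology = "path",
           complexAbundance = "complex")[fn]
  txt <- sprintf("%s(%s:%s)", tok, ns,
                 if (grepl("[ ,:()-]", val)) sprintf('"%s"', val) else val)
  if (fn == "protein" && stats::runif(1) < 0.3)
    txt <- sub("\\)$", ",pmod(P))", txt)
  parse_term(txt)
}

random_statement <- function() {
  rel <- sample(c("increases", "directlyIncreases", "decreases",
                  "directlyDecreases", "association"), 1)
  new_bel_statement(random_term(), rel, random_term())
}
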