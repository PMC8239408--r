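# Synthetic two-layer models and profiles with controlled consistency, so
# every scoring stage is testable end-to-end without external data.

#' Generate a random signed directed network
#'
#' Uniform random distinct directed edges (no self-loops); each edge carries
#' sign -1 with probability \code{p_negative}, +1 otherwise. Node ids are
#' \code{n01, n02, ...}. Pure function of its parameters and seed.
#'
#' With \code{coherent_signs = TRUE}, edge signs come from latent node
#' polarities \eqn{\pi(x) \in \{+1, -1\}} as
#' \eqn{\sigma_{xy} = \pi(x)\pi(y)}: every cycle then has sign product +1,
#' so a sign-coherent assignment of latent coefficients exists over the
#' whole network and "consistent" profiles are exactly representable by the
#' scoring model. Polarities are drawn so the marginal negative-edge
#' probability still equals \code{p_negative} (which must then be at most
#' 0.5).
#'
#' @param n_nodes,n_edges network size; \code{n_edges} at most
#'   \code{n_nodes * (n_nodes - 1)}.
#' @param p_negative probability of a negative edge sign (default 0.25).
#' @param seed integer seed.
#' @param coherent_signs draw cycle-coherent signs from node polarities
#'   (default \code{FALSE}: independent signs per edge).
#' @return a \code{causal_network}.
#' @export
generate_network <- function(n_nodes, n_edges, p_negative = 0.25, seed = 1L,
                             coherent_signs = FALSE) {
  stopifnot(n_nodes >= 1, n_edges >= 0, p_negative >= 0, p_negative <= 1)
  if (n_edges > n_nodes * (n_nodes - 1))
    stop("infeasible edge count: at most n_nodes * (n_nodes - 1) distinct ",
         "directed edges without self-loops", call. = FALSE)
  if (coherent_signs && p_negative > 0.5)
    stop("coherent_signs requires p_negative <= 0.5", call. = FALSE)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  with_seed(substream_seed(seed, "net"), {
    # enumerate ordered pairs (i, j), i != j, and sample without replacement
    pair_idx <- sample.int(n_nodes * (n_nodes - 1), n_edges)
    i <- (pair_idx - 1L) %/% (n_nodes - 1L) + 1L
    off <- (pair_idx - 1L) %% (n_nodes - 1L) + 1L
    j <- ifelse(off >= i, off + 1L, off)
    if (coherent_signs) {
      # Pr(pi = -1) = q with 2q(1-q) = p_negative keeps the edge marginal
      q <- (1 - sqrt(1 - 2 * p_negative)) / 2
      polarity <- ifelse(stats::runif(n_nodes) < q, -1L, 1L)
      sign <- polarity[i] * polarity[j]
    } else {
      sign <- ifelse(stats::runif(n_edges) < p_negative, -1L, 1L)
    }
    new_causal_network(
      nodes = data.frame(id = ids, kind = "protein",
                         stringsAsFactors = FALSE),
      edges = data.frame(source = ids[i], target = ids[j],
                         sign = as.integer(sign),
                         weight = rep(1, n_edges), stringsAsFactors = FALSE),
      provenance = list(generator = "generate_network", n_nodes = n_nodes,
                        n_edges = n_edges, p_negative = p_negative,
                        seed = seed))
  })
}

#' Generate a synthetic transcript layer
#'
#' Makes \code{ceiling(frac_inodes * n_nodes)} nodes inferable, each with a
#' disjoint signed gene signature of the given size (gene ids
#' \code{g0001, ...}).
#'
#' @param net a \code{causal_network}.
#' @param frac_inodes fraction of nodes made inferable, in (0, 1].
#' @param genes_per_inode signature size (>= 1).
#' @param p_negative_sign probability of a -1 signature sign (default 0.3).
#' @param seed integer seed.
#' @return a \code{\link{transcript_layer}}.
#' @export
generate_transcript_layer <- function(net, frac_inodes = 0.5,
                                      genes_per_inode = 10L,
                                      p_negative_sign = 0.3, seed = 1L) {
  stopifnot(inherits(net, "causal_network"),
            frac_inodes > 0, frac_inodes <= 1)
  if (genes_per_inode < 1)
    stop("genes_per_inode must be >= 1", call. = FALSE)
  n <- nrow(net$nodes)
  n_i <- ceiling(frac_inodes * n)
  with_seed(substream_seed(seed, "layer"), {
    inodes <- sort(sample(net$nodes$id, n_i))
    n_genes <- n_i * genes_per_inode
    genes <- sprintf("g%04d", seq_len(n_genes))
    transcript_layer(
      inode_id = rep(inodes, each = genes_per_inode),
      gene_id = genes,
      sign = ifelse(stats::runif(n_genes) < p_negative_sign, -1L, 1L))
  })
}

# latent coefficients by sign-coherent propagation over a BFS spanning
# forest of the causal subgraph; returns values and a coherence flag
.propagate_truth <- function(net, scale) {
  causal <- net$edges[net$edges$sign != 0, , drop = FALSE]
  ids <- net$nodes$id
  c_star <- stats::setNames(rep(0, length(ids)), ids)
  # adjacency over the undirected view, remembering signs
  adj <- vector("list", length(ids))
  names(adj) <- ids
  for (e in seq_len(nrow(causal))) {
    u <- causal$source[e]; v <- causal$target[e]; s <- causal$sign[e]
    adj[[u]] <- c(adj[[u]], list(c(v, s)))
    adj[[v]] <- c(adj[[v]], list(c(u, s)))
  }
  visited <- stats::setNames(rep(FALSE, length(ids)), ids)
  coherent <- TRUE
  for (root in sample(ids)) {
    if (visited[root]) next
    c_star[root] <- scale * sample(c(-1, 1), 1)
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[u]]) {
        v <- nb[1]
        s <- as.numeric(nb[2])
        val <- s * c_star[u]
        if (!visited[v]) {
          c_star[v] <- val        # first-visited parent wins
          visited[v] <- TRUE
          queue <- c(queue, v)
        } else if (abs(c_star[v] - val) > 1e-12) {
          coherent <- FALSE       # a non-tree edge contradicts the forest
        }
      }
    }
  }
  list(c_star = c_star, coherent = coherent)
}

#' Generate an expression profile with known ground truth
#'
#' \strong{consistent} mode draws latent coefficients \eqn{c^*} by
#' propagating a random root value (magnitude \code{scale}, random sign)
#' through the signed network over a BFS spanning forest (child value =
#' parent value times edge sign; first-visited parent wins on conflicting
#' parallel edges), then sets
#' \eqn{\beta_g = s_{xg} c^*(x) + N(0, \tau^2)} for every transcript-layer
#' gene. \strong{null} mode draws \eqn{\beta_g} i.i.d. \eqn{N(0, \tau^2)}
#' with \eqn{c^* = 0}. In both modes 50\% decoy genes (noise-only, off every
#' signature) are appended so permutation tests have off-signature genes to
#' draw, mimicking genome-wide profiles. The per-gene variance field is
#' \eqn{\tau^2}.
#'
#' On networks whose signed cycles are all coherent with the forest
#' assignment (flag \code{coherent} in the returned truth), the noise-free
#' consistent profile is exactly representable: \eqn{J(c^*) = 0} and the fit
#' recovers \eqn{c^*} on anchored components.
#'
#' @param model an \code{npa_model} with at least one iNode.
#' @param mode \code{"consistent"} or \code{"null"}.
#' @param scale root magnitude for the latent coefficients (default 1).
#' @param tau noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return list with \code{profile} (an \code{expression_profile}) and
#'   \code{truth} (class \code{synthetic_truth}: \code{c_star}, \code{mode},
#'   \code{tau}, \code{scale}, \code{seed}, \code{coherent}).
#' @export
generate_profile <- function(model, mode = c("consistent", "null"),
                             scale = 1, tau = 0.1, seed = 1L) {
  stopifnot(inherits(model, "npa_model"))
  mode <- match.arg(mode)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  layer <- model$layer
  n_sig <- nrow(layer)
  n_decoy <- ceiling(0.5 * n_sig)
  decoys <- sprintf("decoy%04d", seq_len(n_decoy))

  with_seed(substream_seed(seed, paste0("profile-", mode)), {
    if (mode == "consistent") {
      pr <- .propagate_truth(model$network, scale)
      c_star <- pr$c_star
      coherent <- pr$coherent
      beta_sig <- layer$sign * c_star[layer$inode_id] +
        stats::rnorm(n_sig, 0, tau)
    } else {
      c_star <- stats::setNames(rep(0, nrow(model$network$nodes)),
                                model$network$nodes$id)
      coherent <- TRUE
      beta_sig <- stats::rnorm(n_sig, 0, tau)
    }
    beta_decoy <- stats::rnorm(n_decoy, 0, tau)
    profile <- expression_profile(
      gene_id = c(layer$gene_id, decoys),
      log2fc = c(unname(beta_sig), beta_decoy),
      variance = rep(tau^2, n_sig + n_decoy))
    truth <- structure(
      list(c_star = c_star, mode = mode, tau = tau, scale = scale,
           seed = seed, coherent = coherent),
      class = "synthetic_truth")
    list(profile = profile, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> mode %s, tau %g, scale %g, coherent %s\n",
              x$mode, x$tau, x$scale, x$coherent))
  invisible(x)
}

#' Write a self-contained fixture suite
#'
#' Writes a worked-example BEL script (a chemical and two protein
#' activities converging on a pathology, as three statements), a 10-node toy
#' model (SIF network, transcript layer, consistent and null profiles with
#' their ground truths), and a JSON manifest listing files and seeds.
#' Regenerating with the same seed reproduces byte-identical files.
#'
#' @param directory writable output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the manifest (also written as \code{manifest.json}).
#' @export
write_fixture_suite <- function(directory, seed = 1L) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (file.access(directory, mode = 2) != 0)
    stop("directory not writable: ", directory, call. = FALSE)
  p <- function(f) file.path(directory, f)

  bel_lines <- c(
    "# worked example: ethanol exposure and morpholino knockdowns reduce brain volume",
    'SET Citation = {"PubMed","Zebrafish brain volume study","B100"}',
    "a(CHEBI:ethanol) -> path(MESHD:Microcephaly)",
    "act(p(ZFIN:agrn)) -| path(MESHD:Microcephaly)",
    "act(p(ZFIN:shha)) -| path(MESHD:Microcephaly)")
  writeLines(bel_lines, p("worked-example.bel"), useBytes = TRUE)

  net <- generate_network(10, 12, p_negative = 0.3, seed = seed)
  layer <- generate_transcript_layer(net, frac_inodes = 0.6,
                                     genes_per_inode = 5, seed = seed)
  model <- attach_transcript_layer(net, layer)
  cons <- generate_profile(model, "consistent", tau = 0.1, seed = seed)
  null <- generate_profile(model, "null", tau = 0.1, seed = seed)

  write_sif(net, p("toy-network.sif"))
  write_transcript_layer(layer, p("toy-layer.tsv"))
  write_expression_profile(cons$profile, p("toy-profile-consistent.tsv"))
  write_expression_profile(null$profile, p("toy-profile-null.tsv"))
  jsonlite::write_json(
    lapply(list(consistent = cons$truth, null = null$truth), unclass),
    p("toy-truths.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    seed = seed,
    files = c("worked-example.bel", "toy-network.sif", "toy-layer.tsv",
              "toy-profile-consistent.tsv", "toy-profile-null.tsv",
              "toy-truths.json"),
    generator = list(n_nodes = 10, n_edges = 12, p_negative = 0.3,
                     frac_inodes = 0.6, genes_per_inode = 5, tau = 0.1))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
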