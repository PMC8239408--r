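# Core estimator: signed-mean activities, quadratic consistency fit,
# mean-of-squares NPA.
#
# Given a two-layer model and a profile beta, the fit minimizes
#   J(c) = sum over causal edges (x -> y, sign s, weight w) of
#            w * (c_y - s * c_x)^2
#        + lambda * sum over anchored iNodes x of (c_x - a_x)^2
# which is a sparse symmetric positive-definite linear system after an
# epsilon ridge. Connected components with no anchored iNode have no data
# pulling them anywhere and come out exactly zero; they are reported.

#' Scoring configuration
#'
#' @param lambda anchor weight on the activity terms (> 0, default 1).
#' @param epsilon ridge regularizer keeping unanchored components determinate
#'   (default 1e-9).
#' @param permutations number of permutations N for the o and k statistics
#'   (default 500; p-values are add-one, so the attainable minimum is
#'   1/(N+1)).
#' @param alpha significance level (default 0.05, i.e. the observed NPA must
#'   sit in the top 5th percentile of the permuted NPAs).
#' @param ci_draws Monte Carlo draws for the confidence interval
#'   (default 1000).
#' @param seed master seed; \code{NULL} draws one at fit time (it is recorded
#'   in the result).
#' @return object of class \code{npa_control}.
#' @export
npa_control <- function(lambda = 1, epsilon = 1e-9, permutations = 500L,
                        alpha = 0.05, ci_draws = 1000L, seed = NULL) {
  stopifnot(lambda > 0, epsilon >= 0, permutations >= 1,
            alpha > 0, alpha < 1)
  structure(list(lambda = lambda, epsilon = epsilon,
                 permutations = as.integer(permutations), alpha = alpha,
                 ci_draws = as.integer(ci_draws), seed = seed),
            class = "npa_control")
}

# scoring node set: endpoints of sign-carrying edges plus all iNodes of the
# attached layer (so an isolated anchored iNode is still scored)
.scoring_nodes <- function(model) {
  net <- model$network
  causal <- net$edges[net$edges$sign != 0, , drop = FALSE]
  ids <- net$nodes$id
  ids[ids %in% c(causal$source, causal$target, unique(model$layer$inode_id))]
}

.causal_edges <- function(model)
  model$network$edges[model$network$edges$sign != 0, , drop = FALSE]

#' Infer iNode activities from an expression profile
#'
#' The activity of iNode x is the signed mean of its measured signature
#' genes: \eqn{a(x) = \sum_{g} s_{xg} \beta_g / m_x} over the \eqn{m_x}
#' signature genes present in the profile. Gene matching is
#' case-insensitive. Unmeasured genes are skipped; iNodes with no measured
#' gene are excluded and listed.
#'
#' @param model an \code{\link{attach_transcript_layer}} model.
#' @param profile an \code{\link{expression_profile}}.
#' @return object of class \code{activity_map}: list with \code{a} (named
#'   activities), \code{n_measured}, \code{n_genes} (signature sizes) and
#'   \code{excluded} (iNodes without measured genes).
#' @export
infer_activities <- function(model, profile) {
  stopifnot(inherits(model, "npa_model"),
            inherits(profile, "expression_profile"))
  if (nrow(profile) == 0L) stop("empty expression profile", call. = FALSE)
  beta <- stats::setNames(profile$log2fc, toupper(profile$gene_id))
  layer <- model$layer
  key <- toupper(layer$gene_id)
  measured <- key %in% names(beta)
  contrib <- ifelse(measured, layer$sign * beta[key], 0)

  inodes <- unique(layer$inode_id)
  sums <- tapply(contrib, factor(layer$inode_id, levels = inodes), sum)
  m <- tapply(measured, factor(layer$inode_id, levels = inodes), sum)
  size <- tapply(rep(1L, nrow(layer)),
                 factor(layer$inode_id, levels = inodes), sum)
  keep <- m > 0
  if (!any(keep))
    stop("profile does not overlap transcript layer", call. = FALSE)
  structure(list(
    a = stats::setNames(as.numeric(sums[keep] / m[keep]), inodes[keep]),
    n_measured = stats::setNames(as.integer(m[keep]), inodes[keep]),
    n_genes = stats::setNames(as.integer(size[keep]), inodes[keep]),
    excluded = inodes[!keep]
  ), class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map> %d iNodes (%d excluded, no measured genes)\n",
              length(x$a), length(x$excluded)))
  invisible(x)
}

# Assemble the SPD system K = B'WB + lambda * diag(anchored) + epsilon * I
# over the scoring nodes; edges may be overridden (k-statistic rewiring).
.build_system <- function(model, anchored_ids, lambda, epsilon,
                          edges = NULL) {
  v <- .scoring_nodes(model)
  n <- length(v)
  idx <- stats::setNames(seq_len(n), v)
  if (is.null(edges)) edges <- .causal_edges(model)
  anchored_ids <- intersect(anchored_ids, v)

  ii <- jj <- integer(0)
  xx <- numeric(0)
  if (nrow(edges)) {
    ex <- idx[edges$source]
    ey <- idx[edges$target]
    s <- edges$sign
    w <- edges$weight
    ii <- c(ex, ey, ex, ey)
    jj <- c(ex, ey, ey, ex)
    xx <- c(w * s^2, w, -w * s, -w * s)
  }
  a_idx <- idx[anchored_ids]
  ii <- c(ii, a_idx, seq_len(n))
  jj <- c(jj, a_idx, seq_len(n))
  xx <- c(xx, rep(lambda, length(a_idx)), rep(epsilon, n))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)

  # components of the causal subgraph (plus isolated scoring nodes) that
  # contain no anchored iNode: their coefficients are identically zero
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("source", "target")] else
      data.frame(source = character(), target = character()),
    directed = FALSE,
    vertices = data.frame(name = v))
  comp <- igraph::components(g)$membership[v]
  anchored_comp <- unique(comp[anchored_ids])
  unanchored <- v[!comp %in% anchored_comp]

  list(K = K, nodes = v, idx = idx, anchored = a_idx,
       unanchored_nodes = unanchored)
}

# solve K c = lambda * a for one or many activity columns
.solve_system <- function(sys, lambda, a_mat) {
  rhs <- matrix(0, nrow = length(sys$nodes), ncol = ncol(a_mat))
  rhs[sys$anchored, ] <- lambda * a_mat[names(sys$anchored), , drop = FALSE]
  ch <- tryCatch(Matrix::Cholesky(sys$K, perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) {
    if (length(sys$unanchored_nodes))
      stop("singular fit system; components without anchored iNodes: ",
           paste(sys$unanchored_nodes, collapse = ", "), call. = FALSE)
    stop("singular fit system", call. = FALSE)
  }
  out <- as.matrix(Matrix::solve(ch, rhs))
  rownames(out) <- sys$nodes
  out
}

#' Fit node coefficients by quadratic consistency minimization
#'
#' Minimizes \deqn{J(c) = \sum_{(x \to y)} w_{xy} (c_y - \sigma_{xy} c_x)^2 +
#' \lambda \sum_{x anchored} (c_x - a_x)^2} over the scoring subgraph as one
#' sparse symmetric positive-definite linear system. Anchored iNodes are
#' those with an inferred activity. Components containing no anchored iNode
#' come out identically zero (after the epsilon ridge) and are reported in
#' the \code{"unanchored_components"} attribute. Parallel conflicting-sign
#' edges contribute two penalty terms, pulling the pair toward zero — the
#' mechanism by which contradictions shrink the score.
#'
#' @param model an \code{npa_model}.
#' @param act an \code{\link{infer_activities}} result.
#' @param config an \code{\link{npa_control}}.
#' @return named numeric vector of coefficients over the scoring nodes.
#' @export
fit_coefficients <- function(model, act, config = npa_control()) {
  stopifnot(inherits(model, "npa_model"), inherits(act, "activity_map"))
  sys <- .build_system(model, names(act$a), config$lambda, config$epsilon)
  a_mat <- matrix(act$a, ncol = 1, dimnames = list(names(act$a), NULL))
  cvec <- .solve_system(sys, config$lambda, a_mat)[, 1]
  cvec[sys$unanchored_nodes] <- 0
  attr(cvec, "unanchored_components") <- sys$unanchored_nodes
  cvec
}

#' Network perturbation amplitude from fitted coefficients
#'
#' \deqn{NPA = \frac{1}{|V_b|} \sum_{x \in V_b} c(x)^2} over the scoring
#' node set. Always non-negative; zero iff all coefficients are zero.
#'
#' @param coeff named coefficient vector from
#'   \code{\link{fit_coefficients}}.
#' @return non-negative scalar.
#' @export
compute_npa <- function(coeff) {
  stopifnot(is.numeric(coeff), length(coeff) >= 1)
  mean(coeff^2)
}

#' Per-node contribution fractions
#'
#' \eqn{contribution(x) = c(x)^2 / \sum_y c(y)^2}; sums to 1 when the NPA is
#' positive. For an all-zero fit the contributions are undefined and
#' returned as \code{NA} with attribute \code{"undefined" = TRUE}.
#'
#' @param coeff named coefficient vector.
#' @return named numeric vector.
#' @export
node_contributions <- function(coeff) {
  tot <- sum(coeff^2)
  if (tot == 0) {
    out <- stats::setNames(rep(NA_real_, length(coeff)), names(coeff))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- coeff^2 / tot
  attributes(out) <- list(names = names(coeff))
  out
}
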