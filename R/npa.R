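# The user-facing estimator and its companion statistics.

# signed-mean operator as a sparse matrix M (iNode x measured gene) so
# activities for many perturbed profiles are one matrix product
.activity_operator <- function(model, profile) {
  beta_key <- toupper(profile$gene_id)
  layer <- model$layer
  key <- toupper(layer$gene_id)
  measured <- key %in% beta_key
  lay <- layer[measured, , drop = FALSE]
  gkey <- toupper(lay$gene_id)
  inodes <- unique(lay$inode_id)
  m <- table(factor(lay$inode_id, levels = inodes))
  M <- Matrix::sparseMatrix(
    i = match(lay$inode_id, inodes),
    j = match(gkey, beta_key),
    x = lay$sign / as.numeric(m[lay$inode_id]),
    dims = c(length(inodes), length(beta_key)),
    dimnames = list(inodes, beta_key))
  M
}

.npa_from_coeff_matrix <- function(C) colMeans(C^2)

#' Parametric Monte Carlo confidence interval for the NPA
#'
#' Assumes the gene expression values follow a normal distribution: each
#' measured gene is redrawn independently as
#' \eqn{\beta^*_g \sim N(\beta_g, v_g)} (missing variances are treated as
#' zero), the model is rescored, and the empirical
#' (\eqn{\alpha/2}, \eqn{1-\alpha/2}) percentiles of the rescored NPAs are
#' returned. Seeded and reproducible via the \code{"ci"} substream of
#' \code{config$seed}.
#'
#' @param model an \code{npa_model}.
#' @param profile an \code{expression_profile} (with variances for a
#'   non-degenerate interval).
#' @param config an \code{\link{npa_control}}.
#' @return numeric \code{c(lo, hi)} with attribute \code{"draws"}.
#' @export
confidence_interval <- function(model, profile, config = npa_control()) {
  stopifnot(inherits(model, "npa_model"))
  if (config$ci_draws < 2) stop("ci_draws must be >= 2", call. = FALSE)
  seed <- if (is.null(config$seed)) stats::runif(1, 1, 2^31 - 2) else
    config$seed
  act <- infer_activities(model, profile)
  sys <- .build_system(model, names(act$a), config$lambda, config$epsilon)
  M <- .activity_operator(model, profile)

  sds <- sqrt(profile$variance)
  G <- nrow(profile)
  D <- config$ci_draws
  draws <- with_seed(substream_seed(seed, "ci"), {
    matrix(stats::rnorm(G * D, mean = profile$log2fc, sd = sds),
           nrow = G, ncol = D)
  })
  A <- as.matrix(M %*% draws)           # iNode activities per draw
  C <- .solve_system(sys, config$lambda, A)
  npa_draws <- .npa_from_coeff_matrix(C)
  ci <- unname(stats::quantile(npa_draws,
                               c(config$alpha / 2, 1 - config$alpha / 2)))
  attr(ci, "draws") <- npa_draws
  ci
}

#' o statistic: transcript-layer permutation test
#'
#' Tests whether the specific assignment of genes to iNode signatures
#' matters. Each permutation redraws the gene endpoint of every
#' transcript-layer edge uniformly without replacement (within each iNode)
#' from the measured gene universe, preserving per-iNode signature sizes and
#' signs, and rescores end-to-end. The add-one upper-tail p-value is
#' \eqn{p_o = (1 + \#\{NPA_{perm} \ge NPA_{obs}\}) / (1 + N)}; significance
#' at \code{alpha} means the observed NPA sits in the top
#' \code{alpha}-quantile of the permuted NPAs.
#'
#' @param model an \code{npa_model}.
#' @param profile an \code{expression_profile}.
#' @param config an \code{\link{npa_control}}.
#' @return list with \code{p} and \code{perm} (the permuted NPA values).
#' @export
o_statistic <- function(model, profile, config = npa_control()) {
  stopifnot(inherits(model, "npa_model"))
  seed <- if (is.null(config$seed)) stats::runif(1, 1, 2^31 - 2) else
    config$seed
  act <- infer_activities(model, profile)
  coeff <- fit_coefficients(model, act, config)
  obs <- compute_npa(coeff)

  beta <- stats::setNames(profile$log2fc, toupper(profile$gene_id))
  U <- length(beta)
  inodes <- unique(model$layer$inode_id)
  sizes <- table(factor(model$layer$inode_id, levels = inodes))
  signs <- split(model$layer$sign, factor(model$layer$inode_id,
                                          levels = inodes))
  if (U < max(sizes))
    stop("measured gene universe smaller than the largest iNode signature",
         call. = FALSE)

  # permuted layers anchor every iNode (all redrawn genes are measured)
  sys <- .build_system(model, inodes, config$lambda, config$epsilon)
  N <- config$permutations
  A <- with_seed(substream_seed(seed, "o"), {
    vapply(seq_len(N), function(p) {
      vapply(inodes, function(x) {
        idx <- sample.int(U, sizes[[x]])
        mean(signs[[x]] * beta[idx])
      }, 0)
    }, numeric(length(inodes)))
  })
  A <- matrix(A, nrow = length(inodes), dimnames = list(inodes, NULL))
  C <- .solve_system(sys, config$lambda, A)
  perm <- .npa_from_coeff_matrix(C)
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + N)
  list(p = p, perm = perm, observed = obs)
}

#' k statistic: functional-layer permutation test
#'
#' Tests the contribution of backbone topology. Each permutation shuffles
#' the target endpoints among the scoring-subgraph edges (sources, signs and
#' weights stay with their edges); permutations creating self-loops are
#' redrawn up to 10 times, then accepted and counted. The transcript layer
#' is untouched. p-value convention as in \code{\link{o_statistic}}.
#'
#' @param model an \code{npa_model}.
#' @param profile an \code{expression_profile}.
#' @param config an \code{\link{npa_control}}.
#' @return list with \code{p}, \code{perm} and \code{self_loops_accepted}.
#' @export
k_statistic <- function(model, profile, config = npa_control()) {
  stopifnot(inherits(model, "npa_model"))
  seed <- if (is.null(config$seed)) stats::runif(1, 1, 2^31 - 2) else
    config$seed
  act <- infer_activities(model, profile)
  coeff <- fit_coefficients(model, act, config)
  obs <- compute_npa(coeff)

  edges <- .causal_edges(model)
  nE <- nrow(edges)
  if (nE < 1) stop("no scoring edges to permute", call. = FALSE)
  a_mat <- matrix(act$a, ncol = 1, dimnames = list(names(act$a), NULL))
  N <- config$permutations
  accepted_loops <- 0L
  perm <- with_seed(substream_seed(seed, "k"), {
    vapply(seq_len(N), function(p) {
      tgt <- NULL
      for (try in seq_len(10L)) {
        cand <- edges$target[sample.int(nE)]
        if (!any(cand == edges$source)) { tgt <- cand; break }
      }
      if (is.null(tgt)) {
        tgt <- edges$target[sample.int(nE)]
        accepted_loops <<- accepted_loops + 1L
      }
      e2 <- edges
      e2$target <- tgt
      sys <- .build_system(model, names(act$a), config$lambda,
                           config$epsilon, edges = e2)
      compute_npa(.solve_system(sys, config$lambda, a_mat)[, 1])
    }, 0)
  })
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + N)
  list(p = p, perm = perm, observed = obs,
       self_loops_accepted = accepted_loops)
}

#' Score an expression profile against a two-layer causal model
#'
#' The full scoring pipeline: signed-mean iNode activities
#' (\code{\link{infer_activities}}), quadratic consistency fit of node
#' coefficients (\code{\link{fit_coefficients}}), network perturbation
#' amplitude (\code{\link{compute_npa}}), parametric Monte Carlo confidence
#' interval, and the o/k permutation companion statistics. All randomness
#' flows from \code{control$seed} through named substreams recorded in the
#' result.
#'
#' @param model an \code{\link{attach_transcript_layer}} model.
#' @param profile an \code{\link{expression_profile}}.
#' @param control an \code{\link{npa_control}}.
#' @param ci,o,k compute the confidence interval / o statistic /
#'   k statistic (each default \code{TRUE}).
#' @return object of class \code{npa}: list with \code{npa}, \code{ci},
#'   \code{p_o}, \code{p_k}, \code{coefficients}, \code{contributions},
#'   \code{activities}, \code{perm_o}, \code{perm_k}, \code{control},
#'   \code{seeds} and the edge list used (for residuals).
#' @examples
#' net <- generate_network(10, 12, p_negative = 0.3, seed = 1)
#' layer <- generate_transcript_layer(net, 0.5, 5, seed = 2)
#' model <- attach_transcript_layer(net, layer)
#' prof <- generate_profile(model, "consistent", tau = 0.1, seed = 3)$profile
#' fit <- npa(model, prof, npa_control(permutations = 100, ci_draws = 100,
#'                                     seed = 42))
#' fit
#' @export
npa <- function(model, profile, control = npa_control(),
                ci = TRUE, o = TRUE, k = TRUE) {
  stopifnot(inherits(model, "npa_model"),
            inherits(profile, "expression_profile"))
  if (is.null(control$seed)) {
    control$seed <- sample.int(2^31 - 2, 1)
    message("no seed supplied; using seed = ", control$seed)
  }
  act <- infer_activities(model, profile)
  coeff <- fit_coefficients(model, act, control)
  value <- compute_npa(coeff)
  contrib <- node_contributions(coeff)

  ci_val <- c(NA_real_, NA_real_)
  npa_draws <- NULL
  if (ci) {
    ci_val <- confidence_interval(model, profile, control)
    npa_draws <- attr(ci_val, "draws")
    attributes(ci_val) <- NULL
  }
  o_res <- if (o) o_statistic(model, profile, control) else NULL
  k_res <- if (k) k_statistic(model, profile, control) else NULL

  structure(list(
    npa = value,
    ci = ci_val,
    p_o = if (o) o_res$p else NA_real_,
    p_k = if (k) k_res$p else NA_real_,
    coefficients = coeff,
    contributions = contrib,
    activities = act$a,
    coverage = act$n_measured,
    excluded_inodes = act$excluded,
    perm_o = o_res$perm,
    perm_k = k_res$perm,
    ci_draws = npa_draws,
    edges = .causal_edges(model),
    control = control,
    seeds = list(
      master = control$seed,
      ci = substream_seed(control$seed, "ci"),
      o = substream_seed(control$seed, "o"),
      k = substream_seed(control$seed, "k"))
  ), class = "npa")
}

#' NPA fold change over a control score
#'
#' Expresses a treatment score relative to a (vehicle) control:
#' \code{fold = treatment$npa / control$npa}, with the treatment confidence
#' interval proportionally rescaled by the control NPA.
#'
#' @param treatment,control \code{\link{npa}} fits.
#' @return list with \code{fold} and \code{scaled_ci}.
#' @export
npa_fold_change <- function(treatment, control) {
  stopifnot(inherits(treatment, "npa"), inherits(control, "npa"))
  if (!isTRUE(control$npa > 0))
    stop("control unperturbed; fold change undefined", call. = FALSE)
  list(fold = treatment$npa / control$npa,
       scaled_ci = treatment$ci / control$npa)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.npa <- function(x, digits = 4, ...) {
  cat("Network perturbation amplitude fit\n")
  cat(sprintf("  NPA: %s", format(x$npa, digits = digits)))
  if (!anyNA(x$ci))
    cat(sprintf("   CI: [%s, %s] (alpha = %g)",
                format(x$ci[1], digits = digits),
                format(x$ci[2], digits = digits), x$control$alpha))
  cat("\n")
  if (!is.na(x$p_o) || !is.na(x$p_k))
    cat(sprintf("  p(o) = %s, p(k) = %s  [N = %d permutations]\n",
                format(x$p_o, digits = digits),
                format(x$p_k, digits = digits), x$control$permutations))
  cat(sprintf("  %d scoring nodes, %d anchored iNodes; seed %s\n",
              length(x$coefficients), length(x$activities),
              format(x$seeds$master)))
  invisible(x)
}

#' @export
coef.npa <- function(object, ...) object$coefficients

#' @export
confint.npa <- function(object, parm, level, ...) {
  m <- matrix(object$ci, nrow = 1,
              dimnames = list("npa", c("lo", "hi")))
  m
}

#' Signed edge residuals of an NPA fit
#'
#' One residual per causal edge: \eqn{r_{xy} = c(y) - \sigma_{xy} c(x)}.
#' Large residuals mark edges where the inferred activities and the network
#' topology contradict each other.
#'
#' @param object an \code{npa} fit.
#' @param ... unused.
#' @return numeric vector named \code{"source -> target"}.
#' @export
residuals.npa <- function(object, ...) {
  e <- object$edges
  c_ <- object$coefficients
  stats::setNames(c_[e$target] - e$sign * c_[e$source],
                  paste(e$source, "->", e$target))
}

#' @export
summary.npa <- function(object, threshold = 0.8, ...) {
  ln <- if (object$npa > 0) leading_nodes(object, threshold) else NULL
  structure(list(fit = object, leading = ln, threshold = threshold),
            class = "summary.npa")
}

#' @export
print.summary.npa <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$leading)) {
    cat(sprintf("\nLeading nodes (cumulative contribution >= %g%%):\n",
                100 * x$threshold))
    print(as.data.frame(x$leading), digits = 4)
  } else {
    cat("\nNo perturbation to decompose (NPA = 0).\n")
  }
  invisible(x)
}

#' Plot per-node contributions of an NPA fit
#'
#' Horizontal bars of the top contributing nodes, colored by inferred
#' direction (red = activated, blue = inactivated), mirroring the standard
#' leading-node color coding.
#'
#' @param x an \code{npa} fit.
#' @param top_n number of nodes shown.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.npa <- function(x, top_n = 15, ...) {
  contrib <- x$contributions
  if (all(is.na(contrib))) {
    warning("all-zero fit: nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  ord <- order(-contrib, names(contrib))[seq_len(min(top_n, length(contrib)))]
  v <- rev(contrib[ord])
  cols <- ifelse(x$coefficients[names(v)] > 0, "firebrick",
                 ifelse(x$coefficients[names(v)] < 0, "steelblue", "grey"))
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(v, horiz = TRUE, las = 1, col = cols,
                    xlab = "contribution to NPA",
                    main = "Node contributions", ...)
  invisible(x)
}
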