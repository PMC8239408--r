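# Activity inference, coefficient fitting, NPA, CI, permutation statistics.

test_that("activities are signed means over measured signature genes", {
  net <- generate_network(3, 2, p_negative = 0, seed = 1)
  layer <- transcript_layer(rep("n01", 2), c("g1", "g2"), c(1, -1))
  model <- attach_transcript_layer(net, layer)

  act <- infer_activities(model, expression_profile(c("g1", "g2"), c(2, -2)))
  expect_equal(unname(act$a["n01"]), 2)   # (+1*2 + (-1)*(-2)) / 2

  act0 <- infer_activities(model, expression_profile(c("g1", "g2"), c(0, 0)))
  expect_equal(unname(act0$a["n01"]), 0)

  # unmeasured genes are skipped; coverage reflects the measured subset
  act1 <- infer_activities(model, expression_profile("g1", 1))
  expect_equal(unname(act1$a["n01"]), 1)
  expect_equal(unname(act1$n_measured["n01"]), 1L)
  expect_equal(unname(act1$n_genes["n01"]), 2L)

  # gene matching is case-insensitive
  act2 <- infer_activities(model, expression_profile(c("G1", "G2"), c(2, -2)))
  expect_equal(act2$a, act$a)

  expect_error(infer_activities(model, expression_profile("absent", 1)),
               "does not overlap")
})

test_that("the coefficient fit solves its analytic anchor cases", {
  # isolated anchored iNode: the anchor term alone sets the coefficient
  iso <- isolated_model(0.5)
  act <- infer_activities(iso$model, iso$profile)
  cc <- fit_coefficients(iso$model, act)
  expect_equal(as.numeric(cc), 0.5, tolerance = 1e-6)

  # consistent propagation along a +1 edge from a single anchor: J = 0
  net <- net_from("p(ZFIN:x) -> p(ZFIN:y)")
  layer <- transcript_layer("p(ZFIN:x)", "gx", 1)
  model <- attach_transcript_layer(net, layer)
  act <- infer_activities(model, expression_profile("gx", 1))
  cc <- fit_coefficients(model, act)
  expect_equal(unname(cc[c("p(ZFIN:x)", "p(ZFIN:y)")]), c(1, 1),
               tolerance = 1e-6)

  # inhibiting edge with both anchors at +1: normal equations give 1/3
  net <- net_from("p(ZFIN:x) -| p(ZFIN:y)")
  layer <- transcript_layer(c("p(ZFIN:x)", "p(ZFIN:y)"), c("gx", "gy"),
                            c(1, 1))
  model <- attach_transcript_layer(net, layer)
  act <- infer_activities(model, expression_profile(c("gx", "gy"), c(1, 1)))
  cc <- fit_coefficients(model, act)
  expect_equal(unname(cc[c("p(ZFIN:x)", "p(ZFIN:y)")]), c(1 / 3, 1 / 3),
               tolerance = 1e-6)
  expect_equal(compute_npa(cc), 1 / 9, tolerance = 1e-6)
})

test_that("NPA is the node-mean of squared coefficients", {
  expect_equal(compute_npa(c(a = 1, b = 1)), 1)
  expect_equal(compute_npa(c(a = 0, b = 0)), 0)
  expect_equal(compute_npa(c(a = 1 / 3, b = 1 / 3)), 1 / 9)
  contrib <- node_contributions(c(a = 0, b = 0))
  expect_true(isTRUE(attr(contrib, "undefined")))
})

test_that("the linear solve matches brute-force minimization of J", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    model <- toy_model(seed = 100 + i, n_nodes = n,
                       n_edges = sample(4:min(14, n * (n - 1)), 1),
                       frac_inodes = 0.6, genes_per_inode = 3)
    prof <- generate_profile(model, "consistent", tau = 0.3,
                             seed = 200 + i)$profile
    act <- infer_activities(model, prof)
    cc <- fit_coefficients(model, act)
    oracle <- oracle_fit(model, act)
    # on unanchored components J is flat and the minimizer non-unique, so
    # the comparison is meaningful only where the system is determinate
    det <- setdiff(names(oracle), attr(cc, "unanchored_components"))
    expect_gt(length(det), 0)
    expect_lt(max(abs(cc[det] - oracle[det])), 1e-6)
    expect_true(all(cc[attr(cc, "unanchored_components")] == 0))
  }
})

test_that("components without anchors come out exactly zero and are reported", {
  # two components; only one carries an anchored iNode
  net <- net_from("p(ZFIN:a) -> p(ZFIN:b)", "p(ZFIN:c) -> p(ZFIN:d)")
  layer <- transcript_layer("p(ZFIN:a)", "ga", 1)
  model <- attach_transcript_layer(net, layer)
  act <- infer_activities(model, expression_profile("ga", 1))
  cc <- fit_coefficients(model, act)
  expect_equal(unname(cc[c("p(ZFIN:c)", "p(ZFIN:d)")]), c(0, 0))
  expect_setequal(attr(cc, "unanchored_components"),
                  c("p(ZFIN:c)", "p(ZFIN:d)"))
})

test_that("scaling and sign-flip invariances hold to solver tolerance", {
  model <- toy_model(seed = 21)
  prof <- generate_profile(model, "consistent", tau = 0.2, seed = 22)$profile
  act <- infer_activities(model, prof)
  cc <- fit_coefficients(model, act)
  base <- compute_npa(cc)

  for (alpha in c(0.5, 2, -3)) {
    prof2 <- expression_profile(prof$gene_id, alpha * prof$log2fc)
    cc2 <- fit_coefficients(model, infer_activities(model, prof2))
    expect_equal(as.numeric(cc2), as.numeric(alpha * cc), tolerance = 1e-8)
    expect_equal(compute_npa(cc2), alpha^2 * base, tolerance = 1e-8)
  }
  expect_gte(base, 0)
})

test_that("confidence intervals degenerate at zero variance and reproduce", {
  model <- toy_model(seed = 5)
  prof <- generate_profile(model, "consistent", tau = 0, seed = 6)$profile
  cfg <- fast_control(seed = 9)
  act <- infer_activities(model, prof)
  value <- compute_npa(fit_coefficients(model, act, cfg))
  ci <- confidence_interval(model, prof, cfg)
  expect_equal(unname(ci[1]), value, tolerance = 1e-12)
  expect_equal(unname(ci[2]), value, tolerance = 1e-12)

  prof2 <- generate_profile(model, "consistent", tau = 0.2, seed = 6)$profile
  ci_a <- confidence_interval(model, prof2, cfg)
  ci_b <- confidence_interval(model, prof2, cfg)
  expect_equal(ci_a, ci_b)
  expect_error(confidence_interval(model, prof2,
                                   npa_control(ci_draws = 1, seed = 1)),
               "ci_draws")
})

test_that("interval width is non-decreasing in the common variance scale", {
  model <- toy_model(seed = 13)
  base <- generate_profile(model, "consistent", tau = 0, seed = 14)$profile
  widths <- vapply(c(0.01, 0.1, 1), function(tau2) {
    prof <- expression_profile(base$gene_id, base$log2fc,
                               variance = rep(tau2, nrow(base)))
    ci <- confidence_interval(model, prof, fast_control(seed = 15,
                                                        ci_draws = 400))
    ci[2] - ci[1]
  }, 0)
  expect_true(all(diff(widths) >= 0))
})

test_that("o statistic is null on flat profiles and reproducible", {
  model <- toy_model(seed = 5)
  genes <- model$layer$gene_id
  flat <- expression_profile(c(genes, "extra1", "extra2"),
                             rep(0, length(genes) + 2))
  res <- o_statistic(model, flat, fast_control(seed = 3))
  expect_equal(res$p, 1)
  expect_true(all(res$perm == 0))

  prof <- generate_profile(model, "consistent", tau = 0.1, seed = 8)$profile
  r1 <- o_statistic(model, prof, fast_control(seed = 4))
  r2 <- o_statistic(model, prof, fast_control(seed = 4))
  expect_equal(r1$perm, r2$perm)
  expect_gte(r1$p, 1 / (fast_control()$permutations + 1))
  expect_lte(r1$p, 1)
})

test_that("o statistic requires a universe covering the largest signature", {
  net <- generate_network(2, 1, p_negative = 0, seed = 1)
  layer <- transcript_layer(rep("n01", 4), paste0("g", 1:4), rep(1, 4))
  model <- attach_transcript_layer(net, layer)
  small <- expression_profile(c("g1", "g2"), c(1, 1))
  expect_error(o_statistic(model, small, fast_control()),
               "universe smaller")
})

test_that("k statistic handles invariant graphs and reproduces", {
  # single causal edge: the target permutation is the identity
  net <- net_from("p(ZFIN:x) -> p(ZFIN:y)")
  layer <- transcript_layer("p(ZFIN:x)", "gx", 1)
  model <- attach_transcript_layer(net, layer)
  prof <- expression_profile("gx", 1)
  res <- k_statistic(model, prof, fast_control(seed = 2))
  expect_equal(res$p, 1)

  model2 <- toy_model(seed = 5)
  prof2 <- generate_profile(model2, "consistent", tau = 0.1, seed = 8)$profile
  r1 <- k_statistic(model2, prof2, fast_control(seed = 6, permutations = 60))
  r2 <- k_statistic(model2, prof2, fast_control(seed = 6, permutations = 60))
  expect_equal(r1$perm, r2$perm)
  expect_gte(r1$p, 1 / 61)
  expect_lte(r1$p, 1)
})

test_that("the full fit populates every report field deterministically", {
  model <- toy_model(seed = 5)
  prof <- generate_profile(model, "consistent", tau = 0.1, seed = 8)$profile
  fit1 <- npa(model, prof, fast_control(seed = 77))
  fit2 <- npa(model, prof, fast_control(seed = 77))
  expect_equal(fit1$npa, fit2$npa)
  expect_equal(fit1$ci, fit2$ci)
  expect_equal(fit1$p_o, fit2$p_o)
  expect_equal(fit1$p_k, fit2$p_k)
  expect_equal(sum(fit1$contributions), 1, tolerance = 1e-12)
  expect_true(all(fit1$coefficients[attr(fit1$coefficients,
                                         "unanchored_components")] == 0))
  expect_named(fit1$seeds, c("master", "ci", "o", "k"))

  # global sign flip negates coefficients, leaves the NPA unchanged
  flipped <- expression_profile(prof$gene_id, -prof$log2fc, variance = prof$variance)
  fit3 <- npa(model, flipped, fast_control(seed = 77), ci = FALSE,
              o = FALSE, k = FALSE)
  expect_equal(as.numeric(fit3$coefficients), as.numeric(-fit1$coefficients),
               tolerance = 1e-10)
  expect_equal(fit3$npa, fit1$npa, tolerance = 1e-10)
})

test_that("fold change rescales the treatment score by the control", {
  model <- toy_model(seed = 5)
  prof <- generate_profile(model, "consistent", tau = 0.1, seed = 8)$profile
  fit <- npa(model, prof, fast_control(seed = 77))
  fc <- npa_fold_change(fit, fit)
  expect_equal(fc$fold, 1)

  t <- fit; t$npa <- 3; t$ci <- c(2, 4)
  ctrl <- fit; ctrl$npa <- 2
  fc <- npa_fold_change(t, ctrl)
  expect_equal(fc$fold, 1.5)
  expect_equal(fc$scaled_ci, c(1, 2))

  ctrl0 <- fit; ctrl0$npa <- 0
  expect_error(npa_fold_change(t, ctrl0), "control unperturbed")
})

test_that("expected NPA decays as transcript signs are randomly flipped", {
  model <- toy_model(seed = 41, n_nodes = 15, n_edges = 18)
  layer <- model$layer
  levels <- c(0, 0.25, 0.5)
  reps <- 40
  means <- vapply(seq_along(levels), function(li) {
    frac <- levels[li]
    vals <- vapply(seq_len(reps), function(r) {
      prof <- generate_profile(model, "consistent", tau = 0.1,
                               seed = 1000 * li + r)$profile
      set.seed(5000 * li + r)
      flip <- sample(nrow(layer), round(frac * nrow(layer)))
      l2 <- layer
      l2$sign[flip] <- -l2$sign[flip]
      m2 <- attach_transcript_layer(model$network, l2)
      compute_npa(fit_coefficients(m2, infer_activities(m2, prof)))
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(means) <= 0))
})
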