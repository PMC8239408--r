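# Compilation into the two-layer causal model.

test_that("the worked example compiles to 4 nodes and 3 signed edges", {
  net <- compile_network(worked_example_statements())
  expect_equal(nrow(net$nodes), 4)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$nodes$id,
                  c("a(CHEBI:ethanol)", "act(p(ZFIN:agrn))",
                    "act(p(ZFIN:shha))", "path(MESHD:Microcephaly)"))
  expect_equal(net$edges$sign, c(1, -1, -1))
  census <- node_type_census(net)
  expect_equal(census[["abundance"]], 1)
  expect_equal(census[["activity"]], 2)
  expect_equal(census[["pathology"]], 1)
  expect_equal(sum(census), nrow(net$nodes))   # counts partition the nodes
})

test_that("duplicate statements merge into one evidence-rich edge", {
  st <- lapply(rep("p(ZFIN:a) -> p(ZFIN:b)", 2), parse_statement)
  net <- compile_network(st)
  expect_equal(nrow(net$edges), 1)
  expect_length(net$evidence[[1]], 2)
})

test_that("conflicting signs are kept as parallel edges and logged", {
  net <- net_from("p(ZFIN:a) -> p(ZFIN:b)", "p(ZFIN:a) -| p(ZFIN:b)")
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c(1, -1))
  expect_match(net$log, "conflicting signs", all = FALSE)
})

test_that("empty statement lists yield an empty network with a warning", {
  expect_warning(net <- compile_network(list()), "empty")
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
  census <- node_type_census(net)
  expect_true(all(census == 0))
})

test_that("compilation is idempotent on the serialized network", {
  net <- net_from("p(ZFIN:a) -> p(ZFIN:b)", "p(ZFIN:b) -| bp(GOBP:x)",
                  "act(p(ZFIN:c)) -> p(ZFIN:a)")
  rel <- c(`-1` = "decreases", `0` = "association", `1` = "increases")
  lines <- sprintf("%s %s %s", net$edges$source,
                   rel[as.character(net$edges$sign)], net$edges$target)
  net2 <- compile_network(lapply(lines, parse_statement))
  expect_setequal(net2$nodes$id, net$nodes$id)
  key <- function(n) sort(paste(n$edges$source, n$edges$target, n$edges$sign))
  expect_equal(key(net2), key(net))
})

test_that("node count equals distinct terms; edges never exceed statements", {
  set.seed(11)
  for (i in 1:20) {
    st <- replicate(sample(2:12, 1), random_statement(), simplify = FALSE)
    net <- compile_network(st)
    terms <- unique(unlist(lapply(st, function(s)
      c(s$subject$canonical_id, s$object$canonical_id))))
    expect_equal(nrow(net$nodes), length(terms))
    expect_lte(nrow(net$edges), length(st))
    expect_equal(sum(node_type_census(net)), nrow(net$nodes))
  }
})

test_that("molecular variants collapse to gene-level nodes", {
  net <- net_from("act(p(ZFIN:gbx2)) -> r(ZFIN:shha)",
                  "p(ZFIN:shha) -> bp(GOBP:x)",
                  "p(ZFIN:shha,pmod(P)) -| bp(GOBP:y)")
  col <- collapse_molecular_variants(net)
  expect_true("ZFIN:shha" %in% col$nodes$id)
  # r(shha), p(shha), p(shha,pmod(P)) are now one node
  expect_equal(sum(grepl("shha", col$nodes$id)), 1)
  expect_lte(nrow(col$nodes), nrow(net$nodes))
  expect_lte(nrow(col$edges), nrow(net$edges))
})

test_that("collapse is the identity on variant-free networks", {
  net <- net_from("bp(GOBP:x) -> path(MESHD:y)", "a(CHEBI:z) -| bp(GOBP:x)")
  col <- collapse_molecular_variants(net)
  expect_setequal(col$nodes$id, net$nodes$id)
  expect_equal(nrow(col$edges), nrow(net$edges))
})

test_that("collapse drops and logs self-loops", {
  net <- net_from("p(ZFIN:x) -> act(p(ZFIN:x))")
  col <- collapse_molecular_variants(net)
  expect_equal(nrow(col$nodes), 1)
  expect_equal(nrow(col$edges), 0)
  expect_match(col$log, "self-loop", all = FALSE)
})

test_that("transcript layers attach with strict/lenient unknown handling", {
  net <- compile_network(worked_example_statements())
  layer <- transcript_layer(
    c("act(p(ZFIN:agrn))", "act(p(ZFIN:shha))"),
    c("agrn_tgt1", "shha_tgt1"), c(1, -1))
  model <- attach_transcript_layer(net, layer)
  expect_s3_class(model, "npa_model")
  expect_length(unique(model$layer$inode_id), 2)

  bad <- transcript_layer(c("act(p(ZFIN:agrn))", "p(ZFIN:nosuch)"),
                          c("g1", "g2"), c(1, 1))
  expect_error(attach_transcript_layer(net, bad, strict = TRUE),
               "p\\(ZFIN:nosuch\\)")
  expect_warning(ok <- attach_transcript_layer(net, bad, strict = FALSE),
                 "nosuch")
  expect_length(unique(ok$layer$inode_id), 1)

  all_bad <- transcript_layer("p(ZFIN:nosuch)", "g1", 1)
  expect_warning(expect_error(
    attach_transcript_layer(net, all_bad), "unscoreable"))
})

test_that("layer invariants reject duplicate genes and bad signs", {
  expect_error(transcript_layer(c("x", "x"), c("g1", "G1"), c(1, 1)),
               "duplicate gene")
  expect_error(transcript_layer("x", "g1", 2), "\\+1 or -1")
  # "+1" string form accepted
  expect_equal(transcript_layer("x", "g1", "+1")$sign, 1L)
})

test_that("a synthetic model round-trips through write/read unchanged", {
  dir <- withr::local_tempdir()
  net <- generate_network(8, 10, seed = 9)
  layer <- generate_transcript_layer(net, 0.5, 4, seed = 9)

  write_sif(net, file.path(dir, "net.sif"))
  net2 <- read_sif(file.path(dir, "net.sif"))
  key <- function(n) sort(paste(n$edges$source, n$edges$target, n$edges$sign))
  expect_setequal(net2$nodes$id, net$nodes$id)
  expect_equal(key(net2), key(net))

  write_graphml(net, file.path(dir, "net.graphml"))
  net3 <- read_graphml(file.path(dir, "net.graphml"))
  expect_setequal(net3$nodes$id, net$nodes$id)
  expect_equal(key(net3), key(net))
  expect_equal(sort(net3$nodes$kind), sort(net$nodes$kind))

  write_transcript_layer(layer, file.path(dir, "layer.tsv"))
  layer2 <- read_transcript_layer(file.path(dir, "layer.tsv"))
  expect_equal(as.data.frame(layer2), as.data.frame(layer))

  # the reassembled model is scoreable
  model <- attach_transcript_layer(net2, layer2)
  expect_s3_class(model, "npa_model")
})
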