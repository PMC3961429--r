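test_that("a minimal well-formed network validates and exposes its candidates", {
  net <- build_network(
    compounds = c("s", "c", "t"),
    reactions = c("r1", "r2"),
    edges = data.frame(from = c("s", "r1", "c", "r2"),
                       to = c("r1", "c", "r2", "t")),
    sources = "s", target = "t",
    host_nodes = c("s", "c", "r1")
  )
  expect_s3_class(net, "metnet")
  expect_identical(additional_reactions(net), "r2")
  expect_identical(net$subs$r2, "c")
  expect_identical(net$producers$t, "r2")
})

test_that("structural violations are rejected with informative errors", {
  edges_ok <- data.frame(from = c("s", "r1"), to = c("r1", "t"))
  expect_error(
    build_network(c("s", "t"), c("r1", "r2"),
                  rbind(edges_ok, data.frame(from = "r1", to = "r2")),
                  sources = "s", target = "t"),
    "bipartiteness.*r1 -> r2"
  )
  expect_error(
    build_network(c("s", "t", "s"), "r1", edges_ok, "s", "t"),
    "duplicate node ids"
  )
  expect_error(
    build_network(c("s", "t"), "r1",
                  data.frame(from = c("s", "r1"), to = c("r1", "zz")),
                  "s", "t"),
    "undeclared ids: zz"
  )
  expect_error(
    build_network(c("s", "t"), "r1", edges_ok, sources = "s", target = "s"),
    "target must not be a source"
  )
  expect_error(
    build_network(c("s", "t"), "r1", edges_ok, sources = "s", target = "r1"),
    "target must be a single declared compound"
  )
})

test_that("sources with incoming edges follow the declared policy", {
  edges <- data.frame(from = c("s", "r1", "t", "r2"),
                      to = c("r1", "t", "r2", "s"))
  expect_error(
    build_network(c("s", "t"), c("r1", "r2"), edges, "s", "t",
                  source_policy = "strict"),
    "no incoming edges"
  )
  expect_warning(
    net <- build_network(c("s", "t"), c("r1", "r2"), edges, "s", "t",
                         source_policy = "strip"),
    "removed 1 edge"
  )
  expect_false(any(net$edges$to == "s"))
  expect_true(all(c("r1", "r2") %in% net$reactions))
})

test_that("reversible reactions decompose into mirrored P/Q halves", {
  sp <- list(
    compounds = c("S", "A", "B", "t"),
    reactions = list(
      list(id = "r0", substrates = "S", products = "A",
           reversible = FALSE, host = TRUE),
      list(id = "R00001", substrates = "A", products = "B",
           reversible = TRUE, host = TRUE),
      list(id = "R00002", substrates = "B", products = "t",
           reversible = FALSE, host = FALSE)
    ),
    sources = "S", target = "t"
  )
  net <- decompose_reversible(sp)
  expect_setequal(net$reactions, c("r0", "P00001", "Q00001", "R00002"))
  expect_identical(net$subs$P00001, "A")
  expect_identical(net$prods$P00001, "B")
  expect_identical(net$subs$Q00001, "B")
  expect_identical(net$prods$Q00001, "A")
  expect_identical(net$reversible_pairs, list(c("P00001", "Q00001")))
  # both halves of a non-host pair are insertion candidates
  expect_true(all(c("P00001", "Q00001") %in% net$reactions))
  expect_identical(additional_reactions(net), "R00002")

  # a reversible reaction consuming a source: its backward half would
  # produce the source; the default policy strips that edge with a warning
  rev_src <- list(
    compounds = c("A", "B"),
    reactions = list(list(id = "R00009", substrates = "A", products = "B",
                          reversible = TRUE, host = TRUE)),
    sources = "A", target = "B"
  )
  expect_warning(net2 <- decompose_reversible(rev_src), "into source")
  expect_false(any(net2$edges$to == "A"))
})

test_that("decomposition doubles reversible reaction counts and is idempotent", {
  k <- 3L
  sp <- list(
    compounds = c("s", paste0("x", 0:3)),
    reactions = c(
      list(list(id = "r0", substrates = "s", products = "x0",
                reversible = FALSE, host = TRUE)),
      lapply(seq_len(k), function(i) {
        list(id = sprintf("R%05d", i),
             substrates = sprintf("x%d", i - 1L), products = sprintf("x%d", i),
             reversible = TRUE, host = i == 1L)
      })
    ),
    sources = "s", target = "x3"
  )
  net <- decompose_reversible(sp)
  expect_length(net$reactions, 2L * k + 1L)
  expect_length(net$reversible_pairs, k)

  again <- decompose_reversible(as_network_spec(net))
  expect_identical(again$reactions, net$reactions)
  expect_identical(again$edges, net$edges)
  expect_identical(again$reversible_pairs, net$reversible_pairs)
  expect_identical(again$host_nodes, net$host_nodes)
})

test_that("duplicate derived ids abort the decomposition", {
  sp <- list(
    compounds = c("A", "B", "t"),
    reactions = list(
      list(id = "R00001", substrates = "A", products = "B",
           reversible = TRUE, host = TRUE),
      list(id = "P00001", substrates = "A", products = "t",
           reversible = FALSE, host = TRUE)
    ),
    sources = "A", target = "t"
  )
  expect_error(decompose_reversible(sp), "duplicate derived reaction id")
})

test_that("JSON serialization round-trips and is deterministic", {
  net <- fixture("CYCTRAP")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, f1)
  back <- read_network_json(f1)
  expect_identical(back$compounds, net$compounds)
  expect_identical(back$reactions, net$reactions)
  expect_identical(back$edges, net$edges)
  expect_identical(back$sources, net$sources)
  expect_identical(back$target, net$target)
  expect_identical(back$host_nodes, net$host_nodes)
  write_network_json(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the host-induced subnetwork is itself a valid network", {
  for (name in c("CHAIN", "CYCTRAP", "BORDER")) {
    hn <- host_network(fixture(name))
    expect_s3_class(hn, "metnet")
    expect_identical(hn$sources, fixture(name)$sources)
    expect_identical(hn$target, fixture(name)$target)
    expect_length(additional_reactions(hn), 0L)
  }
  # CYCTRAP's target is not host-producible
  expect_false(is_producible(host_network(fixture("CYCTRAP")), character()))
})
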