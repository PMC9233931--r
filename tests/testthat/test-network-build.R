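two_layer_net <- function() {
  # 2 samples in one layer sharing 1 species, 1 sample in a second layer
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        age_max = c(1500, 1500, 500),
                        age_min = c(1500, 1500, 500))
  samples$layer <- c(0L, 0L, 1L)
  attr(samples, "n_layers") <- 2L
  occ <- matrix(c(1, 1, 0,
                  0, 1, 1), 3, 2,
                dimnames = list(c("s1", "s2", "s3"), c("tA", "tB")))
  build_taxonomic_network(occ, samples)
}

test_that("taxonomic networks count physical and state nodes correctly", {
  net <- two_layer_net()
  sz <- network_size(net)
  expect_equal(sz$n, 5)          # 3 samples + 2 taxa
  expect_equal(sz$m, 4)          # one edge per presence
  expect_equal(sz$t, 2)
  expect_true(all(net$edges$weight == 1))
  # taxon tB occurs in layers {0, 1} -> 2 state nodes; tA only layer 0
  tb <- net$nodes$id[net$nodes$name == "tB"]
  expect_equal(sum(net$state_nodes$node_id == tb), 2)
  ta <- net$nodes$id[net$nodes$name == "tA"]
  expect_equal(sum(net$state_nodes$node_id == ta), 1)
  # two samples in one layer sharing one species: the shared species has one
  # state node in that layer and two intralayer edges
  shared_edges <- net$edges[net$edges$to == ta, ]
  expect_equal(nrow(shared_edges), 2)

  # taxon occurring in layers {0, 2, 5} gets exactly 3 state nodes
  s6 <- data.frame(sample_id = sprintf("x%d", 1:3),
                   age_max = c(5750, 4750, 3250), age_min = c(5750, 4750, 3250))
  s6 <- assign_layers(s6, span_max = 6000, bin_width = 500)
  expect_identical(s6$layer, c(0L, 2L, 5L))
  occ6 <- matrix(1, 3, 1, dimnames = list(s6$sample_id, "tX"))
  net6 <- build_taxonomic_network(occ6, s6)
  tx <- net6$nodes$id[net6$nodes$name == "tX"]
  expect_equal(sort(net6$state_nodes$layer[net6$state_nodes$node_id == tx]),
               c(0L, 2L, 5L))
})

test_that("trait networks carry weights and drop zero cells", {
  samples <- data.frame(sample_id = "s1", age_max = 500, age_min = 500)
  samples$layer <- 0L
  attr(samples, "n_layers") <- 1L
  tw <- matrix(c(1.0, 0.5, 0), 1, 3,
               dimnames = list("s1", c("We", "Aq", "Wo")))
  net <- build_trait_network(tw, samples)
  expect_equal(network_size(net)$n, 3)     # zero-weight trait dropped
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$weight, c(1.0, 0.5))
  expect_true(all(net$edges$weight > 0 & net$edges$weight <= 1))
  expect_error(build_trait_network(tw[, 3, drop = FALSE], samples), "empty")
})

test_that("physical node count equals samples plus occurring taxa", {
  ds <- make_planted(2, n_samples = 60)
  f <- ingest_filter(ds)
  net <- build_taxonomic_network(f$occ, f$samples)
  sz <- network_size(net)
  expect_equal(sz$n, nrow(f$occ) + sum(colSums(f$occ) > 0))
  expect_equal(sz$m, sum(f$occ))
  # state node count identity: samples once + taxon layer occurrences
  occ_layers <- unique(data.frame(
    t = rep(colnames(f$occ), each = nrow(f$occ))[f$occ > 0],
    l = rep(f$samples$layer, times = ncol(f$occ))[f$occ > 0]))
  expect_equal(sz$n_state_nodes, nrow(f$occ) + nrow(occ_layers))
})

test_that("multilayer files round-trip exactly and reject malformed input", {
  net <- two_layer_net()
  net$relax_rate <- 0.25
  net$relax_limit <- 2L
  path <- withr::local_tempfile(fileext = ".net")
  write_multilayer(net, path)
  # the toy network: 5 vertex records, 4 intra-layer edge records
  lines <- readLines(path)
  expect_length(grep("^\\d+ \"", lines), 5)
  expect_length(lines[seq(which(lines == "*Intra") + 1, length(lines))], 4)
  back <- read_multilayer(path)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$state_nodes, net$state_nodes)
  expect_equal(back$relax_rate, 0.25)
  expect_equal(back$relax_limit, 2L)
  expect_equal(back$n_layers, net$n_layers)

  # weights survive at full double precision
  ds <- make_planted(4, n_samples = 30)
  f <- ingest_filter(ds)
  tn <- build_trait_network(f$trait_weights, f$samples)
  p2 <- withr::local_tempfile(fileext = ".net")
  write_multilayer(tn, p2)
  tn2 <- read_multilayer(p2)
  expect_identical(tn2$edges$weight, tn$edges$weight)

  # an edge between two sample nodes violates bipartiteness
  bad <- c("# kind taxonomic", "# nlayers 1",
           "# role 1 sample", "# role 2 sample",
           "*Vertices 2", '1 "a"', '2 "b"', "*Intra", "1 1 2 1")
  pb <- withr::local_tempfile()
  writeLines(bad, pb)
  expect_error(read_multilayer(pb), "bipartite")
  # malformed edge record is reported with its line number
  bad2 <- c("# role 1 sample", "# role 2 taxon",
            "*Vertices 2", '1 "a"', '2 "b"', "*Intra", "1 1 oops 1")
  pb2 <- withr::local_tempfile()
  writeLines(bad2, pb2)
  expect_error(read_multilayer(pb2), "line 7")
})
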