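test_that("optimizer recovers the two-clique structure and matches enumeration", {
  # two 3-cliques joined by one weak edge, single layer (bipartite analogue:
  # two sample-pairs sharing strong traits, joined by one weak shared trait)
  samples <- data.frame(sample_id = sprintf("s%d", 1:4),
                        age_max = rep(250, 4), age_min = rep(250, 4))
  samples$layer <- rep(0L, 4)
  attr(samples, "n_layers") <- 1L
  w <- rbind(c(1, 0, 0.05),
             c(1, 0, 0),
             c(0, 1, 0.05),
             c(0, 1, 0))
  dimnames(w) <- list(samples$sample_id, c("A", "B", "C"))
  net <- build_trait_network(w, samples)
  fl <- compute_flow(net, 0.25, 1)
  part <- mapeq_optimize(net, 0.25, 1, n_restarts = 10, seed = 1,
                         multilevel = FALSE, flow = fl)
  oracle <- oracle_min_codelength(fl)
  expect_equal(part$codelength, oracle$min, tolerance = 1e-9)
  # the two clusters separate; the optimizer's structure matches the
  # enumerated optimum exactly (as a set partition)
  mods <- part$states$module
  names(mods) <- part$states$name
  expect_equal(ami(mods, oracle$assignment), 1)
  expect_equal(mods[["s1"]], mods[["s2"]])
  expect_equal(mods[["s1"]], mods[["A"]])
  expect_equal(mods[["s3"]], mods[["s4"]])
  expect_equal(mods[["s3"]], mods[["B"]])
  expect_false(mods[["s1"]] == mods[["s3"]])
})

test_that("a uniform complete bipartite layer stays in one module", {
  samples <- data.frame(sample_id = sprintf("s%d", 1:3),
                        age_max = rep(250, 3), age_min = rep(250, 3))
  samples$layer <- rep(0L, 3)
  attr(samples, "n_layers") <- 1L
  occ <- matrix(1, 3, 3, dimnames = list(samples$sample_id, c("A", "B", "C")))
  net <- build_taxonomic_network(occ, samples)
  part <- mapeq_optimize(net, 0.25, 1, n_restarts = 5, seed = 2)
  expect_equal(length(unique(part$states$module)), 1)
})

test_that("optimizer attains the exhaustive minimum on random tiny networks", {
  for (seed in 1:12) {
    net <- random_tiny_network(seed, weighted = seed %% 3 == 0)
    fl <- compute_flow(net, 0.25, 1)
    part <- mapeq_optimize(net, 0.25, 1, n_restarts = 20, seed = seed,
                           multilevel = FALSE, flow = fl)
    oracle <- oracle_min_codelength(fl)
    expect_equal(part$codelength, oracle$min, tolerance = 1e-9,
                 label = sprintf("seed %d optimizer codelength", seed))
  }
})

test_that("reported codelength equals an independent recomputation", {
  ds <- make_planted(6, n_samples = 80)
  f <- ingest_filter(ds)
  net <- build_taxonomic_network(f$occ, f$samples)
  fl <- compute_flow(net, 0.25, 2)
  part <- mapeq_optimize(net, 0.25, 2, n_restarts = 2, seed = 3, flow = fl)
  expect_equal(part$codelength, codelength(fl, part$states$path),
               tolerance = 1e-9)
  flat <- mapeq_optimize(net, 0.25, 2, n_restarts = 2, seed = 3,
                         multilevel = FALSE, flow = fl)
  expect_equal(flat$codelength, oracle_codelength(fl, flat$states$module),
               tolerance = 1e-9)
})

test_that("best codelength is non-increasing in the number of restarts", {
  net <- random_tiny_network(21, weighted = TRUE)
  fl <- compute_flow(net, 0.25, 1)
  Ls <- vapply(c(1, 3, 6, 12), function(nr) {
    mapeq_optimize(net, 0.25, 1, n_restarts = nr, seed = 5,
                   multilevel = FALSE, flow = fl)$codelength
  }, numeric(1))
  expect_true(all(diff(Ls) <= 1e-12))
})

test_that("partitions are deterministic given the seed", {
  ds <- make_planted(9, n_samples = 60)
  f <- ingest_filter(ds)
  net <- build_taxonomic_network(f$occ, f$samples)
  p1 <- mapeq_optimize(net, 0.25, 2, n_restarts = 2, seed = 7)
  p2 <- mapeq_optimize(net, 0.25, 2, n_restarts = 2, seed = 7)
  expect_identical(p1$states$path, p2$states$path)
  expect_identical(p1$codelength, p2$codelength)
})

test_that("single-layer clustering agrees with igraph's infomap on a clear structure", {
  # independent cross-check of the search on an unambiguous planted case
  samples <- data.frame(sample_id = sprintf("s%d", 1:6),
                        age_max = rep(250, 6), age_min = rep(250, 6))
  samples$layer <- rep(0L, 6)
  attr(samples, "n_layers") <- 1L
  occ <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 1, 0, 0),
               c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 0, 1, 1))
  dimnames(occ) <- list(samples$sample_id, c("A", "B", "C", "D"))
  net <- build_taxonomic_network(occ, samples)
  part <- mapeq_optimize(net, 0, 1, n_restarts = 5, seed = 1, multilevel = FALSE)
  g <- igraph::graph_from_edgelist(cbind(
    net$nodes$name[net$edges$from], net$nodes$name[net$edges$to]),
    directed = FALSE)
  ig <- igraph::cluster_infomap(g)
  ours <- part$states$module[match(igraph::V(g)$name, part$states$name)]
  expect_equal(ami(ours, igraph::membership(ig)), 1)
})
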