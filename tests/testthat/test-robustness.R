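make_ref <- function(seed = 1, overlap = 0, n_samples = 100, pool = 14) {
  ds <- make_planted(seed, n_regimes = 2, overlap = overlap,
                     n_samples = n_samples, pool = pool, boundaries = 8000)
  f <- ingest_filter(ds)
  net <- build_taxonomic_network(f$occ, f$samples)
  part <- mapeq_optimize(net, 0.25, 2, n_restarts = 2, seed = seed)
  list(net = net, part = part)
}

test_that("bootstrap replicates perturb weights as configured", {
  x <- make_ref(1)
  reps0 <- bootstrap_networks(x$net, n = 3, weight_sd = 0, seed = 1)
  for (rn in reps0) expect_identical(rn$edges$weight, x$net$edges$weight)
  reps <- bootstrap_networks(x$net, n = 100, weight_sd = 0.1, seed = 5)
  w <- vapply(reps, function(rn) rn$edges$weight[1], numeric(1))
  expect_true(all(unlist(lapply(reps, function(rn) rn$edges$weight)) > 0))
  # CLT bound on the mean multiplier of a unit edge across 100 replicates
  expect_lt(abs(mean(w) - 1), 4 * 0.1 / sqrt(100))
  expect_error(bootstrap_networks(x$net, n = 2, weight_sd = 0.3, seed = 1),
               "weight_sd")
  # determinism
  reps2 <- bootstrap_networks(x$net, n = 100, weight_sd = 0.1, seed = 5)
  expect_identical(reps[[7]]$edges$weight, reps2[[7]]$edges$weight)
})

test_that("zero perturbation gives identity cores, abrupt transitions, full robustness", {
  x <- make_ref(2)
  ens <- bootstrap_ensemble(x$net, x$part, n = 5, weight_sd = 0, seed = 2,
                            n_restarts = 2)
  sc <- significant_cores(x$part, ens)
  st <- x$part$states
  for (m in unique(st$module)) {
    expect_setequal(sc$cores[[as.character(m)]], st$state_id[st$module == m])
  }
  expect_length(sc$insignificant, 0)
  sig <- significance_report(x$net, x$part, ens)
  expect_true(all(sig$transitions$label == "abrupt"))
  expect_true(all(sig$transitions$fraction == 0))
  expect_true(all(sig$layers$robustness == 1))
})

test_that("core membership follows the co-clustering count and conf monotonicity", {
  # hand-built ensemble: 2 reference modules over 6 states; one node flips
  # to the other module in half the replicates
  ref <- structure(list(states = data.frame(
    state_id = 1:6, node_id = 1:6, layer = rep(0:2, 2),
    name = sprintf("n%d", 1:6), role = "sample",
    module = c(1L, 1L, 1L, 2L, 2L, 2L), path = as.character(c(1, 1, 1, 2, 2, 2)),
    flow = rep(1 / 6, 6))), class = "mapeq_partition")
  mk_rep <- function(mod) {
    r <- ref; r$states$module <- mod; r
  }
  flip <- c(1L, 1L, 2L, 2L, 2L, 2L)   # node 3 defects
  keep <- c(1L, 1L, 1L, 2L, 2L, 2L)
  ens <- structure(list(
    replicates = c(replicate(10, mk_rep(flip), simplify = FALSE),
                   replicate(10, mk_rep(keep), simplify = FALSE)),
    reference = ref, n = 20, weight_sd = 0.1, seed = 1),
    class = "bootstrap_ensemble")
  sc95 <- significant_cores(ref, ens, conf = 0.95)
  expect_setequal(sc95$cores[["1"]], c(1L, 2L))   # the 50% defector is out
  expect_setequal(sc95$cores[["2"]], 4:6)
  expect_identical(sc95$insignificant, 3L)
  sc50 <- significant_cores(ref, ens, conf = 0.5)
  expect_setequal(sc50$cores[["1"]], 1:3)
  # raising conf never enlarges a core
  for (m in c("1", "2")) {
    expect_true(all(sc95$cores[[m]] %in% sc50$cores[[m]]))
  }
  # transition fraction counts replicates whose core majorities coincide
  tt <- transition_type(sc95$cores[["1"]], sc95$cores[["2"]], ens)
  expect_equal(tt$fraction, 0)
  expect_identical(tt$label, "abrupt")
  expect_error(transition_type(integer(0), sc95$cores[["2"]], ens), "empty core")
})

test_that("the 5% boundary is inclusive for gradual labels", {
  ref <- structure(list(states = data.frame(
    state_id = 1:4, node_id = 1:4, layer = c(0L, 0L, 1L, 1L),
    name = sprintf("n%d", 1:4), role = "sample",
    module = c(1L, 1L, 2L, 2L), path = as.character(c(1, 1, 2, 2)),
    flow = rep(0.25, 4))), class = "mapeq_partition")
  mk_rep <- function(mod) { r <- ref; r$states$module <- mod; r }
  merged <- rep(1L, 4)
  apart <- c(1L, 1L, 2L, 2L)
  ens <- structure(list(
    replicates = c(replicate(5, mk_rep(merged), simplify = FALSE),
                   replicate(95, mk_rep(apart), simplify = FALSE)),
    reference = ref, n = 100, weight_sd = 0.1, seed = 1),
    class = "bootstrap_ensemble")
  tt <- transition_type(1:2, 3:4, ens, alpha = 0.05)
  expect_equal(tt$fraction, 0.05)
  expect_identical(tt$label, "gradual")   # 0.05 >= 0.05: mutually non-significant
  ens$replicates <- c(replicate(4, mk_rep(merged), simplify = FALSE),
                      replicate(96, mk_rep(apart), simplify = FALSE))
  expect_identical(transition_type(1:2, 3:4, ens)$label, "abrupt")
})

test_that("layer Jaccard uses co-clustered pair sets", {
  ref <- structure(list(states = data.frame(
    state_id = 1:4, node_id = 1:4, layer = rep(0L, 4),
    name = sprintf("n%d", 1:4), role = "sample",
    module = rep(1L, 4), path = rep("1", 4), flow = rep(0.25, 4))),
    class = "mapeq_partition")
  splt <- ref; splt$states$module <- c(1L, 1L, 2L, 2L)
  ens <- structure(list(replicates = list(splt), reference = ref, n = 1,
                        weight_sd = 0.1, seed = 1),
                   class = "bootstrap_ensemble")
  # replicate splits one 4-node module into 2+2: 2 of 6 reference pairs survive
  expect_equal(fossilnet:::.pair_jaccard(ref$states$module, splt$states$module),
               2 / 6)
  lr <- layer_robustness(ref, ens, jaccard_threshold = 0.70)
  expect_equal(lr$robustness, 0)   # 1/3 < 0.7
  lr2 <- layer_robustness(ref, ens, jaccard_threshold = 0.30)
  expect_equal(lr2$robustness, 1)
})

test_that("robustness dips at a planted regime boundary", {
  # qualitative property, averaged over seeds: layers at the regime switch
  # are less often reproduced than regime interiors
  vals <- vapply(1:3, function(seed) {
    x <- make_ref(seed, overlap = 0.5, n_samples = 120, pool = 14)
    ens <- bootstrap_ensemble(x$net, x$part, n = 8, weight_sd = 0.1,
                              seed = seed, n_restarts = 2)
    lr <- layer_robustness(x$part, ens)
    boundary <- lr$layer %in% 14:17          # switch at layer 16 (8000 BP)
    interior <- lr$layer %in% c(2:10, 20:30)
    mean(lr$robustness[interior]) - mean(lr$robustness[boundary])
  }, numeric(1))
  expect_gte(mean(vals), 0)
})
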