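# Independent oracles used across the suite.  These re-derive quantities
# from first principles (enumeration, explicit Markov chains, entropy-form
# codelength) and must stay independent of the package's optimized paths.

# All set partitions of n items as restricted-growth assignment vectors.
enumerate_set_partitions <- function(n) {
  parts <- list()
  recurse <- function(prefix, k) {
    if (length(prefix) == n) {
      parts[[length(parts) + 1]] <<- prefix
      return(invisible())
    }
    for (j in seq_len(k + 1)) recurse(c(prefix, j), max(k, j))
  }
  recurse(integer(0), 0L)
  parts
}

# Two-level map-equation codelength written in entropy form, straight from
# the definition: index codebook rate x entropy of module exit rates, plus
# per-module codebook rate x entropy of (pooled physical visits, exit).
oracle_codelength <- function(flow, modules) {
  p <- flow$visit_rate
  phys <- flow$states$node_id
  fe <- flow$flow_edges
  mods <- sort(unique(modules))
  hs <- function(w) {                      # Shannon entropy of weights
    w <- w[w > 0]
    if (!length(w)) return(0)
    w <- w / sum(w)
    -sum(w * log2(w))
  }
  q <- vapply(mods, function(m) {
    sum(fe$flow[modules[fe$from] == m & modules[fe$to] != m])
  }, numeric(1))
  L <- sum(q) * hs(q)
  for (i in seq_along(mods)) {
    members <- which(modules == mods[i])
    pooled <- tapply(p[members], phys[members], sum)
    rate <- sum(pooled) + q[i]
    L <- L + rate * hs(c(as.numeric(pooled), q[i]))
  }
  L
}

# Exhaustive minimum two-level codelength over all set partitions.
oracle_min_codelength <- function(flow) {
  n <- length(flow$visit_rate)
  parts <- enumerate_set_partitions(n)
  vals <- vapply(parts, function(m) oracle_codelength(flow, m), numeric(1))
  list(min = min(vals), assignment = parts[[which.min(vals)]])
}

# A small random multilayer network with at most `max_states` state nodes.
random_tiny_network <- function(seed, max_states = 8, weighted = FALSE) {
  set.seed(seed)
  repeat {
    n_layers <- sample(1:2, 1)
    n_samples <- sample(1:3, 1)
    n_taxa <- sample(1:3, 1)
    s_layer <- sample(0:(n_layers - 1), n_samples, replace = TRUE)
    mat <- matrix(0, n_samples, n_taxa,
                  dimnames = list(sprintf("s%d", seq_len(n_samples)),
                                  sprintf("t%d", seq_len(n_taxa))))
    for (i in seq_len(n_samples)) {
      k <- sample(seq_len(n_taxa), 1)
      mat[i, sample(n_taxa, k)] <- if (weighted) round(runif(k, 0.2, 1), 2) else 1
    }
    samples <- data.frame(sample_id = rownames(mat),
                          age_max = 1000 * (n_layers - s_layer),
                          age_min = 1000 * (n_layers - s_layer))
    samples$layer <- s_layer
    attr(samples, "n_layers") <- n_layers
    net <- try(suppressWarnings(
      if (weighted) build_trait_network(mat, samples)
      else build_taxonomic_network(mat, samples)), silent = TRUE)
    if (inherits(net, "try-error")) next
    if (nrow(net$state_nodes) <= max_states) return(net)
  }
}

# Small planted-regime dataset for pipeline-level tests.
make_planted <- function(seed, n_regimes = 3, overlap = 0, n_samples = 150,
                         pool = 16, boundaries = c(10000, 4000),
                         mean_richness = 12) {
  cfg <- regime_config(n_regimes, boundaries, n_species_per_regime = pool,
                       species_overlap_fraction = overlap,
                       mean_richness = mean_richness)
  generate_dataset(cfg, n_sites = 20, n_samples = n_samples, age_noise = 0,
                   seed = seed)
}
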