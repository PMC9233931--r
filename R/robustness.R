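# Bootstrap assessment of module significance.
#
# Replicate networks perturb every intralayer edge weight with a draw from
# Normal(1, sd^2) (redrawing non-positive values), are re-clustered with the
# same settings, and the replicate partitions are compared with the
# reference solution: per-module significant cores, abrupt-versus-gradual
# labels for successive module pairs (mutual significance at the 5% level),
# and per-layer robustness via Jaccard similarity of co-clustered pairs.

#' Bootstrap replicate networks with perturbed edge weights
#'
#' Each replicate multiplies every edge weight by an independent draw from
#' `Normal(1, weight_sd^2)`; non-positive draws are redrawn, and `weight_sd`
#' must keep 0 more than four standard deviations below the mean.  For an
#' unweighted (taxonomic) network the unit weights simply become the draws.
#'
#' @param net a `multilayer_network`.
#' @param n number of replicates.
#' @param weight_sd standard deviation of the weight perturbation
#'   (`1 - 4 * weight_sd > 0` enforced; `0` reproduces the input network).
#' @param seed integer seed.
#' @return List of `n` `multilayer_network` replicates.
#' @export
bootstrap_networks <- function(net, n = 100, weight_sd = 0.1, seed = 1) {
  stopifnot(inherits(net, "multilayer_network"), n >= 1)
  if (weight_sd < 0 || (weight_sd > 0 && 1 - 4 * weight_sd <= 0))
    stop("bootstrap_networks: weight_sd must satisfy 1 - 4*weight_sd > 0")
  set.seed(seed)
  m <- nrow(net$edges)
  lapply(seq_len(n), function(i) {
    rep_net <- net
    if (weight_sd > 0) {
      mult <- stats::rnorm(m, 1, weight_sd)
      while (any(mult <= 0)) {
        bad <- mult <= 0
        mult[bad] <- stats::rnorm(sum(bad), 1, weight_sd)
      }
      rep_net$edges$weight <- net$edges$weight * mult
    }
    rep_net
  })
}

#' Cluster bootstrap replicates into an ensemble
#'
#' @param net the reference `multilayer_network`.
#' @param ref the reference `mapeq_partition`.
#' @param n number of replicates.
#' @param weight_sd weight perturbation (see [bootstrap_networks()]).
#' @param seed integer seed (drives both the perturbation and the replicate
#'   clustering restarts).
#' @param n_restarts restarts per replicate clustering.
#' @return An object of class `bootstrap_ensemble`: `replicates` (list of
#'   `mapeq_partition`), `reference`, `n`, `weight_sd`, `seed`.
#' @export
bootstrap_ensemble <- function(net, ref, n = 100, weight_sd = 0.1, seed = 1,
                               n_restarts = 10) {
  nets <- bootstrap_networks(net, n, weight_sd, seed)
  parts <- lapply(seq_len(n), function(i) {
    mapeq_optimize(nets[[i]], r = ref$relax_rate, l = ref$relax_limit,
                   n_restarts = n_restarts, seed = seed + i)
  })
  for (pt in parts) {
    if (!identical(pt$states$state_id, ref$states$state_id))
      stop("bootstrap_ensemble: replicate partition covers a different state-node set")
  }
  structure(list(replicates = parts, reference = ref, n = n,
                 weight_sd = weight_sd, seed = seed),
            class = "bootstrap_ensemble")
}

# replicate module labels as a matrix (state nodes x replicates)
.ensemble_labels <- function(ensemble) {
  vapply(ensemble$replicates, function(pt) pt$states$module,
         integer(nrow(ensemble$reference$states)))
}

#' Significant cores of the reference modules
#'
#' For each reference module, finds the largest subset of its state nodes
#' that co-cluster in at least `conf` of the bootstrap replicates: in each
#' replicate the subset's majority module is identified, and the node with
#' the lowest rate of agreement with that majority is dropped until every
#' remaining node agrees in at least `conf` of the replicates.  Nodes
#' outside every core are flagged insignificant.
#'
#' @param ref the reference `mapeq_partition`.
#' @param ensemble a `bootstrap_ensemble`.
#' @param conf required co-clustering rate (default 0.95, i.e. the 5% level).
#' @return List with `cores` (per reference module, integer state ids),
#'   `insignificant` (state ids outside all cores), and `core_table`
#'   (data frame state_id, module, in_core).
#' @export
significant_cores <- function(ref, ensemble, conf = 0.95) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  if (!length(ensemble$replicates)) stop("significant_cores: empty ensemble")
  labels <- .ensemble_labels(ensemble)
  st <- ref$states
  cores <- list()
  for (m in sort(unique(st$module))) {
    members <- which(st$module == m)
    repeat {
      if (!length(members)) break
      sub <- labels[members, , drop = FALSE]
      # majority module of the current subset in each replicate
      maj <- apply(sub, 2, function(col) {
        tb <- tabulate(col)
        which.max(tb)
      })
      agree <- rowMeans(sweep(sub, 2, maj, "=="))
      if (min(agree) >= conf) break
      members <- members[-which.min(agree)]
    }
    cores[[as.character(m)]] <- st$state_id[members]
  }
  in_core <- st$state_id %in% unlist(cores)
  list(cores = cores,
       insignificant = st$state_id[!in_core],
       core_table = data.frame(state_id = st$state_id, module = st$module,
                               in_core = in_core))
}

#' Label a module transition abrupt or gradual
#'
#' Two successive modules are mutually significant - and their transition
#' abrupt - if their cores land in the same module (majority of each core)
#' in less than `alpha` of the bootstrap partitions; otherwise (fraction
#' `>= alpha`, boundary inclusive) the transition is gradual.
#'
#' @param coreA,coreB state-node id vectors (cores of the older and younger
#'   module).
#' @param ensemble a `bootstrap_ensemble`.
#' @param alpha significance level (default 0.05).
#' @return List with `label` (`"abrupt"` or `"gradual"`) and `fraction` (of
#'   replicates in which the cores co-cluster).
#' @export
transition_type <- function(coreA, coreB, ensemble, alpha = 0.05) {
  if (!length(coreA) || !length(coreB))
    stop("transition_type: empty core (module without a significant core)")
  labels <- .ensemble_labels(ensemble)
  idx <- ensemble$reference$states$state_id
  ia <- match(coreA, idx); ib <- match(coreB, idx)
  same <- vapply(seq_len(ncol(labels)), function(k) {
    majA <- which.max(tabulate(labels[ia, k]))
    majB <- which.max(tabulate(labels[ib, k]))
    majA == majB
  }, logical(1))
  fraction <- mean(same)
  list(label = if (fraction < alpha) "abrupt" else "gradual",
       fraction = fraction)
}

# Jaccard similarity between the co-clustered pair sets of two labelings.
.pair_jaccard <- function(lab1, lab2) {
  n <- length(lab1)
  if (n < 2) return(1)
  pairs <- utils::combn(n, 2)
  same1 <- lab1[pairs[1, ]] == lab1[pairs[2, ]]
  same2 <- lab2[pairs[1, ]] == lab2[pairs[2, ]]
  union <- sum(same1 | same2)
  if (union == 0) return(1)   # both labelings fully discrete: identical pair sets
  sum(same1 & same2) / union
}

#' Per-layer robustness of the reference solution
#'
#' For each layer, both the reference partition and each bootstrap partition
#' are restricted to the layer's state nodes; the Jaccard index between
#' their sets of co-clustered node pairs is computed, and the layer's
#' robustness is the fraction of replicates with Jaccard above the
#' threshold.
#'
#' @param ref the reference `mapeq_partition`.
#' @param ensemble a `bootstrap_ensemble`.
#' @param jaccard_threshold similarity threshold (default 0.70).
#' @return Data frame (layer, robustness, n_state_nodes).  Layers with fewer
#'   than two state nodes are reported as 1 with a warning.
#' @export
layer_robustness <- function(ref, ensemble, jaccard_threshold = 0.70) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  labels <- .ensemble_labels(ensemble)
  st <- ref$states
  layers <- sort(unique(st$layer))
  rob <- vapply(layers, function(ly) {
    idx <- which(st$layer == ly)
    if (length(idx) < 2) {
      warning("layer_robustness: layer ", ly,
              " has fewer than 2 state nodes; robustness reported as 1")
      return(1)
    }
    jac <- vapply(seq_len(ncol(labels)), function(k) {
      .pair_jaccard(st$module[idx], labels[idx, k])
    }, numeric(1))
    mean(jac > jaccard_threshold)
  }, numeric(1))
  data.frame(layer = layers, robustness = rob,
             n_state_nodes = as.vector(table(factor(st$layer, levels = layers))))
}

#' Full significance report for a clustered network
#'
#' Convenience wrapper combining [significant_cores()], [transition_type()]
#' over temporally successive module pairs (from [extract_timeline()]), and
#' [layer_robustness()].
#'
#' @param net the reference network.
#' @param ref the reference partition.
#' @param ensemble a `bootstrap_ensemble`.
#' @param alpha significance level for transitions.
#' @param jaccard_threshold layer-robustness threshold.
#' @return List with `cores`, `transitions` (data frame older, younger,
#'   fraction, label), `layers`.
#' @export
significance_report <- function(net, ref, ensemble, alpha = 0.05,
                                jaccard_threshold = 0.70) {
  tl <- extract_timeline(ref, net)
  sc <- significant_cores(ref, ensemble)
  mods <- tl$modules
  trans <- NULL
  if (nrow(mods) > 1) {
    trans <- do.call(rbind, lapply(seq_len(nrow(mods) - 1), function(i) {
      cA <- sc$cores[[as.character(mods$module[i])]]
      cB <- sc$cores[[as.character(mods$module[i + 1])]]
      tt <- transition_type(cA, cB, ensemble, alpha)
      data.frame(older = mods$name[i], younger = mods$name[i + 1],
                 fraction = tt$fraction, label = tt$label,
                 stringsAsFactors = FALSE)
    }))
  }
  list(cores = sc, transitions = trans,
       layers = layer_robustness(ref, ensemble, jaccard_threshold))
}
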