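# Trait importance from clustering flow, and IndVal indicator analysis.
#
# The importance of a trait for a module is the probability that the random
# walker visits the trait (its flow volume).  Flows are standardized within
# each (module, layer) to percent flow, and the indicator value analysis
# asks which traits significantly mark groups of layers (e.g. the layer
# spans of the species-based modules), permuting layer-to-group labels.

#' Percent flow per trait per module per layer
#'
#' For every (module, layer) cell of a trait-network partition, normalizes
#' the visit rates of the trait state nodes to percentages (summing to 100
#' over the traits with nonzero flow in that cell).
#'
#' @param part a `mapeq_partition` of the trait network.
#' @param net the trait `multilayer_network` the partition was computed on.
#' @return Data frame (class `flow_table`) with columns `trait`, `module`,
#'   `layer`, `flow`, `percent_flow`.
#' @export
percent_flow <- function(part, net) {
  stopifnot(inherits(part, "mapeq_partition"))
  if (net$kind != "trait" || part$kind != "trait")
    stop("percent_flow: needs a partition of the trait network")
  if (nrow(part$states) != nrow(net$state_nodes))
    stop("percent_flow: partition does not match the network")
  st <- part$states[part$states$role == "trait", , drop = FALSE]
  if (!nrow(st)) stop("percent_flow: no trait state nodes in the partition")
  key <- paste(st$module, st$layer)
  tot <- tapply(st$flow, key, sum)
  out <- data.frame(trait = st$name, module = st$module, layer = st$layer,
                    flow = st$flow,
                    percent_flow = 100 * st$flow / as.numeric(tot[key]),
                    stringsAsFactors = FALSE)
  out <- out[out$flow > 0, , drop = FALSE]
  out <- out[order(out$module, out$layer, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("flow_table", "data.frame")
  out
}

# trait x layer matrix of per-layer percent flow (flow normalized over the
# traits of each layer, modules pooled)
flow_by_layer <- function(flows) {
  agg <- stats::aggregate(flow ~ trait + layer, data = flows, FUN = sum)
  traits <- sort(unique(agg$trait))
  layers <- sort(unique(agg$layer))
  m <- matrix(0, length(traits), length(layers),
              dimnames = list(traits, as.character(layers)))
  m[cbind(match(agg$trait, traits), match(agg$layer, layers))] <- agg$flow
  sweep(m, 2, colSums(m), "/") * 100
}

#' Indicator value (IndVal) analysis of trait flows
#'
#' For each trait and group of layers: specificity
#' `A = mean percent flow in the group / sum of the group means`, fidelity
#' `B = fraction of the group's layers where the trait's flow is > 0`,
#' `IndVal = sqrt(A * B)`, with a permutation p-value obtained by shuffling
#' the layer-to-group labels (`p = (1 + #{IndVal* >= IndVal}) / (1 +
#' n_perm)`).  The group-equalized (group-mean) form of specificity is used.
#'
#' @param flows a `flow_table` from [percent_flow()], or directly a numeric
#'   trait x layer matrix of per-layer flows.
#' @param groups named vector mapping layer (as character name or in order
#'   of the matrix columns) to group label; every layer with flow must be
#'   assigned to exactly one group, and there must be at least 2 groups.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return Data frame (class `indval_result`): `trait`, `group`, `A`, `B`,
#'   `indval`, `p`, `significant` (p < 0.05).
#' @export
indval <- function(flows, groups, n_perm = 999, seed = 1) {
  m <- if (inherits(flows, "flow_table")) flow_by_layer(flows) else as.matrix(flows)
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(m), names(groups))
    if (length(missing))
      stop("indval: layers without a group assignment: ",
           paste(missing, collapse = ", "))
    g <- factor(unname(groups[colnames(m)]))
  } else {
    if (length(groups) != ncol(m))
      stop("indval: groups must cover every layer")
    g <- factor(groups)
  }
  if (nlevels(g) < 2) stop("indval: need at least 2 groups")
  if (any(table(g) == 0)) stop("indval: group with zero layers")
  stat <- function(grp) {
    # rows: traits; A from group means, B from presence fractions
    means <- matrix(vapply(levels(g), function(lv)
      rowMeans(m[, grp == lv, drop = FALSE]), numeric(nrow(m))),
      nrow(m), nlevels(g), dimnames = list(rownames(m), levels(g)))
    pres <- matrix(vapply(levels(g), function(lv)
      rowMeans(m[, grp == lv, drop = FALSE] > 0), numeric(nrow(m))),
      nrow(m), nlevels(g), dimnames = list(rownames(m), levels(g)))
    tot <- rowSums(means)
    A <- means / ifelse(tot > 0, tot, 1)
    list(A = A, B = pres, iv = sqrt(A * pres))
  }
  obs <- stat(g)
  set.seed(seed)
  exceed <- matrix(0L, nrow(m), nlevels(g))
  for (k in seq_len(n_perm)) {
    ivp <- stat(sample(g))$iv
    exceed <- exceed + (ivp >= obs$iv - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    trait = rep(rownames(m), nlevels(g)),
    group = rep(levels(g), each = nrow(m)),
    A = as.vector(obs$A), B = as.vector(obs$B),
    indval = as.vector(obs$iv), p = as.vector(p),
    stringsAsFactors = FALSE)
  out$significant <- out$p < 0.05
  out <- out[order(out$group, -out$indval), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("indval_result", "data.frame")
  out
}

#' Layer groups mirroring the modules of another (e.g. species) timeline
#'
#' Builds the layer-to-group map for [indval()] from a timeline's per-layer
#' dominance: each layer is labeled with the module that dominates it.
#'
#' @param timeline a `module_timeline` (typically of the taxonomic network).
#' @return Named character vector (names = layers, values = module names).
#' @export
layer_groups <- function(timeline) {
  stats::setNames(timeline$layer_dominance$name,
                  as.character(timeline$layer_dominance$layer))
}
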