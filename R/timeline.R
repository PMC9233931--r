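# Reading temporal structure out of a partition: which module dominates
# each layer, and where dominance shifts (the biotic transitions).

#' Temporal timeline of a partition's modules
#'
#' Orders top-level modules by the age of their flow-weighted median layer
#' (oldest first, renamed `M1`, `M2`, ...), determines for every occupied
#' layer which module dominates it (largest within-layer flow share; ties go
#' to the older module), and reports a transition wherever dominance passes
#' from one module to another between consecutive occupied layers.
#'
#' @param part a `mapeq_partition`.
#' @param net the `multilayer_network` the partition was computed on (used
#'   for the time axis; `span_max` and `bin_width` convert layer indices to
#'   years BP).
#' @return An object of class `module_timeline`: `modules` (name, module id,
#'   layers occupied, flow, member counts), `layer_dominance` (layer, ruling
#'   module, flow share, age of the bin mid-point in years BP), and
#'   `transitions` (older module, younger module, boundary layer and years
#'   BP).
#' @export
extract_timeline <- function(part, net) {
  stopifnot(inherits(part, "mapeq_partition"))
  st <- part$states
  span <- if (!is.na(net$span_max)) net$span_max else net$n_layers * 500
  bw <- if (!is.na(net$bin_width)) net$bin_width else 500
  mods <- sort(unique(st$module))
  med_layer <- vapply(mods, function(m) {
    s <- st[st$module == m, ]
    weighted_median(s$layer, s$flow)
  }, numeric(1))
  # oldest (smallest median layer) first; ties by smaller module id
  ord <- order(med_layer, mods)
  mods <- mods[ord]
  rank_of <- stats::setNames(seq_along(mods), mods)
  modules <- do.call(rbind, lapply(seq_along(mods), function(k) {
    s <- st[st$module == mods[k], ]
    data.frame(name = paste0("M", k), module = mods[k],
               first_layer = min(s$layer), last_layer = max(s$layer),
               n_layers = length(unique(s$layer)),
               n_samples = sum(s$role == "sample"),
               n_features = length(unique(s$name[s$role != "sample"])),
               flow = sum(s$flow), stringsAsFactors = FALSE)
  }))
  # per-layer dominance by flow share
  layers <- sort(unique(st$layer))
  dom <- vapply(layers, function(ly) {
    s <- st[st$layer == ly, ]
    fl <- tapply(s$flow, s$module, sum)
    best <- max(fl)
    winners <- as.integer(names(fl)[fl >= best - 1e-15])
    # tie: the older module (smaller temporal rank) retains the layer
    winners[which.min(rank_of[as.character(winners)])]
  }, numeric(1))
  share <- vapply(seq_along(layers), function(i) {
    s <- st[st$layer == layers[i], ]
    sum(s$flow[s$module == dom[i]]) / sum(s$flow)
  }, numeric(1))
  layer_dominance <- data.frame(
    layer = layers, module = dom,
    name = paste0("M", rank_of[as.character(dom)]),
    flow_share = share,
    age_bp = span - (layers + 0.5) * bw)
  chg <- which(diff(dom) != 0)
  transitions <- if (length(chg)) data.frame(
    older = paste0("M", rank_of[as.character(dom[chg])]),
    younger = paste0("M", rank_of[as.character(dom[chg + 1])]),
    boundary_layer = layers[chg + 1],
    age_bp = span - layers[chg + 1] * bw,
    stringsAsFactors = FALSE
  ) else data.frame(older = character(0), younger = character(0),
                    boundary_layer = integer(0), age_bp = numeric(0))
  structure(list(modules = modules, layer_dominance = layer_dominance,
                 transitions = transitions, span_max = span, bin_width = bw),
            class = "module_timeline")
}

#' @export
print.module_timeline <- function(x, ...) {
  cat("module timeline (oldest first):\n")
  for (i in seq_len(nrow(x$modules))) {
    m <- x$modules[i, ]
    cat(sprintf("  %s: layers %d-%d, %d samples, %d taxa/traits, flow %.3f\n",
                m$name, m$first_layer, m$last_layer, m$n_samples,
                m$n_features, m$flow))
  }
  if (nrow(x$transitions)) {
    cat("transitions:\n")
    for (i in seq_len(nrow(x$transitions))) {
      tr <- x$transitions[i, ]
      cat(sprintf("  %s -> %s at %g BP (layer boundary %d)\n",
                  tr$older, tr$younger, tr$age_bp, tr$boundary_layer))
    }
  } else cat("no transitions\n")
  invisible(x)
}

#' Species (or trait) membership of a timeline module
#'
#' @param part a `mapeq_partition`.
#' @param timeline the matching `module_timeline`.
#' @param name module name (e.g. `"M1"`).
#' @return Character vector of member taxon/trait names.
#' @export
module_members <- function(part, timeline, name) {
  row <- timeline$modules[timeline$modules$name == name, ]
  if (!nrow(row)) stop("module_members: no module named ", name)
  st <- part$states
  unique(st$name[st$module == row$module & st$role != "sample"])
}
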