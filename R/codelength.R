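# The multilevel map equation.
#
# A partition of state nodes into (possibly nested) modules is scored by the
# per-step description length of the random walk: the root index codebook
# codes entries into top modules; each internal module's codebook codes
# entries into its submodules plus its own exit; each leaf module's codebook
# codes the visits to its members plus its exit.  Two conventions matter:
# (i) because the flow is stationary, every module's enter rate equals its
# exit rate, so all boundary terms use the module's exit flow; and (ii)
# state nodes of the same physical node (a taxon or trait occurring in
# several layers) assigned to the same leaf module share a codeword, so
# their visit rates are pooled before the entropy is taken.

# exit flow of a member set under the stationary edge flows
.boundary_flow <- function(flow_edges, member) {
  inside <- logical(max(flow_edges$from, flow_edges$to, member))
  inside[member] <- TRUE
  sum(flow_edges$flow[inside[flow_edges$from] & !inside[flow_edges$to]])
}

#' Map-equation codelength of a (multilevel) partition
#'
#' @param flow a `flow_model` (see [compute_flow()]).
#' @param partition either a `mapeq_partition`, or a vector over state nodes:
#'   integers for a two-level partition, or character module paths such as
#'   `"2"` / `"2:1"` for nested modules (states live at the leaves).
#' @return Codelength in bits.  For the one-module partition this is exactly
#'   the Shannon entropy of the physical-node visit rates (state nodes of
#'   the same physical node pooled, as they share a codeword).
#' @export
codelength <- function(flow, partition) {
  stopifnot(inherits(flow, "flow_model"))
  if (inherits(partition, "mapeq_partition")) partition <- partition$states$path
  paths <- as.character(partition)
  p <- flow$visit_rate
  if (length(paths) != length(p) || anyNA(paths))
    stop("codelength: partition must cover every state node")
  fe <- flow$flow_edges
  phys <- flow$states$node_id
  split_paths <- strsplit(paths, ":", fixed = TRUE)
  # every module (tree node) = a distinct proper prefix or full path
  prefixes <- unique(unlist(lapply(split_paths, function(s)
    vapply(seq_along(s), function(d) paste(s[seq_len(d)], collapse = ":"), ""))))
  q <- vapply(prefixes, function(pref) {
    member <- which(startsWith(paste0(paths, ":"), paste0(pref, ":")))
    .boundary_flow(fe, member)
  }, numeric(1))
  parent_of <- function(pref) {
    s <- strsplit(pref, ":", fixed = TRUE)[[1]]
    if (length(s) == 1) "" else paste(s[-length(s)], collapse = ":")
  }
  parents <- vapply(prefixes, parent_of, "")
  is_leaf_module <- prefixes %in% paths
  if (any(is_leaf_module & prefixes %in% parents))
    stop("codelength: a module cannot both hold states and have submodules")
  L <- 0
  # root index codebook
  top_q <- q[parents == ""]
  L <- L + plogp(sum(top_q)) - sum(plogp(top_q))
  # internal module codebooks
  for (i in which(!is_leaf_module)) {
    ch_q <- q[parents == prefixes[i]]
    L <- L + plogp(sum(ch_q) + q[i]) - sum(plogp(ch_q)) - plogp(q[i])
  }
  # leaf module codebooks (visit rates pooled per physical node)
  for (i in which(is_leaf_module)) {
    sel <- paths == prefixes[i]
    member_p <- as.numeric(tapply(p[sel], phys[sel], sum))
    L <- L + plogp(sum(member_p) + q[i]) - plogp(q[i]) - sum(plogp(member_p))
  }
  as.numeric(L)
}
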