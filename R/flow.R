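# Flow model of the relaxed multilayer random walk.
#
# A walker at state node (u, alpha) follows, with probability (1 - r), an
# intralayer edge of u in layer alpha (proportional to edge weight); with
# probability r it relaxes: it picks a layer beta uniformly among the layers
# within relax limit l of alpha in which physical node u has a state node
# (the current layer included) and then follows an intralayer edge of u in
# beta.  For a physical node present in a single reachable layer the relax
# step degenerates to the intralayer step.  Visit rates are the stationary
# distribution of this chain; for a network that is not ergodic as a whole,
# each connected component is solved separately and weighted by its share of
# state nodes.

#' Compute the flow model of a multilayer network
#'
#' @param net a `multilayer_network`.
#' @param r relax rate in \[0, 1).
#' @param l relax limit (layers in each temporal direction, >= 0).
#' @param tol L1 convergence tolerance of the stationary solve.
#' @return An object of class `flow_model`: `states` (state-node table),
#'   `visit_rate` (stationary probabilities, summing to 1), `transition`
#'   (sparse state-to-state matrix, rows summing to 1), `flow_edges`
#'   (data frame `from`, `to`, `flow` of stationary edge flows) and
#'   `n_components`.
#' @export
compute_flow <- function(net, r = 0.25, l = 2, tol = 1e-12) {
  stopifnot(inherits(net, "multilayer_network"), r >= 0, r < 1, l >= 0)
  sn <- net$state_nodes
  ns <- nrow(sn)
  skey <- paste(sn$node_id, sn$layer)
  sid_of <- stats::setNames(sn$state_id, skey)
  e <- net$edges
  a <- unname(sid_of[paste(e$from, e$layer)])
  b <- unname(sid_of[paste(e$to, e$layer)])
  if (any(table(c(a, b))[as.character(seq_len(ns))] %in% NA))
    stop("compute_flow: state node with no intralayer edges")
  # intralayer step: symmetric incidence, rows normalized by state strength
  str <- numeric(ns)
  add <- rowsum(c(e$weight, e$weight), c(a, b))
  str[as.integer(rownames(add))] <- add[, 1]
  if (any(str == 0)) stop("compute_flow: state node with no intralayer edges")
  W <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = c(e$weight / str[a], e$weight / str[b]),
                            dims = c(ns, ns))
  # relax mixing: C[s, s'] = weight put on taking the intralayer step from
  # the state s' of the same physical node (eligible layers, uniform)
  ci <- list(); cj <- list(); cx <- list()
  by_node <- split(seq_len(ns), sn$node_id)
  for (states in by_node) {
    lay <- sn$layer[states]
    for (k in seq_along(states)) {
      elig <- states[abs(lay - lay[k]) <= l]
      nelig <- length(elig)
      w <- rep(r / nelig, nelig)
      w[elig == states[k]] <- w[elig == states[k]] + (1 - r)
      ci[[length(ci) + 1]] <- rep(states[k], nelig)
      cj[[length(cj) + 1]] <- elig
      cx[[length(cx) + 1]] <- w
    }
  }
  C <- Matrix::sparseMatrix(i = unlist(ci), j = unlist(cj), x = unlist(cx),
                            dims = c(ns, ns))
  TT <- C %*% W
  # connected components on the undirected support (communication classes)
  comp <- .components(ns, rbind(cbind(c(a, b), c(b, a)),
                                cbind(unlist(ci), unlist(cj))))
  n_comp <- max(comp)
  p <- numeric(ns)
  for (cc in seq_len(n_comp)) {
    idx <- which(comp == cc)
    share <- length(idx) / ns
    if (length(idx) == 1) { p[idx] <- share; next }
    Tc <- TT[idx, idx, drop = FALSE]
    v <- rep(1 / length(idx), length(idx))
    for (it in seq_len(100000L)) {
      # lazy step: same stationary distribution, kills the bipartite period
      v_new <- 0.5 * v + 0.5 * as.vector(Matrix::crossprod(Tc, v))
      if (sum(abs(v_new - v)) < tol) { v <- v_new; break }
      v <- v_new
    }
    p[idx] <- v / sum(v) * share
  }
  fs <- Matrix::summary(TT)
  fe <- data.frame(from = fs$i, to = fs$j, flow = fs$x * p[fs$i])
  fe <- fe[fe$flow > 0, , drop = FALSE]
  rownames(fe) <- NULL
  states <- sn
  states$name <- net$nodes$name[match(states$node_id, net$nodes$id)]
  states$role <- net$nodes$role[match(states$node_id, net$nodes$id)]
  structure(list(states = states, visit_rate = p, transition = TT,
                 flow_edges = fe, n_components = n_comp, component = comp,
                 relax_rate = r, relax_limit = l),
            class = "flow_model")
}

# Connected components from an (undirected-support) edge matrix of node ids.
.components <- function(n, edge_pairs) {
  adj <- split(edge_pairs[, 2], factor(edge_pairs[, 1], levels = seq_len(n)))
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("flow model: %d state nodes, %d flow edges, %d component(s), r = %g, l = %d\n",
              length(x$visit_rate), nrow(x$flow_edges), x$n_components,
              x$relax_rate, x$relax_limit))
  invisible(x)
}
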