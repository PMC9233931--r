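# Search for the minimum-codelength partition.
#
# The search is the classic map-equation core loop: randomized greedy moves
# of nodes to the neighboring module with the best codelength gain, followed
# by aggregation of modules into super-nodes and repetition, which yields a
# flat (two-level) partition.  The multilevel solution is then assembled in
# both directions: index levels are added above the flat modules by
# clustering the module graph (coarse-tuning; the same greedy applies with
# module enter flows as node flows), and nested submodules are sought
# recursively inside each leaf module.  State nodes of the same physical
# node share a codeword within a module, which the move gains account for.
# Restarts differ in the seeded node-visit order; the best solution is kept
# and its codelength recomputed from scratch with codelength().

# Objective terms that moves can change, for one level of modules:
#   f = plogp(sum(Q) + extra_q) - 2 sum(plogp(Q)) + sum_m(plogp(P_m + Q_m))
#       - sum_{u,m}(plogp(PA[u, m]))
# Q[m]: module exit flow; P[m]: member visit rate; PA[u, m]: pooled visit
# rate of physical node u's members in m; extra_q: exit flow of the
# enclosing module (0 at the root).

# Pooled physical masses as a dense (compact phys id) x module matrix.
.pa_build <- function(pid, pw, mod, nmod) {
  upid <- sort(unique(unlist(pid)))
  cid <- lapply(pid, function(x) match(x, upid))
  PA <- matrix(0, length(upid), nmod)
  for (v in seq_along(cid)) {
    ix <- cbind(cid[[v]], mod[v])
    PA[ix] <- PA[ix] + pw[[v]]
  }
  list(PA = PA, cid = cid)
}

.module_exits <- function(nmod, mod, ef, et, ew, ext_out) {
  Q <- numeric(nmod)
  if (length(ef)) {
    cross <- mod[ef] != mod[et]
    if (any(cross)) {
      add <- rowsum(ew[cross], mod[ef][cross])
      Q[as.integer(rownames(add))] <- add[, 1]
    }
  }
  addx <- rowsum(ext_out, mod)
  Q[as.integer(rownames(addx))] <- Q[as.integer(rownames(addx))] + addx[, 1]
  Q
}

.ml_objective <- function(p, ef, et, ew, ext_out, extra_q, mod, pid, pw) {
  nmod <- max(mod)
  P <- numeric(nmod)
  addP <- rowsum(p, mod); P[as.integer(rownames(addP))] <- addP[, 1]
  Q <- .module_exits(nmod, mod, ef, et, ew, ext_out)
  pa <- rowsum(unlist(pw), paste0(rep(mod, lengths(pid)), "|", unlist(pid)))
  plogp(sum(Q) + extra_q) - 2 * sum(plogp(Q)) + sum(plogp(P + Q)) -
    sum(plogp(pa[, 1]))
}
# Greedy node moves until no move improves f, processed through an
# active-node queue (a node is re-examined when a neighbor moves).  pid/pw:
# per-node physical breakdown (ids and masses); a unique id per node
# disables pooling.
.ml_greedy <- function(p, ef, et, ew, ext_out, extra_q, mod, pid, pw) {
  n <- length(p)
  out_idx <- split(seq_along(ef), factor(ef, levels = seq_len(n)))
  in_idx <- split(seq_along(et), factor(et, levels = seq_len(n)))
  nbrs <- lapply(seq_len(n), function(v)
    unique(c(et[out_idx[[v]]], ef[in_idx[[v]]])))
  wout <- ext_out
  if (length(ef)) {
    add <- rowsum(ew, ef)
    wout[as.integer(rownames(add))] <- wout[as.integer(rownames(add))] + add[, 1]
  }
  nmod <- max(mod)
  P <- numeric(nmod)
  addP <- rowsum(p, mod); P[as.integer(rownames(addP))] <- addP[, 1]
  Q <- .module_exits(nmod, mod, ef, et, ew, ext_out)
  SQ <- sum(Q)
  pb <- .pa_build(pid, pw, mod, nmod)
  PA <- pb$PA; cid <- pb$cid
  eps <- 1e-10
  queue <- sample.int(n)
  in_queue <- rep(TRUE, n)
  head <- 1L
  # near-degenerate landscapes (e.g. fully symmetric unit weights) can emit
  # endless micro-gain cascades; cap the total work per call
  max_evals <- 60L * n + 1000L
  while (head <= length(queue) && head <= max_evals) {
    alpha <- queue[head]
    head <- head + 1L
    in_queue[alpha] <- FALSE
    a <- mod[alpha]
    oe <- out_idx[[alpha]]; ie <- in_idx[[alpha]]
    if (!length(oe) && !length(ie)) next
    fo_tab <- if (length(oe)) rowsum(ew[oe], mod[et[oe]]) else NULL
    fi_tab <- if (length(ie)) rowsum(ew[ie], mod[ef[ie]]) else NULL
    cand <- sort(unique(c(
      if (!is.null(fo_tab)) as.integer(rownames(fo_tab)),
      if (!is.null(fi_tab)) as.integer(rownames(fi_tab)))))
    lookup <- function(tab, m) {
      if (is.null(tab)) return(numeric(length(m)))
      v <- tab[match(as.character(m), rownames(tab)), 1]
      v[is.na(v)] <- 0
      v
    }
    fo_a <- lookup(fo_tab, a); fi_a <- lookup(fi_tab, a)
    dQa <- -(wout[alpha] - fo_a) + fi_a
    newQa <- Q[a] + dQa
    ids <- cid[[alpha]]; ws <- pw[[alpha]]
    pa_a_old <- PA[ids, a]
    d_remove <- -2 * (plogp(newQa) - plogp(Q[a])) +
      plogp(P[a] - p[alpha] + newQa) - plogp(P[a] + Q[a]) -
      sum(plogp(pa_a_old - ws)) + sum(plogp(pa_a_old))
    cand <- cand[cand != a]
    if (!length(cand)) next
    fo_b <- lookup(fo_tab, cand); fi_b <- lookup(fi_tab, cand)
    dQb <- (wout[alpha] - fo_b) - fi_b
    newQb <- Q[cand] + dQb
    pa_b_all <- PA[ids, cand, drop = FALSE]
    d_pa_b <- colSums(plogp(pa_b_all)) - colSums(plogp(pa_b_all + ws))
    dL <- plogp(SQ + dQa + dQb + extra_q) - plogp(SQ + extra_q) + d_remove -
      2 * (plogp(newQb) - plogp(Q[cand])) +
      plogp(P[cand] + p[alpha] + newQb) - plogp(P[cand] + Q[cand]) + d_pa_b
    j <- which.min(dL)             # cand sorted: ties go to the lowest module
    if (dL[j] < -eps) {
      b <- cand[j]
      Q[a] <- newQa
      Q[b] <- Q[b] + dQb[j]
      SQ <- SQ + dQa + dQb[j]
      P[a] <- P[a] - p[alpha]
      P[b] <- P[b] + p[alpha]
      PA[ids, a] <- PA[ids, a] - ws
      PA[ids, b] <- PA[ids, b] + ws
      mod[alpha] <- b
      wake <- c(alpha, nbrs[[alpha]])
      wake <- wake[!in_queue[wake]]
      if (length(wake)) {
        queue <- c(queue, wake)
        in_queue[wake] <- TRUE
      }
    }
  }
  mod
}

# Greedy moves + module aggregation, repeated to convergence.  Returns the
# leaf-level module assignment (contiguous integers).
.ml_two_level <- function(p, ef, et, ew, ext_out, extra_q, pid, pw) {
  n <- length(p)
  leaf <- seq_len(n)
  p_l <- p; ef_l <- ef; et_l <- et; ew_l <- ew; ext_l <- ext_out
  pid_l <- pid; pw_l <- pw
  repeat {
    mod <- .ml_greedy(p_l, ef_l, et_l, ew_l, ext_l, extra_q,
                      seq_along(p_l), pid_l, pw_l)
    mod <- match(mod, sort(unique(mod)))
    if (max(mod) == length(p_l)) break      # nothing merged: converged
    leaf <- mod[leaf]
    p_l <- as.vector(rowsum(p_l, mod))
    ext_l <- as.vector(rowsum(ext_l, mod))
    groups <- split(seq_along(pid_l), mod)
    pid_new <- vector("list", length(groups))
    pw_new <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      ids <- unlist(pid_l[groups[[gi]]])
      ws <- unlist(pw_l[groups[[gi]]])
      agg <- rowsum(ws, ids)
      pid_new[[gi]] <- as.integer(rownames(agg))
      pw_new[[gi]] <- agg[, 1]
    }
    pid_l <- pid_new; pw_l <- pw_new
    if (length(ef_l)) {
      mf <- mod[ef_l]; mt <- mod[et_l]
      keep <- mf != mt
      if (any(keep)) {
        agg <- rowsum(ew_l[keep], paste(mf[keep], mt[keep]))
        key <- do.call(rbind, strsplit(rownames(agg), " "))
        ef_l <- as.integer(key[, 1]); et_l <- as.integer(key[, 2]); ew_l <- agg[, 1]
      } else {
        ef_l <- integer(0); et_l <- integer(0); ew_l <- numeric(0)
      }
    }
    if (!length(ef_l) || length(p_l) == 1) break
  }
  leaf
}

# Coarse-tune: add index levels above a flat partition by clustering the
# module graph (node flow = module exit flow).  Returns a list of
# assignment vectors, bottom-most first (possibly empty).
.ml_superlevels <- function(mod, ef, et, ew, ext_out) {
  levels <- list()
  K <- max(mod)
  q <- .module_exits(K, mod, ef, et, ew, ext_out)
  agg_edges <- function(assign, f, t, w) {
    gf <- assign[f]; gt <- assign[t]
    keep <- gf != gt
    if (!any(keep)) return(list(f = integer(0), t = integer(0), w = numeric(0)))
    agg <- rowsum(w[keep], paste(gf[keep], gt[keep]))
    key <- do.call(rbind, strsplit(rownames(agg), " "))
    list(f = as.integer(key[, 1]), t = as.integer(key[, 2]), w = agg[, 1])
  }
  e <- agg_edges(mod, ef, et, ew)
  for (round in 1:10) {
    if (K < 3 || sum(q) <= 0 || !length(e$f)) break
    pid1 <- as.list(seq_len(K))             # unique ids: no physical pooling
    pw1 <- as.list(q)
    grp <- .ml_two_level(q, e$f, e$t, e$w, numeric(K), 0, pid1, pw1)
    grp <- match(grp, sort(unique(grp)))
    if (max(grp) < 2 || max(grp) == K) break
    f_grouped <- .ml_objective(q, e$f, e$t, e$w, numeric(K), 0, grp, pid1, pw1)
    f_flat <- plogp(sum(q)) - sum(plogp(q))
    if (f_grouped >= f_flat - 1e-12) break  # strict improvement required
    levels[[length(levels) + 1]] <- grp
    # next round clusters the group graph
    qnew <- .module_exits(max(grp), grp, e$f, e$t, e$w, numeric(K))
    e <- agg_edges(grp, e$f, e$t, e$w)
    q <- qnew
    K <- max(grp)
  }
  levels
}

# Chains of tree labels (top -> flat module), with single-child wrapper
# modules contracted away so the hierarchy may be unbalanced.
.ml_chains <- function(K, sup) {
  nl <- length(sup)
  cc <- lapply(sup, tabulate)               # children counts per group
  vapply(seq_len(K), function(m) {
    ids <- integer(nl)
    cur <- m
    for (k in seq_len(nl)) { cur <- sup[[k]][cur]; ids[k] <- cur }
    labels <- paste0("s", nl, ".", ids[nl]) # topmost level always kept
    if (nl > 1) {
      for (k in seq(nl - 1, 1)) {
        if (cc[[k + 1]][ids[k + 1]] > 1)
          labels <- c(labels, paste0("s", k, ".", ids[k]))
      }
    }
    if (cc[[1]][ids[1]] > 1) labels <- c(labels, paste0("f", m))
    paste(labels, collapse = ":")
  }, "")
}

# Contract internal tree nodes that have a single child (a wrapper module
# and its only child are the same node set; the wrapper's label survives).
.contract_paths <- function(paths) {
  repeat {
    sp <- strsplit(paths, ":", fixed = TRUE)
    ch <- list()
    for (s in sp) {
      if (length(s) < 2) next
      for (d in 1:(length(s) - 1)) {
        key <- paste(s[1:d], collapse = ":")
        ch[[key]] <- union(ch[[key]], s[d + 1])
      }
    }
    single <- names(ch)[lengths(ch) == 1]
    if (!length(single)) break
    key <- single[1]
    pref <- paste0(key, ":", ch[[key]][1])
    npref <- nchar(pref)
    hit <- startsWith(paths, pref) &
      (nchar(paths) == npref | substr(paths, npref + 1, npref + 1) == ":")
    paths[hit] <- paste0(key, substring(paths[hit], npref + 1))
  }
  paths
}

# Renumber path components as integers unique within each parent.
.canonical_paths <- function(paths) {
  sp <- strsplit(paths, ":", fixed = TRUE)
  maxd <- max(lengths(sp))
  res <- rep("", length(sp))
  for (d in seq_len(maxd)) {
    has <- lengths(sp) >= d
    comp <- vapply(sp[has], `[`, "", d)
    parent <- res[has]
    newid <- integer(length(comp))
    for (pr in unique(parent)) {
      sel <- parent == pr
      newid[sel] <- match(comp[sel], unique(comp[sel]))
    }
    res[has] <- ifelse(parent == "", as.character(newid),
                       paste(parent, newid, sep = ":"))
  }
  res
}

# Recursive submodule search inside one leaf module (fine-tune).
.ml_split <- function(members, p, ef, et, ew, wout_leaf, phys) {
  if (length(members) < 3) return(NULL)
  pos <- match(seq_along(p), members)       # original id -> local id (NA outside)
  keep <- !is.na(pos[ef]) & !is.na(pos[et])
  lef <- pos[ef[keep]]; let <- pos[et[keep]]; lew <- ew[keep]
  p_sub <- p[members]
  int_out <- numeric(length(members))
  if (length(lef)) {
    add <- rowsum(lew, lef)
    int_out[as.integer(rownames(add))] <- add[, 1]
  }
  ext_sub <- wout_leaf[members] - int_out
  ext_sub[ext_sub < 0] <- 0                 # guard against roundoff
  q_par <- sum(ext_sub)
  pid <- as.list(phys[members]); pw <- as.list(p_sub)
  sub <- .ml_two_level(p_sub, lef, let, lew, ext_sub, q_par, pid, pw)
  nsub <- max(sub)
  if (nsub < 2) return(NULL)
  f_split <- .ml_objective(p_sub, lef, let, lew, ext_sub, q_par, sub, pid, pw)
  pa_one <- rowsum(p_sub, phys[members])
  f_nosplit <- plogp(sum(p_sub) + q_par) - sum(plogp(pa_one[, 1]))
  if (f_split >= f_nosplit - 1e-12) return(NULL)
  split(members, sub)
}

#' Optimize the map-equation partition of a multilayer network
#'
#' Runs `n_restarts` randomized restarts of the greedy search.  Each restart
#' finds a flat partition by node moves and module aggregation, then (when
#' `multilevel = TRUE`) adds index levels above it by clustering the module
#' graph and searches for nested submodules inside each module.  The lowest-
#' codelength solution over the restarts is returned; deterministic for a
#' fixed seed, and the reported codelength is recomputed from scratch with
#' [codelength()].
#'
#' @param net a `multilayer_network`.
#' @param r relax rate (default 0.25).
#' @param l relax limit in layers (default 2).
#' @param n_restarts number of randomized restarts (use several hundred for
#'   production solutions; small values keep experiments fast).
#' @param seed integer seed.
#' @param multilevel assemble a multilevel solution?  `FALSE` returns the
#'   best flat (two-level) partition.
#' @param flow optionally a precomputed `flow_model` for `net` (must match
#'   `r` and `l`).
#' @return An object of class `mapeq_partition`: `states` (state-node table
#'   with `module` = top-level module, `path` and `flow` columns),
#'   `codelength` (bits), `module_flow`, `n_restarts`, `seed`.
#' @export
mapeq_optimize <- function(net, r = 0.25, l = 2, n_restarts = 20, seed = 1,
                           multilevel = TRUE, flow = NULL) {
  if (is.null(flow)) flow <- compute_flow(net, r, l)
  p <- flow$visit_rate
  fe <- flow$flow_edges
  ef <- fe$from; et <- fe$to; ew <- fe$flow
  n <- length(p)
  phys <- flow$states$node_id
  pid <- as.list(phys); pw <- as.list(p)
  wout_leaf <- numeric(n)
  if (length(ef)) {
    add <- rowsum(ew, ef)
    wout_leaf[as.integer(rownames(add))] <- add[, 1]
  }
  set.seed(seed)
  best_paths <- NULL
  best_L <- Inf
  for (rep in seq_len(n_restarts)) {
    flat <- .ml_two_level(p, ef, et, ew, numeric(n), 0, pid, pw)
    flat <- match(flat, sort(unique(flat)))
    paths <- as.character(flat)
    if (multilevel) {
      # index levels above the flat modules
      sup <- .ml_superlevels(flat, ef, et, ew, numeric(n))
      if (length(sup)) {
        chain <- .ml_chains(max(flat), sup)
        paths <- chain[flat]
      }
      # every connected component is clustered independently and forms its
      # own top-level branch (zero flow crosses components, so this wrapper
      # level is codelength-neutral)
      if (flow$n_components > 1) {
        comp_of_state <- flow$component
        paths <- paste0("c", comp_of_state, ":", paths)
        paths <- .contract_paths(paths)
      }
      # nested submodules below each leaf module
      stack <- split(seq_len(n), paths)
      prefix <- names(stack)
      while (length(stack)) {
        members <- stack[[1]]
        pref <- prefix[[1]]
        stack <- stack[-1]; prefix <- prefix[-1]
        groups <- .ml_split(members, p, ef, et, ew, wout_leaf, phys)
        if (!is.null(groups)) {
          for (g in seq_along(groups)) {
            gp <- paste0(pref, ":", g)
            paths[groups[[g]]] <- gp
            stack[[length(stack) + 1]] <- groups[[g]]
            prefix[[length(prefix) + 1]] <- gp
          }
        }
      }
    }
    paths <- .canonical_paths(paths)
    L <- codelength(flow, paths)
    if (L < best_L - 1e-12) {
      best_L <- L
      best_paths <- paths
    }
  }
  states <- flow$states
  states$module <- as.integer(vapply(strsplit(best_paths, ":", fixed = TRUE),
                                     `[`, "", 1))
  states$path <- best_paths
  states$flow <- p
  module_flow <- tapply(p, states$module, sum)
  structure(list(states = states, codelength = best_L,
                 module_flow = module_flow, n_restarts = n_restarts,
                 seed = seed, relax_rate = flow$relax_rate,
                 relax_limit = flow$relax_limit, kind = net$kind,
                 n_layers = net$n_layers, span_max = net$span_max,
                 bin_width = net$bin_width),
            class = "mapeq_partition")
}

#' @export
print.mapeq_partition <- function(x, ...) {
  cat(sprintf("map-equation partition: %d state nodes in %d top module(s), codelength %.6f bits (N = %d restarts, seed %d)\n",
              nrow(x$states), length(unique(x$states$module)), x$codelength,
              x$n_restarts, x$seed))
  invisible(x)
}

#' Write a partition as a flat TSV table
#'
#' Columns: state node id, layer, physical node, role, top module, module
#' path, flow volume.
#'
#' @param part a `mapeq_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  df <- part$states[, c("state_id", "layer", "name", "role", "module", "path", "flow")]
  write_tsv(df, path)
}
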