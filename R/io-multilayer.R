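# Plain-text serialization of multilayer networks.
#
# The on-disk dialect follows the *Vertices / *Intra convention of the
# multilayer map-equation ecosystem:
#
#   # key value            header comments carrying kind, nlayers, relax
#   # role <id> <role>       parameters and node roles
#   *Vertices <n>
#   <id> "<name>"
#   *Intra
#   <layer> <node> <node> <weight>
#
# Layer ids are 1-based in the file (0-based internally); weights are
# written at full double precision so that read(write(net)) is an identity.

#' Write a multilayer network to a plain-text file
#'
#' @param net a `multilayer_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multilayer <- function(net, path) {
  validate_multilayer(net)
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(c("# fossilnet multilayer network",
               paste("# kind", net$kind),
               paste("# nlayers", net$n_layers),
               paste("# relaxrate", num(net$relax_rate)),
               paste("# relaxlimit", net$relax_limit),
               paste("# spanmax", num(net$span_max)),
               paste("# binwidth", num(net$bin_width)),
               paste("# role", net$nodes$id, net$nodes$role)), con)
  writeLines(sprintf("*Vertices %d", nrow(net$nodes)), con)
  writeLines(sprintf("%d \"%s\"", net$nodes$id, net$nodes$name), con)
  writeLines("*Intra", con)
  writeLines(sprintf("%d %d %d %s", net$edges$layer + 1L, net$edges$from,
                     net$edges$to, num(net$edges$weight)), con)
  invisible(path)
}

#' Read a multilayer network from a plain-text file
#'
#' Parses the dialect written by [write_multilayer()].  Malformed section
#' headers, unparsable records and dangling node references are reported
#' with their line number; structural invariants (bipartiteness, positive
#' weights) are re-checked after parsing.
#'
#' @param path input file path.
#' @return A `multilayer_network`.
#' @export
read_multilayer <- function(path) {
  lines <- readLines(path)
  meta <- list(kind = "taxonomic", nlayers = NA, relaxrate = NA,
               relaxlimit = NA, spanmax = NA, binwidth = NA)
  roles <- character(0)
  section <- ""
  vertices <- list(); edges <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      parts <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] %in% names(meta))
        meta[[parts[1]]] <- parts[2]
      if (length(parts) == 3 && parts[1] == "role")
        roles[parts[2]] <- parts[3]
      next
    }
    if (startsWith(ln, "*")) {
      word <- tolower(strsplit(ln, "\\s+")[[1]][1])
      if (word == "*vertices") section <- "vertices"
      else if (word == "*intra") section <- "intra"
      else stop("read_multilayer: unknown section header '", ln, "' at line ", i)
      next
    }
    if (section == "vertices") {
      m <- regmatches(ln, regexec("^(\\d+)\\s+\"(.*)\"\\s*$", ln))[[1]]
      if (length(m) != 3)
        stop("read_multilayer: malformed vertex record at line ", i)
      vertices[[length(vertices) + 1]] <- data.frame(
        id = as.integer(m[2]), name = m[3], stringsAsFactors = FALSE)
    } else if (section == "intra") {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 4 || anyNA(suppressWarnings(as.numeric(parts))))
        stop("read_multilayer: malformed intra-layer edge record at line ", i)
      edges[[length(edges) + 1]] <- data.frame(
        layer = as.integer(parts[1]) - 1L, from = as.integer(parts[2]),
        to = as.integer(parts[3]), weight = as.numeric(parts[4]))
    } else {
      stop("read_multilayer: record outside any section at line ", i)
    }
  }
  if (!length(vertices)) stop("read_multilayer: no *Vertices section")
  nodes <- do.call(rbind, vertices)
  nodes$role <- unname(roles[as.character(nodes$id)])
  if (anyNA(nodes$role))
    stop("read_multilayer: missing '# role <id> <role>' entry for some node")
  e <- if (length(edges)) do.call(rbind, edges) else
    stop("read_multilayer: no intra-layer edges")
  bad <- !(e$from %in% nodes$id) | !(e$to %in% nodes$id)
  if (any(bad))
    stop("read_multilayer: edge references unknown node id (first at intra record ",
         which(bad)[1], ")")
  # orient edges sample -> feature regardless of file order
  from_role <- nodes$role[match(e$from, nodes$id)]
  to_role <- nodes$role[match(e$to, nodes$id)]
  flip <- from_role != "sample" & to_role == "sample"
  tmp <- e$from[flip]; e$from[flip] <- e$to[flip]; e$to[flip] <- tmp
  e <- e[order(e$layer, e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  n_layers <- if (!is.na(meta$nlayers)) as.integer(meta$nlayers) else max(e$layer) + 1L
  # rebuild state nodes from edges (samples: single state; features: per layer)
  sample_ids <- nodes$id[nodes$role == "sample"]
  s_states <- unique(e[e$from %in% sample_ids, c("from", "to", "layer")])
  s_layer <- unique(e[, c("from", "layer")])
  if (anyDuplicated(s_layer$from))
    stop("read_multilayer: a sample node appears in more than one layer")
  f_states <- unique(e[, c("to", "layer")])
  sn <- rbind(data.frame(node_id = s_layer$from, layer = s_layer$layer),
              data.frame(node_id = f_states$to, layer = f_states$layer))
  sn <- sn[order(sn$node_id, sn$layer), , drop = FALSE]
  sn$state_id <- seq_len(nrow(sn))
  rownames(sn) <- NULL
  new_multilayer(nodes, sn[, c("state_id", "node_id", "layer")], e, n_layers,
                 kind = meta$kind,
                 relax_rate = suppressWarnings(as.numeric(meta$relaxrate)),
                 relax_limit = suppressWarnings(as.integer(meta$relaxlimit)),
                 span_max = suppressWarnings(as.numeric(meta$spanmax)),
                 bin_width = suppressWarnings(as.numeric(meta$binwidth)))
}
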