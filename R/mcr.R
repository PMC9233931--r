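# Mutual climatic range (MCR) palaeotemperature reconstruction.
#
# Each species' thermal envelope is a tolerated region of (TMin, TMax)
# climate space - here an axis-aligned rectangle (tmin_lo..tmin_hi x
# tmax_lo..tmax_hi), with an engine that also accepts arbitrary boolean
# masks on the grid.  The reconstruction rasterizes the envelopes of the
# module's climate-indicator, non-herbivorous species onto a lattice,
# counts overlapping species per lattice point, and reports the region of
# greatest overlap as the most probable thermal range, plus the percentage
# of species covering that region.

.usable_envelopes <- function(species, envelopes, exclude_herbivores = TRUE) {
  env <- envelopes[envelopes$taxon %in% species, , drop = FALSE]
  if (!is.null(env$climate_indicator))
    env <- env[as.logical(env$climate_indicator), , drop = FALSE]
  if (exclude_herbivores && !is.null(env$herbivore))
    env <- env[!as.logical(env$herbivore), , drop = FALSE]
  if (any(env$tmin_lo > env$tmin_hi) || any(env$tmax_lo > env$tmax_hi))
    stop("mcr: degenerate envelope (lo > hi) for ",
         paste(env$taxon[env$tmin_lo > env$tmin_hi | env$tmax_lo > env$tmax_hi],
               collapse = ", "))
  env
}

#' MCR reconstruction for a set of species
#'
#' @param species character vector of taxon names (e.g. the species members
#'   of one module).
#' @param envelopes data frame with columns `taxon`, `tmin_lo`, `tmin_hi`,
#'   `tmax_lo`, `tmax_hi` and optionally `herbivore`, `climate_indicator`.
#' @param grid_step lattice resolution in degrees C (default 0.5).
#' @param exclude_herbivores drop herbivorous species (their ranges may track
#'   host plants rather than climate)?  Default `TRUE`.
#' @param masks optional named list of logical matrices (one per taxon, on
#'   the common lattice) overriding the rectangle rasterization.
#' @return An object of class `mcr_result`: `tmin_range`, `tmax_range`
#'   (degrees C, extent of the maximum-overlap region), `percent_overlap`
#'   (100 x species covering that region / species used), `n_species_used`,
#'   and the lattice axes.
#' @export
mcr_reconstruct <- function(species, envelopes, grid_step = 0.5,
                            exclude_herbivores = TRUE, masks = NULL) {
  if (grid_step <= 0) stop("mcr_reconstruct: grid_step must be positive")
  env <- .usable_envelopes(species, envelopes, exclude_herbivores)
  if (!nrow(env))
    stop("mcr_reconstruct: no usable (climate-indicator, non-herbivore) species")
  # lattice points at whole multiples of grid_step covering all envelopes,
  # so the result is invariant to translating the grid by whole steps
  xax <- seq(floor(min(env$tmin_lo) / grid_step),
             ceiling(max(env$tmin_hi) / grid_step)) * grid_step
  yax <- seq(floor(min(env$tmax_lo) / grid_step),
             ceiling(max(env$tmax_hi) / grid_step)) * grid_step
  count <- matrix(0L, length(xax), length(yax))
  eps <- 1e-9
  for (i in seq_len(nrow(env))) {
    if (!is.null(masks) && env$taxon[i] %in% names(masks)) {
      count <- count + (masks[[env$taxon[i]]] * 1L)
    } else {
      inx <- xax >= env$tmin_lo[i] - eps & xax <= env$tmin_hi[i] + eps
      iny <- yax >= env$tmax_lo[i] - eps & yax <= env$tmax_hi[i] + eps
      count[inx, iny] <- count[inx, iny] + 1L
    }
  }
  best <- max(count)
  hit <- which(count == best, arr.ind = TRUE)
  structure(list(
    tmin_range = c(min(xax[hit[, 1]]), max(xax[hit[, 1]])),
    tmax_range = c(min(yax[hit[, 2]]), max(yax[hit[, 2]])),
    percent_overlap = 100 * best / nrow(env),
    n_species_used = nrow(env),
    max_count = best,
    grid_step = grid_step,
    tmin_axis = xax, tmax_axis = yax),
    class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf("MCR: TMin %.1f..%.1f C, TMax %.1f..%.1f C, overlap %.0f%% of %d species\n",
              x$tmin_range[1], x$tmin_range[2], x$tmax_range[1],
              x$tmax_range[2], x$percent_overlap, x$n_species_used))
  invisible(x)
}

#' Jackknifed MCR reconstruction
#'
#' Reruns [mcr_reconstruct()] once per leave-one-out subset of the usable
#' species and reports, for each range endpoint, the extremes across the
#' reruns - the error bars of the reconstruction.
#'
#' @inheritParams mcr_reconstruct
#' @return List with `full` (the all-species `mcr_result`), `jackknife_tmin`
#'   and `jackknife_tmax` (`c(lo_min, hi_max)` across reruns), and `runs`
#'   (data frame of per-rerun ranges, one row per left-out species).
#' @export
jackknife_mcr <- function(species, envelopes, grid_step = 0.5,
                          exclude_herbivores = TRUE) {
  env <- .usable_envelopes(species, envelopes, exclude_herbivores)
  if (nrow(env) < 2)
    stop("jackknife_mcr: need at least 2 usable species")
  full <- mcr_reconstruct(env$taxon, envelopes, grid_step, exclude_herbivores)
  runs <- do.call(rbind, lapply(seq_len(nrow(env)), function(i) {
    r <- mcr_reconstruct(env$taxon[-i], envelopes, grid_step, exclude_herbivores)
    data.frame(left_out = env$taxon[i],
               tmin_lo = r$tmin_range[1], tmin_hi = r$tmin_range[2],
               tmax_lo = r$tmax_range[1], tmax_hi = r$tmax_range[2],
               percent_overlap = r$percent_overlap,
               stringsAsFactors = FALSE)
  }))
  list(full = full,
       jackknife_tmin = c(min(runs$tmin_lo, full$tmin_range[1]),
                          max(runs$tmin_hi, full$tmin_range[2])),
       jackknife_tmax = c(min(runs$tmax_lo, full$tmax_range[1]),
                          max(runs$tmax_hi, full$tmax_range[2])),
       runs = runs)
}

#' MCR reconstruction for every module of a taxonomic partition
#'
#' @param part a `mapeq_partition` of the taxonomic network.
#' @param timeline the matching `module_timeline`.
#' @param envelopes envelope table (see [mcr_reconstruct()]).
#' @param grid_step lattice resolution.
#' @param jackknife also run the leave-one-out routine?
#' @return Data frame with one row per module (name, ranges, percent
#'   overlap, species counts, jackknife extremes).
#' @export
mcr_by_module <- function(part, timeline, envelopes, grid_step = 0.5,
                          jackknife = TRUE) {
  do.call(rbind, lapply(timeline$modules$name, function(nm) {
    sp <- module_members(part, timeline, nm)
    r <- mcr_reconstruct(sp, envelopes, grid_step)
    row <- data.frame(module = nm,
                      tmin_lo = r$tmin_range[1], tmin_hi = r$tmin_range[2],
                      tmax_lo = r$tmax_range[1], tmax_hi = r$tmax_range[2],
                      percent_overlap = r$percent_overlap,
                      n_species_used = r$n_species_used,
                      stringsAsFactors = FALSE)
    if (jackknife && r$n_species_used >= 2) {
      jk <- jackknife_mcr(sp, envelopes, grid_step)
      row$jk_tmin_lo <- jk$jackknife_tmin[1]; row$jk_tmin_hi <- jk$jackknife_tmin[2]
      row$jk_tmax_lo <- jk$jackknife_tmax[1]; row$jk_tmax_hi <- jk$jackknife_tmax[2]
    } else {
      row$jk_tmin_lo <- row$jk_tmin_hi <- row$jk_tmax_lo <- row$jk_tmax_hi <- NA_real_
    }
    row
  }))
}
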