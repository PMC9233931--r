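# Filtering of dated samples and construction of the analysis matrices.
#
# Dated occurrence records are reduced to a temporally reliable core before
# network assembly: samples whose age mid-point is older than 16,000 BP are
# dropped (they would create disconnected nodes and sparse layers at the old
# end of the sequence), samples whose age range exceeds 2000 years are
# dropped (large dating uncertainty would smear temporal structure), and
# only occurrences identified to species level are kept.  Surviving samples
# are binned into ordered 500-year layers.

#' Derive age mid-point and range for dated samples
#'
#' @param samples data frame with `age_max` and `age_min` columns (years BP).
#' @return The data frame with `midpoint` and `age_range` columns added.
#' @export
annotate_ages <- function(samples) {
  bad <- samples$age_min > samples$age_max
  if (any(bad))
    stop("annotate_ages: age_min > age_max for sample(s) ",
         paste(samples$sample_id[bad], collapse = ", "))
  if (any(samples$age_min < 0))
    stop("annotate_ages: negative age_min for sample(s) ",
         paste(samples$sample_id[samples$age_min < 0], collapse = ", "))
  samples$midpoint <- (samples$age_max + samples$age_min) / 2
  samples$age_range <- samples$age_max - samples$age_min
  samples
}

#' Filter dated samples by age mid-point and age range
#'
#' Keeps samples whose temporal mid-point (middle of the dated interval) is
#' at most `max_midpoint` years BP and whose age range (interval width) is at
#' most `max_range` years.  Exclusion counts per rule are recorded in the
#' `"filter_log"` attribute of the result.
#'
#' @param samples data frame of dated samples (`sample_id`, `age_max`,
#'   `age_min`, ...).
#' @param max_midpoint oldest accepted mid-point (years BP).
#' @param max_range widest accepted age range (years).
#' @return The retained samples, annotated with `midpoint` and `age_range`.
#' @export
filter_samples <- function(samples, max_midpoint = 16000, max_range = 2000) {
  samples <- annotate_ages(samples)
  too_old <- samples$midpoint > max_midpoint
  too_wide <- samples$age_range > max_range
  keep <- !too_old & !too_wide
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- list(
    n_input = nrow(samples),
    n_excluded_midpoint = sum(too_old),
    n_excluded_range = sum(too_wide & !too_old),
    excluded = data.frame(
      sample_id = samples$sample_id[!keep],
      rule = ifelse(too_old[!keep], "midpoint > max_midpoint", "age_range > max_range"),
      stringsAsFactors = FALSE)
  )
  out
}

#' Keep only occurrences identified to species level
#'
#' Builds the binary sample x species presence matrix from long-form
#' occurrence records carrying a taxonomic `rank` tag.  Records above species
#' level are dropped, and samples left with no species-level occurrence are
#' removed (and logged).
#'
#' @param occurrences data frame with `sample_id`, `taxon`, `rank` columns;
#'   accepted ranks are `"species"`, `"genus"`, `"family"`.
#' @param samples optional data frame of (already filtered) samples; if
#'   given, occurrences of unknown samples are dropped and the matrix rows
#'   follow `samples$sample_id`.
#' @return A binary matrix (samples x species) with a `"filter_log"`
#'   attribute listing dropped occurrence counts and emptied samples.
#' @export
filter_species_level <- function(occurrences, samples = NULL) {
  ranks <- unique(occurrences$rank)
  unknown <- setdiff(ranks, c("species", "genus", "family"))
  if (length(unknown))
    stop("filter_species_level: unknown rank tag(s): ",
         paste(unknown, collapse = ", "), " (first offending record: taxon '",
         occurrences$taxon[occurrences$rank %in% unknown][1], "')")
  if (!is.null(samples))
    occurrences <- occurrences[occurrences$sample_id %in% samples$sample_id, , drop = FALSE]
  n_dropped <- sum(occurrences$rank != "species")
  occ <- occurrences[occurrences$rank == "species", , drop = FALSE]
  sample_ids <- if (!is.null(samples)) samples$sample_id else unique(occurrences$sample_id)
  taxa <- sort(unique(occ$taxon))
  mat <- matrix(0L, length(sample_ids), length(taxa),
                dimnames = list(sample_ids, taxa))
  if (nrow(occ))
    mat[cbind(match(occ$sample_id, sample_ids), match(occ$taxon, taxa))] <- 1L
  empty <- rowSums(mat) == 0
  out <- mat[!empty, , drop = FALSE]
  attr(out, "filter_log") <- list(
    n_occurrences_dropped = n_dropped,
    emptied_samples = sample_ids[empty])
  out
}

#' Assign filtered samples to ordered time layers
#'
#' Bins sample age mid-points into `span_max / bin_width` contiguous layers,
#' ordered from oldest (layer 0) to youngest.  Bins are half-open on the old
#' side: a mid-point exactly on a bin edge falls in the younger layer, and a
#' mid-point of exactly 0 BP is clamped into the youngest layer.
#'
#' @param samples data frame with a `midpoint` column (see
#'   [filter_samples()]).
#' @param span_max oldest accepted age (years BP); must be a multiple of
#'   `bin_width`.
#' @param bin_width layer width in years.
#' @return The samples with an integer `layer` column (0-based, 0 = oldest).
#' @export
assign_layers <- function(samples, span_max = 16000, bin_width = 500) {
  if (bin_width <= 0) stop("assign_layers: bin_width must be positive")
  if (span_max %% bin_width != 0)
    stop("assign_layers: bin_width must divide span_max")
  if (is.null(samples$midpoint)) samples <- annotate_ages(samples)
  if (any(samples$midpoint > span_max))
    stop("assign_layers: sample mid-point older than span_max; filter first")
  n_layers <- span_max %/% bin_width
  layer <- floor((span_max - samples$midpoint) / bin_width)
  layer[layer >= n_layers] <- n_layers - 1L   # midpoint exactly 0 BP
  samples$layer <- as.integer(layer)
  attr(samples, "n_layers") <- as.integer(n_layers)
  attr(samples, "span_max") <- span_max
  attr(samples, "bin_width") <- bin_width
  samples
}

#' Relax limit implied by the accepted age range
#'
#' Translates the dating-uncertainty tolerance of the sample filter into the
#' number of adjacent layers, in each temporal direction, that a random
#' walker is allowed to relax to: a sample's mid-point can be at most half
#' its age range away from its true age, so the limit is
#' `ceiling((max_range / 2) / bin_width)`, floored at 1 (the smallest value
#' that enables interlayer connections) whenever `max_range > 0`.
#'
#' @param max_range widest accepted age range (years).
#' @param bin_width layer width (years).
#' @return Integer relax limit (number of layers).
#' @examples
#' compute_relax_limit(2000, 500) # 2
#' @export
compute_relax_limit <- function(max_range, bin_width) {
  if (bin_width <= 0) stop("compute_relax_limit: bin_width must be positive")
  if (max_range < 0) stop("compute_relax_limit: max_range must be >= 0")
  if (max_range == 0) return(0L)
  max(1L, as.integer(ceiling((max_range / 2) / bin_width)))
}

#' Sample x trait weight matrix from occurrences and species traits
#'
#' For each sample and trait, the weight is the fraction of the sample's
#' species that carry the trait.  Weights lie in \[0, 1\]; a sample's weights
#' can sum to more than 1 because species carry several traits.  Trait
#' columns with zero total weight are dropped (and logged).
#'
#' @param occ binary sample x species matrix (see [filter_species_level()]).
#' @param species_traits data frame with `taxon` and `trait` columns
#'   (multi-membership: several rows per species).
#' @return A numeric sample x trait matrix with a `"dropped_traits"`
#'   attribute.
#' @export
build_trait_weights <- function(occ, species_traits) {
  taxa <- colnames(occ)
  missing <- setdiff(taxa, unique(species_traits$taxon))
  if (length(missing))
    stop("build_trait_weights: species missing from trait table: ",
         paste(missing, collapse = ", "))
  traits <- sort(unique(species_traits$trait))
  # species x trait membership
  st <- species_traits[species_traits$taxon %in% taxa, , drop = FALSE]
  memb <- matrix(0, length(taxa), length(traits), dimnames = list(taxa, traits))
  memb[cbind(match(st$taxon, taxa), match(st$trait, traits))] <- 1
  counts <- occ %*% memb                    # species-per-trait counts per sample
  weights <- counts / rowSums(occ)
  zero <- colSums(weights) == 0
  out <- weights[, !zero, drop = FALSE]
  attr(out, "dropped_traits") <- traits[zero]
  out
}

#' Apply the full filtering stage to raw input tables
#'
#' Convenience wrapper: filters samples by mid-point and range, keeps
#' species-level occurrences, assigns layers, and builds the sample x trait
#' weight matrix.
#'
#' @param tables list with `samples`, `occurrences`, `traits` data frames
#'   (as from [read_dataset()]).
#' @param max_midpoint,max_range,bin_width filtering and binning parameters.
#' @param site_class optional site class to retain (e.g. `"natural"`); `NULL`
#'   keeps all.
#' @return List with `samples` (filtered, layered), `occ` (presence matrix),
#'   `trait_weights`, `relax_limit`, and a `report` of exclusion counts.
#' @export
ingest_filter <- function(tables, max_midpoint = 16000, max_range = 2000,
                          bin_width = 500, site_class = NULL) {
  samples <- tables$samples
  if (!is.null(site_class) && !is.null(samples$site_class))
    samples <- samples[samples$site_class %in% site_class, , drop = FALSE]
  samples <- filter_samples(samples, max_midpoint, max_range)
  slog <- attr(samples, "filter_log")
  occ <- filter_species_level(tables$occurrences, samples)
  olog <- attr(occ, "filter_log")
  samples <- samples[samples$sample_id %in% rownames(occ), , drop = FALSE]
  samples <- assign_layers(samples, span_max = max_midpoint, bin_width = bin_width)
  occ <- occ[samples$sample_id, , drop = FALSE]
  tw <- if (!is.null(tables$traits)) build_trait_weights(occ, tables$traits) else NULL
  list(samples = samples, occ = occ, trait_weights = tw,
       relax_limit = compute_relax_limit(max_range, bin_width),
       report = list(samples = slog, occurrences = olog))
}
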