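# Synthetic fossil-record generator with planted temporal regimes.
#
# Emulates the structure of a Quaternary occurrence database: dated sediment
# samples from natural deposits, a sample x species presence table with mixed
# taxonomic resolution, species-to-habitat-trait multi-membership, and
# per-species thermal envelopes.  Community turnover is planted at known
# regime boundaries so downstream clustering can be scored against truth.

#' The 21 habitat trait codes used throughout the package
#'
#' Short codes for habitat-affinity categories of the kind used in
#' palaeoentomological trait classifications (wetlands, aquatics, woodland
#' indicators, dung, synanthropic habitats, ...).
#' @export
habitat_traits <- c("We", "Aq", "ISt", "IRu", "Op", "Me", "Sa", "He", "Ha",
                    "Wo", "ICo", "IDe", "Dr", "Pa", "Di", "Ca", "Du", "IDu",
                    "Mo", "St", "Ge")

default_trait_profile <- function(n_regimes, traits = habitat_traits) {
  # Each regime concentrates probability on a different block of traits,
  # mimicking e.g. open-wet-habitat faunas giving way to woodland and then
  # synanthropic/agropastoral faunas.
  k <- length(traits)
  prof <- matrix(1, n_regimes, k, dimnames = list(NULL, traits))
  anchor <- floor(seq(1, k - 2, length.out = n_regimes))
  for (g in seq_len(n_regimes)) {
    prof[g, anchor[g]:(anchor[g] + 2)] <- 8
  }
  sweep(prof, 1, rowSums(prof), "/")
}

#' Configuration of planted temporal regimes
#'
#' Describes the ground truth a synthetic fossil dataset is generated from:
#' how many successive faunal regimes exist, when (years BP) each regime
#' hands over to the next, how many species each regime's pool holds, what
#' fraction of species adjacent regimes share, each regime's true climate
#' (mean temperature of the coldest and warmest month), and each regime's
#' distribution over habitat traits.
#'
#' @param n_regimes number of successive regimes (>= 1).
#' @param boundaries regime switch times in years BP, strictly decreasing
#'   (older to younger); length `n_regimes - 1`.
#' @param n_species_per_regime species pool size of each regime.
#' @param species_overlap_fraction fraction(s) in \[0, 1\] of a regime's pool
#'   shared with the next (adjacent) regime; a scalar applies to every
#'   boundary, a vector of length `n_regimes - 1` sets each boundary
#'   separately (0 plants a hard compositional break, larger values a softer
#'   one).
#' @param regime_temperature numeric matrix with `n_regimes` rows and columns
#'   `tmin`, `tmax` (degrees C): the true climate each regime's species must
#'   tolerate.
#' @param trait_profile matrix (`n_regimes` x 21) of per-regime trait
#'   probabilities; rows sum to 1.  Defaults concentrate different trait
#'   blocks per regime.
#' @param span_bp total time span covered (years BP; samples are younger).
#' @param bin_width layer width in years used for the truth labeling.
#' @param mean_richness mean species count per sample (Poisson, floored at 1).
#' @param boundary_mixing_scale e-folding scale (years) over which species
#'   shared across a soft boundary are used away from that boundary.
#' @return An object of class `regime_config`.
#' @export
regime_config <- function(n_regimes = 3,
                          boundaries = c(10000, 4000),
                          n_species_per_regime = 20,
                          species_overlap_fraction = 0,
                          regime_temperature = NULL,
                          trait_profile = NULL,
                          span_bp = 16000,
                          bin_width = 500,
                          mean_richness = 15,
                          boundary_mixing_scale = 1000) {
  if (n_regimes < 1) stop("regime_config: need at least one regime")
  if (n_species_per_regime < 1) stop("regime_config: need at least one species per regime")
  boundaries <- if (n_regimes > 1) boundaries[seq_len(n_regimes - 1)] else numeric(0)
  if (n_regimes > 1) {
    if (length(boundaries) != n_regimes - 1 || anyNA(boundaries))
      stop("regime_config: need n_regimes - 1 boundaries")
    if (any(diff(boundaries) >= 0))
      stop("regime_config: boundaries must be strictly decreasing in years BP (older -> younger)")
    if (any(boundaries <= 0) || any(boundaries >= span_bp))
      stop("regime_config: boundaries must lie strictly inside (0, span_bp)")
  }
  if (n_regimes > 1) {
    species_overlap_fraction <- rep_len(species_overlap_fraction, n_regimes - 1)
  } else species_overlap_fraction <- numeric(0)
  if (any(species_overlap_fraction < 0) || any(species_overlap_fraction > 1))
    stop("regime_config: species_overlap_fraction must be in [0, 1]")
  if (is.null(regime_temperature)) {
    # cold late-glacial climate warming towards the present
    tmin <- seq(-12, 2, length.out = max(n_regimes, 2))[seq_len(n_regimes)]
    regime_temperature <- cbind(tmin = tmin, tmax = tmin + 16)
  }
  regime_temperature <- matrix(as.numeric(regime_temperature), n_regimes, 2,
                               dimnames = list(NULL, c("tmin", "tmax")))
  if (any(regime_temperature[, "tmin"] > regime_temperature[, "tmax"]))
    stop("regime_config: regime tmin must not exceed tmax")
  if (is.null(trait_profile)) trait_profile <- default_trait_profile(n_regimes)
  trait_profile <- as.matrix(trait_profile)
  if (nrow(trait_profile) != n_regimes || ncol(trait_profile) != length(habitat_traits))
    stop("regime_config: trait_profile must be n_regimes x 21")
  structure(list(n_regimes = n_regimes, boundaries = boundaries,
                 n_species_per_regime = n_species_per_regime,
                 species_overlap_fraction = species_overlap_fraction,
                 regime_temperature = regime_temperature,
                 trait_profile = trait_profile,
                 span_bp = span_bp, bin_width = bin_width,
                 mean_richness = mean_richness,
                 boundary_mixing_scale = boundary_mixing_scale),
            class = "regime_config")
}

# Regime index (1 = oldest) of an age in years BP given decreasing boundaries.
regime_of_age <- function(age_bp, config) {
  if (config$n_regimes == 1) return(rep(1L, length(age_bp)))
  # boundaries decreasing; regime k covers (boundaries[k], boundaries[k-1]]
  1L + rowSums(outer(age_bp, config$boundaries, "<="))
}

#' Generate a synthetic fossil dataset with planted regimes
#'
#' Draws dated samples across the configured time span, assigns each sample
#' the species pool of the regime containing its true age, attaches habitat
#' traits (1-3 per species, drawn from the regime's trait profile) and
#' thermal envelopes that contain every regime temperature the species is
#' exposed to.  The returned dataset carries the layer-to-regime truth map.
#'
#' @param config a [regime_config()].
#' @param n_sites number of deposits samples are spread over.
#' @param n_samples number of dated samples.
#' @param age_noise dating uncertainty in years: each sample's age interval is
#'   `true age +- age_noise` (range width `2 * age_noise`).
#' @param seed integer seed; the dataset is a pure function of
#'   `(config, n_sites, n_samples, age_noise, seed)`.
#' @return An object of class `synthetic_dataset`: a list with data frames
#'   `samples`, `occurrences` (long form with a `rank` column), `traits`,
#'   `envelopes`, `truth` (layer -> regime) and the species `pools`.
#' @export
generate_dataset <- function(config, n_sites = 30, n_samples = 200,
                             age_noise = 0, seed = 1) {
  stopifnot(inherits(config, "regime_config"))
  if (n_samples < config$n_regimes)
    stop("generate_dataset: need at least one sample per regime (n_samples >= n_regimes)")
  if (age_noise < 0) stop("generate_dataset: age_noise must be >= 0")
  set.seed(seed)

  K <- config$n_regimes
  npr <- config$n_species_per_regime
  n_shared <- if (K > 1) as.integer(round(config$species_overlap_fraction * npr))
              else integer(0)

  # species pools: regime k shares its last n_shared[k] species with k+1
  n_total <- npr + sum(npr - n_shared)
  species <- sprintf("sp%04d", seq_len(n_total))
  pools <- vector("list", K)
  pools[[1]] <- seq_len(npr)
  nxt <- npr + 1L
  if (K > 1) {
    for (k in 2:K) {
      s <- n_shared[k - 1]
      carried <- if (s > 0) utils::tail(pools[[k - 1]], s) else integer(0)
      fresh <- seq.int(nxt, length.out = npr - s)
      pools[[k]] <- c(carried, fresh)
      nxt <- nxt + npr - s
    }
  }

  # dated samples: true ages uniform over the span (kept >= age_noise so the
  # symmetric interval stays within [0, span])
  true_age <- stats::runif(n_samples, min = age_noise,
                           max = config$span_bp - 1e-9)
  true_age <- sort(true_age, decreasing = TRUE)
  regime <- regime_of_age(true_age, config)
  samples <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n_samples)),
    site_id = sprintf("site%03d", sample.int(n_sites, n_samples, replace = TRUE)),
    age_max = true_age + age_noise,
    age_min = true_age - age_noise,
    site_class = "natural",
    stringsAsFactors = FALSE
  )

  # occurrences: per-sample richness ~ Poisson(mean_richness), floored at 1.
  # Species shared with an adjacent regime are boundary dwellers: their
  # sampling weight decays with the sample's temporal distance from the
  # shared boundary (scale = boundary_mixing_scale years), so a soft
  # boundary blends compositions locally rather than across whole regimes.
  decay <- config$boundary_mixing_scale
  occ <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    k <- regime[i]
    pool <- pools[[k]]
    w <- rep(1, length(pool))
    if (k > 1 && n_shared[k - 1] > 0) {
      sh <- pool %in% pools[[k - 1]]
      w[sh] <- pmin(w[sh], exp(-abs(true_age[i] - config$boundaries[k - 1]) / decay))
    }
    if (k < K && n_shared[k] > 0) {
      sh <- pool %in% pools[[k + 1]]
      w[sh] <- pmin(w[sh], exp(-abs(true_age[i] - config$boundaries[k]) / decay))
    }
    rich <- min(max(stats::rpois(1, config$mean_richness), 1L), length(pool))
    taxa <- species[sort(sample(pool, rich, prob = w))]
    occ[[i]] <- data.frame(sample_id = samples$sample_id[i], taxon = taxa,
                           rank = "species", stringsAsFactors = FALSE)
  }
  occurrences <- do.call(rbind, occ)
  rownames(occurrences) <- NULL

  # traits: 1-3 traits per species from the profile of its first regime
  first_regime <- vapply(seq_len(n_total),
                         function(s) which(vapply(pools, function(p) s %in% p, TRUE))[1],
                         integer(1))
  traits <- do.call(rbind, lapply(seq_len(n_total), function(s) {
    k <- min(sample.int(3, 1), length(habitat_traits))
    tr <- sample(habitat_traits, k, prob = config$trait_profile[first_regime[s], ])
    data.frame(taxon = species[s], trait = tr, stringsAsFactors = FALSE)
  }))

  # thermal envelopes: contain every regime temperature the species meets
  env <- do.call(rbind, lapply(seq_len(n_total), function(s) {
    ks <- which(vapply(pools, function(p) s %in% p, TRUE))
    tmins <- config$regime_temperature[ks, "tmin"]
    tmaxs <- config$regime_temperature[ks, "tmax"]
    data.frame(taxon = species[s],
               tmin_lo = min(tmins) - stats::runif(1, 1, 6),
               tmin_hi = max(tmins) + stats::runif(1, 1, 6),
               tmax_lo = min(tmaxs) - stats::runif(1, 1, 6),
               tmax_hi = max(tmaxs) + stats::runif(1, 1, 6),
               herbivore = stats::runif(1) < 0.2,
               climate_indicator = TRUE,
               stringsAsFactors = FALSE)
  }))

  n_layers <- config$span_bp %/% config$bin_width
  layer_mid_age <- config$span_bp - (seq_len(n_layers) - 0.5) * config$bin_width
  truth <- data.frame(layer = seq_len(n_layers) - 1L,
                      regime = regime_of_age(layer_mid_age, config))

  structure(list(samples = samples, occurrences = occurrences, traits = traits,
                 envelopes = env, truth = truth, pools = pools,
                 species = species, config = config,
                 injected = list(samples = character(0), occurrences = integer(0))),
            class = "synthetic_dataset")
}

#' Inject records that violate the filtering rules
#'
#' Adds, on top of a clean dataset, exactly `n_old` samples whose age
#' mid-point exceeds 16,000 BP, `n_wide` samples whose age range exceeds
#' 2000 years, and `n_coarse_taxa` occurrences identified only to genus
#' level, so that the downstream filters have known work to do.  Injected
#' record ids are listed in the `injected` metadata.
#'
#' @param dataset a `synthetic_dataset`.
#' @param n_old,n_wide,n_coarse_taxa counts of violations of each kind.
#' @param seed integer seed.
#' @return The augmented `synthetic_dataset`.
#' @export
inject_filter_violations <- function(dataset, n_old = 0, n_wide = 0,
                                     n_coarse_taxa = 0, seed = 1) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (n_old == 0 && n_wide == 0 && n_coarse_taxa == 0) return(dataset)
  set.seed(seed)
  ds <- dataset
  sp <- ds$species
  pool1 <- ds$pools[[1]]
  add_sample <- function(id, age_max, age_min) {
    data.frame(sample_id = id, site_id = "site999", age_max = age_max,
               age_min = age_min, site_class = "natural", stringsAsFactors = FALSE)
  }
  new_samples <- list()
  new_occ <- list()
  if (n_old > 0) {
    for (i in seq_len(n_old)) {
      id <- sprintf("old%03d", i)
      mid <- stats::runif(1, 16500, 18000)   # mid-point > 16,000 BP
      half <- stats::runif(1, 100, 900)      # range <= 2000: only the age rule fires
      new_samples[[length(new_samples) + 1]] <- add_sample(id, mid + half, mid - half)
      new_occ[[length(new_occ) + 1]] <- data.frame(
        sample_id = id, taxon = sp[sample(pool1, 1)], rank = "species",
        stringsAsFactors = FALSE)
    }
  }
  if (n_wide > 0) {
    for (i in seq_len(n_wide)) {
      id <- sprintf("wide%03d", i)
      mid <- stats::runif(1, 3000, 12000)    # mid-point fine: only the range rule fires
      half <- stats::runif(1, 1100, 1500)    # range in (2200, 3000) years
      new_samples[[length(new_samples) + 1]] <- add_sample(id, mid + half, mid - half)
      new_occ[[length(new_occ) + 1]] <- data.frame(
        sample_id = id, taxon = sp[sample(pool1, 1)], rank = "species",
        stringsAsFactors = FALSE)
    }
  }
  if (length(new_samples)) {
    add <- do.call(rbind, new_samples)
    ds$samples <- rbind(ds$samples, add)
    ds$occurrences <- rbind(ds$occurrences, do.call(rbind, new_occ))
    ds$injected$samples <- c(ds$injected$samples, add$sample_id)
  }
  if (n_coarse_taxa > 0) {
    # genus-level occurrences attached to existing (clean) samples
    hosts <- sample(dataset$samples$sample_id, n_coarse_taxa, replace = TRUE)
    coarse <- data.frame(sample_id = hosts,
                         taxon = sprintf("Genus%03d indet.", seq_len(n_coarse_taxa)),
                         rank = "genus", stringsAsFactors = FALSE)
    first_new <- nrow(ds$occurrences) + 1L
    ds$occurrences <- rbind(ds$occurrences, coarse)
    ds$injected$occurrences <- c(ds$injected$occurrences,
                                 seq.int(first_new, length.out = n_coarse_taxa))
  }
  rownames(ds$samples) <- rownames(ds$occurrences) <- NULL
  ds
}

#' Write a synthetic dataset to a directory of TSV tables
#'
#' Writes `samples.tsv` (sample_id, site_id, age_max, age_min, site_class),
#' `occurrences.tsv` (sample_id, taxon, rank), `traits.tsv` (taxon, trait),
#' `envelopes.tsv` (taxon, tmin_lo, tmin_hi, tmax_lo, tmax_hi, herbivore,
#' climate_indicator) and `truth.tsv` (layer, regime).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(dataset$samples, file.path(dir, "samples.tsv"))
  write_tsv(dataset$occurrences, file.path(dir, "occurrences.tsv"))
  write_tsv(dataset$traits, file.path(dir, "traits.tsv"))
  write_tsv(dataset$envelopes, file.path(dir, "envelopes.tsv"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read the four input tables (and truth, if present) from a directory
#'
#' @param dir directory holding `samples.tsv`/`.csv` etc. as written by
#'   [write_dataset()].
#' @return A list with elements `samples`, `occurrences`, `traits`,
#'   `envelopes` and (if present) `truth`.
#' @export
read_dataset <- function(dir) {
  find <- function(stem) {
    for (ext in c("tsv", "csv")) {
      p <- file.path(dir, paste0(stem, ".", ext))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  out <- list()
  for (stem in c("samples", "occurrences", "traits", "envelopes", "truth")) {
    p <- find(stem)
    if (is.null(p)) {
      if (stem %in% c("samples", "occurrences"))
        stop("read_dataset: required table '", stem, "' not found in ", dir)
      next
    }
    out[[stem]] <- read_table_auto(p)
  }
  out
}
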