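test_that("generation is deterministic and respects single-regime / zero-overlap cases", {
  cfg1 <- regime_config(1, n_species_per_regime = 10)
  ds <- generate_dataset(cfg1, n_sites = 5, n_samples = 5, age_noise = 0, seed = 1)
  expect_true(all(ds$occurrences$taxon %in% ds$species[ds$pools[[1]]]))
  expect_true(all(ds$truth$regime == 1))

  cfg3 <- regime_config(3, c(10000, 4000), n_species_per_regime = 12,
                        species_overlap_fraction = 0)
  ds3 <- generate_dataset(cfg3, n_sites = 10, n_samples = 60, seed = 7)
  # no species occurs in samples of two different regimes
  mid <- (ds3$samples$age_max + ds3$samples$age_min) / 2
  reg <- 1L + rowSums(outer(mid, cfg3$boundaries, "<="))
  by_taxon <- split(reg[match(ds3$occurrences$sample_id, ds3$samples$sample_id)],
                    ds3$occurrences$taxon)
  expect_true(all(lengths(lapply(by_taxon, unique)) == 1))

  # identical config + seed => identical dataset
  ds3b <- generate_dataset(cfg3, n_sites = 10, n_samples = 60, seed = 7)
  expect_identical(ds3, ds3b)
  ds3c <- generate_dataset(cfg3, n_sites = 10, n_samples = 60, seed = 8)
  expect_false(identical(ds3$occurrences, ds3c$occurrences))
})

test_that("adjacent pools share exactly the configured number of species", {
  cfg <- regime_config(2, 8000, n_species_per_regime = 20,
                       species_overlap_fraction = 0.5)
  ds <- generate_dataset(cfg, n_sites = 5, n_samples = 20, seed = 3)
  shared <- intersect(ds$pools[[1]], ds$pools[[2]])
  expect_length(shared, 10)
  expect_length(union(ds$pools[[1]], ds$pools[[2]]), 30)
})

test_that("planted signal is block-diagonal and envelopes contain regime temperatures", {
  cfg <- regime_config(2, 8000, n_species_per_regime = 10,
                       species_overlap_fraction = 0)
  ds <- generate_dataset(cfg, n_sites = 8, n_samples = 50, age_noise = 0, seed = 2)
  filt <- ingest_filter(ds)
  # block-diagonal: order samples by regime, species by pool
  mid <- filt$samples$midpoint
  reg <- ifelse(mid > 8000, 1L, 2L)
  for (k in 1:2) {
    other_pool <- ds$species[ds$pools[[if (k == 1) 2 else 1]]]
    block <- filt$occ[reg == k, colnames(filt$occ) %in% other_pool, drop = FALSE]
    expect_true(all(block == 0))
  }
  # envelope consistency
  env <- ds$envelopes
  for (k in 1:2) {
    sp <- ds$species[ds$pools[[k]]]
    e <- env[env$taxon %in% sp, ]
    expect_true(all(e$tmin_lo <= cfg$regime_temperature[k, "tmin"]))
    expect_true(all(e$tmin_hi >= cfg$regime_temperature[k, "tmin"]))
    expect_true(all(e$tmax_lo <= cfg$regime_temperature[k, "tmax"]))
    expect_true(all(e$tmax_hi >= cfg$regime_temperature[k, "tmax"]))
  }
  # every sample has >= 1 occurrence, every species in the tables has a trait
  expect_true(all(ds$samples$sample_id %in% ds$occurrences$sample_id))
  expect_true(all(ds$species %in% ds$traits$taxon))
})

test_that("invalid configurations are rejected", {
  expect_error(regime_config(0), "at least one regime")
  expect_error(regime_config(3, c(4000, 10000)), "strictly decreasing")
  expect_error(regime_config(2, 8000, species_overlap_fraction = 1.5), "\\[0, 1\\]")
  cfg <- regime_config(2, 8000)
  expect_error(generate_dataset(cfg, n_samples = 1, seed = 1), "n_samples >= n_regimes")
})

test_that("injected violations are flagged and later filtered exactly", {
  ds <- make_planted(5, n_samples = 40)
  n_occ0 <- nrow(ds$occurrences)
  aug <- inject_filter_violations(ds, n_old = 3, n_wide = 2, n_coarse_taxa = 5, seed = 9)
  expect_identical(inject_filter_violations(ds, 0, 0, 0), ds)
  expect_equal(nrow(aug$samples), nrow(ds$samples) + 5)
  expect_length(aug$injected$samples, 5)
  wide <- aug$samples[startsWith(aug$samples$sample_id, "wide"), ]
  expect_true(all(wide$age_max - wide$age_min > 2000))
  old <- aug$samples[startsWith(aug$samples$sample_id, "old"), ]
  expect_true(all((old$age_max + old$age_min) / 2 > 16000))
  expect_true(all(old$age_max - old$age_min <= 2000))

  filt_clean <- ingest_filter(ds)
  filt_aug <- ingest_filter(aug)
  expect_equal(filt_aug$report$samples$n_excluded_midpoint, 3)
  expect_equal(filt_aug$report$samples$n_excluded_range, 2)
  expect_equal(filt_aug$report$occurrences$n_occurrences_dropped, 5)
  expect_identical(dim(filt_aug$occ), dim(filt_clean$occ))
})

test_that("datasets round-trip through the TSV tables", {
  ds <- make_planted(11, n_samples = 25)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$samples$sample_id, ds$samples$sample_id)
  expect_equal(back$samples$age_max, ds$samples$age_max)
  expect_equal(nrow(back$occurrences), nrow(ds$occurrences))
  expect_equal(back$envelopes$tmin_lo, ds$envelopes$tmin_lo)
  expect_equal(back$truth$regime, ds$truth$regime)
})
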