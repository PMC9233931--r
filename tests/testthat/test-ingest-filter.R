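samples_df <- function(...) {
  rows <- list(...)
  data.frame(sample_id = sprintf("s%d", seq_along(rows)),
             age_max = vapply(rows, `[`, 0, 1),
             age_min = vapply(rows, `[`, 0, 2))
}

test_that("sample filters apply the mid-point and range rules independently", {
  s <- samples_df(c(17000, 16000),   # midpoint 16500 > 16000 -> out
                  c(1000, 500),      # midpoint 750, range 500 -> kept
                  c(3000, 500))      # range 2500 > 2000 -> out despite midpoint 1750
  out <- filter_samples(s)
  expect_identical(out$sample_id, "s2")
  log <- attr(out, "filter_log")
  expect_equal(log$n_excluded_midpoint, 1)
  expect_equal(log$n_excluded_range, 1)
  # boundary: midpoint exactly 16000 and range exactly 2000 are kept
  keep <- filter_samples(samples_df(c(17000, 15000)))
  expect_equal(nrow(keep), 1)
  # invalid interval is an error, not a silent drop
  expect_error(filter_samples(samples_df(c(500, 1000))), "age_min > age_max")
})

test_that("filtering is idempotent", {
  ds <- make_planted(3, n_samples = 40)
  aug <- inject_filter_violations(ds, 2, 2, 0, seed = 1)
  once <- filter_samples(aug$samples)
  twice <- filter_samples(once)
  attr(once, "filter_log") <- attr(twice, "filter_log") <- NULL
  expect_identical(once, twice)
})

test_that("species-level filter drops coarse records and emptied samples", {
  occ <- data.frame(
    sample_id = c("a", "a", "a", "b"),
    taxon = c("Patrobus septentrionis", "Bembidion sp.", "Carabidae indet.",
              "Agonum sp."),
    rank = c("species", "genus", "family", "genus"))
  m <- filter_species_level(occ)
  expect_identical(rownames(m), "a")
  expect_identical(colnames(m), "Patrobus septentrionis")
  log <- attr(m, "filter_log")
  expect_equal(log$n_occurrences_dropped, 3)
  expect_identical(log$emptied_samples, "b")
  # all-species input is an identity on the incidence structure
  occ2 <- occ[occ$rank == "species", ]
  m2 <- filter_species_level(occ2)
  expect_equal(sum(m2), 1)
  expect_error(filter_species_level(transform(occ, rank = "subgenus")),
               "unknown rank")
})

test_that("layer assignment bins mid-points oldest-first with edge clamping", {
  s <- samples_df(c(15750, 15750), c(0, 0), c(15500, 15500), c(8000, 8000))
  out <- assign_layers(s)
  expect_identical(out$layer, c(0L, 31L, 1L, 16L))
  expect_equal(attr(out, "n_layers"), 32L)
  # order preserving: older midpoint implies layer index <= younger's
  ds <- make_planted(7, n_samples = 60)
  f <- ingest_filter(ds)
  o <- order(-f$samples$midpoint)
  expect_true(all(diff(f$samples$layer[o]) >= 0))
  expect_error(assign_layers(samples_df(c(17000, 17000))), "older than span_max")
  expect_error(assign_layers(samples_df(c(100, 100)), bin_width = 300),
               "divide span_max")
})

test_that("relax limit follows the half-range rule with a floor of one layer", {
  expect_identical(compute_relax_limit(2000, 500), 2L)
  expect_identical(compute_relax_limit(500, 500), 1L)
  expect_identical(compute_relax_limit(4000, 1000), 2L)
  expect_identical(compute_relax_limit(100, 500), 1L)
  expect_identical(compute_relax_limit(0, 500), 0L)
  expect_error(compute_relax_limit(2000, 0), "positive")
})

test_that("trait weights are species fractions and invariant to relabeling", {
  occ <- matrix(c(1, 1, 0, 1), 1, 4,
                dimnames = list("s1", c("spA", "spB", "spC", "spD")))
  occ <- occ[, occ[1, ] > 0, drop = FALSE]   # 3 species present
  st <- data.frame(taxon = c("spA", "spB", "spD", "spD"),
                   trait = c("Wo", "Wo", "We", "Aq"))
  w <- build_trait_weights(occ, st)
  expect_equal(w["s1", "Wo"], 2 / 3)
  expect_equal(w["s1", "We"], 1 / 3)
  expect_equal(w["s1", "Aq"], 1 / 3)
  expect_true(all(w >= 0 & w <= 1))

  occ2 <- matrix(1, 1, 2, dimnames = list("s1", c("spA", "spB")))
  st2 <- data.frame(taxon = c("spA", "spB", "spA"),
                    trait = c("We", "We", "Aq"))
  w2 <- build_trait_weights(occ2, st2)
  expect_equal(w2["s1", "We"], 1)      # all species bear the trait
  expect_equal(w2["s1", "Aq"], 0.5)
  # relabeling species leaves the weights unchanged
  occ3 <- occ2; colnames(occ3) <- c("x1", "x2")
  st3 <- transform(st2, taxon = c("x1", "x2", "x1"))
  expect_equal(unname(build_trait_weights(occ3, st3)), unname(w2))
  expect_error(build_trait_weights(occ2, st2[st2$taxon != "spB", ]),
               "missing from trait table: spB")
})

test_that("tables read with auto-detected delimiters", {
  df <- data.frame(sample_id = c("a", "b"), age_max = c(100, 200),
                   age_min = c(50, 100))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  csv <- withr::local_tempfile(fileext = ".csv")
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(df, csv, sep = ",", row.names = FALSE, quote = FALSE)
  expect_equal(fossilnet:::read_table_auto(tsv), df)
  expect_equal(fossilnet:::read_table_auto(csv), df)
})
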