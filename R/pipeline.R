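# End-to-end orchestration: ingest (or simulate) -> filter -> build both
# networks -> cluster -> bootstrap -> MCR -> trait importance -> report.

#' Configuration of a full pipeline run
#'
#' Collects every tunable parameter with the defaults of the reference
#' analysis: samples filtered to mid-point <= 16,000 BP and age range <=
#' 2000 years, 500-year layers, relax rate 0.25 with the relax limit derived
#' from the accepted age range (l = 2 at the defaults), 500 optimizer
#' restarts, 100 bootstrap replicates with weight sd 0.1, a 0.5 degree MCR
#' grid and 999 IndVal permutations.
#'
#' @param max_midpoint,max_range sample filters (years BP / years).
#' @param bin_width layer width (years).
#' @param relax_rate relax rate r.
#' @param relax_limit relax limit l; `NULL` derives it from `max_range` and
#'   `bin_width` via [compute_relax_limit()] (an explicit override is noted
#'   in the manifest).
#' @param n_restarts optimizer restarts per network.
#' @param bootstrap_n,bootstrap_sd,bootstrap_restarts bootstrap settings.
#' @param mcr_grid_step MCR lattice step (degrees C).
#' @param indval_n_perm IndVal permutations.
#' @param seed integer master seed (per-stage seeds derive from it).
#' @return A list of class `run_config`.
#' @export
run_config <- function(max_midpoint = 16000, max_range = 2000, bin_width = 500,
                       relax_rate = 0.25, relax_limit = NULL, n_restarts = 500,
                       bootstrap_n = 100, bootstrap_sd = 0.1,
                       bootstrap_restarts = 10, mcr_grid_step = 0.5,
                       indval_n_perm = 999, seed = 1) {
  derived <- compute_relax_limit(max_range, bin_width)
  overridden <- !is.null(relax_limit) && relax_limit != derived
  structure(list(max_midpoint = max_midpoint, max_range = max_range,
                 bin_width = bin_width, relax_rate = relax_rate,
                 relax_limit = relax_limit %||% derived,
                 relax_limit_overridden = overridden,
                 n_restarts = n_restarts, bootstrap_n = bootstrap_n,
                 bootstrap_sd = bootstrap_sd,
                 bootstrap_restarts = bootstrap_restarts,
                 mcr_grid_step = mcr_grid_step,
                 indval_n_perm = indval_n_perm, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' @param input either a directory of input tables (see [read_dataset()]), a
#'   list of tables, or a `synthetic_dataset`.
#' @param out_dir output directory for the run artifacts (created).
#' @param config a [run_config()].
#' @param bootstrap run the bootstrap significance stage?  (It re-clusters
#'   `bootstrap_n` replicate networks and dominates the runtime.)
#' @return Invisibly, a list with every intermediate object (`filtered`,
#'   `tax_net`, `trait_net`, `tax_part`, `trait_part`, `tax_timeline`,
#'   `trait_timeline`, `mcr`, `flows`, `indval`, and if requested
#'   `significance`).  Artifacts are written to `out_dir` as TSV / text
#'   files plus a JSON manifest.
#' @export
run_pipeline <- function(input, out_dir, config = run_config(),
                         bootstrap = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tables <- stage("ingest", {
    if (is.character(input)) read_dataset(input)
    else if (inherits(input, "synthetic_dataset")) input
    else input
  })
  filt <- stage("filter", ingest_filter(
    tables, max_midpoint = config$max_midpoint, max_range = config$max_range,
    bin_width = config$bin_width))
  write_tsv(filt$samples, file.path(out_dir, "samples_filtered.tsv"))
  writeLines(c(
    sprintf("samples in: %d", filt$report$samples$n_input),
    sprintf("excluded by mid-point rule: %d", filt$report$samples$n_excluded_midpoint),
    sprintf("excluded by age-range rule: %d", filt$report$samples$n_excluded_range),
    sprintf("occurrences dropped above species level: %d",
            filt$report$occurrences$n_occurrences_dropped),
    sprintf("samples emptied by the rank filter: %d",
            length(filt$report$occurrences$emptied_samples))),
    file.path(out_dir, "filter_report.txt"))

  tax_net <- stage("build-net", build_taxonomic_network(filt$occ, filt$samples))
  write_multilayer_with_params <- function(net, file) {
    net$relax_rate <- config$relax_rate
    net$relax_limit <- config$relax_limit
    write_multilayer(net, file.path(out_dir, file))
    net
  }
  tax_net <- write_multilayer_with_params(tax_net, "taxonomic_network.net")
  trait_net <- NULL
  if (!is.null(filt$trait_weights)) {
    trait_net <- stage("build-net", build_trait_network(filt$trait_weights, filt$samples))
    trait_net <- write_multilayer_with_params(trait_net, "trait_network.net")
  }

  tax_part <- stage("cluster", mapeq_optimize(
    tax_net, r = config$relax_rate, l = config$relax_limit,
    n_restarts = config$n_restarts, seed = config$seed))
  write_partition(tax_part, file.path(out_dir, "partition_taxonomic.tsv"))
  tax_tl <- extract_timeline(tax_part, tax_net)
  write_tsv(tax_tl$modules, file.path(out_dir, "timeline_taxonomic.tsv"))
  write_tsv(tax_tl$transitions, file.path(out_dir, "transitions_taxonomic.tsv"))

  out <- list(config = config, filtered = filt, tax_net = tax_net,
              tax_part = tax_part, tax_timeline = tax_tl)

  if (!is.null(trait_net)) {
    trait_part <- stage("cluster", mapeq_optimize(
      trait_net, r = config$relax_rate, l = config$relax_limit,
      n_restarts = config$n_restarts, seed = config$seed + 1))
    write_partition(trait_part, file.path(out_dir, "partition_trait.tsv"))
    trait_tl <- extract_timeline(trait_part, trait_net)
    write_tsv(trait_tl$modules, file.path(out_dir, "timeline_trait.tsv"))
    out$trait_net <- trait_net
    out$trait_part <- trait_part
    out$trait_timeline <- trait_tl

    flows <- stage("traits", percent_flow(trait_part, trait_net))
    write_tsv(flows, file.path(out_dir, "trait_flow.tsv"))
    out$flows <- flows
    groups <- layer_groups(tax_tl)
    common <- intersect(as.character(unique(flows$layer)), names(groups))
    if (length(unique(groups[common])) >= 2) {
      iv <- stage("traits", indval(flows, groups[common],
                                   n_perm = config$indval_n_perm,
                                   seed = config$seed + 2))
      write_tsv(iv, file.path(out_dir, "indval.tsv"))
      out$indval <- iv
    }
  }

  if (!is.null(tables$envelopes)) {
    mcr_tab <- stage("mcr", mcr_by_module(tax_part, tax_tl, tables$envelopes,
                                          grid_step = config$mcr_grid_step))
    write_tsv(mcr_tab, file.path(out_dir, "mcr.tsv"))
    out$mcr <- mcr_tab
  }

  if (bootstrap) {
    ens <- stage("bootstrap", bootstrap_ensemble(
      tax_net, tax_part, n = config$bootstrap_n,
      weight_sd = config$bootstrap_sd, seed = config$seed + 3,
      n_restarts = config$bootstrap_restarts))
    sig <- stage("bootstrap", significance_report(tax_net, tax_part, ens))
    write_tsv(sig$cores$core_table, file.path(out_dir, "significant_cores.tsv"))
    if (!is.null(sig$transitions))
      write_tsv(sig$transitions, file.path(out_dir, "transition_types.tsv"))
    write_tsv(sig$layers, file.path(out_dir, "layer_robustness.tsv"))
    out$significance <- sig
  }

  manifest <- list(
    package = "fossilnet",
    package_version = as.character(utils::packageVersion("fossilnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = NULL,  # deliberately omitted: outputs are a pure function of inputs + config
    config = unclass(config),
    network_sizes = list(taxonomic = network_size(tax_net),
                         trait = if (!is.null(trait_net)) network_size(trait_net)),
    codelengths = list(taxonomic = tax_part$codelength,
                       trait = if (!is.null(out$trait_part)) out$trait_part$codelength))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  invisible(out)
}
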