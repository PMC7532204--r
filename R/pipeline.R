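# End-to-end orchestration: simulate (or load) -> inclusion filter ->
# exposure -> sensitivity -> adaptive capacity -> scoring -> robustness.

#' Island inclusion filter
#'
#' Retains islands whose occupying endemic species count strictly exceeds
#' `min_species` (default 5, i.e. the ">5 species" rule); dropped islands
#' are reported with their counts.
#'
#' @param occurrences long-format occurrence table (`island_id`,
#'   `species_id`).
#' @param min_species islands must harbour strictly more species than this.
#' @return character vector of retained island ids, with a `dropped`
#'   attribute (named integer vector of the dropped islands' counts).
#' @export
filter_islands <- function(occurrences, min_species = 5L) {
  counts <- table(occurrences$island_id)
  keep <- counts > min_species
  dropped <- counts[!keep]
  if (length(dropped) > 0)
    message("dropping ", length(dropped), " island(s) with <= ", min_species,
            " species: ",
            paste(sprintf("%s (%d)", names(dropped), dropped), collapse = ", "))
  retained <- names(counts)[keep]
  if (length(retained) == 0L)
    stopf("no island passes the >%d species inclusion filter", min_species)
  attr(retained, "dropped") <- stats::setNames(as.integer(dropped),
                                               names(dropped))
  retained
}

#' Run the full vulnerability pipeline
#'
#' Generates (or loads) the data, applies the inclusion filter, computes
#' the exposure, sensitivity and adaptive-capacity variables, standardizes
#' and aggregates them, scores TOPSIS vulnerability, and produces the
#' robustness reports. Identical configs produce identical outputs.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   * `scenario` — a [vuln_scenario()] or the list of its arguments, OR
#'   * `data_dir` — a directory of real/pre-generated inputs in the
#'     [simulate_to_dir()] layout (`islands.csv`, `climate_grid.csv`,
#'     `traits.csv`, `occurrences.csv`, `trees.nwk`);
#'   * `method` — standardization scheme (default `"minmax"`);
#'   * `buffer_km` — exposure buffer (default 0);
#'   * `weights` — TOPSIS weights (default equal);
#'   * `mass_bins` — body-mass bins for functional entities (default from
#'     the scenario, else 4);
#'   * `fp_seed` — seed for polytomy resolutions (default the scenario
#'     seed, else 1);
#'   * `out_dir` — optional directory; when given, all stage outputs plus a
#'     `manifest.yaml` are written as CSV/Newick.
#' @return a list bundle: `islands`, `traits`, `occurrences`, `trees`,
#'   `exposure` (+ `exposure_per_scenario`), `sensitivity`, `adaptive`,
#'   `raw_vars`, `components`, `vulnerability`, `archipelagos`,
#'   `correlations`, `loo`, `associations`, `retained_islands`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  method <- config$method %||% "minmax"
  buffer_km <- config$buffer_km %||% 0
  weights <- unlist(config$weights %||% c(1, 1, 1))

  if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (!inherits(sc, "vuln_scenario")) sc <- do.call(vuln_scenario, sc)
    islands <- generate_islands(sc)
    grid <- generate_climate(islands, sc)
    sp <- generate_species(islands, sc)
    trees <- generate_phylogenies(sp$traits$species_id, sc)
    mass_bins <- config$mass_bins %||% sc$mass_bins
    fp_seed <- config$fp_seed %||% sc$seed
  } else if (!is.null(config$data_dir)) {
    dd <- config$data_dir
    need <- c("islands.csv", "climate_grid.csv", "traits.csv",
              "occurrences.csv", "trees.nwk")
    miss <- need[!file.exists(file.path(dd, need))]
    if (length(miss) > 0)
      stopf("pipeline stage 'load': missing input file(s) in '%s': %s",
            dd, paste(miss, collapse = ", "))
    islands <- utils::read.csv(file.path(dd, "islands.csv"),
                               stringsAsFactors = FALSE)
    grid <- utils::read.csv(file.path(dd, "climate_grid.csv"),
                            stringsAsFactors = FALSE)
    sp <- list(traits = utils::read.csv(file.path(dd, "traits.csv"),
                                        stringsAsFactors = FALSE),
               occurrences = utils::read.csv(file.path(dd, "occurrences.csv"),
                                             stringsAsFactors = FALSE))
    trees <- ape::read.tree(file.path(dd, "trees.nwk"))
    if (inherits(trees, "phylo")) trees <- c(trees)
    mass_bins <- config$mass_bins %||% 4L
    fp_seed <- config$fp_seed %||% 1L
  } else {
    stopf("pipeline stage 'load': config needs `scenario` or `data_dir`")
  }

  retained <- filter_islands(sp$occurrences)
  islands <- islands[islands$island_id %in% retained, , drop = FALSE]
  occ <- sp$occurrences[sp$occurrences$island_id %in% retained, , drop = FALSE]
  grid <- grid[grid$island_id %in% retained, , drop = FALSE]

  exposure <- multi_scenario_exposure(grid, buffer_km = buffer_km)

  assignment <- assign_entities(sp$traits, mass_bins = mass_bins)
  sens <- island_sensitivity(islands$island_id, occ, sp$traits, assignment)

  fp_means <- fp_ensemble(trees, seed = fp_seed)
  adaptive <- island_adaptive(islands, occ, fp_means)

  raw_vars <- Reduce(function(a, b) merge(a, b, by = "island_id", sort = FALSE),
                     list(exposure$ensemble[c("island_id", "mean_sed")],
                          sens, adaptive))
  raw_vars <- raw_vars[match(islands$island_id, raw_vars$island_id), ]
  rownames(raw_vars) <- NULL

  var_spec <- default_variable_spec()
  components <- component_scores(raw_vars, var_spec, method)
  vuln <- topsis(components, weights)

  archipelagos <- archipelago_summary(vuln, islands)
  correlations <- suppressWarnings(correlation_screen(raw_vars, var_spec))
  loo <- suppressMessages(leave_one_out(raw_vars, var_spec, method, weights))
  richness <- as.data.frame(table(occ$island_id), stringsAsFactors = FALSE)
  names(richness) <- c("island_id", "endemic_richness")
  predictors <- merge(raw_vars[c("island_id", "habitat_breadth",
                                 "diet_breadth", "generation_length",
                                 "redundancy")],
                      richness, by = "island_id", sort = FALSE)
  predictors <- merge(predictors,
                      components,
                      by = "island_id", sort = FALSE)
  associations <- association_report(vuln, predictors)

  bundle <- list(islands = islands, traits = sp$traits, occurrences = occ,
                 trees = trees,
                 exposure = exposure$ensemble,
                 exposure_per_scenario = exposure$per_scenario,
                 sensitivity = sens, adaptive = adaptive,
                 raw_vars = raw_vars, components = components,
                 vulnerability = vuln, archipelagos = archipelagos,
                 correlations = correlations, loo = loo,
                 associations = associations,
                 retained_islands = retained,
                 config = list(method = method, buffer_km = buffer_km,
                               weights = as.numeric(weights),
                               mass_bins = mass_bins, fp_seed = fp_seed))
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Write every tabular stage output plus a manifest. No timestamps: a
# re-run of the same config must be byte-identical.
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("islands", "traits", "occurrences", "exposure",
              "exposure_per_scenario", "sensitivity", "adaptive", "raw_vars",
              "components", "vulnerability", "archipelagos", "correlations",
              "loo", "associations")
  for (nm in tables)
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  ape::write.tree(bundle$trees, file.path(dir, "trees.nwk"))
  manifest <- list(package = "islevuln",
                   version = as.character(utils::packageVersion("islevuln")),
                   config = bundle$config,
                   n_islands = nrow(bundle$islands),
                   n_species = nrow(bundle$traits))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
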