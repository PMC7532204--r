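#' Define a synthetic archipelago scenario
#'
#' A scenario bundles every parameter of the synthetic-data generator:
#' archipelago layout, climate baseline and per-archipelago future shifts,
#' species-trait distributions, phylogeny ensemble settings, and island
#' attributes. Together with its `seed` it fully determines all generated
#' tables: the same scenario always yields byte-identical data.
#'
#' The defaults emulate the shape of a real global island dataset at desk
#' scale: 5 archipelagos of 8 islands, each island holding more than 5
#' endemic species (target 12 per island) and at least 10 climate grid
#' points, future climates from 5 GCM-like scenario blocks, and a 100-tree
#' phylogeny ensemble containing polytomies.
#'
#' Climate variables (six, plus two seasonality standardizers) follow the
#' usual bioclimatic set: annual mean temperature, maximum temperature of
#' the warmest month, minimum temperature of the coldest month (degrees C),
#' annual precipitation, precipitation of the wettest and driest months
#' (mm). The future shift for archipelago a and variable k is
#' `shift_scale[a] * shift_profile[k]`, scaled per GCM block by an evenly
#' spaced multiplier in `1 +/- gcm_spread`, plus Gaussian noise `noise_sd[k]`.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   substream from it.
#' @param n_archipelagos,islands_per_archipelago archipelago layout.
#' @param n_grid_points integer range (length 2) of climate grid points per
#'   island; minimum must be >= 1 (defaults keep >= 10 per island).
#' @param species_per_island_target target endemic richness per island; must
#'   exceed 5 so every generated island passes the inclusion filter.
#' @param multi_island_fraction fraction of each island's species drawn from
#'   an archipelago-shared pool (multi-island endemics, confined to one
#'   archipelago); 0 makes every species a single-island endemic.
#' @param shift_scale per-archipelago shift magnitudes (recycled/truncated to
#'   `n_archipelagos`); degrees C of warming per unit profile.
#' @param shift_profile named length-6 per-unit future-minus-current offsets.
#' @param noise_sd named length-6 non-negative Gaussian noise s.d. applied to
#'   future values.
#' @param gcm_labels labels of the future scenario blocks.
#' @param gcm_spread half-width of the evenly spaced per-GCM shift
#'   multipliers around 1.
#' @param climate_base named length-8 baseline means (six variables plus
#'   `s_temp`, `s_prec` seasonality standardizers, drawn log-normal and hence
#'   strictly positive).
#' @param habitat_count_range,diet_count_range integer ranges for the number
#'   of habitats / diets per species.
#' @param gl_meanlog,gl_sdlog log-normal parameters of generation length
#'   (years).
#' @param mass_meanlog,mass_sdlog log-normal parameters of body mass (grams).
#' @param n_trait_levels number of levels of each categorical redundancy
#'   trait (main diet, foraging niche, foraging period, habitat niche
#'   breadth).
#' @param mass_bins default number of quantile bins used when categorizing
#'   body mass into functional entities.
#' @param polytomy_fraction fraction of internal edges collapsed to
#'   polytomies in each generated tree, in [0, 1].
#' @param n_trees number of trees in the phylogeny ensemble.
#' @param pa_beta,extinct_beta shape parameters of the Beta distributions for
#'   protected-area fraction and per-island extinction probability.
#' @param richness_range integer range of total (all-vertebrate) island
#'   richness used as the extinction-rate denominator.
#' @param planted_archipelago optional archipelago id (e.g. `"A1"`) given
#'   maximal planted vulnerability: maximal climate shift, single-habitat
#'   single-diet species with tripled generation length, zero protected-area
#'   coverage, zero surrounding land mass, and zero past extinctions.
#'
#' @return an object of class `vuln_scenario` (a validated list).
#' @seealso [generate_islands()], [generate_climate()], [generate_species()],
#'   [generate_phylogenies()], [run_pipeline()]
#' @export
vuln_scenario <- function(seed = 1L,
                          n_archipelagos = 5L,
                          islands_per_archipelago = 8L,
                          n_grid_points = c(10L, 30L),
                          species_per_island_target = 12L,
                          multi_island_fraction = 0.3,
                          shift_scale = NULL,
                          shift_profile = c(tmean = 1, tmax_warm = 1.2,
                                            tmin_cold = 0.8, prec_ann = -40,
                                            prec_wet = -15, prec_dry = -5),
                          noise_sd = c(tmean = 0.3, tmax_warm = 0.4,
                                       tmin_cold = 0.4, prec_ann = 20,
                                       prec_wet = 8, prec_dry = 3),
                          gcm_labels = paste0("GCM", 1:5),
                          gcm_spread = 0.15,
                          climate_base = c(tmean = 22, tmax_warm = 28,
                                           tmin_cold = 16, prec_ann = 1500,
                                           prec_wet = 300, prec_dry = 40,
                                           s_temp = 2, s_prec = 30),
                          habitat_count_range = c(1L, 6L),
                          diet_count_range = c(1L, 5L),
                          gl_meanlog = log(4), gl_sdlog = 0.4,
                          mass_meanlog = log(150), mass_sdlog = 1.2,
                          n_trait_levels = 4L,
                          mass_bins = 4L,
                          polytomy_fraction = 0.2,
                          n_trees = 100L,
                          pa_beta = c(2, 5),
                          extinct_beta = c(1, 9),
                          richness_range = c(50L, 400L),
                          planted_archipelago = NULL) {
  check_number(seed, "seed")
  check_number(n_archipelagos, "n_archipelagos", lower = 1)
  check_number(islands_per_archipelago, "islands_per_archipelago", lower = 1)
  if (species_per_island_target <= 5)
    stopf("`species_per_island_target` must exceed 5 (inclusion filter), got %s",
          species_per_island_target)
  check_number(multi_island_fraction, "multi_island_fraction", 0, 1)
  check_number(polytomy_fraction, "polytomy_fraction", 0, 1)
  check_number(n_trees, "n_trees", lower = 1)
  check_number(gcm_spread, "gcm_spread", 0, 1)
  if (n_grid_points[1] < 1) stopf("`n_grid_points` minimum must be >= 1")
  if (is.null(shift_scale))
    shift_scale <- seq(0.5, 2.5, length.out = n_archipelagos)
  shift_scale <- rep_len(shift_scale, n_archipelagos)
  vars6 <- c("tmean", "tmax_warm", "tmin_cold",
             "prec_ann", "prec_wet", "prec_dry")
  stopifnot(all(vars6 %in% names(shift_profile)),
            all(vars6 %in% names(noise_sd)),
            all(c(vars6, "s_temp", "s_prec") %in% names(climate_base)),
            all(noise_sd >= 0), all(is.finite(shift_profile)))
  if (!is.null(planted_archipelago))
    stopifnot(is.character(planted_archipelago),
              length(planted_archipelago) == 1L)
  sc <- list(seed = as.integer(seed),
             n_archipelagos = as.integer(n_archipelagos),
             islands_per_archipelago = as.integer(islands_per_archipelago),
             n_grid_points = as.integer(n_grid_points),
             species_per_island_target = as.integer(species_per_island_target),
             multi_island_fraction = multi_island_fraction,
             shift_scale = shift_scale,
             shift_profile = shift_profile[vars6],
             noise_sd = noise_sd[vars6],
             gcm_labels = gcm_labels,
             gcm_spread = gcm_spread,
             climate_base = climate_base,
             habitat_count_range = as.integer(habitat_count_range),
             diet_count_range = as.integer(diet_count_range),
             gl_meanlog = gl_meanlog, gl_sdlog = gl_sdlog,
             mass_meanlog = mass_meanlog, mass_sdlog = mass_sdlog,
             n_trait_levels = as.integer(n_trait_levels),
             mass_bins = as.integer(mass_bins),
             polytomy_fraction = polytomy_fraction,
             n_trees = as.integer(n_trees),
             pa_beta = pa_beta,
             extinct_beta = extinct_beta,
             richness_range = as.integer(richness_range),
             planted_archipelago = planted_archipelago)
  class(sc) <- "vuln_scenario"
  sc
}

#' @export
print.vuln_scenario <- function(x, ...) {
  cat("Synthetic island-vulnerability scenario\n")
  cat(sprintf("  seed %d | %d archipelagos x %d islands | target %d spp/island\n",
              x$seed, x$n_archipelagos, x$islands_per_archipelago,
              x$species_per_island_target))
  cat(sprintf("  %d GCM blocks | %d trees (polytomy fraction %.2f)\n",
              length(x$gcm_labels), x$n_trees, x$polytomy_fraction))
  if (!is.null(x$planted_archipelago))
    cat(sprintf("  planted vulnerable archipelago: %s\n",
                x$planted_archipelago))
  invisible(x)
}

#' Read or write a scenario as YAML
#'
#' @param path file path.
#' @return `read_scenario()` returns a `vuln_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("shift_profile", "noise_sd", "climate_base"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  do.call(vuln_scenario, cfg)
}

#' @param scenario a `vuln_scenario`.
#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "vuln_scenario"))
  out <- unclass(scenario)
  # named vectors must go out as YAML maps or their names are lost
  for (nm in c("shift_profile", "noise_sd", "climate_base"))
    out[[nm]] <- as.list(out[[nm]])
  # full double precision so a YAML round trip reproduces runs exactly
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}
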