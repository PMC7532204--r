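#' Generate the island table of a synthetic scenario
#'
#' Draws one row per island: archipelago membership, planar island centre
#' (km), number of climate grid points, protected-area fraction,
#' surrounding-land-mass proportions within three nested buffers, total
#' vertebrate richness and past extinction count. A planted archipelago (if
#' configured) receives zero protected-area coverage, zero surrounding land
#' mass (maximal geographic isolation) and zero past extinctions.
#'
#' @param scenario a [vuln_scenario()].
#' @return a data.frame with columns `island_id`, `archipelago_id`,
#'   `center_x`, `center_y`, `n_grid_points`, `pa_fraction`, `iso_100`,
#'   `iso_1000`, `iso_10000`, `extinct_count`, `total_richness`.
#' @export
generate_islands <- function(scenario) {
  stopifnot(inherits(scenario, "vuln_scenario"))
  na <- scenario$n_archipelagos
  ni <- scenario$islands_per_archipelago
  withr::with_seed(stage_seed(scenario$seed, "islands"), {
    arch_id <- paste0("A", seq_len(na))
    # archipelago centres spread over a 2000 km square, islands within 100 km
    ax <- stats::runif(na, 0, 2000)
    ay <- stats::runif(na, 0, 2000)
    rows <- vector("list", na)
    for (a in seq_len(na)) {
      iso <- t(apply(matrix(stats::runif(ni * 3), ni), 1, sort))
      richness <- sample(scenario$richness_range[1]:scenario$richness_range[2],
                         ni, replace = TRUE)
      ext_p <- stats::rbeta(ni, scenario$extinct_beta[1],
                            scenario$extinct_beta[2])
      rows[[a]] <- data.frame(
        island_id = paste0(arch_id[a], "_I", seq_len(ni)),
        archipelago_id = arch_id[a],
        center_x = ax[a] + stats::runif(ni, -100, 100),
        center_y = ay[a] + stats::runif(ni, -100, 100),
        n_grid_points = sample(scenario$n_grid_points[1]:scenario$n_grid_points[2],
                               ni, replace = TRUE),
        pa_fraction = stats::rbeta(ni, scenario$pa_beta[1], scenario$pa_beta[2]),
        iso_100 = iso[, 1], iso_1000 = iso[, 2], iso_10000 = iso[, 3],
        extinct_count = stats::rbinom(ni, richness, ext_p),
        total_richness = richness,
        stringsAsFactors = FALSE)
    }
    islands <- do.call(rbind, rows)
    planted <- scenario$planted_archipelago
    if (!is.null(planted)) {
      if (!planted %in% islands$archipelago_id)
        stopf("planted archipelago '%s' not among generated ids", planted)
      sel <- islands$archipelago_id == planted
      islands$pa_fraction[sel] <- 0
      islands$iso_100[sel] <- 0
      islands$iso_1000[sel] <- 0
      islands$iso_10000[sel] <- 0
      islands$extinct_count[sel] <- 0L
    }
    rownames(islands) <- NULL
    islands
  })
}

#' Generate paired current/future climate grids
#'
#' Produces one row per (island, grid point, future scenario block). Current
#' values of the six climate variables are the scenario baseline plus an
#' island-level offset plus point-level variation; the two seasonality
#' standardizers are drawn log-normal per point (strictly positive by
#' construction, and guarded by resampling should a non-positive value ever
#' arise). Future values add the archipelago shift (scaled by a per-GCM
#' multiplier) and Gaussian noise. Grid points carry planar x,y coordinates
#' (km) around the island centre.
#'
#' The planted archipelago (if any) receives a shift of three times the
#' maximal configured `shift_scale`.
#'
#' @param islands an island table from [generate_islands()].
#' @param scenario the same [vuln_scenario()].
#' @return a data.frame with columns `island_id`, `point_id`, `x`, `y`,
#'   `scenario`, `cur_*` (6), `fut_*` (6), `s_temp`, `s_prec`.
#' @export
generate_climate <- function(islands, scenario) {
  stopifnot(inherits(scenario, "vuln_scenario"))
  if (any(islands$n_grid_points < 1))
    stopf("every island needs n_grid_points >= 1")
  vars6 <- names(scenario$shift_profile)
  base <- scenario$climate_base
  gcms <- scenario$gcm_labels
  mult <- if (length(gcms) == 1L) 1 else
    seq(1 - scenario$gcm_spread, 1 + scenario$gcm_spread,
        length.out = length(gcms))
  arch_ids <- unique(islands$archipelago_id)
  shift_by_arch <- stats::setNames(scenario$shift_scale[seq_along(arch_ids)],
                                   arch_ids)
  planted <- scenario$planted_archipelago
  if (!is.null(planted))
    shift_by_arch[planted] <- 3 * max(scenario$shift_scale)
  # island-level variation of the current climate, relative to baseline
  island_sd <- c(2, 2, 2, 300, 60, 15)
  point_sd <- island_sd / 10
  withr::with_seed(stage_seed(scenario$seed, "climate"), {
    out <- vector("list", nrow(islands))
    for (i in seq_len(nrow(islands))) {
      isl <- islands[i, ]
      np <- isl$n_grid_points
      cur <- matrix(rep(base[vars6], each = np), nrow = np)
      cur <- cur + matrix(rep(stats::rnorm(6, 0, island_sd), each = np),
                          nrow = np)
      cur <- cur + sapply(point_sd, function(s) stats::rnorm(np, 0, s))
      rlnorm_pos <- function(n, m) {
        x <- stats::rlnorm(n, log(m), 0.3)
        while (any(x <= 0)) x[x <= 0] <- stats::rlnorm(sum(x <= 0), log(m), 0.3)
        x
      }
      s_temp <- rlnorm_pos(np, base[["s_temp"]])
      s_prec <- rlnorm_pos(np, base[["s_prec"]])
      x <- isl$center_x + stats::runif(np, -5, 5)
      y <- isl$center_y + stats::runif(np, -5, 5)
      shift <- shift_by_arch[[isl$archipelago_id]] * scenario$shift_profile
      blocks <- vector("list", length(gcms))
      for (g in seq_along(gcms)) {
        fut <- cur + matrix(rep(mult[g] * shift, each = np), nrow = np) +
          sapply(scenario$noise_sd, function(s)
            if (s > 0) stats::rnorm(np, 0, s) else numeric(np))
        df <- data.frame(island_id = isl$island_id, point_id = seq_len(np),
                         x = x, y = y, scenario = gcms[g],
                         stringsAsFactors = FALSE)
        df[paste0("cur_", vars6)] <- as.data.frame(cur)
        df[paste0("fut_", vars6)] <- as.data.frame(fut)
        df$s_temp <- s_temp
        df$s_prec <- s_prec
        blocks[[g]] <- df
      }
      out[[i]] <- do.call(rbind, blocks)
    }
    grid <- do.call(rbind, out)
    rownames(grid) <- NULL
    grid
  })
}

#' Generate species traits and the island-occurrence matrix
#'
#' Each island receives single-island endemics plus, when
#' `multi_island_fraction > 0`, species from an archipelago-shared pool
#' (multi-island endemics never cross archipelagos). Every island's species
#' count strictly exceeds 5. Traits are drawn per the scenario
#' distributions; species of the planted archipelago are maximally
#' specialized (one habitat, one diet) with tripled generation length.
#'
#' @param islands an island table from [generate_islands()].
#' @param scenario the same [vuln_scenario()].
#' @return a list with `traits` (one row per species: `species_id`,
#'   `habitats` and `diets` as pipe-delimited category strings,
#'   `generation_length`, `main_diet`, `foraging_niche`, `foraging_period`,
#'   `habitat_niche_breadth`, `body_mass`) and `occurrences` (long format:
#'   `island_id`, `species_id`).
#' @export
generate_species <- function(islands, scenario) {
  stopifnot(inherits(scenario, "vuln_scenario"))
  tgt <- scenario$species_per_island_target
  if (tgt <= 5) stopf("species_per_island_target must exceed 5")
  f <- scenario$multi_island_fraction
  withr::with_seed(stage_seed(scenario$seed, "species"), {
    occ <- list()
    next_id <- 1L
    new_ids <- function(n) {
      ids <- sprintf("sp%04d", seq.int(next_id, length.out = n))
      next_id <<- next_id + n
      ids
    }
    for (arch in unique(islands$archipelago_id)) {
      isl_ids <- islands$island_id[islands$archipelago_id == arch]
      m <- length(isl_ids)
      n_shared_per_island <- if (m > 1) round(f * tgt) else 0L
      n_single <- tgt - n_shared_per_island
      # shared pool sized for ~2 islands per multi-island endemic; a pool
      # species drawn by a single island stays a single-island endemic
      shared_pool <- if (n_shared_per_island > 0)
        new_ids(max(n_shared_per_island, round(n_shared_per_island * m / 2)))
      else character(0)
      for (isl in isl_ids) {
        shared <- if (length(shared_pool) > 0)
          sample(shared_pool, n_shared_per_island) else character(0)
        # extra singletons so endemic richness varies around the target
        extra <- sample(0:max(1L, round(tgt / 2)), 1L)
        occ[[length(occ) + 1L]] <- data.frame(
          island_id = isl, species_id = c(new_ids(n_single + extra), shared),
          stringsAsFactors = FALSE)
      }
    }
    occurrences <- do.call(rbind, occ)
    occurrences <- occurrences[!duplicated(occurrences), ]
    rownames(occurrences) <- NULL
    species <- sort(unique(occurrences$species_id))
    n <- length(species)
    lv <- function(pre) paste0(pre, seq_len(scenario$n_trait_levels))
    draw_cats <- function(k_range) {
      vapply(seq_len(n), function(i) {
        k <- sample(k_range[1]:k_range[2], 1)
        paste(sample(paste0("cat", 1:10), k), collapse = "|")
      }, character(1))
    }
    traits <- data.frame(
      species_id = species,
      habitats = draw_cats(scenario$habitat_count_range),
      diets = draw_cats(scenario$diet_count_range),
      generation_length = stats::rlnorm(n, scenario$gl_meanlog,
                                        scenario$gl_sdlog),
      main_diet = sample(lv("diet"), n, replace = TRUE),
      foraging_niche = sample(lv("niche"), n, replace = TRUE),
      foraging_period = sample(lv("period"), n, replace = TRUE),
      habitat_niche_breadth = sample(lv("breadth"), n, replace = TRUE),
      body_mass = stats::rlnorm(n, scenario$mass_meanlog, scenario$mass_sdlog),
      stringsAsFactors = FALSE)
    planted <- scenario$planted_archipelago
    if (!is.null(planted)) {
      planted_sp <- unique(occurrences$species_id[
        occurrences$island_id %in%
          islands$island_id[islands$archipelago_id == planted]])
      sel <- traits$species_id %in% planted_sp
      pick1 <- function(x) vapply(strsplit(x, "|", fixed = TRUE),
                                  `[`, character(1), 1)
      traits$habitats[sel] <- pick1(traits$habitats[sel])
      traits$diets[sel] <- pick1(traits$diets[sel])
      traits$generation_length[sel] <- 3 * traits$generation_length[sel]
    }
    list(traits = traits, occurrences = occurrences)
  })
}

#' Generate an ensemble of phylogenies with polytomies
#'
#' Each tree is an independent random rooted topology over the same tip set
#' with branch lengths drawn uniform on (0.1, 1); a `polytomy_fraction`
#' share of internal edges is then collapsed to multifurcations (their
#' length removed), emulating unresolved relationships. Retained edges keep
#' strictly positive lengths.
#'
#' @param species_labels character vector of >= 2 tip labels.
#' @param scenario the [vuln_scenario()] (uses `n_trees`,
#'   `polytomy_fraction`, and the tree-stage seed).
#' @return an `ape::multiPhylo` of `n_trees` trees sharing the tip set.
#' @export
generate_phylogenies <- function(species_labels, scenario) {
  stopifnot(inherits(scenario, "vuln_scenario"))
  n <- length(species_labels)
  if (n < 2) stopf("need >= 2 species labels to build a phylogeny, got %d", n)
  withr::with_seed(stage_seed(scenario$seed, "trees"), {
    trees <- vector("list", scenario$n_trees)
    for (i in seq_len(scenario$n_trees)) {
      tr <- ape::rtree(n, tip.label = sample(species_labels),
                       br = function(k) stats::runif(k, 0.1, 1))
      internal <- which(tr$edge[, 2] > n)
      k <- floor(scenario$polytomy_fraction * length(internal))
      if (k > 0) {
        tr$edge.length[sample(internal, k)] <- 0
        tr <- ape::di2multi(tr, tol = 1e-12)
      }
      trees[[i]] <- tr
    }
    class(trees) <- "multiPhylo"
    trees
  })
}

#' Write all synthetic tables of a scenario to a directory
#'
#' Writes `islands.csv`, `climate_grid.csv`, `traits.csv`,
#' `occurrences.csv` (long format) and `trees.nwk` (multi-tree Newick).
#'
#' @param scenario a [vuln_scenario()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
simulate_to_dir <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  islands <- generate_islands(scenario)
  grid <- generate_climate(islands, scenario)
  sp <- generate_species(islands, scenario)
  trees <- generate_phylogenies(sp$traits$species_id, scenario)
  utils::write.csv(islands, file.path(dir, "islands.csv"), row.names = FALSE)
  utils::write.csv(grid, file.path(dir, "climate_grid.csv"), row.names = FALSE)
  utils::write.csv(sp$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(sp$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  ape::write.tree(trees, file.path(dir, "trees.nwk"))
  invisible(dir)
}
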