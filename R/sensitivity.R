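# Sensitivity: four species-level variables (habitat specialization,
# dietary specialization, generation length, ecological redundancy)
# averaged per island over the occupying endemics.

split_cats <- function(x) {
  if (is.list(x)) return(lapply(x, unique))
  lapply(strsplit(as.character(x), "|", fixed = TRUE), unique)
}

#' Habitat and dietary breadth of species
#'
#' The number of distinct habitat (or diet) categories a species uses.
#' Duplicated categories collapse before counting; fewer categories means a
#' more specialized — hence more sensitive — species.
#'
#' @param x a character vector of pipe-delimited category strings (e.g.
#'   `"forest|shrubland"`) or a list of category vectors.
#' @return an integer vector of category counts (each >= 1).
#' @export
habitat_breadth <- function(x) {
  sets <- split_cats(x)
  n <- vapply(sets, function(s) length(s[nzchar(s)]), integer(1))
  if (any(n == 0L)) stopf("empty habitat list for %d species", sum(n == 0L))
  n
}

#' @rdname habitat_breadth
#' @export
diet_breadth <- function(x) {
  sets <- split_cats(x)
  n <- vapply(sets, function(s) length(s[nzchar(s)]), integer(1))
  if (any(n == 0L)) stopf("empty diet list for %d species", sum(n == 0L))
  n
}

#' Group species into functional entities
#'
#' A functional entity is a group of species with an identical combination
#' of categorized ecological traits: main diet, foraging niche, foraging
#' period, habitat niche breadth, and a body-mass category. Body mass is
#' binned into `mass_bins` quantile bins of log10 mass over the full
#' species pool (quantile bins avoid empty classes under skewed masses).
#'
#' @param traits a species trait table (see [generate_species()]); needs
#'   columns `species_id`, `main_diet`, `foraging_niche`, `foraging_period`,
#'   `habitat_niche_breadth`, `body_mass`.
#' @param mass_bins number of body-mass quantile bins (>= 1).
#' @return a list with `assignment` (data.frame `species_id`, `entity_id`)
#'   and `sizes` (named integer vector of entity member counts).
#' @export
assign_entities <- function(traits, mass_bins = 4L) {
  check_number(mass_bins, "mass_bins", lower = 1)
  cats <- c("main_diet", "foraging_niche", "foraging_period",
            "habitat_niche_breadth")
  for (cc in cats)
    if (any(is.na(traits[[cc]]) | !nzchar(traits[[cc]])))
      stopf("missing values in trait '%s'", cc)
  stopifnot(all(traits$body_mass > 0))
  lm <- log10(traits$body_mass)
  breaks <- unique(stats::quantile(lm, probs = seq(0, 1, length.out = mass_bins + 1)))
  mass_bin <- if (length(breaks) < 2L) rep(1L, length(lm)) else
    as.integer(cut(lm, breaks, include.lowest = TRUE))
  entity_id <- paste(traits$main_diet, traits$foraging_niche,
                     traits$foraging_period, traits$habitat_niche_breadth,
                     paste0("m", mass_bin), sep = "::")
  assignment <- data.frame(species_id = traits$species_id,
                           entity_id = entity_id, stringsAsFactors = FALSE)
  sizes <- table(entity_id)
  list(assignment = assignment,
       sizes = stats::setNames(as.integer(sizes), names(sizes)))
}

#' Ecological redundancy of species
#'
#' The number of species sharing a species' functional entity, counting the
#' species itself — a functionally unique species has redundancy 1.
#'
#' @param species_ids species to look up.
#' @param assignment the result of [assign_entities()].
#' @return an integer vector, same length as `species_ids`.
#' @export
redundancy <- function(species_ids, assignment) {
  idx <- match(species_ids, assignment$assignment$species_id)
  if (anyNA(idx))
    stopf("species not assigned to an entity: %s",
          paste(species_ids[is.na(idx)], collapse = ", "))
  unname(assignment$sizes[assignment$assignment$entity_id[idx]])
}

#' Per-island raw sensitivity variables
#'
#' Arithmetic means, over the island's occupying species, of habitat
#' breadth, dietary breadth, generation length (years) and ecological
#' redundancy. Multi-island endemics contribute to every island they
#' occupy. Values are raw (unstandardized, unoriented); direction flips
#' happen once, in scoring.
#'
#' @param island_id island to evaluate (or a vector; one row each).
#' @param occurrences long-format occurrence table (`island_id`,
#'   `species_id`).
#' @param traits the species trait table.
#' @param assignment the result of [assign_entities()] on the full pool.
#' @return a data.frame `island_id`, `habitat_breadth`, `diet_breadth`,
#'   `generation_length`, `redundancy`.
#' @export
island_sensitivity <- function(island_id, occurrences, traits, assignment) {
  hb <- habitat_breadth(traits$habitats)
  db <- diet_breadth(traits$diets)
  rd <- redundancy(traits$species_id, assignment)
  rows <- lapply(island_id, function(isl) {
    sp <- occurrences$species_id[occurrences$island_id == isl]
    if (length(sp) == 0L)
      stopf("island '%s' has no occupying species (should be filtered upstream)",
            isl)
    idx <- match(sp, traits$species_id)
    if (anyNA(idx))
      stopf("species without traits on island '%s': %s", isl,
            paste(sp[is.na(idx)], collapse = ", "))
    data.frame(island_id = isl,
               habitat_breadth = mean(hb[idx]),
               diet_breadth = mean(db[idx]),
               generation_length = mean(traits$generation_length[idx]),
               redundancy = mean(rd[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
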