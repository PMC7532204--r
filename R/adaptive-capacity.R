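# Adaptive capacity: surrounding land mass (geographic isolation),
# protected-area coverage, fair-proportion evolutionary distinctiveness
# over a tree ensemble, and past extinction rate.

#' Randomly resolve polytomies in a tree
#'
#' Replaces every multifurcation by a uniformly random sequence of
#' bifurcations; inserted edges have length 0, so the tip set and total
#' branch length are unchanged. Binary trees are returned untouched.
#'
#' @param tree an `ape::phylo`.
#' @param seed optional integer seed making the resolution reproducible
#'   (the caller's RNG state is preserved).
#' @return a binary `ape::phylo`.
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.binary(tree)) return(tree)
  if (is.null(seed)) return(ape::multi2di(tree, random = TRUE))
  withr::with_seed(as.integer(seed), ape::multi2di(tree, random = TRUE))
}

#' Fair-proportion evolutionary distinctiveness
#'
#' For each tip, the sum over the edges on its root-to-tip path of the edge
#' length divided by the number of tips descending from that edge: every
#' branch's length is split equally among the tips it supports. Summed over
#' all tips this returns the tree's total branch length. Polytomies are
#' allowed (the divisor is the descendant-tip count regardless of degree).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return a named numeric vector of FP values, one per tip.
#' @export
fair_proportion <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  tree <- stats::reorder(tree, "postorder")
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  ndesc <- numeric(nnode)
  ndesc[seq_len(n)] <- 1
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]
  for (i in seq_along(e1))              # children precede parents
    ndesc[e1[i]] <- ndesc[e1[i]] + ndesc[e2[i]]
  acc <- numeric(nnode)                 # FP accumulated root -> node
  for (i in rev(seq_along(e1)))         # reverse postorder = preorder
    acc[e2[i]] <- acc[e1[i]] + tree$edge.length[i] / ndesc[e2[i]]
  stats::setNames(acc[seq_len(n)], tree$tip.label)
}

#' Ensemble fair proportion over many trees
#'
#' Resolves each tree's polytomies at random (seeded per tree), computes
#' fair proportion, and returns the per-species mean across trees —
#' averaging over phylogenetic uncertainty the way distinctiveness is
#' usually computed on posterior tree sets.
#'
#' @param trees an `ape::multiPhylo` (or list of `phylo`) over one tip set.
#' @param seed integer seed governing all polytomy resolutions.
#' @return a named numeric vector of per-species mean FP.
#' @export
fp_ensemble <- function(trees, seed = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stopf("need at least one tree")
  tips <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), tips))
      stopf("tree %d has a different tip set", i)
  acc <- stats::setNames(numeric(length(tips)), tips)
  for (i in seq_along(trees)) {
    tr <- resolve_polytomies(trees[[i]], seed = stage_seed(seed, "resolve", i))
    fp <- fair_proportion(tr)
    acc <- acc + fp[tips]
  }
  acc / length(trees)
}

#' Surrounding-land-mass score of an island
#'
#' The sum of the proportions of land mass within the three nested buffer
#' distances (100, 1000 and 10,000 km) around the island. High values mean
#' much nearby land — potential climate refuges — i.e. LOW geographic
#' isolation; the score therefore enters adaptive capacity positively.
#'
#' @param proportions numeric length-3 vector of proportions in [0, 1]
#'   (small, medium, large buffer).
#' @return their sum, in [0, 3].
#' @export
geographic_isolation <- function(proportions) {
  stopifnot(length(proportions) == 3L)
  if (any(!is.finite(proportions) | proportions < 0 | proportions > 1))
    stopf("land-mass proportions must lie in [0, 1]")
  sum(proportions)
}

#' Past extinction rate of an island
#'
#' The ratio of recorded vertebrate extinctions (since 1500 CE) to the
#' island's total vertebrate richness. Under the extinction-filter
#' hypothesis the surviving pool of a high-extinction island is enriched in
#' resistant species, so this rate enters adaptive capacity positively.
#'
#' @param extinct_count non-negative integer, `<= total_richness`.
#' @param total_richness positive integer.
#' @return the ratio, in [0, 1].
#' @export
extinction_rate <- function(extinct_count, total_richness) {
  if (total_richness <= 0) stopf("total_richness must be > 0")
  if (extinct_count < 0 || extinct_count > total_richness)
    stopf("extinct_count must lie in [0, total_richness]")
  extinct_count / total_richness
}

#' Per-island raw adaptive-capacity variables
#'
#' One row per island: the surrounding-land-mass sum, protected-area
#' fraction, mean ensemble fair proportion over the occupying species, and
#' extinction rate.
#'
#' @param islands the island table ([generate_islands()] column contract).
#' @param occurrences long-format occurrence table.
#' @param fp_means named per-species FP vector from [fp_ensemble()].
#' @return a data.frame `island_id`, `isolation_sum`, `pa_fraction`,
#'   `mean_fp`, `extinction_rate`.
#' @export
island_adaptive <- function(islands, occurrences, fp_means) {
  rows <- lapply(seq_len(nrow(islands)), function(i) {
    isl <- islands[i, ]
    sp <- occurrences$species_id[occurrences$island_id == isl$island_id]
    missing <- setdiff(sp, names(fp_means))
    if (length(missing) > 0)
      stopf("species missing from the tree tip set on island '%s': %s",
            isl$island_id, paste(missing, collapse = ", "))
    data.frame(island_id = isl$island_id,
               isolation_sum = geographic_isolation(
                 c(isl$iso_100, isl$iso_1000, isl$iso_10000)),
               pa_fraction = isl$pa_fraction,
               mean_fp = mean(fp_means[sp]),
               extinction_rate = extinction_rate(isl$extinct_count,
                                                 isl$total_richness),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
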