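# Small seeded fixtures shared across test files.

tiny_scenario <- function(...) {
  args <- utils::modifyList(
    list(seed = 11L, n_archipelagos = 2L, islands_per_archipelago = 3L,
         n_grid_points = c(5L, 8L), species_per_island_target = 6L,
         gcm_labels = c("GCM1", "GCM2"), n_trees = 5L),
    list(...))
  do.call(vuln_scenario, args)
}

# a random rooted tree, optionally with collapsed internal edges
random_test_tree <- function(n_tips, polytomies = FALSE) {
  tr <- ape::rtree(n_tips, br = function(k) stats::runif(k, 0.1, 1))
  if (polytomies && n_tips > 3) {
    internal <- which(tr$edge[, 2] > n_tips)
    k <- max(1L, floor(0.3 * length(internal)))
    tr$edge.length[sample(internal, k)] <- 0
    tr <- ape::di2multi(tr, tol = 1e-12)
  }
  tr
}

# raw island-level variable table with independent uniform columns
random_raw_vars <- function(n_islands, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(island_id = sprintf("I%03d", seq_len(n_islands)))
    for (v in default_variable_spec()$name)
      df[[v]] <- stats::runif(n_islands)
    df
  })
}
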