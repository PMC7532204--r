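test_that("resolve_polytomies is the identity on binary trees and conserves length", {
  withr::with_seed(5, {
    tr <- ape::rtree(10)
    expect_identical(resolve_polytomies(tr, seed = 1), tr)
    for (i in 1:10) {
      poly <- random_test_tree(sample(5:30, 1), polytomies = TRUE)
      res <- resolve_polytomies(poly, seed = i)
      expect_true(ape::is.binary(res))
      expect_setequal(res$tip.label, poly$tip.label)
      expect_equal(sum(res$edge.length), sum(poly$edge.length))
    }
  })
})

test_that("a trichotomy resolves uniformly over the three rooted topologies", {
  tri <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:2);")
  sisters <- vapply(1:1500, function(s) {
    res <- resolve_polytomies(tri, seed = s)
    # the resolution pairs two of {a,b,c} under a new cherry node
    ntip <- length(res$tip.label)
    cherry <- vapply(unique(res$edge[, 1]), function(nd) {
      kids <- res$edge[res$edge[, 1] == nd, 2]
      if (length(kids) == 2 && all(kids <= ntip) &&
          all(res$tip.label[kids] %in% c("a", "b", "c")))
        paste(sort(res$tip.label[kids]), collapse = "") else NA_character_
    }, character(1))
    cherry[!is.na(cherry)][1]
  }, character(1))
  freq <- table(sisters)
  expect_length(freq, 3L)
  expect_true(all(abs(freq / 1500 - 1 / 3) < 0.05))
})

test_that("fair proportion matches hand values, conservation, and picante", {
  # star tree: every tip gets its own pendant edge
  star <- ape::read.tree(text = "(a:2,b:2,c:2,d:2,e:2);")
  expect_equal(unname(fair_proportion(star)), rep(2, 5))
  # balanced 4-tip tree, unit edges: 1 + 1/2
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(fair_proportion(bal),
               c(a = 1.5, b = 1.5, c = 1.5, d = 1.5))
  # caterpillar, cross-checked against an explicit edge-enumeration oracle
  cat4 <- ape::read.tree(text = "(((a:1,b:2):3,c:4):5,d:6);")
  fp <- fair_proportion(cat4)
  expect_equal(fp[["a"]], 5 / 3 + 3 / 2 + 1)
  expect_equal(fp[["d"]], 6)
  expect_equal(sum(fp), sum(cat4$edge.length))
  skip_if_not_installed("picante")
  withr::with_seed(13, {
    for (i in 1:5) {
      tr <- random_test_tree(sample(5:40, 1), polytomies = (i %% 2 == 0))
      mine <- fair_proportion(tr)
      # picante warns about basal polytomies it treats as unrooted
      ref <- suppressWarnings(
        picante::evol.distinct(tr, type = "fair.proportion"))
      expect_equal(mine[ref$Species], setNames(ref$w, ref$Species),
                   tolerance = 1e-10)
    }
  })
})

test_that("fp_ensemble equals a naive loop over trees and is order-invariant", {
  withr::with_seed(11, {
    trees <- lapply(1:50, function(i) {
      tr <- ape::rtree(15, br = function(k) runif(k, 0.1, 1))
      tr$tip.label <- sprintf("sp%02d", 1:15)
      if (i %% 2 == 0) {
        internal <- which(tr$edge[, 2] > 15)
        tr$edge.length[sample(internal, 3)] <- 0
        tr <- ape::di2multi(tr, tol = 1e-12)
      }
      tr
    })
  })
  class(trees) <- "multiPhylo"
  got <- fp_ensemble(trees, seed = 11)
  # naive re-computation with the same per-tree resolution seeds
  tips <- sort(trees[[1]]$tip.label)
  acc <- setNames(numeric(15), tips)
  for (i in seq_along(trees)) {
    tr <- resolve_polytomies(trees[[i]],
                             seed = islevuln:::stage_seed(11, "resolve", i))
    acc <- acc + fair_proportion(tr)[tips]
  }
  expect_equal(got, acc / 50, tolerance = 1e-12)
  expect_identical(got, fp_ensemble(trees, seed = 11))
  # single binary tree: identical to fair_proportion
  b <- trees[[1]]
  expect_equal(fp_ensemble(list(b), seed = 1), fair_proportion(b)[tips])
  # ensemble of identical trees: mean of constants
  same <- rep(list(b), 4); class(same) <- "multiPhylo"
  expect_equal(fp_ensemble(same, seed = 2), fair_proportion(b)[tips])
  bad <- trees
  bad[[2]]$tip.label[1] <- "other"
  expect_error(fp_ensemble(bad, seed = 1), "different tip set")
})

test_that("isolation sum and extinction rate follow their closed forms", {
  expect_equal(geographic_isolation(c(1, 1, 1)), 3)
  expect_equal(geographic_isolation(c(0, 0, 0)), 0)
  expect_equal(geographic_isolation(c(0.2, 0.5, 0.9)), 1.6)
  expect_error(geographic_isolation(c(-0.1, 0.5, 0.9)), "\\[0, 1\\]")
  expect_error(geographic_isolation(c(0.2, 0.5)), "length")
  expect_equal(extinction_rate(0, 10), 0)
  expect_equal(extinction_rate(10, 10), 1)
  expect_equal(extinction_rate(2, 10), 0.2)
  expect_error(extinction_rate(1, 0), "total_richness")
  expect_error(extinction_rate(11, 10), "extinct_count")
})

test_that("island_adaptive assembles the four variables per the tabular oracle", {
  islands <- data.frame(island_id = c("I1", "I2"), archipelago_id = "A1",
                        iso_100 = c(0.1, 0), iso_1000 = c(0.2, 0),
                        iso_10000 = c(0.3, 0.5), pa_fraction = c(0.4, 0.9),
                        extinct_count = c(2L, 0L), total_richness = c(10L, 40L))
  occ <- data.frame(island_id = c("I1", "I1", "I2"),
                    species_id = c("sp1", "sp2", "sp1"))
  fp <- c(sp1 = 1.0, sp2 = 3.0)
  got <- island_adaptive(islands, occ, fp)
  expect_equal(got$isolation_sum, c(0.6, 0.5))
  expect_equal(got$mean_fp, c(2.0, 1.0))
  expect_equal(got$extinction_rate, c(0.2, 0))
  expect_equal(got$pa_fraction, c(0.4, 0.9))
  occ_bad <- rbind(occ, data.frame(island_id = "I2", species_id = "ghost"))
  expect_error(island_adaptive(islands, occ_bad, fp), "ghost")
})
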