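test_that("correlation screen matches the rank formula and flags collinearity", {
  rv <- random_raw_vars(30, seed = 3)
  scr <- correlation_screen(rv)
  # only within-component pairs: C(4,2) for sensitivity + C(4,2) for AC
  expect_equal(nrow(scr), 12L)
  expect_true(all(scr$rho >= -1 & scr$rho <= 1))
  # self-correlation and antithetic variables
  rv2 <- rv
  rv2$diet_breadth <- rv2$habitat_breadth
  rv2$redundancy <- -rv2$habitat_breadth
  scr2 <- correlation_screen(rv2)
  pick <- function(s, v1, v2)
    s$rho[(s$var1 == v1 & s$var2 == v2) | (s$var1 == v2 & s$var2 == v1)]
  expect_equal(pick(scr2, "habitat_breadth", "diet_breadth"), 1)
  expect_equal(pick(scr2, "habitat_breadth", "redundancy"), -1)
  expect_true(all(scr2$flagged[abs(scr2$rho) >= 0.7]))
  # hand value: ranks (1,2,3,4) vs (1,3,2,4), sum d^2 = 2 -> rho = 0.8
  rv3 <- random_raw_vars(4, seed = 4)
  rv3$habitat_breadth <- c(1, 2, 3, 4)
  rv3$diet_breadth <- c(1, 3, 2, 4)
  expect_equal(pick(correlation_screen(rv3), "habitat_breadth",
                    "diet_breadth"), 0.8)
  # constant column: NA with warning
  rv4 <- rv
  rv4$pa_fraction <- 0.5
  w <- capture_warnings(scr4 <- correlation_screen(rv4))
  expect_true(length(w) > 0 && all(grepl("constant", w)))
  expect_true(anyNA(scr4$rho[scr4$var1 == "pa_fraction" |
                               scr4$var2 == "pa_fraction"]))
})

test_that("independent variables are rarely flagged at n = 100 islands", {
  flagged <- vapply(1:40, function(s) {
    any(correlation_screen(random_raw_vars(100, seed = 1000 + s))$flagged)
  }, logical(1))
  expect_gte(mean(!flagged), 0.95)
})

test_that("leave-one-out congruence matches a from-scratch re-run oracle", {
  rv <- random_raw_vars(25, seed = 6)
  spec <- default_variable_spec()
  expect_message(loo <- leave_one_out(rv, spec, "minmax"), "skipping")
  expect_equal(nrow(loo), 8L)       # exposure's single variable is skipped
  expect_true(all(loo$rho_vulnerability >= -1 & loo$rho_vulnerability <= 1))
  # unaffected components keep rho = 1
  expect_true(all(loo$rho_exposure == 1))
  # oracle: drop a variable by hand and re-run the pipeline independently
  v <- "generation_length"
  red_spec <- spec[spec$name != v, ]
  full <- topsis(component_scores(rv, spec, "minmax"))
  red <- topsis(component_scores(rv, red_spec, "minmax"))
  expect_equal(loo$rho_vulnerability[loo$dropped_variable == v],
               cor(full$vulnerability, red$vulnerability,
                   method = "spearman"))

  # a component made of an exact duplicate pair: dropping either copy halves
  # the sum without touching ranks, so congruence is perfect
  spec2 <- spec[spec$name %in% c("mean_sed", "habitat_breadth",
                                 "diet_breadth", "isolation_sum",
                                 "pa_fraction"), ]
  rv2 <- rv
  rv2$diet_breadth <- rv2$habitat_breadth
  loo2 <- suppressMessages(leave_one_out(rv2, spec2, "minmax"))
  expect_equal(loo2$rho_sensitivity[loo2$dropped_variable == "diet_breadth"],
               1)
})

test_that("leave-one-out survives a degenerate constant-sum component", {
  # two antithetic variables cancel: the full sensitivity sum is constant
  spec <- data.frame(
    name = c("mean_sed", "habitat_breadth", "diet_breadth",
             "isolation_sum", "pa_fraction"),
    component = c("exposure", "sensitivity", "sensitivity",
                  "adaptive_capacity", "adaptive_capacity"),
    direction = c("increases_component", "increases_component",
                  "decreases_component", "increases_component",
                  "increases_component"),
    stringsAsFactors = FALSE)
  rv <- random_raw_vars(10, seed = 8)[c("island_id", "mean_sed",
                                        "habitat_breadth", "isolation_sum",
                                        "pa_fraction")]
  rv$diet_breadth <- rv$habitat_breadth   # oriented copies sum to 1
  loo <- suppressWarnings(suppressMessages(leave_one_out(rv, spec, "minmax")))
  row <- loo[loo$dropped_variable == "habitat_breadth", ]
  expect_true(is.na(row$rho_sensitivity))
})

test_that("archipelago summary: means, sample sd, ranks, high fraction", {
  islands <- data.frame(island_id = paste0("I", 1:6),
                        archipelago_id = c("A", "A", "A", "B", "B", "C"))
  vuln <- data.frame(island_id = paste0("I", 1:6),
                     vulnerability = c(0.2, 0.4, 0.9, 0.7, 0.3, 0.4))
  s <- archipelago_summary(vuln, islands)
  a <- s[s$archipelago_id == "A", ]
  expect_equal(a$mean_vulnerability, 0.5)
  expect_equal(a$sd, sqrt(sum((c(0.2, 0.4, 0.9) - 0.5)^2) / 2))
  expect_equal(a$sd, 0.3605551, tolerance = 1e-6)
  expect_equal(a$frac_high, 1 / 3)
  expect_equal(s$sd[s$archipelago_id == "C"], 0)   # singleton
  expect_setequal(s$rank, 1:3)
  expect_equal(s$archipelago_id[s$rank == 1], "A")  # 0.5 beats B's 0.5? no:
  # A mean 0.5, B mean 0.5 -> tie broken by first occurrence; C mean 0.4 last
  expect_equal(s$archipelago_id[s$rank == 3], "C")
  # archipelago means bounded by island extremes
  expect_true(all(s$mean_vulnerability >= tapply(vuln$vulnerability,
    islands$archipelago_id, min)[s$archipelago_id]))
  expect_error(archipelago_summary(
    data.frame(island_id = "X", vulnerability = 0.1), islands), "missing")
})

test_that("association report reproduces hand rank correlations", {
  vuln <- data.frame(island_id = paste0("I", 1:4),
                     vulnerability = c(1, 2, 3, 4) / 10)
  pred <- data.frame(island_id = paste0("I", 1:4),
                     same = c(1, 2, 3, 4),
                     worked = c(2, 1, 4, 3))
  rep <- suppressWarnings(association_report(vuln, pred))
  expect_equal(rep$rho[rep$predictor == "same"], 1)
  # ranks (1,2,3,4) vs (2,1,4,3): sum d^2 = 4 -> rho = 1 - 24/60 = 0.6
  expect_equal(rep$rho[rep$predictor == "worked"], 0.6)
  expect_error(association_report(vuln[1:3, ], pred[1:3, ]), ">= 4")
  # order invariance
  rep2 <- suppressWarnings(association_report(vuln[4:1, ], pred))
  expect_equal(rep2$rho, rep$rho)
})

test_that("planted generation-length signal surfaces as a positive association", {
  sc <- tiny_scenario(n_archipelagos = 4L, islands_per_archipelago = 6L,
                      species_per_island_target = 8L, seed = 17L,
                      planted_archipelago = "A4", n_trees = 8L)
  b <- suppressMessages(suppressWarnings(run_pipeline(list(scenario = sc))))
  rho_gl <- b$associations$rho[b$associations$predictor == "generation_length"]
  expect_gt(rho_gl, 0)
})
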