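# Robustness and descriptive analyses: variable correlation screen,
# leave-one-variable-out congruence, archipelago roll-ups, and
# trait/component/richness associations with vulnerability.

#' Pairwise correlation screen within components
#'
#' Spearman correlations between all variable pairs within each component,
#' flagging pairs at or beyond the conventional collinearity threshold
#' (|rho| >= 0.7 by default). A constant column yields `NA` with a warning.
#'
#' @param raw_vars data.frame of raw island-level variables (with
#'   `island_id`).
#' @param var_spec variable spec, see [default_variable_spec()].
#' @param threshold absolute-rho flag threshold.
#' @return a data.frame `component`, `var1`, `var2`, `rho`, `flagged`.
#' @export
correlation_screen <- function(raw_vars, var_spec = default_variable_spec(),
                               threshold = 0.7) {
  check_variable_spec(var_spec, raw_vars)
  if (nrow(raw_vars) < 3L) stopf("need >= 3 islands for a correlation screen")
  rows <- list()
  for (comp in unique(var_spec$component)) {
    vars <- var_spec$name[var_spec$component == comp]
    if (length(vars) < 2L) next
    for (i in seq_len(length(vars) - 1L)) for (j in seq.int(i + 1L, length(vars))) {
      rho <- spearman(raw_vars[[vars[i]]], raw_vars[[vars[j]]])
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, var1 = vars[i], var2 = vars[j], rho = rho,
        flagged = !is.na(rho) && abs(rho) >= threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-variable-out congruence analysis
#'
#' For every variable whose component retains at least one other variable,
#' the component scores and TOPSIS vulnerability are recomputed without it
#' and compared to the full model by Spearman's rho over islands. A rho
#' near 1 means the variable does not drive the pattern. Single-variable
#' components (exposure) cannot be reduced and are skipped with a notice.
#'
#' @inheritParams component_scores
#' @param weights TOPSIS weights, see [topsis()].
#' @return a data.frame `dropped_variable`, `component`, `rho_exposure`,
#'   `rho_sensitivity`, `rho_adaptive_capacity`, `rho_vulnerability`,
#'   `method`.
#' @export
leave_one_out <- function(raw_vars, var_spec = default_variable_spec(),
                          method = c("minmax", "log_minmax", "cdf"),
                          weights = c(1, 1, 1)) {
  method <- match.arg(method)
  check_variable_spec(var_spec, raw_vars)
  full_comp <- component_scores(raw_vars, var_spec, method)
  full_vuln <- topsis(full_comp, weights)
  comps <- c("exposure", "sensitivity", "adaptive_capacity")
  rows <- list()
  for (v in var_spec$name) {
    comp <- var_spec$component[var_spec$name == v]
    if (sum(var_spec$component == comp) < 2L) {
      message("skipping '", v, "': only variable of component '", comp, "'")
      next
    }
    vs <- var_spec[var_spec$name != v, , drop = FALSE]
    red_comp <- component_scores(raw_vars, vs, method)
    red_vuln <- topsis(red_comp, weights)
    rhos <- vapply(comps, function(cc)
      suppressWarnings(spearman(full_comp[[cc]], red_comp[[cc]])), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      dropped_variable = v, component = comp,
      rho_exposure = rhos[["exposure"]],
      rho_sensitivity = rhos[["sensitivity"]],
      rho_adaptive_capacity = rhos[["adaptive_capacity"]],
      rho_vulnerability = suppressWarnings(
        spearman(full_vuln$vulnerability, red_vuln$vulnerability)),
      method = method, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Archipelago roll-up of island vulnerability
#'
#' Per archipelago: mean vulnerability, sample (n-1) standard deviation
#' (0 for singleton archipelagos), descending-mean rank, island count, and
#' the fraction of islands above the high-vulnerability threshold (0.5).
#'
#' @param vuln a vulnerability table from [topsis()].
#' @param islands the island table (maps `island_id` to `archipelago_id`).
#' @param high_threshold vulnerability above this counts as highly
#'   vulnerable.
#' @return a data.frame `archipelago_id`, `mean_vulnerability`, `sd`,
#'   `rank`, `n_islands`, `frac_high`, ordered by rank.
#' @export
archipelago_summary <- function(vuln, islands, high_threshold = 0.5) {
  idx <- match(vuln$island_id, islands$island_id)
  if (anyNA(idx))
    stopf("islands missing from the island table: %s",
          paste(vuln$island_id[is.na(idx)], collapse = ", "))
  arch <- islands$archipelago_id[idx]
  agg <- function(f) tapply(vuln$vulnerability, arch, f)
  means <- agg(mean)
  sds <- agg(function(x) if (length(x) < 2L) 0 else stats::sd(x))
  out <- data.frame(archipelago_id = names(means),
                    mean_vulnerability = as.numeric(means),
                    sd = as.numeric(sds),
                    n_islands = as.integer(agg(length)),
                    frac_high = as.numeric(agg(function(x)
                      mean(x > high_threshold))),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$mean_vulnerability, ties.method = "first")
  out <- out[order(out$rank),
             c("archipelago_id", "mean_vulnerability", "sd", "rank",
               "n_islands", "frac_high")]
  rownames(out) <- NULL
  out
}

#' Associations between vulnerability and island-level predictors
#'
#' Spearman's rho and a two-sided p-value for island vulnerability against
#' each supplied predictor (island-mean traits, components, richness, ...).
#' P-values use the asymptotic approximation by default; set
#' `exact = TRUE` for the exact null distribution at small n without ties.
#'
#' @param vuln a vulnerability table from [topsis()].
#' @param predictors a data.frame with `island_id` and one column per
#'   predictor.
#' @param exact passed to [stats::cor.test()].
#' @return a data.frame `predictor`, `rho`, `p_value`, `n`.
#' @export
association_report <- function(vuln, predictors, exact = FALSE) {
  stopifnot("island_id" %in% names(predictors))
  idx <- match(vuln$island_id, predictors$island_id)
  if (anyNA(idx)) stopf("predictors missing for some islands")
  if (nrow(vuln) < 4L)
    stopf("need >= 4 islands for an association report, got %d", nrow(vuln))
  vars <- setdiff(names(predictors), "island_id")
  rows <- lapply(vars, function(v) {
    ct <- suppressWarnings(stats::cor.test(vuln$vulnerability,
                                           predictors[[v]][idx],
                                           method = "spearman",
                                           exact = exact))
    data.frame(predictor = v, rho = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(vuln),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
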