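# Scoring: 0-1 standardization (three schemes), direction orientation,
# component aggregation, and TOPSIS vulnerability.

#' Standardize a variable to [0, 1]
#'
#' Three schemes: `minmax` is the linear rescale `(x - min)/(max - min)`;
#' `log_minmax` applies `ln(x + 1)` first (compressing the upper end so
#' extreme values are less influential), shifting by the minimum first
#' (with a warning) if negatives are present; `cdf` replaces each value by
#' its percentile rank (average ties), rescaled so the smallest rank maps
#' to 0 and the largest to 1. All schemes are rank-preserving and map the
#' minimum to 0 and the maximum to 1. A constant vector is uninformative:
#' every value maps to 0.5, with a warning (symmetric under direction
#' flips).
#'
#' @param x numeric vector of >= 2 finite values.
#' @param method `"minmax"`, `"log_minmax"` or `"cdf"`.
#' @return a numeric vector in [0, 1].
#' @export
standardize <- function(x, method = c("minmax", "log_minmax", "cdf")) {
  method <- match.arg(method)
  if (length(x) < 2L || any(!is.finite(x)))
    stopf("standardize() needs >= 2 finite values")
  if (max(x) == min(x)) {
    warning("constant variable: standardized to 0.5 everywhere",
            call. = FALSE)
    return(rep(0.5, length(x)))
  }
  switch(method,
    minmax = (x - min(x)) / (max(x) - min(x)),
    log_minmax = {
      if (any(x < 0)) {
        warning("negative values shifted by the minimum before log(x + 1)",
                call. = FALSE)
        x <- x - min(x)
      }
      lx <- log1p(x)
      (lx - min(lx)) / (max(lx) - min(lx))
    },
    cdf = {
      r <- rank(x, ties.method = "average")
      (r - min(r)) / (max(r) - min(r))
    })
}

#' Orient a standardized variable into its component
#'
#' A variable either increases its component (identity) or decreases it
#' (reflected as `1 - x`), so that after orientation every variable points
#' the same way within its component — e.g. broad habitat breadth lowers
#' sensitivity, so it enters the sensitivity component reflected.
#'
#' @param x numeric vector in [0, 1].
#' @param direction `"increases_component"` or `"decreases_component"`.
#' @return the oriented vector, still in [0, 1].
#' @export
orient <- function(x, direction = c("increases_component",
                                    "decreases_component")) {
  direction <- match.arg(direction)
  if (any(!is.finite(x) | x < 0 | x > 1))
    stopf("orient() expects values in [0, 1]")
  if (direction == "increases_component") x else 1 - x
}

#' The default variable specification of the pipeline
#'
#' Nine variables: one exposure, four sensitivity, four adaptive-capacity,
#' each with its direction. Specialized (low-breadth), long-generation,
#' low-redundancy faunas are more sensitive; surrounding land mass,
#' protected areas, distinct evolutionary history and a strong past
#' extinction filter raise adaptive capacity.
#'
#' @return a data.frame with columns `name`, `component`, `direction`.
#' @export
default_variable_spec <- function() {
  data.frame(
    name = c("mean_sed",
             "habitat_breadth", "diet_breadth", "generation_length",
             "redundancy",
             "isolation_sum", "pa_fraction", "mean_fp", "extinction_rate"),
    component = c("exposure",
                  rep("sensitivity", 4), rep("adaptive_capacity", 4)),
    direction = c("increases_component",
                  "decreases_component", "decreases_component",
                  "increases_component", "decreases_component",
                  rep("increases_component", 4)),
    stringsAsFactors = FALSE)
}

check_variable_spec <- function(var_spec, raw_vars) {
  need <- c("name", "component", "direction")
  stopifnot(all(need %in% names(var_spec)))
  bad <- setdiff(var_spec$name, names(raw_vars))
  if (length(bad) > 0)
    stopf("variable columns missing from data: %s", paste(bad, collapse = ", "))
  if (anyDuplicated(var_spec$name))
    stopf("duplicated variable in spec")
  stopifnot(all(var_spec$component %in%
                  c("exposure", "sensitivity", "adaptive_capacity")),
            all(var_spec$direction %in%
                  c("increases_component", "decreases_component")))
  invisible(var_spec)
}

#' Aggregate standardized, oriented variables into the three components
#'
#' Each variable is standardized with `method`, oriented per the variable
#' spec, summed within its component, and the three component sums are
#' re-standardized with the same method so each component lives on [0, 1].
#'
#' @param raw_vars a data.frame with `island_id` plus one column per
#'   variable named in `var_spec` (raw values).
#' @param var_spec a variable spec ([default_variable_spec()] layout).
#' @param method standardization scheme, see [standardize()].
#' @return a data.frame `island_id`, `exposure`, `sensitivity`,
#'   `adaptive_capacity`, all in [0, 1].
#' @export
component_scores <- function(raw_vars, var_spec = default_variable_spec(),
                             method = c("minmax", "log_minmax", "cdf")) {
  method <- match.arg(method)
  check_variable_spec(var_spec, raw_vars)
  out <- data.frame(island_id = raw_vars$island_id, stringsAsFactors = FALSE)
  for (comp in c("exposure", "sensitivity", "adaptive_capacity")) {
    vs <- var_spec[var_spec$component == comp, , drop = FALSE]
    if (nrow(vs) == 0L) stopf("component '%s' has no variables", comp)
    total <- rep(0, nrow(raw_vars))
    for (i in seq_len(nrow(vs)))
      total <- total + orient(standardize(raw_vars[[vs$name[i]]], method),
                              vs$direction[i])
    out[[comp]] <- standardize(total, method)
  }
  out
}

#' TOPSIS vulnerability from the component matrix
#'
#' Ranks islands by relative distance to two ideal solutions. The positive
#' ideal (no vulnerability) has minimal exposure, minimal sensitivity and
#' maximal adaptive capacity over the observed islands; the negative ideal
#' is the reverse. Vulnerability is `d_pos / (d_pos + d_neg)` with Euclidean
#' distances on the (optionally weighted) component space: an island at the
#' positive ideal scores 0, at the negative ideal 1. If all islands
#' coincide on all components the score is defined as 0.5 everywhere, with
#' a warning.
#'
#' @param components a data.frame `island_id`, `exposure`, `sensitivity`,
#'   `adaptive_capacity` with entries in [0, 1].
#' @param weights named or positional numeric length-3 criterion weights
#'   (exposure, sensitivity, adaptive_capacity); equal by default.
#' @return a data.frame `island_id`, `d_pos`, `d_neg`, `vulnerability`.
#' @export
topsis <- function(components, weights = c(1, 1, 1)) {
  comps <- c("exposure", "sensitivity", "adaptive_capacity")
  stopifnot(all(comps %in% names(components)), nrow(components) >= 2L)
  m <- as.matrix(components[comps])
  if (any(!is.finite(m) | m < 0 | m > 1))
    stopf("component entries must lie in [0, 1]")
  if (!is.null(names(weights)) && all(comps %in% names(weights)))
    weights <- weights[comps]
  stopifnot(length(weights) == 3L, all(weights > 0))
  w <- sweep(m, 2, as.numeric(weights), `*`)
  pos <- c(min(w[, 1]), min(w[, 2]), max(w[, 3]))   # no vulnerability
  neg <- c(max(w[, 1]), max(w[, 2]), min(w[, 3]))   # maximal vulnerability
  d_pos <- sqrt(rowSums(sweep(w, 2, pos)^2))
  d_neg <- sqrt(rowSums(sweep(w, 2, neg)^2))
  denom <- d_pos + d_neg
  vuln <- ifelse(denom > 0, d_pos / denom, 0.5)
  if (any(denom == 0))
    warning("islands identical on all components: vulnerability set to 0.5",
            call. = FALSE)
  data.frame(island_id = components$island_id, d_pos = d_pos, d_neg = d_neg,
             vulnerability = vuln, stringsAsFactors = FALSE)
}
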