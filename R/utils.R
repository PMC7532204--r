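# Internal helpers shared across modules.

# Derive a stage-local seed from the master seed so that every stochastic
# stage (islands -> climate -> species -> trees -> resolutions) draws from
# its own substream. Changing a downstream stage's config never perturbs an
# upstream stage's draws. Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage, index = 0L) {
  stages <- c(islands = 101L, climate = 211L, species = 307L,
              trees = 401L, resolve = 503L, replicate = 601L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 1009 + index) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

# Spearman's rank correlation; NA (with a warning) when either side is
# constant, matching the degenerate-column contract used throughout.
spearman <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector: Spearman's rho undefined, returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
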