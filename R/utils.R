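# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed; stays within 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 1000003 * as.double(k)) %% 2147483647L)
}

# Run expr with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards so library code does not perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Mixed-radix index of a configuration: `assign` is an integer vector of
# 1-based levels, `sizes` the level counts; last position varies fastest.
config_index <- function(assign, sizes) {
  if (length(assign) == 0L) return(1L)
  idx <- 0L
  for (i in seq_along(assign)) idx <- idx * sizes[i] + (assign[i] - 1L)
  idx + 1L
}

# All configurations over `sizes` as a matrix (rows in config_index order).
config_grid <- function(sizes) {
  if (length(sizes) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  g <- expand.grid(rev(lapply(sizes, seq_len)), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g[, rev(seq_along(sizes)), drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(n, what = "n") {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n))
    stop(sprintf("'%s' must be a single positive integer", what), call. = FALSE)
  invisible(as.integer(n))
}
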