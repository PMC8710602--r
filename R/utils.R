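#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All seeded operations in the package go
# through this so that library code never perturbs the user's RNG stream.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range. Simple multiplicative hash; collisions across the
# (subject, condition, trial) lattice are astronomically unlikely at the
# scales used here.
child_seed <- function(parent, ...) {
  idx <- c(...)
  h <- as.double(parent) %% 2147483629
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  }
  as.integer(h) + 1L
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))
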