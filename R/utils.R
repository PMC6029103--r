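# internal helpers shared across modules

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL leaves the ambient RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (!allow_na && is.na(x)) stop(sprintf("`%s` must not be NA", name), call. = FALSE)
  if (!is.na(x)) {
    if (strict_lower && x <= lower) {
      stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
    }
    if (!strict_lower && x < lower) {
      stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
    }
    if (x > upper) stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

# numeric Jacobian of f: R^p -> R^q (central differences), used for delta-method SEs
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}
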