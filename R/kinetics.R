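#' Exponential-mixture bulk-fraction model
#'
#' Evaluates the closed-form solution of the attachment kinetics when
#' detachment is negligible: starting from an all-planktonic population
#' (\eqn{N_b(0) = N}), the bulk fraction decays as a mixture of exponentials,
#' \deqn{N_b(t)/N = \sum_i f_i \exp(-\alpha_i t),}
#' one component per attachment phenotype with initial number fraction
#' \eqn{f_i} and attachment rate \eqn{\alpha_i}.
#'
#' @param t time(s) in seconds, all >= 0.
#' @param fractions component number fractions, summing to 1.
#' @param rates attachment rates in s^-1, same length as `fractions`.
#' @return the bulk fraction `N_b(t)/N` for each `t`; 1 at `t = 0`,
#'   non-increasing in `t`.
#' @examples
#' model_nb(900, c(0.8, 0.2), c(5.45e-3, 2.52e-4))  # ~0.165 still in bulk
#' @export
model_nb <- function(t, fractions, rates) {
  if (length(fractions) != length(rates)) {
    stop("`fractions` and `rates` must have the same length", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  if (any(rates < 0)) stop("`rates` must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("`t` must be >= 0 (seconds)", call. = FALSE)
  drop(exp(-outer(t, rates)) %*% fractions)
}

#' Construct a kinetics fit object from known parameters
#'
#' Wraps a set of mixture parameters as a `kinetics_fit`, the container
#' returned by [fit_mixture()]. Useful for evaluating [derived_quantities()]
#' on published parameter values without refitting.
#'
#' @param fractions component fractions (sum to 1, tolerance 1e-6).
#' @param rates attachment rates in s^-1, strictly decreasing (fast first).
#' @param rss residual sum of squares on the N_b/N scale, if known.
#' @param n_points number of fitted points, if known.
#' @return an object of class `kinetics_fit`.
#' @export
kinetics_fit <- function(fractions, rates, rss = NA_real_, n_points = NA_integer_) {
  k <- length(fractions)
  if (length(rates) != k) stop("`fractions`/`rates` length mismatch", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1", call. = FALSE)
  if (any(rates <= 0)) stop("rates must be > 0", call. = FALSE)
  if (k > 1L && any(diff(rates) >= 0)) {
    stop("rates must be strictly decreasing (fast component first)", call. = FALSE)
  }
  if (!is.na(rss) && rss < 0) stop("rss must be >= 0", call. = FALSE)
  structure(
    list(k = k, fractions = as.numeric(fractions), rates = as.numeric(rates),
         rss = rss, n_points = n_points, criterion = NA_real_,
         param_se = NULL, warnings = character(0)),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> k = %d component(s)", x$k))
  if (!is.na(x$rss)) cat(sprintf(", rss = %.3g on %d points", x$rss, x$n_points))
  cat("\n")
  tab <- data.frame(fraction = x$fractions, rate_per_s = x$rates)
  if (!is.null(x$param_se)) {
    tab$se_fraction <- x$param_se$fractions
    tab$se_rate <- x$param_se$rates
  }
  print(tab)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# pull (time, bulk-fraction) pairs out of the accepted series representations
series_xy <- function(series) {
  df <- as.data.frame(series)
  if (!"time_s" %in% names(df)) stop("series must have a `time_s` column", call. = FALSE)
  if (all(c("n_bulk", "n_total") %in% names(df))) {
    y <- df$n_bulk / df$n_total
  } else if ("frac_bulk" %in% names(df)) {
    y <- df$frac_bulk
  } else {
    stop("series must have `n_bulk`+`n_total` or `frac_bulk` columns", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1)) {
    stop("bulk fractions must be finite and in [0, 1]", call. = FALSE)
  }
  list(t = df$time_s, y = y)
}

# unconstrained parameterization: fractions via softmax (last logit fixed at 0),
# rates via log. Keeps the optimizer unconstrained while enforcing sum-to-one
# and positivity exactly.
par_to_model <- function(par, k) {
  if (k == 1L) {
    list(fractions = 1, rates = exp(par))
  } else {
    z <- c(par[seq_len(k - 1L)], 0)
    w <- exp(z - max(z))
    list(fractions = w / sum(w), rates = exp(par[k:(2L * k - 1L)]))
  }
}

#' Fit an exponential mixture to an attachment count series
#'
#' Least-squares fit of the mixture decay `N_b(t)/N = sum_i f_i exp(-a_i t)`
#' to a bulk-fraction series, on the untransformed fraction scale. The
#' sum-to-one constraint on fractions is enforced by a softmax
#' parameterization and rate positivity by log parameterization, so the
#' optimizer (BFGS) runs unconstrained. Multiple starts with log-uniform rate
#' initializations guard against local minima; the best-RSS solution is
#' returned with components sorted fast to slow.
#'
#' Approximate parameter standard errors come from the Gauss-Newton
#' covariance at the optimum, mapped to the (fraction, rate) scale by the
#' delta method; they are indicative, not exact.
#'
#' @param series an [count_series()] result, or any data.frame with `time_s`
#'   plus either `n_bulk` and `n_total` columns or a `frac_bulk` column.
#' @param k number of mixture components, 1..4.
#' @param n_starts number of random multi-starts (default 20).
#' @param rate_bounds range (s^-1) of the log-uniform rate initializations;
#'   default `c(1e-5, 1e-1)`.
#' @param seed integer seed controlling the starts; the fit is deterministic
#'   given `seed`.
#' @return a `kinetics_fit` with fields `k`, `fractions`, `rates` (s^-1,
#'   decreasing), `rss`, `n_points`, `criterion` (small-sample corrected AIC),
#'   `param_se`, and `warnings` (non-empty when components are nearly
#'   collinear: rates closer than 3x or a fraction below 0.02).
#' @examples
#' t <- seq(0, 3600, 3)
#' y <- model_nb(t, c(0.8, 0.2), c(5.45e-3, 2.52e-4))
#' fit_mixture(data.frame(time_s = t, frac_bulk = y), k = 2, seed = 1)
#' @export
fit_mixture <- function(series, k, n_starts = 20, rate_bounds = c(1e-5, 1e-1),
                        seed = NULL) {
  check_scalar(k, "k", lower = 1, upper = 4)
  k <- as.integer(k)
  check_scalar(n_starts, "n_starts", lower = 1)
  if (length(rate_bounds) != 2L || any(rate_bounds <= 0) ||
      rate_bounds[1] >= rate_bounds[2]) {
    stop("`rate_bounds` must be an increasing pair of positive rates", call. = FALSE)
  }
  xy <- series_xy(series)
  t <- xy$t
  y <- xy$y
  n <- length(t)
  if (n < 10L) stop("series must have at least 10 points", call. = FALSE)

  obj <- function(par) {
    m <- par_to_model(par, k)
    r <- y - drop(exp(-outer(t, m$rates)) %*% m$fractions)
    sum(r * r)
  }

  npar <- 2L * k - 1L
  fits <- with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      logr <- sort(stats::runif(k, log(rate_bounds[1]), log(rate_bounds[2])),
                   decreasing = TRUE)
      par0 <- if (k == 1L) logr else c(stats::rnorm(k - 1L, 0, 1), logr)
      tryCatch(
        stats::optim(par0, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL
      )
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    stop("mixture fit failed: no multi-start converged (k = ", k,
         ", n = ", n, " points)", call. = FALSE)
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  # polish the winner
  best <- tryCatch(
    stats::optim(best$par, obj, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) best
  )

  m <- par_to_model(best$par, k)
  ord <- order(m$rates, decreasing = TRUE)
  fractions <- m$fractions[ord]
  rates <- m$rates[ord]
  rss <- best$value

  # small-sample corrected information criterion (Gaussian working likelihood);
  # p counts k rates, k-1 free fractions and the residual variance
  p <- 2L * k
  aicc <- n * log(max(rss, 1e-300) / n) + 2 * p
  if (n - p - 1 > 0) aicc <- aicc + 2 * p * (p + 1) / (n - p - 1)

  param_se <- fit_param_se(best$par, k, t, y, rss, n, ord)

  warnings <- character(0)
  if (k > 1L) {
    ratio <- rates[-k] / rates[-1L]
    if (any(ratio < 3)) {
      warnings <- c(warnings,
                    "collinear components: adjacent rates closer than 3x")
    }
    if (any(fractions < 0.02)) {
      warnings <- c(warnings, "component fraction below 0.02")
    }
  }

  out <- kinetics_fit(fractions, rates, rss = rss, n_points = n)
  out$criterion <- aicc
  out$param_se <- param_se
  out$warnings <- warnings
  out$convergence <- best$convergence
  out
}

# delta-method SEs on the (fractions, rates) scale from the Gauss-Newton
# covariance of the unconstrained parameters; NA when the design is singular
fit_param_se <- function(par, k, t, y, rss, n, ord) {
  res <- try({
    model_fun <- function(p) {
      m <- par_to_model(p, k)
      drop(exp(-outer(t, m$rates)) %*% m$fractions)
    }
    J <- num_jacobian(model_fun, par)
    p_eff <- length(par)
    sigma2 <- rss / max(n - p_eff, 1)
    cov_par <- sigma2 * solve(crossprod(J))
    theta_fun <- function(p) {
      m <- par_to_model(p, k)
      c(m$fractions, m$rates)
    }
    Jt <- num_jacobian(theta_fun, par)
    cov_theta <- Jt %*% cov_par %*% t(Jt)
    se <- sqrt(pmax(diag(cov_theta), 0))
    list(fractions = se[seq_len(k)][ord], rates = se[k + seq_len(k)][ord])
  }, silent = TRUE)
  if (inherits(res, "try-error")) list(fractions = rep(NA_real_, k),
                                       rates = rep(NA_real_, k)) else res
}

#' Select the number of attachment phenotypes
#'
#' Fits mixtures with `k = 1..k_max` components and selects the component
#' count minimizing a small-sample corrected information criterion (AICc on a
#' Gaussian working likelihood). Identifiability guards then reject a
#' selected `k` whose fit is not interpretable as distinct phenotypes: if any
#' two recovered rates differ by less than 3x, or any component fraction is
#' below 0.02, the selection collapses to `k - 1` (repeatedly, down to 1).
#'
#' @inheritParams fit_mixture
#' @param k_max largest component count to consider (<= 4). Default 3.
#' @return the selected `kinetics_fit`, with an extra `criterion_all`
#'   data.frame (per-k RSS and criterion scores, plus which k was selected).
#' @export
select_k <- function(series, k_max = 3, n_starts = 20,
                     rate_bounds = c(1e-5, 1e-1), seed = NULL) {
  check_scalar(k_max, "k_max", lower = 1, upper = 4)
  k_max <- as.integer(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    sub_seed <- if (is.null(seed)) NULL else as.integer(seed) + k
    fits[[k]] <- fit_mixture(series, k, n_starts = n_starts,
                             rate_bounds = rate_bounds, seed = sub_seed)
  }
  crit <- vapply(fits, `[[`, numeric(1), "criterion")
  k_sel <- which.min(crit)
  # identifiability guards: collapse while the selected fit is degenerate
  while (k_sel > 1L && length(fits[[k_sel]]$warnings) > 0L) {
    k_sel <- k_sel - 1L
  }
  out <- fits[[k_sel]]
  out$criterion_all <- data.frame(
    k = seq_len(k_max),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    criterion = crit,
    selected = seq_len(k_max) == k_sel
  )
  out
}

#' Quantities derived from a kinetics fit
#'
#' @param fit a `kinetics_fit`.
#' @return a list with `fraction_fast` (number fraction of the fastest
#'   component), `rate_ratio` (`alpha_fast / alpha_slow`; `NA` for a
#'   single-component fit, where it is undefined), and `percent_attached_at`,
#'   a function of time (s) returning `100 * (1 - N_b(t)/N)`.
#' @examples
#' fit <- kinetics_fit(c(0.8, 0.2), c(5.45e-3, 2.52e-4))
#' dq <- derived_quantities(fit)
#' dq$rate_ratio             # ~21.6
#' dq$percent_attached_at(900)  # ~83.5% attached within 15 min
#' @export
derived_quantities <- function(fit) {
  stopifnot(inherits(fit, "kinetics_fit"))
  fractions <- fit$fractions
  rates <- fit$rates
  list(
    fraction_fast = fractions[1],
    rate_ratio = if (fit$k >= 2L) rates[1] / rates[fit$k] else NA_real_,
    percent_attached_at = function(t) 100 * (1 - model_nb(t, fractions, rates))
  )
}
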