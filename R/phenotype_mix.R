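#' Phenotype mixture parameters for surface attachment
#'
#' A `phenotype_mix` holds the generative truth for a population of planktonic
#' cells in which `k >= 1` attachment phenotypes coexist: per-phenotype number
#' fractions, attachment rates \eqn{\alpha_i} (s\eqn{^{-1}}), and detachment
#' rates \eqn{\beta_i} (s\eqn{^{-1}}). The bulk-cell fraction then follows
#' \deqn{dN_b/dt = -dN_s/dt = -\sum_i \alpha_i N_b^i(t) + \sum_i \beta_i N_s^i(t).}
#' Components are indexed fastest first: `attach_rates` must be strictly
#' decreasing so that component 1 is always the fast-attaching phenotype.
#'
#' @param fractions numeric vector of per-phenotype number fractions; must lie
#'   in \[0, 1\] and sum to 1 (tolerance 1e-12).
#' @param attach_rates attachment rates \eqn{\alpha_i} in s^-1, strictly
#'   decreasing, all >= 0.
#' @param detach_rates detachment rates \eqn{\beta_i} in s^-1, all >= 0;
#'   recycled to the number of phenotypes. Default 0: detachment is negligible
#'   in the experiments this models (net attachment >> net detachment).
#' @return an object of class `phenotype_mix`.
#' @examples
#' mix_late_exponential()
#' phenotype_mix(1, attach_rates = log(2) / 300)
#' @seealso [mix_late_exponential()], [simulate_attachment()], [model_nb()]
#' @export
phenotype_mix <- function(fractions, attach_rates, detach_rates = 0) {
  if (!is.numeric(fractions) || length(fractions) < 1L) {
    stop("`fractions` must be a non-empty numeric vector", call. = FALSE)
  }
  k <- length(fractions)
  if (length(attach_rates) != k) {
    stop("`attach_rates` must have one entry per phenotype", call. = FALSE)
  }
  detach_rates <- rep_len(detach_rates, k)
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    stop("all fractions must be finite and in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-12) {
    stop("fractions must sum to 1 (tolerance 1e-12)", call. = FALSE)
  }
  if (any(!is.finite(attach_rates)) || any(attach_rates < 0)) {
    stop("attach rates must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(detach_rates)) || any(detach_rates < 0)) {
    stop("detach rates must be finite and >= 0", call. = FALSE)
  }
  if (k > 1L && any(diff(attach_rates) >= 0)) {
    stop("attach rates must be strictly decreasing (component 1 = fastest)",
         call. = FALSE)
  }
  structure(
    list(fractions = as.numeric(fractions),
         attach_rates = as.numeric(attach_rates),
         detach_rates = as.numeric(detach_rates)),
    class = "phenotype_mix"
  )
}

#' @export
print.phenotype_mix <- function(x, ...) {
  cat(sprintf("<phenotype_mix> %d phenotype(s)\n", length(x$fractions)))
  print(data.frame(fraction = x$fractions,
                   attach_rate_per_s = x$attach_rates,
                   detach_rate_per_s = x$detach_rates))
  invisible(x)
}

#' Two-phenotype mixture reported for later-exponential-phase cultures
#'
#' Convenience preset: approximately 80% of planktonic cells carry the
#' fast-attaching phenotype (alpha_fast = 5.45e-3 s^-1) and 20% the
#' slow-attaching phenotype (alpha_slow = 2.52e-4 s^-1), the parameter regime
#' reported for P. aeruginosa harvested in the later exponential growth phase
#' (OD600 ~ 1.2). Detachment is set to zero.
#'
#' @return a [phenotype_mix()] with two components.
#' @export
mix_late_exponential <- function() {
  phenotype_mix(fractions = c(0.8, 0.2),
                attach_rates = c(5.45e-3, 2.52e-4))
}

#' Simulation configuration for attachment movies
#'
#' Parameters of a synthetic single-cell attachment experiment: a fixed field
#' of view imaged at a constant frame interval while an initially planktonic
#' population attaches to the glass surface. Defaults mirror the experimental
#' setup this emulates: 165 x 139 um field, one frame every 3 s, ~1 h movies.
#'
#' @param n_cells number of cells to simulate (>= 1).
#' @param duration movie length in seconds (> 0). Default 3600.
#' @param frame_interval seconds between frames (> 0). Default 3.
#' @param seed integer seed; all randomness of a simulation flows from it.
#' @param jitter_attached positional noise (um, per-frame SD per axis) of
#'   attached cells. Default 0.05 um.
#' @param diffusion_bulk effective diffusion coefficient (um^2/s) of mobile
#'   cells; per-frame displacement SD per axis is `sqrt(2 * D * dt)`.
#'   Default 1 um^2/s.
#' @param field field of view width and height in um. Default `c(165, 139)`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cells, duration = 3600, frame_interval = 3,
                       seed = NULL, jitter_attached = 0.05,
                       diffusion_bulk = 1, field = c(165, 139)) {
  check_scalar(n_cells, "n_cells", lower = 1)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  check_scalar(jitter_attached, "jitter_attached", lower = 0)
  check_scalar(diffusion_bulk, "diffusion_bulk", lower = 0)
  if (!is.numeric(field) || length(field) != 2L || any(field <= 0)) {
    stop("`field` must be two positive dimensions (um)", call. = FALSE)
  }
  structure(
    list(n_cells = as.integer(n_cells), duration = duration,
         frame_interval = frame_interval, seed = seed,
         jitter_attached = jitter_attached, diffusion_bulk = diffusion_bulk,
         field = as.numeric(field)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d cells, %.0f s at %.3g s/frame, field %.0f x %.0f um\n",
    x$n_cells, x$duration, x$frame_interval, x$field[1], x$field[2]))
  invisible(x)
}
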