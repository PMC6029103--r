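#' Biofilm local-thickness map
#'
#' An n x m grid of local biofilm thickness values (um), the reduced form of
#' a confocal z-stack after upstream segmentation. Carries the lateral pixel
#' size for reference; the summary metrics below do not depend on it.
#'
#' @param grid numeric matrix of local thickness values, all >= 0.
#' @param pixel_size lateral pixel size in um (> 0). Default 1.
#' @return an object of class `height_map`.
#' @export
height_map <- function(grid, pixel_size = 1) {
  grid <- as.matrix(grid)
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  if (!is.numeric(grid) || any(!is.finite(grid))) {
    stop("grid must be finite numeric", call. = FALSE)
  }
  if (any(grid < 0)) stop("thickness values must be >= 0", call. = FALSE)
  check_scalar(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(list(grid = grid, pixel_size = pixel_size), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px (%.3g um/px), mean %.3g um, Ra* %.3g\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              mean_thickness(x),
              if (mean(x$grid) > 0) roughness_coefficient(x) else NA))
  invisible(x)
}

#' Average biofilm thickness
#'
#' Arithmetic mean of the local thickness values (um) — the standard
#' biomass-height summary of biofilm image analysis.
#'
#' @param map a [height_map()].
#' @return mean thickness in um.
#' @export
mean_thickness <- function(map) {
  stopifnot(inherits(map, "height_map"))
  mean(map$grid)
}

#' Roughness coefficient Ra*
#'
#' Normalized mean absolute deviation of local thickness,
#' \deqn{Ra^* = \frac{1}{N} \sum_i |L_i - \bar L| / \bar L,}
#' the standard dimensionless measure of how uneven a biofilm surface is:
#' 0 for a perfectly flat film, larger for patchy ones (bounded by 2 for any
#' nonnegative map). Invariant under uniform scaling of thickness.
#'
#' @param map a [height_map()].
#' @return Ra* (dimensionless, >= 0).
#' @export
roughness_coefficient <- function(map) {
  stopifnot(inherits(map, "height_map"))
  m <- mean(map$grid)
  if (m <= 0) stop("mean thickness must be > 0 to define roughness", call. = FALSE)
  mean(abs(map$grid - m)) / m
}

#' Simulate a biofilm thickness map with a target roughness
#'
#' Generates a nonnegative local-thickness grid as a (optionally spatially
#' smoothed) log-normal random field calibrated so that the expected
#' roughness coefficient equals `roughness_target`: for a log-normal field
#' the population Ra* is `2 * (2 * pnorm(sigma/2) - 1)`, which is inverted
#' for the log-scale SD sigma. Because Ra* of any nonnegative field is
#' bounded by 2, targets at or above 2 are rejected as unattainable without
#' violating nonnegativity. A target of 0 yields a constant map.
#'
#' @param mean_thickness target mean thickness in um (> 0).
#' @param roughness_target target Ra* (dimensionless, in \[0, 2)).
#' @param grid grid dimensions `c(n, m)`. Default `c(64, 64)`.
#' @param seed integer seed.
#' @param smooth apply a 3x3 moving-average to the underlying Gaussian field
#'   (re-standardized afterwards) so neighboring pixels are correlated, as in
#'   a real biofilm. Default TRUE.
#' @param pixel_size lateral pixel size in um. Default 1.24 (a typical
#'   confocal setting).
#' @return a [height_map()] whose sample roughness is within ~10% of the
#'   target at the default grid size.
#' @export
simulate_heightmap <- function(mean_thickness, roughness_target,
                               grid = c(64, 64), seed = NULL, smooth = TRUE,
                               pixel_size = 1.24) {
  check_scalar(mean_thickness, "mean_thickness", lower = 0, strict_lower = TRUE)
  check_scalar(roughness_target, "roughness_target", lower = 0)
  if (roughness_target >= 2) {
    stop("roughness_target >= 2 is unattainable for a nonnegative map ",
         "(Ra* of any nonnegative field is < 2)", call. = FALSE)
  }
  if (length(grid) != 2L || any(grid < 1)) {
    stop("`grid` must be two positive dimensions", call. = FALSE)
  }
  n <- as.integer(grid[1]); m <- as.integer(grid[2])
  if (roughness_target == 0) {
    return(height_map(matrix(mean_thickness, n, m), pixel_size))
  }
  # invert Ra* = 2 (2 Phi(sigma/2) - 1) for the log-scale SD
  sigma <- 2 * stats::qnorm((roughness_target + 2) / 4)
  g <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (smooth && n >= 3L && m >= 3L) {
      sm <- z
      for (i in seq_len(n)) {
        for (j in seq_len(m)) {
          ii <- max(1L, i - 1L):min(n, i + 1L)
          jj <- max(1L, j - 1L):min(m, j + 1L)
          sm[i, j] <- mean(z[ii, jj])
        }
      }
      z <- (sm - mean(sm)) / stats::sd(sm)
    }
    z
  })
  vals <- mean_thickness * exp(sigma * g - sigma^2 / 2)
  height_map(vals, pixel_size)
}
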