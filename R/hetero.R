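#' Background-subtract fluorescence intensities
#'
#' Subtracts the average per-pixel background fluorescence from raw per-cell
#' intensities, clipping negative results at zero. The number of clipped
#' values is reported as an attribute so downstream analyses can tell how
#' much of the signal sat below background.
#'
#' @param raw raw intensities (a.u.), vectorized.
#' @param background background level (a.u., >= 0); scalar or per-cell.
#' @return corrected intensities with attributes `n_clipped` and `clipped`
#'   (logical mask).
#' @export
subtract_background <- function(raw, background) {
  if (any(background < 0)) stop("`background` must be >= 0", call. = FALSE)
  out <- raw - background
  clipped <- out < 0
  out[clipped] <- 0
  attr(out, "n_clipped") <- sum(clipped)
  attr(out, "clipped") <- clipped
  out
}

#' Coefficient of variation
#'
#' Standard deviation divided by the mean — the standard dimensionless
#' measure of cell-to-cell expression heterogeneity. The SD uses the sample
#' (n - 1) denominator. Requires a strictly positive mean; a CV of a
#' non-positive-mean sample is not meaningful for intensity data.
#'
#' @param values numeric vector, length >= 2.
#' @return the CV (dimensionless, >= 0).
#' @examples
#' cv(rlnorm(1e4, 5.4, 0.83))  # ~0.99, a strongly heterogeneous reporter
#' @export
cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be > 0 to define a CV", call. = FALSE)
  stats::sd(values) / m
}

#' Proportion of cells above an intensity cutoff
#'
#' Strict comparison (`> cutoff`), matching the convention "intensity
#' greater than X a.u.".
#'
#' @param values intensities (a.u.).
#' @param cutoff threshold (a.u.).
#' @return a list: `prop`, its binomial standard error `se`
#'   (`sqrt(p(1-p)/n)`), and `n`.
#' @export
fraction_above <- function(values, cutoff) {
  n <- length(values)
  if (n < 1L) stop("need at least 1 value", call. = FALSE)
  p <- mean(values > cutoff)
  list(prop = p, se = sqrt(p * (1 - p) / n), n = n)
}

#' Pearson correlation between two fluorescence channels
#'
#' @param table a fluorescence table (data.frame) with one column per
#'   channel.
#' @param ch_a,ch_b channel column names.
#' @return a list: `estimate` (Pearson r in \[-1, 1\]) and `n`.
#' @export
channel_correlation <- function(table, ch_a, ch_b) {
  table <- as.data.frame(table)
  if (!all(c(ch_a, ch_b) %in% names(table))) {
    stop("channels not found in table: ", ch_a, ", ", ch_b, call. = FALSE)
  }
  a <- table[[ch_a]]
  b <- table[[ch_b]]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 paired cells", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a channel: correlation undefined", call. = FALSE)
  }
  list(estimate = stats::cor(a, b), n = length(a))
}

#' Gaussian-kernel density estimate at 100 points
#'
#' Probability density estimate with a normal kernel and Silverman's
#' rule-of-thumb bandwidth, evaluated at 100 equally spaced points spanning
#' the data range — the standard presentation for single-cell intensity
#' distributions.
#'
#' @param values numeric vector, length >= 2.
#' @return a list: `x` (100 evaluation points from min to max), `y`
#'   (nonnegative densities), `bw` (bandwidth), and `integral` (trapezoid
#'   integral of the same estimate over an extended support; close to 1).
#' @export
kde_100 <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  d <- stats::density(values, bw = "nrd0", n = 100,
                      from = min(values), to = max(values))
  full <- stats::density(values, bw = "nrd0", n = 512)  # default extended support
  integral <- sum(diff(full$x) * (utils::head(full$y, -1) + utils::tail(full$y, -1)) / 2)
  list(x = d$x, y = d$y, bw = d$bw, integral = integral)
}

#' CV trajectory over time
#'
#' Per-timepoint coefficient of variation of an intensity column, e.g. to
#' follow how expression heterogeneity of initially attached founder cells
#' grows as they divide and differentiate.
#'
#' @param table data.frame with a `time_h` column and the intensity column.
#' @param channel intensity column name. Default `"egfp_au"`.
#' @return a data.frame `(time_h, cv, n)` sorted by time.
#' @export
cv_trajectory <- function(table, channel = "egfp_au") {
  table <- as.data.frame(table)
  if (!all(c("time_h", channel) %in% names(table))) {
    stop("table must have columns `time_h` and `", channel, "`", call. = FALSE)
  }
  groups <- split(table[[channel]], table$time_h)
  out <- data.frame(
    time_h = as.numeric(names(groups)),
    cv = vapply(groups, cv, numeric(1)),
    n = vapply(groups, length, integer(1))
  )
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unpaired two-sided Student's t test
#'
#' Thin wrapper around the classic equal-variance two-sample t test, the
#' comparison used for population-level intensity differences. No new
#' statistics: plumbing around [stats::t.test()].
#'
#' @param a,b numeric samples, each length >= 2.
#' @return a list: `t`, `p`, `means` (length 2), `sds` (length 2), `df`.
#' @export
two_sample_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       means = c(mean(a), mean(b)), sds = c(stats::sd(a), stats::sd(b)),
       df = unname(tt$parameter))
}

#' Heterogeneity summary of one cell population
#'
#' Bundles the standard single-population heterogeneity statistics: sample
#' size, mean, SD, CV and the proportions above a set of intensity cutoffs
#' (monotone non-increasing in the cutoff by construction).
#'
#' @param values background-subtracted intensities (a.u.), length >= 2.
#' @param cutoffs intensity cutoffs (a.u.). Default `c(500, 1000)`.
#' @return a `heterogeneity_summary` list: `n`, `mean`, `sd`, `cv`,
#'   `fractions_above` (named by cutoff).
#' @export
heterogeneity_summary <- function(values, cutoffs = c(500, 1000)) {
  fr <- vapply(cutoffs, function(ct) fraction_above(values, ct)$prop,
               numeric(1))
  names(fr) <- as.character(cutoffs)
  structure(
    list(n = length(values), mean = mean(values), sd = stats::sd(values),
         cv = cv(values), fractions_above = fr),
    class = "heterogeneity_summary"
  )
}

#' @export
print.heterogeneity_summary <- function(x, ...) {
  cat(sprintf("<heterogeneity_summary> n = %d, mean %.3g, sd %.3g, CV %.3g\n",
              x$n, x$mean, x$sd, x$cv))
  cat("fractions above:",
      paste(sprintf("%s a.u.: %.3g", names(x$fractions_above),
                    x$fractions_above), collapse = ", "), "\n")
  invisible(x)
}
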