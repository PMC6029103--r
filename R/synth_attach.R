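#' Simulate per-cell surface attachment as a continuous-time Markov process
#'
#' Event-driven realization of the per-cell attachment/detachment dynamics
#' underlying the bulk-fraction model: each cell is assigned a phenotype by its
#' number fraction, then waits an exponential time with rate \eqn{\alpha_i}
#' before attaching; when \eqn{\beta_i > 0} an attached cell detaches with
#' rate \eqn{\beta_i} and re-enters the bulk pool (alternating renewal).
#' Waiting times are drawn exactly, then discretized to the frame grid; this
#' avoids the per-frame Bernoulli bias a frame-by-frame scheme would introduce
#' at coarse frame intervals.
#'
#' The returned object stores per-cell state-transition times compactly.
#' [track_table()] materializes the per-frame tracking table (positions,
#' attached flags), and [count_series()] builds the bulk/surface count series
#' directly from the event times.
#'
#' @param mix a [phenotype_mix()].
#' @param cfg a [sim_config()]; randomness is controlled by `cfg$seed`.
#' @return an object of class `cell_tracks`: a list with `cells` (per-cell
#'   phenotype assignment), `events` (per-cell state-transition times in s,
#'   alternating attach/detach, truncated to the movie), `time_s` (frame
#'   grid), and the generating `mix` and `config`.
#' @examples
#' trk <- simulate_attachment(mix_late_exponential(),
#'                            sim_config(n_cells = 200, seed = 1))
#' head(count_series(trk))
#' @export
simulate_attachment <- function(mix, cfg) {
  stopifnot(inherits(mix, "phenotype_mix"), inherits(cfg, "sim_config"))
  n <- cfg$n_cells
  k <- length(mix$fractions)
  time_s <- seq(0, cfg$duration, by = cfg$frame_interval)

  out <- with_seed(cfg$seed, {
    phenotype <- sample.int(k, n, replace = TRUE, prob = mix$fractions)
    alpha <- mix$attach_rates[phenotype]
    beta <- mix$detach_rates[phenotype]

    if (all(mix$detach_rates == 0)) {
      t_attach <- rep(Inf, n)
      pos <- alpha > 0
      if (any(pos)) t_attach[pos] <- stats::rexp(sum(pos), rate = alpha[pos])
      events <- lapply(seq_len(n), function(i) {
        if (t_attach[i] <= cfg$duration) t_attach[i] else numeric(0)
      })
    } else {
      # alternating attach/detach renewal per cell
      events <- lapply(seq_len(n), function(i) {
        ev <- numeric(0)
        t <- 0
        attached <- FALSE
        repeat {
          r <- if (attached) beta[i] else alpha[i]
          if (r <= 0) break
          t <- t + stats::rexp(1, rate = r)
          if (t > cfg$duration) break
          ev <- c(ev, t)
          attached <- !attached
        }
        ev
      })
    }
    list(phenotype = phenotype, events = events)
  })

  structure(
    list(
      cells = data.frame(
        cell_id = sprintf("c%04d", seq_len(n)),
        phenotype = out$phenotype,
        parent_id = NA_character_,
        stringsAsFactors = FALSE
      ),
      events = out$events,
      time_s = time_s,
      mix = mix,
      config = cfg
    ),
    class = "cell_tracks"
  )
}

#' @export
print.cell_tracks <- function(x, ...) {
  n_att <- sum(vapply(x$events, function(e) length(e) %% 2L == 1L, logical(1)))
  cat(sprintf("<cell_tracks> %d cells, %d frames; %d attached at movie end\n",
              nrow(x$cells), length(x$time_s), n_att))
  invisible(x)
}

# TRUE iff a cell with transition times `ev` is attached at time t
# (odd number of transitions at or before t)
attached_at <- function(ev, t) {
  if (length(ev) == 0L) return(rep(FALSE, length(t)))
  (findInterval(t, ev) %% 2L) == 1L
}

#' Materialize the per-frame tracking table of a simulation
#'
#' Expands a compact [simulate_attachment()] result into the long per-frame
#' tracking-table format produced by a single-cell tracking pipeline: one row
#' per cell per frame with xy position and attached flag. Mobile cells perform
#' an unbounded random walk with per-frame step SD `sqrt(2 * D * dt)` per axis
#' starting from a uniform position in the field; attached cells sit at their
#' attachment position plus Gaussian jitter of SD `jitter_attached`.
#' Positions are drawn from a stream derived from the simulation seed
#' (`cfg$seed + 1`), so the same simulation always yields the same table.
#'
#' @param x a `cell_tracks` object.
#' @return a data.frame with columns
#'   `cell_id, parent_id, phenotype, frame, time_s, x_um, y_um, attached`.
#' @seealso [write_tracks()] for the on-disk CSV with the same columns.
#' @export
track_table <- function(x) {
  stopifnot(inherits(x, "cell_tracks"))
  cfg <- x$config
  t <- x$time_s
  nf <- length(t)
  n <- nrow(x$cells)
  step_sd <- sqrt(2 * cfg$diffusion_bulk * cfg$frame_interval)
  pos_seed <- if (is.null(cfg$seed)) NULL else as.integer(cfg$seed) + 1L

  pieces <- with_seed(pos_seed, {
    x0 <- stats::runif(n, 0, cfg$field[1])
    y0 <- stats::runif(n, 0, cfg$field[2])
    lapply(seq_len(n), function(i) {
      att <- attached_at(x$events[[i]], t)
      xs <- numeric(nf)
      ys <- numeric(nf)
      xs[1] <- x0[i]; ys[1] <- y0[i]
      dx <- stats::rnorm(nf - 1L, 0, step_sd)
      dy <- stats::rnorm(nf - 1L, 0, step_sd)
      jx <- stats::rnorm(nf, 0, cfg$jitter_attached)
      jy <- stats::rnorm(nf, 0, cfg$jitter_attached)
      anchor <- c(NA_real_, NA_real_)
      for (f in seq_len(nf)) {
        if (att[f]) {
          if (is.na(anchor[1])) {
            anchor <- if (f == 1L) c(x0[i], y0[i]) else c(xs[f - 1L], ys[f - 1L])
          }
          xs[f] <- anchor[1] + jx[f]
          ys[f] <- anchor[2] + jy[f]
        } else {
          anchor <- c(NA_real_, NA_real_)
          if (f > 1L) {
            xs[f] <- xs[f - 1L] + dx[f - 1L]
            ys[f] <- ys[f - 1L] + dy[f - 1L]
          }
        }
      }
      list(x = xs, y = ys, att = att)
    })
  })

  data.frame(
    cell_id = rep(x$cells$cell_id, each = nf),
    parent_id = rep(x$cells$parent_id, each = nf),
    phenotype = rep(x$cells$phenotype, each = nf),
    frame = rep.int(seq_len(nf), n),
    time_s = rep.int(t, n),
    x_um = unlist(lapply(pieces, `[[`, "x"), use.names = FALSE),
    y_um = unlist(lapply(pieces, `[[`, "y"), use.names = FALSE),
    attached = unlist(lapply(pieces, `[[`, "att"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
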