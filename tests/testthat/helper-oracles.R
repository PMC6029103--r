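# independent oracles and small fixture builders used across test files

# brute-force ODE integration of the per-phenotype bulk dynamics
# dNb_i/dt = -alpha_i Nb_i (detachment neglected), summed to Nb(t)/N
ode_nb_oracle <- function(t, fractions, rates) {
  if (requireNamespace("deSolve", quietly = TRUE)) {
    rhs <- function(t, y, parms) list(-parms * y)
    out <- deSolve::ode(y = fractions, times = t, func = rhs, parms = rates,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    rowSums(out[, -1, drop = FALSE])
  } else {
    # fine-step RK4 fallback, still independent of the closed form
    sapply(t, function(tt) {
      y <- fractions
      if (tt == 0) return(sum(y))
      h <- tt / 2000
      for (i in 1:2000) {
        k1 <- -rates * y
        k2 <- -rates * (y + h / 2 * k1)
        k3 <- -rates * (y + h / 2 * k2)
        k4 <- -rates * (y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      sum(y)
    })
  }
}

# tracking table of one synthetic cell: random walk until t_attach, then
# frozen (plus optional jitter). Used as a known-truth classifier fixture.
one_cell_track <- function(t_attach, n_frames = 200, dt = 3, step_sd = 2,
                           jitter = 0, cell_id = "c0001", seed = 1) {
  set.seed(seed)
  time_s <- (seq_len(n_frames) - 1) * dt
  x <- numeric(n_frames); y <- numeric(n_frames)
  for (f in 2:n_frames) {
    if (time_s[f] < t_attach) {
      x[f] <- x[f - 1] + rnorm(1, 0, step_sd)
      y[f] <- y[f - 1] + rnorm(1, 0, step_sd)
    } else {
      x[f] <- x[f - 1] + rnorm(1, 0, jitter)
      y[f] <- y[f - 1] + rnorm(1, 0, jitter)
    }
  }
  data.frame(cell_id = cell_id, parent_id = NA_character_, phenotype = 1L,
             frame = seq_len(n_frames), time_s = time_s, x_um = x, y_um = y,
             attached = time_s >= t_attach, stringsAsFactors = FALSE)
}

# hand-built two-generation tracking table: mother divides at t_div into two
# daughters with prescribed fates ("stay" runs to the end, "leave" detaches)
division_fixture <- function(fates = c("stay", "stay"), n_frames = 40,
                             dt = 3, t_div_frame = 10) {
  mk <- function(id, parent, f0, f1, leave_last = FALSE) {
    frames <- f0:f1
    att <- rep(TRUE, length(frames))
    if (leave_last) att[length(att)] <- FALSE
    data.frame(cell_id = id, parent_id = parent, phenotype = NA_integer_,
               frame = frames, time_s = (frames - 1) * dt,
               x_um = 0, y_um = 0, attached = att, stringsAsFactors = FALSE)
  }
  rows <- list(mk("m1", NA_character_, 1L, t_div_frame))
  for (d in 1:2) {
    id <- paste0("d", d)
    if (fates[d] == "stay") {
      rows[[d + 1L]] <- mk(id, "m1", t_div_frame + 1L, n_frames)
    } else {
      rows[[d + 1L]] <- mk(id, "m1", t_div_frame + 1L, t_div_frame + 6L,
                           leave_last = TRUE)
    }
  }
  do.call(rbind, rows)
}

# relabel generator "stay" fates as "censored" under the movie-edge rule the
# track reconstruction applies, for exact round-trip comparison
censor_forest <- function(forest, t_censor) {
  duration <- forest$config$duration
  nd <- forest$nodes
  edge <- nd$fate == "stay" & is.na(nd$t_division_s) &
    (duration - nd$t_birth_s) < t_censor
  nd$fate[edge] <- "censored"
  forest$nodes <- nd
  forest
}
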