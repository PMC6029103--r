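#' Classify a single track as attached or mobile per frame
#'
#' Surrogate for the tracking-pipeline decision of whether a cell is
#' surface-attached at each frame: a frame is "attached" iff the maximum
#' pairwise displacement among the positions in the trailing window of
#' `window` frames is below `threshold`. The first `window - 1` frames
#' inherit the first decided state. A track shorter than the window is
#' classified as a whole by its total maximum displacement.
#'
#' Defaults (5 frames = 15 s at the standard frame interval, 1 um) are the
#' simplest auditable stand-in for a dedicated pole-tracking classifier.
#'
#' @param xy two-column matrix (or data.frame) of positions in um, one row
#'   per frame, in frame order.
#' @param window trailing window length in frames (>= 2). Default 5.
#' @param threshold displacement threshold in um (> 0). Default 1.
#' @return logical vector, one entry per frame; TRUE = attached.
#' @export
classify_attached <- function(xy, window = 5, threshold = 1) {
  check_scalar(window, "window", lower = 2)
  check_scalar(threshold, "threshold", lower = 0, strict_lower = TRUE)
  window <- as.integer(window)
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("`xy` must have two columns (x, y)", call. = FALSE)
  nf <- nrow(xy)
  if (nf == 0L) stop("empty track", call. = FALSE)
  x <- xy[, 1]; y <- xy[, 2]

  if (nf < window) {
    d <- max(stats::dist(xy))
    return(rep(d < threshold, nf))
  }

  # max pairwise distance in each trailing window, vectorized over lag pairs
  idx <- window:nf
  dmax <- rep(0, length(idx))
  for (l1 in 0:(window - 2L)) {
    for (l2 in (l1 + 1L):(window - 1L)) {
      d <- sqrt((x[idx - l1] - x[idx - l2])^2 + (y[idx - l1] - y[idx - l2])^2)
      dmax <- pmax(dmax, d)
    }
  }
  state <- dmax < threshold
  c(rep(state[1], window - 1L), state)
}

#' Re-classify every track in a tracking table
#'
#' Applies [classify_attached()] per cell and replaces the `attached` column,
#' mimicking what an analysis of real tracking output would do (where no
#' ground-truth flag exists).
#'
#' @param tracks a tracking table as produced by [track_table()] /
#'   [read_tracks()] (columns `cell_id`, `frame`, `x_um`, `y_um`, ...).
#' @inheritParams classify_attached
#' @return the tracking table with `attached` replaced by the classifier
#'   decision.
#' @export
classify_tracks <- function(tracks, window = 5, threshold = 1) {
  tracks <- as.data.frame(tracks)
  need <- c("cell_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    stop("`tracks` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  tracks <- tracks[order(tracks$cell_id, tracks$frame), , drop = FALSE]
  att <- unlist(lapply(split(seq_len(nrow(tracks)), tracks$cell_id), function(i) {
    classify_attached(tracks[i, c("x_um", "y_um")], window, threshold)
  }), use.names = FALSE)
  # split() returns groups in cell_id order, matching the row sort above
  tracks$attached <- att
  rownames(tracks) <- NULL
  tracks
}

new_attachment_series <- function(time_s, n_bulk, n_surface) {
  n_total <- n_bulk + n_surface
  if (any(n_bulk < 0) || any(n_surface < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (length(unique(n_total)) != 1L) {
    stop("count conservation violated: n_bulk + n_surface must be constant",
         call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  structure(
    data.frame(time_s = time_s, n_bulk = n_bulk, n_surface = n_surface,
               n_total = n_total),
    class = c("attachment_series", "data.frame")
  )
}

#' Build the bulk/surface count series from tracks
#'
#' Counts attached (surface) and mobile (bulk) cells at every frame of the
#' shared frame grid. Conservation `n_bulk + n_surface = n_total` holds at
#' every frame by construction and is asserted. Two inputs are accepted:
#' a compact [simulate_attachment()] result (counts are taken from the
#' generator's own event bookkeeping — exact truth), or a per-frame tracking
#' table whose `attached` column carries classifier decisions.
#'
#' @param x a `cell_tracks` object or a tracking-table data.frame.
#' @param ... unused.
#' @return an `attachment_series` data.frame with columns
#'   `time_s, n_bulk, n_surface, n_total`.
#' @export
count_series <- function(x, ...) UseMethod("count_series")

#' @rdname count_series
#' @export
count_series.cell_tracks <- function(x, ...) {
  t <- x$time_s
  n <- nrow(x$cells)
  lens <- lengths(x$events)
  if (all(lens <= 1L)) {
    ta <- sort(unlist(x$events, use.names = FALSE))
    n_surface <- findInterval(t, ta)
  } else {
    ev <- unlist(x$events, use.names = FALSE)
    sgn <- unlist(lapply(lens, function(l) {
      if (l == 0L) numeric(0) else rep_len(c(1, -1), l)
    }), use.names = FALSE)
    o <- order(ev)
    sf <- stats::stepfun(ev[o], c(0, cumsum(sgn[o])))
    n_surface <- sf(t)
  }
  new_attachment_series(t, n - n_surface, n_surface)
}

#' @rdname count_series
#' @export
count_series.data.frame <- function(x, ...) {
  if (nrow(x) == 0L) stop("empty track set", call. = FALSE)
  need <- c("cell_id", "time_s", "attached")
  if (!all(need %in% names(x))) {
    stop("tracking table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  grids <- split(x$time_s, x$cell_id)
  ref <- grids[[1]]
  same <- vapply(grids, function(g) {
    length(g) == length(ref) && all(sort(g) == sort(ref))
  }, logical(1))
  if (!all(same)) {
    stop("inconsistent frame grids: all tracks must share the frame grid",
         call. = FALSE)
  }
  agg <- tapply(x$attached, x$time_s, sum)
  t <- as.numeric(names(agg))
  o <- order(t)
  n_surface <- as.numeric(agg)[o]
  n_cells <- length(grids)
  new_attachment_series(t[o], n_cells - n_surface, n_surface)
}

#' @export
print.attachment_series <- function(x, ...) {
  cat(sprintf("<attachment_series> %d frames, %d cells; %.1f%% attached at end\n",
              nrow(x), x$n_total[1],
              100 * x$n_surface[nrow(x)] / max(x$n_total[1], 1)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' @export
plot.attachment_series <- function(x, fit = NULL, ...) {
  plot(x$time_s, x$n_bulk / x$n_total, xlab = "time (s)",
       ylab = expression(N[b](t) / N), pch = 16, cex = 0.4,
       col = "steelblue", ...)
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "kinetics_fit"))
    graphics::lines(x$time_s, model_nb(x$time_s, fit$fractions, fit$rates),
                    col = "orange", lwd = 2)
  }
  invisible(x)
}

#' Attachment vs detachment event balance
#'
#' Counts mobile-to-attached (attachment) and attached-to-mobile (detachment)
#' transitions over all tracks and reports their ratio. A ratio below 10
#' raises a flag: the exponential-mixture analysis neglects the detachment
#' term, which is only admissible when net attachment dominates.
#'
#' @param x a `cell_tracks` object or a tracking table with `cell_id`,
#'   `frame` and logical `attached` columns.
#' @return a `flux_summary` list: `n_attach_events`, `n_detach_events`,
#'   `ratio` (= attach / max(detach, 1)) and `flag` (TRUE when ratio < 10).
#' @export
flux_check <- function(x) {
  if (inherits(x, "cell_tracks")) {
    lens <- lengths(x$events)
    n_att <- sum(ceiling(lens / 2))
    n_det <- sum(floor(lens / 2))
  } else {
    x <- as.data.frame(x)
    need <- c("cell_id", "frame", "attached")
    if (!all(need %in% names(x))) {
      stop("tracking table must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    x <- x[order(x$cell_id, x$frame), , drop = FALSE]
    tr <- unlist(lapply(split(x$attached, x$cell_id), diff), use.names = FALSE)
    n_att <- sum(tr == 1)
    n_det <- sum(tr == -1)
  }
  ratio <- n_att / max(n_det, 1)
  structure(
    list(n_attach_events = n_att, n_detach_events = n_det,
         ratio = ratio, flag = ratio < 10),
    class = "flux_summary"
  )
}

#' @export
print.flux_summary <- function(x, ...) {
  cat(sprintf("<flux_summary> %d attach, %d detach events (ratio %.3g)%s\n",
              x$n_attach_events, x$n_detach_events, x$ratio,
              if (x$flag) " -- WARNING: detachment not negligible" else ""))
  invisible(x)
}

#' Reconstruct a lineage forest from parent-linked tracks
#'
#' Builds division-event genealogies from a tracking table whose `parent_id`
#' column links daughter tracks to their mother. A division occurs where a
#' mother's track ends and daughter tracks begin. Each daughter's fate is
#' inferred from how its track ends: a final mobile frame before the movie
#' end is an explicit detach ("leave"); a track reaching the movie end is
#' "stay" when observed for at least `censor_frames` frames after birth and
#' "censored" otherwise (movie-edge rule); a track itself ending in a
#' division is "stay" (the cell remained to divide). A track lost early
#' while attached, with no daughters, is "censored".
#'
#' Daughters whose parent id is unknown, or whose birth frame does not abut
#' the parent's last frame, are returned in the `orphans` attribute rather
#' than silently dropped. Parent cycles are a structural error.
#'
#' @param tracks tracking table with columns `cell_id`, `parent_id`,
#'   `frame`, `time_s`, `attached`.
#' @param censor_frames minimum frames a daughter must be observed
#'   post-division to count as "stay" at the movie edge. Default 3.
#' @return a `lineage_forest` (see [simulate_lineage()]) with an `orphans`
#'   character vector attribute.
#' @export
extract_division_events <- function(tracks, censor_frames = 3) {
  tracks <- as.data.frame(tracks)
  need <- c("cell_id", "parent_id", "frame", "time_s", "attached")
  if (!all(need %in% names(tracks))) {
    stop("tracking table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tracks <- tracks[order(tracks$cell_id, tracks$frame), , drop = FALSE]
  by_cell <- split(tracks, tracks$cell_id)
  ids <- names(by_cell)
  t_birth <- vapply(by_cell, function(d) d$time_s[1], numeric(1))
  t_last <- vapply(by_cell, function(d) d$time_s[nrow(d)], numeric(1))
  last_attached <- vapply(by_cell, function(d) d$attached[nrow(d)], logical(1))
  n_frames <- vapply(by_cell, nrow, integer(1))
  parent <- vapply(by_cell, function(d) as.character(d$parent_id[1]), character(1))
  parent[parent %in% c("NA", "")] <- NA_character_
  t_end_movie <- max(tracks$time_s)
  dt <- stats::median(diff(sort(unique(tracks$time_s))))

  # cycle check via parent traversal
  for (i in seq_along(ids)) {
    seen <- character(0)
    p <- ids[i]
    while (!is.na(p)) {
      if (p %in% seen) stop("parent cycle detected at cell ", p, call. = FALSE)
      seen <- c(seen, p)
      p <- if (p %in% ids) parent[match(p, ids)] else NA_character_
    }
  }

  orphans <- character(0)
  for (i in seq_along(ids)) {
    p <- parent[i]
    if (is.na(p)) next
    if (!(p %in% ids)) {
      orphans <- c(orphans, ids[i])
      parent[i] <- NA_character_
    } else if (t_birth[i] - t_last[match(p, ids)] > 1.5 * dt ||
               t_birth[i] < t_last[match(p, ids)] - 0.5 * dt) {
      orphans <- c(orphans, ids[i])
      parent[i] <- NA_character_
    }
  }

  has_daughters <- ids %in% parent
  t_division <- ifelse(has_daughters, t_last, NA_real_)
  fate <- character(length(ids))
  for (i in seq_along(ids)) {
    if (has_daughters[i]) {
      fate[i] <- "stay"            # remained attached until it divided
    } else if (!last_attached[i]) {
      fate[i] <- "leave"           # explicit detach event
    } else if (t_last[i] >= t_end_movie - 0.5 * dt) {
      fate[i] <- if (n_frames[i] >= censor_frames) "stay" else "censored"
    } else {
      fate[i] <- "censored"        # lost while attached, no division
    }
  }

  nodes <- data.frame(
    id = ids, parent = parent, t_birth_s = t_birth,
    t_division_s = t_division,
    t_end_s = t_last, fate = fate, stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  out <- structure(
    list(nodes = nodes, roots = ids[is.na(parent)], config = NULL),
    class = "lineage_forest"
  )
  attr(out, "orphans") <- orphans
  out
}
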