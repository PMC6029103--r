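#' Lineage simulation configuration
#'
#' Parameters of a synthetic flow-cell genealogy: founder cells attached at
#' time 0 grow and divide; at every division an independent postdivision fate
#' is drawn from `fate_probs` — both daughters stay on the surface, exactly
#' one stays, or both leave (detach under flow). Division intervals are
#' exponential with the stated mean (the interval distribution is a modeling
#' choice; see the package vignette). A leaving daughter detaches after a
#' truncated-exponential residence time, so every drawn "leave" produces an
#' observable detach event within the movie.
#'
#' @param n_founders number of founder (mother) cells. Default 50.
#' @param fate_probs probabilities `c(p_both_stay, p_one_stays, p_both_leave)`;
#'   nonnegative, summing to 1 (tolerance 1e-12).
#' @param mean_division_interval mean time between divisions in seconds.
#'   Default 2400 s (~40 min, typical for surface-growing P. aeruginosa).
#' @param duration observation window in seconds. Default 72000 s (20 h, the
#'   early-biofilm monitoring window this emulates).
#' @param mean_residence_leave mean surface-residence time (s) of a leaving
#'   daughter before its detach event. Default `mean_division_interval / 5`.
#' @param seed integer seed.
#' @param max_nodes safety cap on the forest size (supercritical fate
#'   distributions grow geometrically). Default 2e5; exceeding it is an error.
#' @return an object of class `lineage_config`.
#' @seealso [fate_presets()] for per-strain fate distributions.
#' @export
lineage_config <- function(n_founders = 50,
                           fate_probs = c(0.27, 0.43, 0.30),
                           mean_division_interval = 2400,
                           duration = 72000,
                           mean_residence_leave = mean_division_interval / 5,
                           seed = NULL, max_nodes = 2e5) {
  check_scalar(n_founders, "n_founders", lower = 1)
  check_scalar(mean_division_interval, "mean_division_interval",
               lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(mean_residence_leave, "mean_residence_leave",
               lower = 0, strict_lower = TRUE)
  if (!is.numeric(fate_probs) || length(fate_probs) != 3L ||
      any(fate_probs < 0)) {
    stop("`fate_probs` must be 3 nonnegative probabilities", call. = FALSE)
  }
  if (abs(sum(fate_probs) - 1) > 1e-12) {
    stop("`fate_probs` must sum to 1 (tolerance 1e-12)", call. = FALSE)
  }
  structure(
    list(n_founders = as.integer(n_founders),
         fate_probs = as.numeric(fate_probs),
         mean_division_interval = mean_division_interval,
         duration = duration,
         mean_residence_leave = mean_residence_leave,
         seed = seed, max_nodes = max_nodes),
    class = "lineage_config"
  )
}

#' Postdivision fate distributions for the three reference strains
#'
#' Per-strain `c(p_both_stay, p_one_stays, p_both_leave)` triples matching
#' the reported early-biofilm behavior: the Psl-heterogeneous wild type
#' divides asymmetrically (one daughter stays, one leaves, the dominant
#' category at > 40%); the uniformly Psl-expressing B0034psl strain keeps
#' both daughters attached (~80% both-stay); the Psl-deficient PAOYs1 strain
#' loses both daughters most of the time (60% both-leave). Only the headline
#' component of each triple is a reported value; the split of the remainder
#' is a fixed package choice (see the vignette).
#'
#' @param strain one of `"PAO1"`, `"B0034psl"`, `"PAOYs1"`.
#' @return a named numeric triple summing to 1.
#' @export
fate_presets <- function(strain = c("PAO1", "B0034psl", "PAOYs1")) {
  strain <- match.arg(strain)
  p <- switch(strain,
    PAO1 = c(0.27, 0.43, 0.30),
    B0034psl = c(0.80, 0.15, 0.05),
    PAOYs1 = c(0.10, 0.30, 0.60)
  )
  names(p) <- c("both_stay", "one_stays", "both_leave")
  p
}

# residence time of a leaving daughter: exponential truncated at the time
# remaining in the movie, so the detach event is always observed
rexp_trunc <- function(n, rate, upper) {
  u <- stats::runif(n, 0, stats::pexp(upper, rate))
  stats::qexp(u, rate)
}

#' Simulate genealogical trees with postdivision fates
#'
#' Generates a `lineage_forest`: founders attached at t = 0 divide at
#' exponential intervals; each division draws an independent fate from
#' `fate_probs`. "Stay" daughters continue dividing until the observation
#' window ends; "leave" daughters terminate with a recorded detach event.
#' A duration shorter than the first division interval yields a valid forest
#' with zero divisions.
#'
#' @param cfg a [lineage_config()].
#' @return an object of class `lineage_forest`: a list with `nodes` (one row
#'   per cell: `id`, `parent`, `t_birth_s`, `t_division_s` (NA if the cell
#'   never divides), `t_end_s` (division, detach, or movie end), `fate` in
#'   `{"stay", "leave"}`), `roots` (founder ids) and `config`.
#' @examples
#' f <- simulate_lineage(lineage_config(n_founders = 10,
#'                                      fate_probs = fate_presets("PAOYs1"),
#'                                      seed = 1))
#' fate_probabilities(classify_fates(f))
#' @export
simulate_lineage <- function(cfg) {
  stopifnot(inherits(cfg, "lineage_config"))
  div_rate <- 1 / cfg$mean_division_interval
  leave_rate <- 1 / cfg$mean_residence_leave

  forest <- with_seed(cfg$seed, {
    rows <- list()
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("L%06d", counter)
    }
    add_node <- function(i, p, tb, td, te, f) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = i, parent = p, t_birth_s = tb, t_division_s = td,
        t_end_s = te, fate = f, stringsAsFactors = FALSE)
    }

    # FIFO queue of living (stay) cells: id, parent id, birth time
    queue <- lapply(seq_len(cfg$n_founders), function(i) {
      list(id = new_id(), parent = NA_character_, t_birth = 0)
    })
    head_i <- 1L

    while (head_i <= length(queue)) {
      cur <- queue[[head_i]]
      head_i <- head_i + 1L
      td <- cur$t_birth + stats::rexp(1, div_rate)
      if (td > cfg$duration) {
        add_node(cur$id, cur$parent, cur$t_birth, NA_real_, cfg$duration, "stay")
        next
      }
      add_node(cur$id, cur$parent, cur$t_birth, td, td, "stay")
      cat_fate <- sample.int(3L, 1L, prob = cfg$fate_probs)
      n_stay <- c(2L, 1L, 0L)[cat_fate]
      for (d in 1:2) {
        di <- new_id()
        if (d <= n_stay) {
          queue[[length(queue) + 1L]] <- list(id = di, parent = cur$id,
                                              t_birth = td)
        } else {
          te <- td + rexp_trunc(1, leave_rate, cfg$duration - td)
          add_node(di, cur$id, td, NA_real_, te, "leave")
        }
      }
      if (counter > cfg$max_nodes) {
        stop("lineage exceeds max_nodes = ", cfg$max_nodes,
             " (supercritical fate distribution?)", call. = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  nodes <- forest[order(forest$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(
    list(nodes = nodes, roots = nodes$id[is.na(nodes$parent) &
                                           nodes$t_birth_s == 0],
         config = cfg),
    class = "lineage_forest"
  )
}

#' @export
print.lineage_forest <- function(x, ...) {
  nd <- sum(!is.na(x$nodes$t_division_s))
  cat(sprintf("<lineage_forest> %d cells in %d tree(s), %d division event(s)\n",
              nrow(x$nodes), length(x$roots), nd))
  invisible(x)
}

#' Render a lineage forest as a per-frame tracking table
#'
#' Turns a `lineage_forest` into the long tracking-table format the
#' track-processing functions consume, for round-trip validation against
#' [extract_division_events()]: each cell is present (attached) from birth to
#' its end time; a leaving cell's final frame is mobile (the detach event);
#' positions are a small jitter around a per-tree anchor.
#'
#' @param forest a `lineage_forest`.
#' @param frame_interval frame spacing in seconds. Default 3.
#' @param jitter positional jitter SD in um. Default 0.05.
#' @param seed integer seed for positions.
#' @return a tracking-table data.frame (same columns as [track_table()]).
#' @export
lineage_to_tracks <- function(forest, frame_interval = 3, jitter = 0.05,
                              seed = NULL) {
  stopifnot(inherits(forest, "lineage_forest"))
  nodes <- forest$nodes
  duration <- if (!is.null(forest$config)) forest$config$duration else
    max(nodes$t_end_s)
  pieces <- with_seed(seed, {
    anchors_x <- stats::runif(nrow(nodes), 0, 100)
    anchors_y <- stats::runif(nrow(nodes), 0, 100)
    lapply(seq_len(nrow(nodes)), function(i) {
      f0 <- ceiling(nodes$t_birth_s[i] / frame_interval)
      f1 <- floor(min(nodes$t_end_s[i], duration) / frame_interval)
      if (f1 < f0) f1 <- f0
      frames <- f0:f1
      nf <- length(frames)
      att <- rep(TRUE, nf)
      if (nodes$fate[i] == "leave") att[nf] <- FALSE
      data.frame(
        cell_id = nodes$id[i],
        parent_id = nodes$parent[i],
        phenotype = NA_integer_,
        frame = frames + 1L,
        time_s = frames * frame_interval,
        x_um = anchors_x[i] + stats::rnorm(nf, 0, jitter),
        y_um = anchors_y[i] + stats::rnorm(nf, 0, jitter),
        attached = att,
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
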