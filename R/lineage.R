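#' Classify postdivision daughter fates on a lineage forest
#'
#' Every division event has exactly two daughters; each daughter either
#' stayed on the surface (it divided again or was still attached at the end
#' of the observation window) or left (an explicit detach event). Divisions
#' are partitioned into three exhaustive, mutually exclusive categories:
#' both daughters stay, exactly one stays, or both leave. A division with any
#' censored daughter (observed too briefly to call) is excluded from the
#' classified total `n_div` and counted in `n_censored` instead.
#'
#' @param forest a `lineage_forest` from [simulate_lineage()] or
#'   [extract_division_events()].
#' @return a `fate_counts` list: `n_both_stay`, `n_one_stays`,
#'   `n_both_leave`, `n_div` (their sum), `n_censored`.
#' @export
classify_fates <- function(forest) {
  stopifnot(inherits(forest, "lineage_forest"))
  nodes <- forest$nodes
  div_ids <- nodes$id[!is.na(nodes$t_division_s)]
  counts <- c(both_stay = 0L, one_stays = 0L, both_leave = 0L)
  n_censored <- 0L
  bad <- character(0)
  for (p in div_ids) {
    daughters <- nodes[!is.na(nodes$parent) & nodes$parent == p, , drop = FALSE]
    if (nrow(daughters) != 2L) {
      bad <- c(bad, p)
      next
    }
    f <- daughters$fate
    if (any(f == "censored")) {
      n_censored <- n_censored + 1L
    } else {
      n_stay <- sum(f == "stay")
      counts[3L - n_stay] <- counts[3L - n_stay] + 1L
    }
  }
  if (length(bad)) {
    stop("division node(s) without exactly 2 daughters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_both_stay = unname(counts[1]), n_one_stays = unname(counts[2]),
         n_both_leave = unname(counts[3]), n_div = sum(counts),
         n_censored = n_censored),
    class = "fate_counts"
  )
}

#' @export
print.fate_counts <- function(x, ...) {
  cat(sprintf(paste0("<fate_counts> n_div = %d (both stay %d, one stays %d, ",
                     "both leave %d); %d censored\n"),
              x$n_div, x$n_both_stay, x$n_one_stays, x$n_both_leave,
              x$n_censored))
  invisible(x)
}

#' Postdivision fate probabilities with uncertainty
#'
#' Estimates the per-category fate probabilities as category counts divided
#' by the total number of classified divisions `n_div`. Uncertainty is
#' reported two ways: `err_literal = 1 / n_div`, the convention used in the
#' source experiments' figure legends, and the binomial standard error
#' `sqrt(p (1 - p) / n_div)` per category, which is the appropriate quantity
#' for inference (the literal convention is most plausibly a shorthand for
#' `1 / sqrt(n_div)`; both are preserved so either can be reproduced).
#'
#' @param counts a `fate_counts` from [classify_fates()].
#' @return a `fate_probabilities` list: `p` (named probabilities summing
#'   to 1), `n_div`, `err_literal`, `err_binomial` (named, per category),
#'   and `available`. When `n_div = 0` the probabilities are absent
#'   (`available = FALSE` with an explanatory `reason`).
#' @export
fate_probabilities <- function(counts) {
  stopifnot(inherits(counts, "fate_counts"))
  if (counts$n_div < 1L) {
    return(structure(
      list(available = FALSE,
           reason = "no classified divisions (n_div = 0)",
           p = NULL, n_div = 0L,
           err_literal = NA_real_, err_binomial = NULL),
      class = "fate_probabilities"
    ))
  }
  n <- counts$n_div
  p <- c(both_stay = counts$n_both_stay,
         one_stays = counts$n_one_stays,
         both_leave = counts$n_both_leave) / n
  structure(
    list(available = TRUE, reason = NULL, p = p, n_div = n,
         err_literal = 1 / n,
         err_binomial = sqrt(p * (1 - p) / n)),
    class = "fate_probabilities"
  )
}

#' @export
print.fate_probabilities <- function(x, ...) {
  if (!x$available) {
    cat("<fate_probabilities> unavailable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<fate_probabilities> n_div = %d (err_literal 1/n = %.4g)\n",
              x$n_div, x$err_literal))
  print(data.frame(p = x$p, se_binomial = x$err_binomial))
  invisible(x)
}
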