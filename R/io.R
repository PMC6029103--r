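#' Read and write the pipeline's plain-text interchange formats
#'
#' All on-disk formats are plain text with fixed columns:
#' \describe{
#'   \item{tracks CSV}{`cell_id,parent_id,phenotype,frame,time_s,x_um,y_um,attached`}
#'   \item{series CSV}{`time_s,n_bulk,n_surface,n_total`}
#'   \item{fluorescence CSV}{`cell_id,population,egfp_au,lectin_au,latent_au`}
#'   \item{lineage JSON}{`{"nodes": [{"id","parent","t_birth_s","t_division_s",`
#'     `"t_end_s","fate"}], "config": {...}}` with fate in
#'     `{"stay","leave","censored"}` (`t_end_s` carries the detach/censoring
#'     time so forests round-trip exactly)}
#'   \item{height-map CSV}{a plain n x m numeric grid, no header}
#' }
#'
#' @param x the object to write.
#' @param path file path.
#' @return readers return the parsed object; writers return `path`
#'   invisibly.
#' @name attachkin-io
NULL

tracks_cols <- c("cell_id", "parent_id", "phenotype", "frame", "time_s",
                 "x_um", "y_um", "attached")

#' @rdname attachkin-io
#' @export
write_tracks <- function(x, path) {
  x <- as.data.frame(x)
  if (!all(tracks_cols %in% names(x))) {
    stop("tracks table must have columns ", paste(tracks_cols, collapse = ","),
         call. = FALSE)
  }
  utils::write.csv(x[, tracks_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname attachkin-io
#' @export
read_tracks <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(x), tracks_cols)) {
    stop("not a tracks CSV: expected columns ",
         paste(tracks_cols, collapse = ","), call. = FALSE)
  }
  x$attached <- as.logical(x$attached)
  x$cell_id <- as.character(x$cell_id)
  x$parent_id <- as.character(x$parent_id)
  x
}

#' @rdname attachkin-io
#' @export
write_series <- function(x, path) {
  x <- as.data.frame(x)
  cols <- c("time_s", "n_bulk", "n_surface", "n_total")
  if (!all(cols %in% names(x))) {
    stop("series must have columns ", paste(cols, collapse = ","), call. = FALSE)
  }
  utils::write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname attachkin-io
#' @export
read_series <- function(path) {
  x <- utils::read.csv(path)
  cols <- c("time_s", "n_bulk", "n_surface", "n_total")
  if (!identical(names(x), cols)) {
    stop("not a series CSV: expected columns ", paste(cols, collapse = ","),
         call. = FALSE)
  }
  structure(x, class = c("attachment_series", "data.frame"))
}

#' @rdname attachkin-io
#' @export
write_fluor <- function(x, path) {
  x <- as.data.frame(x)
  cols <- c("cell_id", "population", "egfp_au", "lectin_au", "latent_au")
  if (!all(cols %in% names(x))) {
    stop("fluorescence table must have columns ", paste(cols, collapse = ","),
         call. = FALSE)
  }
  utils::write.csv(x[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname attachkin-io
#' @export
read_fluor <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("cell_id", "population", "egfp_au", "lectin_au", "latent_au")
  if (!identical(names(x), cols)) {
    stop("not a fluorescence CSV: expected columns ",
         paste(cols, collapse = ","), call. = FALSE)
  }
  x
}

#' @rdname attachkin-io
#' @export
write_lineage_json <- function(x, path) {
  stopifnot(inherits(x, "lineage_forest"))
  nodes <- x$nodes
  payload <- list(
    nodes = lapply(seq_len(nrow(nodes)), function(i) {
      list(
        id = nodes$id[i],
        parent = if (is.na(nodes$parent[i])) NULL else nodes$parent[i],
        t_birth_s = nodes$t_birth_s[i],
        t_division_s = if (is.na(nodes$t_division_s[i])) NULL else
          nodes$t_division_s[i],
        t_end_s = nodes$t_end_s[i],
        fate = nodes$fate[i]
      )
    }),
    config = if (is.null(x$config)) NULL else unclass(x$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname attachkin-io
#' @export
read_lineage_json <- function(path) {
  payload <- jsonlite::read_json(path)
  pick <- function(node, field, default = NA) {
    v <- node[[field]]
    if (is.null(v)) default else v
  }
  nodes <- do.call(rbind, lapply(payload$nodes, function(nd) {
    data.frame(
      id = pick(nd, "id", NA_character_),
      parent = pick(nd, "parent", NA_character_),
      t_birth_s = as.numeric(pick(nd, "t_birth_s", NA_real_)),
      t_division_s = as.numeric(pick(nd, "t_division_s", NA_real_)),
      t_end_s = as.numeric(pick(nd, "t_end_s", NA_real_)),
      fate = pick(nd, "fate", NA_character_),
      stringsAsFactors = FALSE
    )
  }))
  cfg <- payload$config
  if (!is.null(cfg)) {
    cfg$fate_probs <- as.numeric(unlist(cfg$fate_probs))
    cfg <- do.call(lineage_config,
                   cfg[intersect(names(cfg), names(formals(lineage_config)))])
  }
  structure(
    list(nodes = nodes,
         roots = nodes$id[is.na(nodes$parent)],
         config = cfg),
    class = "lineage_forest"
  )
}

#' @rdname attachkin-io
#' @param pixel_size lateral pixel size (um) to attach when reading a
#'   height-map grid.
#' @export
write_heightmap <- function(x, path) {
  stopifnot(inherits(x, "height_map"))
  utils::write.table(x$grid, path, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(path)
}

#' @rdname attachkin-io
#' @export
read_heightmap <- function(path, pixel_size = 1) {
  g <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(g) <- NULL
  height_map(g, pixel_size)
}
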