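#' Hexagonal electrode-array geometry
#'
#' Builds the planar electrode layout of a full-frame HD-MEA chip: `n_rows`
#' rows of `n_cols` electrodes on a hexagonal (triangular) lattice. Odd rows
#' are shifted by `pitch/2` in x and rows are spaced `pitch * sqrt(3)/2`
#' apart, so that every interior electrode has exactly six nearest
#' neighbours at distance `pitch`. Electrode ids are 0-based, row-major.
#'
#' The default lattice has 102 x 192 = 19,584 electrodes at 18.0 um pitch
#' (an extent of roughly 1.6 x 3.4 mm^2), the geometry of the dual-mode
#' array the analysis targets.
#'
#' @param n_rows,n_cols lattice dimensions (>= 1).
#' @param pitch nearest-neighbour electrode distance in um (> 0).
#' @return An object of class `electrode_array`: a list with integer vector
#'   `ids` (0-based), numeric vectors `x` and `y` (um), and the lattice
#'   parameters.
#' @examples
#' arr <- hex_array(4, 4)
#' neighbors_within(arr, 5L, 18)
#' @export
hex_array <- function(n_rows = 102L, n_cols = 192L, pitch = 18) {
  if (length(n_rows) != 1L || length(n_cols) != 1L || n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("invalid parameter: n_rows and n_cols must be positive integers")
  if (length(pitch) != 1L || !is.finite(pitch) || pitch <= 0)
    stop("invalid parameter: pitch must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  r <- rep(seq_len(n_rows) - 1L, each = n_cols)
  c <- rep(seq_len(n_cols) - 1L, times = n_rows)
  structure(list(
    ids   = r * n_cols + c,
    x     = c * pitch + (r %% 2L) * pitch / 2,
    y     = r * pitch * sqrt(3) / 2,
    n_rows = n_rows, n_cols = n_cols, pitch = pitch
  ), class = "electrode_array")
}

#' Electrode array from explicit positions
#'
#' @param ids integer electrode ids (distinct).
#' @param x,y coordinates in um.
#' @return An `electrode_array` without lattice parameters.
#' @export
electrode_array <- function(ids, x, y) {
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("invalid parameter: duplicated electrode ids")
  if (length(x) != length(ids) || length(y) != length(ids))
    stop("invalid parameter: ids, x, y must have equal length")
  o <- order(ids)
  structure(list(ids = ids[o], x = as.numeric(x)[o], y = as.numeric(y)[o]),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat("<electrode_array> ", length(x$ids), " electrodes",
      if (!is.null(x$pitch)) sprintf(", %d x %d hex lattice, pitch %.1f um",
                                     x$n_rows, x$n_cols, x$pitch),
      "\n", sep = "")
  invisible(x)
}

#' Number of electrodes
#' @param array an `electrode_array`.
#' @export
n_electrodes <- function(array) length(array$ids)

#' Electrode positions
#' @param array an `electrode_array`.
#' @param ids optional electrode ids to look up (error on unknown id).
#' @return two-column matrix of x, y in um.
#' @export
electrode_positions <- function(array, ids = NULL) {
  if (is.null(ids)) return(cbind(x = array$x, y = array$y))
  idx <- match(as.integer(ids), array$ids)
  if (anyNA(idx)) stop("unknown electrode id: ", paste(ids[is.na(idx)], collapse = ", "))
  cbind(x = array$x[idx], y = array$y[idx])
}

#' Electrodes within a radius of a center electrode
#'
#' All electrodes (excluding the center itself) at Euclidean distance
#' `<= radius` um from `center`, in ascending-id order. Distances are
#' compared with a 1e-6 um tolerance so lattice neighbours at exactly one
#' pitch are retained despite floating-point rounding.
#'
#' @param array an `electrode_array`.
#' @param center electrode id.
#' @param radius search radius in um (>= 0).
#' @return integer vector of electrode ids.
#' @export
neighbors_within <- function(array, center, radius) {
  if (length(radius) != 1L || !is.finite(radius) || radius < 0)
    stop("invalid parameter: radius must be >= 0")
  p <- electrode_positions(array, center)
  d2 <- (array$x - p[1, "x"])^2 + (array$y - p[1, "y"])^2
  keep <- d2 <= (radius + 1e-6)^2 & array$ids != as.integer(center)
  sort(array$ids[keep])
}

#' Write / read electrode geometry as CSV
#'
#' Plain-text exchange format with columns `id,x_um,y_um`; coordinates are
#' written with 17 significant digits so doubles round-trip exactly.
#'
#' @param array an `electrode_array`.
#' @param path CSV file path.
#' @export
write_geometry_csv <- function(array, path) {
  df <- data.frame(id = array$ids,
                   x_um = sprintf("%.17g", array$x),
                   y_um = sprintf("%.17g", array$y))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  if (!file.exists(path)) stop("format error: missing geometry file ", path)
  df <- utils::read.csv(path)
  need <- c("id", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("format error: geometry CSV missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  electrode_array(df$id, as.numeric(df$x_um), as.numeric(df$y_um))
}
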