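#' Cell mosaic container
#'
#' A labelled point set of cell centers (cone or RPE) for one participant, in
#' retinal microns.  The horizontal axis carries signed eccentricity
#' (negative = nasal) through the `um_per_deg` magnification scale; x = 0 is
#' the anatomically designated foveal center, supplied by the caller.
#'
#' @param x,y cell-center coordinates in um (equal length, no duplicates).
#' @param participant_id participant identifier.
#' @param cell_type `"cone"` or `"rpe"`.
#' @param window analysis window `c(xmin, xmax, ymin, ymax)` in um; defaults
#'   to the bounding box of the points.  All points must lie inside it.
#' @param um_per_deg retinal magnification (um per degree), default 282.
#' @return An object of class `cell_mosaic`: a list with elements `x`, `y`
#'   (um), `ecc_deg` (signed eccentricity of each cell), `participant_id`,
#'   `cell_type`, `window`, `um_per_deg`.
#' @examples
#' m <- cell_mosaic(runif(50, -100, 100), runif(50, -50, 50), "p1", "cone")
#' m
#' @export
cell_mosaic <- function(x, y, participant_id = "s1",
                        cell_type = c("cone", "rpe"),
                        window = NULL, um_per_deg = 282) {
  cell_type <- match.arg(cell_type)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("cell coordinates must be finite")
  }
  if (anyDuplicated(cbind(x, y))) stop("duplicate cell centers")
  check_scale(um_per_deg)
  if (is.null(window)) {
    if (length(x) == 0L) stop("an empty mosaic needs an explicit `window`")
    window <- c(range(x), range(y))
  }
  if (length(window) != 4L || window[1] >= window[2] || window[3] >= window[4]) {
    stop("`window` must be c(xmin, xmax, ymin, ymax) with positive extent")
  }
  if (any(x < window[1] | x > window[2] | y < window[3] | y > window[4])) {
    stop("all points must lie inside `window`")
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         ecc_deg = as.numeric(x) / um_per_deg,
         participant_id = as.character(participant_id),
         cell_type = cell_type,
         window = as.numeric(window), um_per_deg = um_per_deg),
    class = "cell_mosaic"
  )
}

#' @export
print.cell_mosaic <- function(x, ...) {
  cat(sprintf(
    "<cell_mosaic> %s, %s: %d cells, window [%.0f, %.0f] x [%.0f, %.0f] um (%.1f um/deg)\n",
    x$participant_id, x$cell_type, length(x$x),
    x$window[1], x$window[2], x$window[3], x$window[4], x$um_per_deg))
  invisible(x)
}

#' @export
as.data.frame.cell_mosaic <- function(x, ...) {
  data.frame(participant_id = x$participant_id, cell_type = x$cell_type,
             x_um = x$x, y_um = x$y, ecc_deg = x$ecc_deg)
}

#' Read and write cell-center tables
#'
#' CSV interchange format with columns `participant_id`, `cell_type`
#' (`cone`/`rpe`), `x_um`, `y_um`, `ecc_deg` (signed, negative = nasal).
#'
#' @param path file path.
#' @param mosaics a `cell_mosaic` or list of them (for writing).
#' @param um_per_deg magnification used to rebuild mosaics on read.
#' @return `read_cell_table()`: a list of `cell_mosaic` objects (one per
#'   participant x cell type); `write_cell_table()`: the path, invisibly.
#' @export
write_cell_table <- function(mosaics, path) {
  if (inherits(mosaics, "cell_mosaic")) mosaics <- list(mosaics)
  tab <- do.call(rbind, lapply(mosaics, as.data.frame))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path, um_per_deg = 282) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "cell_type", "x_um", "y_um")
  if (!all(need %in% names(tab))) {
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  }
  parts <- split(tab, list(tab$participant_id, tab$cell_type), drop = TRUE)
  out <- lapply(parts, function(d) {
    cell_mosaic(d$x_um, d$y_um, participant_id = d$participant_id[1],
                cell_type = d$cell_type[1], um_per_deg = um_per_deg)
  })
  names(out) <- vapply(out, function(m)
    paste(m$participant_id, m$cell_type, sep = "."), character(1))
  out
}

#' Read and write thickness-profile tables
#'
#' CSV with columns `participant_id`, `ecc_deg`, `thickness_mm` (ILM to
#' RPE-BrM distance).
#'
#' @param profiles a `thickness_profile` or list of them.
#' @param path file path.
#' @return `read_thickness_table()`: list of `thickness_profile` objects.
#' @export
write_thickness_table <- function(profiles, path) {
  if (inherits(profiles, "thickness_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(participant_id = p$participant_id, ecc_deg = p$grid,
               thickness_mm = p$thickness)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thickness_table
#' @export
read_thickness_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$participant_id), function(d) {
    thickness_profile(d$ecc_deg, d$thickness_mm, d$participant_id[1])
  })
}

#' Retinal thickness profile
#'
#' @param grid eccentricities in degrees, strictly increasing.
#' @param thickness thickness in mm (ILM to RPE-BrM), all > 0.
#' @param participant_id identifier.
#' @return An object of class `thickness_profile`.
#' @export
thickness_profile <- function(grid, thickness, participant_id = "s1") {
  if (length(grid) != length(thickness)) stop("grid/thickness length mismatch")
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing")
  }
  if (any(thickness <= 0)) stop("thickness must be > 0 (mm)")
  structure(list(grid = as.numeric(grid), thickness = as.numeric(thickness),
                 participant_id = as.character(participant_id)),
            class = "thickness_profile")
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf(
    "<thickness_profile> %s: %d points, ecc [%.2f, %.2f] deg, thickness [%.3f, %.3f] mm\n",
    x$participant_id, length(x$grid), min(x$grid), max(x$grid),
    min(x$thickness), max(x$thickness)))
  invisible(x)
}
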