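#' Voronoi tessellation statistics for a cell mosaic
#'
#' Tessellates the cell centers and returns one record per cell: number of
#' Voronoi neighbours (cells sharing a Voronoi edge, i.e. Delaunay
#' neighbours), mean inter-cell distance to those neighbours (ICD, um),
#' Voronoi polygon area (um^2), a bounded flag (all Voronoi vertices strictly
#' inside `bounding_region`), signed eccentricity, and the local density
#' implied by the ICD under hexagonal packing ([icd_to_density()]).
#'
#' Cells on the convex hull (or whose polygons are clipped by the analysis
#' window) have vertices on the window border and are therefore never
#' bounded with respect to any region contained in the window.
#'
#' @param mosaic a [cell_mosaic()].
#' @param bounding_region region for the bounded flag: `c(xmin, xmax, ymin,
#'   ymax)` in um, or a [roi_spec()].  Defaults to the mosaic window (so hull
#'   cells are unbounded).
#' @return A data frame of class `voronoi_stats` with columns `x_um`, `y_um`,
#'   `ecc_deg`, `n_neighbors`, `icd_um`, `area_um2`, `bounded`,
#'   `density_icd_mm2`, plus attributes `tiles` (per-cell Voronoi vertex
#'   matrices), `window`, `um_per_deg`, `participant_id`, `cell_type`.
#' @examples
#' m <- cell_mosaic(runif(60, 0, 100), runif(60, 0, 100), cell_type = "cone")
#' vs <- mosaic_stats(m)
#' head(vs)
#' @export
mosaic_stats <- function(mosaic, bounding_region = NULL) {
  stopifnot(inherits(mosaic, "cell_mosaic"))
  n <- length(mosaic$x)
  if (n < 4L) stop("tessellation needs at least 4 points")
  if (qr(cbind(mosaic$x - mean(mosaic$x), mosaic$y - mean(mosaic$y)))$rank < 2L) {
    stop("points are collinear; Voronoi tessellation is degenerate")
  }
  if (is.null(bounding_region)) bounding_region <- mosaic$window

  dd <- deldir::deldir(mosaic$x, mosaic$y, rw = mosaic$window,
                       suppressMsge = TRUE)
  # neighbours = cells sharing a Voronoi edge of positive length (dirsgs);
  # this excludes the degenerate zero-length edges a Delaunay triangulation
  # introduces for cocircular configurations such as square lattices
  seg <- dd$dirsgs
  elen <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  keep <- elen > 1e-9
  i1 <- seg$ind1[keep]
  i2 <- seg$ind2[keep]
  # centre-to-centre distance for each neighbouring pair
  pdist <- sqrt((mosaic$x[i1] - mosaic$x[i2])^2 +
                  (mosaic$y[i1] - mosaic$y[i2])^2)
  nn <- numeric(n)
  icd_sum <- numeric(n)
  tab1 <- tapply(pdist, i1, sum)
  tab2 <- tapply(pdist, i2, sum)
  icd_sum[as.integer(names(tab1))] <- icd_sum[as.integer(names(tab1))] + tab1
  icd_sum[as.integer(names(tab2))] <- icd_sum[as.integer(names(tab2))] + tab2
  cnt1 <- table(i1)
  cnt2 <- table(i2)
  nn[as.integer(names(cnt1))] <- nn[as.integer(names(cnt1))] + cnt1
  nn[as.integer(names(cnt2))] <- nn[as.integer(names(cnt2))] + cnt2
  icd <- icd_sum / pmax(nn, 1)

  tiles <- deldir::tile.list(dd)
  tile_xy <- lapply(tiles, function(t) cbind(t$x, t$y))
  area <- vapply(tiles, function(t) t$area, numeric(1))

  out <- data.frame(
    x_um = mosaic$x, y_um = mosaic$y, ecc_deg = mosaic$ecc_deg,
    n_neighbors = as.integer(nn), icd_um = icd, area_um2 = area,
    bounded = vapply(tile_xy, tile_in_region, logical(1),
                     region = bounding_region),
    density_icd_mm2 = icd_to_density(icd)
  )
  attr(out, "tiles") <- tile_xy
  attr(out, "window") <- mosaic$window
  attr(out, "um_per_deg") <- mosaic$um_per_deg
  attr(out, "participant_id") <- mosaic$participant_id
  attr(out, "cell_type") <- mosaic$cell_type
  class(out) <- c("voronoi_stats", "data.frame")
  out
}

# strict containment of all polygon vertices in a region; vertices within
# floating-point reach of the boundary count as outside (tiles clipped at
# the analysis window land exactly on it up to rounding)
tile_in_region <- function(xy, region) {
  if (inherits(region, "roi_spec")) {
    return(all(in_roi(region, xy[, 1], xy[, 2], strict = TRUE)))
  }
  tol <- 1e-7 * max(region[2] - region[1], region[4] - region[3])
  all(xy[, 1] > region[1] + tol & xy[, 1] < region[2] - tol &
        xy[, 2] > region[3] + tol & xy[, 2] < region[4] - tol)
}

#' Region-of-interest specification
#'
#' @param center ROI center `c(x, y)` in um.
#' @param shape `"square"` (side `size` um), `"circle"` (diameter `size` um)
#'   or `"adaptive_square"` (smallest centered square containing exactly
#'   `size` bounded cells; requires `mode = "bounded"`).
#' @param size side length / diameter in um, or target bounded-cell count.
#' @param mode `"bounded"` counts cells whose Voronoi polygons lie wholly
#'   (strictly) inside the ROI; `"unbounded"` counts cells whose centers fall
#'   in the ROI.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center = c(0, 0),
                     shape = c("square", "circle", "adaptive_square"),
                     size = 50, mode = c("bounded", "unbounded")) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  if (shape == "adaptive_square" && mode != "bounded") {
    stop("adaptive_square requires mode = 'bounded'")
  }
  if (!is.numeric(size) || size <= 0) stop("`size` must be > 0")
  structure(list(center = as.numeric(center), shape = shape,
                 size = as.numeric(size), mode = mode),
            class = "roi_spec")
}

# point-in-ROI test for square/circle (strict = open region)
in_roi <- function(roi, x, y, strict = FALSE, side = NULL) {
  cx <- roi$center[1]; cy <- roi$center[2]
  if (roi$shape == "circle") {
    r <- roi$size / 2
    d2 <- (x - cx)^2 + (y - cy)^2
    if (strict) d2 < r^2 else d2 <= r^2
  } else {
    h <- (if (is.null(side)) roi$size else side) / 2
    if (strict) {
      x > cx - h & x < cx + h & y > cy - h & y < cy + h
    } else {
      x >= cx - h & x <= cx + h & y >= cy - h & y <= cy + h
    }
  }
}

roi_area_mm2 <- function(roi, side = NULL) {
  if (roi$shape == "circle") {
    pi * (roi$size / 2)^2 / 1e6
  } else {
    s <- if (is.null(side)) roi$size else side
    s^2 / 1e6
  }
}

#' ROI cell density
#'
#' Density of cells within a region of interest.  In `bounded` mode only
#' cells whose Voronoi polygons are wholly contained in the ROI are counted,
#' and the density denominator is the summed Voronoi area of those cells:
#' on a perfect lattice this reproduces the true density exactly, whereas
#' the nominal ROI area (available via `denominator = "roi_area"`) loses a
#' border layer of cells and biases the density down by one cell-ring.  In
#' `unbounded` mode cells whose centers fall inside the ROI are counted and
#' the nominal ROI area is always the denominator.
#' `adaptive_square` ROIs grow the smallest centered square containing
#' exactly `roi$size` bounded cells, found by bisection on the side length.
#'
#' @param stats a `voronoi_stats` object from [mosaic_stats()].
#' @param roi a [roi_spec()].
#' @param denominator `"voronoi_area"` (default for bounded mode) or
#'   `"roi_area"`; ignored (nominal area) in unbounded mode.
#' @return A list with `density_mm2`, `count`, `area_mm2`, and for adaptive
#'   ROIs the realized `side_um`.
#' @export
roi_density <- function(stats, roi, denominator = c("voronoi_area", "roi_area")) {
  stopifnot(inherits(stats, "voronoi_stats"), inherits(roi, "roi_spec"))
  denominator <- match.arg(denominator)
  tiles <- attr(stats, "tiles")
  if (is.null(tiles)) stop("`stats` has lost its tile attribute; pass the full mosaic_stats() result")

  if (roi$shape == "adaptive_square") {
    return(adaptive_square_density(stats, roi, tiles, denominator))
  }

  idx <- if (roi$mode == "unbounded") {
    which(in_roi(roi, stats$x_um, stats$y_um))
  } else {
    which(vapply(tiles, function(xy)
      all(in_roi(roi, xy[, 1], xy[, 2], strict = TRUE)), logical(1)))
  }
  count <- length(idx)
  if (count == 0L) warning("ROI contains no cells; density is 0")
  area <- if (roi$mode == "bounded" && denominator == "voronoi_area" &&
              count > 0L) {
    sum(stats$area_um2[idx]) / 1e6
  } else {
    roi_area_mm2(roi)
  }
  list(density_mm2 = count / area, count = count, area_mm2 = area)
}

adaptive_square_density <- function(stats, roi, tiles, denominator) {
  target <- round(roi$size)
  count_at <- function(side) {
    sum(vapply(tiles, function(xy)
      all(in_roi(roi, xy[, 1], xy[, 2], strict = TRUE, side = side)),
      logical(1)))
  }
  win <- attr(stats, "window")
  hi <- 2 * max(win[2] - win[1], win[4] - win[3])
  if (count_at(hi) < target) {
    stop("adaptive ROI target of ", target, " bounded cells is unreachable")
  }
  lo <- 0
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= target) hi <- mid else lo <- mid
  }
  count <- count_at(hi)
  if (count != target) {
    # symmetric configurations admit several cells entering at once; the
    # smallest ROI reaching the target is still well defined
    warning("smallest square ROI reaching ", target,
            " bounded cells contains ", count,
            " (count jumps past the target)")
  }
  idx <- which(vapply(tiles, function(xy)
    all(in_roi(roi, xy[, 1], xy[, 2], strict = TRUE, side = hi)), logical(1)))
  area <- if (denominator == "voronoi_area") {
    sum(stats$area_um2[idx]) / 1e6
  } else {
    hi^2 / 1e6
  }
  list(density_mm2 = count / area, count = count, area_mm2 = area,
       side_um = hi)
}

#' Cones per RPE cell
#'
#' Assigns every cone center to the Voronoi region of the nearest RPE cell
#' (point-in-Voronoi-region membership is equivalent to nearest-center
#' assignment; distance ties are broken toward the RPE cell with the
#' lexicographically smaller center) and counts cones per *bounded* RPE
#' cell.  Cones whose nearest RPE cell is unbounded are reported as
#' unassigned, not dropped silently.
#'
#' @param cone_mosaic a [cell_mosaic()] of cones sharing the RPE coordinate
#'   frame.
#' @param rpe_stats a `voronoi_stats` object for the RPE mosaic (its
#'   `bounded` flags define which RPE cells are scored).
#' @return A data frame (class `cones_per_rpe`) with one row per bounded RPE
#'   cell: `x_um`, `y_um`, `ecc_deg`, `area_um2`, `n_cones`; attribute
#'   `unassigned` gives the number of cones falling in unbounded RPE regions.
#' @export
cones_per_rpe <- function(cone_mosaic, rpe_stats) {
  stopifnot(inherits(cone_mosaic, "cell_mosaic"),
            inherits(rpe_stats, "voronoi_stats"))
  nr <- nrow(rpe_stats)
  centers <- cbind(rpe_stats$x_um, rpe_stats$y_um)
  cones <- cbind(cone_mosaic$x, cone_mosaic$y)
  counts <- integer(nr)
  unassigned <- 0L
  if (nrow(cones) > 0L) {
    k <- min(8L, nr)
    nnres <- FNN::get.knnx(centers, cones, k = k)
    assign_idx <- integer(nrow(cones))
    for (i in seq_len(nrow(cones))) {
      d <- nnres$nn.dist[i, ]
      cand <- nnres$nn.index[i, d <= d[1] + 1e-9]
      if (length(cand) > 1L) {
        cand <- cand[order(centers[cand, 1], centers[cand, 2])]
      }
      assign_idx[i] <- cand[1]
    }
    tb <- table(assign_idx)
    counts[as.integer(names(tb))] <- as.integer(tb)
    unassigned <- sum(counts[!rpe_stats$bounded])
  }
  out <- data.frame(
    x_um = rpe_stats$x_um[rpe_stats$bounded],
    y_um = rpe_stats$y_um[rpe_stats$bounded],
    ecc_deg = rpe_stats$ecc_deg[rpe_stats$bounded],
    area_um2 = rpe_stats$area_um2[rpe_stats$bounded],
    n_cones = counts[rpe_stats$bounded]
  )
  attr(out, "unassigned") <- unassigned
  class(out) <- c("cones_per_rpe", "data.frame")
  out
}

#' Extract per-cell meridian observations
#'
#' Restricts a tessellated mosaic to the horizontal-meridian strip
#' (|vertical position| <= `vertical_halfwidth_deg`) and returns the signed
#' eccentricity, ICD, and ICD-implied density of each retained cell, ready
#' for density-profile fitting.
#'
#' @param stats a `voronoi_stats` object.
#' @param vertical_halfwidth_deg half-height of the strip in degrees
#'   (default 0.5).
#' @param bounded_only keep only bounded cells (default FALSE).
#' @return Data frame with `ecc_deg` (negative = nasal), `icd_um`,
#'   `density_icd_mm2`, `log10_density`, sorted by eccentricity.
#' @export
meridian_extract <- function(stats, vertical_halfwidth_deg = 0.5,
                             bounded_only = FALSE) {
  stopifnot(inherits(stats, "voronoi_stats"))
  half_um <- vertical_halfwidth_deg * attr(stats, "um_per_deg")
  keep <- abs(stats$y_um) <= half_um
  if (bounded_only) keep <- keep & stats$bounded
  d <- stats[keep, , drop = FALSE]
  out <- data.frame(ecc_deg = d$ecc_deg, icd_um = d$icd_um,
                    density_icd_mm2 = d$density_icd_mm2,
                    log10_density = log10(d$density_icd_mm2))
  out[order(out$ecc_deg), , drop = FALSE]
}
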