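# lattice builders and brute-force oracles shared across the suite

# hexagonal lattice with nearest-neighbour spacing `s`, centered near (0, 0)
hex_mosaic <- function(s, nx = 21, ny = 21, cell_type = "cone",
                       um_per_deg = 282, center = c(0, 0)) {
  pts <- do.call(rbind, lapply(0:(ny - 1), function(r) {
    cbind((0:(nx - 1)) * s + (r %% 2) * s / 2, r * s * cos(pi / 6))
  }))
  pts[, 1] <- pts[, 1] - mean(range(pts[, 1])) + center[1]
  pts[, 2] <- pts[, 2] - mean(range(pts[, 2])) + center[2]
  cell_mosaic(pts[, 1], pts[, 2], cell_type = cell_type,
              um_per_deg = um_per_deg)
}

square_mosaic <- function(s, nx = 21, ny = 21, cell_type = "cone") {
  x <- rep(0:(nx - 1), each = ny) * s
  y <- rep(0:(ny - 1), nx) * s
  cell_mosaic(x - mean(range(x)), y - mean(range(y)), cell_type = cell_type)
}

# index of the cell closest to the lattice centroid (deep interior)
interior_cell <- function(stats) {
  which.min((stats$x_um - mean(stats$x_um))^2 +
              (stats$y_um - mean(stats$y_um))^2)
}

# ray-casting point-in-polygon; boundary points are counted as inside
point_in_poly <- function(px, py, xp, yp) {
  n <- length(xp)
  inside <- logical(length(px))
  for (k in seq_along(px)) {
    cnt <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if (((yp[i] > py[k]) != (yp[j] > py[k])) &&
          (px[k] < (xp[j] - xp[i]) * (py[k] - yp[i]) / (yp[j] - yp[i]) + xp[i])) {
        cnt <- !cnt
      }
      j <- i
    }
    inside[k] <- cnt
  }
  inside
}

# brute-force cones-per-RPE oracle: point-in-polygon against every bounded
# RPE Voronoi tile
brute_cones_per_rpe <- function(cone_mosaic, rpe_stats) {
  tiles <- attr(rpe_stats, "tiles")
  idx <- which(rpe_stats$bounded)
  counts <- vapply(idx, function(i) {
    sum(point_in_poly(cone_mosaic$x, cone_mosaic$y,
                      tiles[[i]][, 1], tiles[[i]][, 2]))
  }, numeric(1))
  data.frame(x_um = rpe_stats$x_um[idx], y_um = rpe_stats$y_um[idx],
             n_cones = counts)
}

# closed-form first-principal-component (Deming) slope for a 2x2 covariance
deming_closed_form <- function(x, y) {
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  l1 <- (sxx + syy + sqrt((sxx - syy)^2 + 4 * sxy^2)) / 2
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = l1 / (sxx + syy))
}
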