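# deterministic sub-stream seed: pure function of (seed, index, salt)
stream_seed <- function(seed, index = 0L, salt = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + index * 104729 + salt * 7919
  as.integer(s %% 2147483629) + 1L
}

#' Population configuration for synthetic studies
#'
#' Bundles the population truth of a synthetic multi-participant study: the
#' cone power-law profile, the RPE generalized-exponential profile, the
#' foveal-shape model, the imaged field, the retinal magnification and the
#' mosaic jitter.  Defaults emulate the study conditions the package is
#' designed around: 23 participants, +/-6 degrees of horizontal eccentricity
#' within a +/-0.5 degree vertical strip at 282 um/deg, cone peak densities
#' near 1.3e5 cells/mm^2, RPE peaks near 7.5e3 cells/mm^2, and thickness
#' noise of 0.005 mm.
#'
#' @param n_participants number of participants (>= 1), default 23.
#' @param cone_profile a [power_law_params()] (population truth).
#' @param rpe_profile a [genexp_params()].
#' @param shape_model a [shape_lmm_params()]; by default solved with
#'   [shape_variance_components()] so the between-individual variance split
#'   realizes the canonical 46.3 / 52.2 / 1.5 decomposition.
#' @param field_extent_deg `c(nasal_max, temporal_max, vertical_halfwidth)`
#'   in degrees, all > 0.
#' @param deg_to_um retinal magnification, um per degree (> 0).
#' @param jitter_sd_frac mosaic jitter SD as a fraction of local spacing,
#'   in `[0, 0.5]`.
#' @param thickness_noise_sd Gaussian noise SD on thickness, mm.
#' @param n_thickness_grid thickness grid points across the field.
#' @param seed master seed; every generated quantity is a pure function of
#'   it.
#' @return List of class `population_config`.
#' @export
population_config <- function(n_participants = 23,
                              cone_profile = power_law_params(),
                              rpe_profile = genexp_params(),
                              shape_model = NULL,
                              field_extent_deg = c(nasal_max = 6,
                                                   temporal_max = 6,
                                                   vertical_halfwidth = 0.5),
                              deg_to_um = 282,
                              jitter_sd_frac = 0.12,
                              thickness_noise_sd = 0.005,
                              n_thickness_grid = 61,
                              seed = 1) {
  if (n_participants < 1) stop("`n_participants` must be >= 1")
  if (any(field_extent_deg <= 0)) stop("field extents must be > 0")
  check_scale(deg_to_um)
  if (jitter_sd_frac < 0 || jitter_sd_frac > 0.5) {
    stop("`jitter_sd_frac` must be in [0, 0.5]")
  }
  stopifnot(inherits(cone_profile, "power_law_params"),
            inherits(rpe_profile, "genexp_params"))
  if (is.null(shape_model)) {
    shape_model <- shape_variance_components(cone_profile = cone_profile,
                                             rpe_profile = rpe_profile,
                                             sigma = thickness_noise_sd)
  }
  stopifnot(inherits(shape_model, "shape_lmm_params"))
  structure(list(n_participants = as.integer(n_participants),
                 cone_profile = cone_profile, rpe_profile = rpe_profile,
                 shape_model = shape_model,
                 field_extent_deg = setNames(as.numeric(field_extent_deg),
                                             c("nasal_max", "temporal_max",
                                               "vertical_halfwidth")),
                 deg_to_um = deg_to_um, jitter_sd_frac = jitter_sd_frac,
                 thickness_noise_sd = thickness_noise_sd,
                 n_thickness_grid = as.integer(n_thickness_grid),
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Solve shape-model variance components for a target variance split
#'
#' Chooses the random-effect SDs of the foveal-shape model so that, under
#' the package's variance-decomposition convention (see
#' [variance_decomposition()]) evaluated at the population ICD profiles on a
#' regular meridian grid, the between-individual variance splits into the
#' requested percentages.  The residual SD `sigma` anchors the absolute
#' scale: the total variance is `sigma^2 / (residual share)`.
#'
#' @param split named percentages `c(intercept, cone, rpe, residual)`
#'   summing to 100; default `c(46.3, 40.0, 12.2, 1.5)` (the canonical
#'   intercept / combined-slope / residual decomposition with the combined
#'   52.2% split between cone and RPE roughly in proportion to their
#'   coefficients).
#' @param beta0,beta_c,beta_r fixed effects (defaults: cohort estimates
#'   0.006, 0.291, 0.064).
#' @param sigma residual SD, mm.
#' @param cone_profile,rpe_profile population profiles used to evaluate the
#'   covariates.
#' @param grid_deg meridian grid on which the covariate moments are taken.
#' @return A [shape_lmm_params()] realizing the split.
#' @export
shape_variance_components <- function(split = c(intercept = 46.3, cone = 40.0,
                                                rpe = 12.2, residual = 1.5),
                                      beta0 = 0.006, beta_c = 0.291,
                                      beta_r = 0.064, sigma = 0.005,
                                      cone_profile = power_law_params(),
                                      rpe_profile = genexp_params(),
                                      grid_deg = seq(-5, 5, length.out = 200)) {
  if (abs(sum(split) - 100) > 1e-6) stop("`split` must sum to 100")
  if (any(split < 0)) stop("shares must be >= 0")
  if (split[["residual"]] <= 0) stop("residual share must be > 0")
  x_c <- log10(density_to_icd(10^eval_power_profile(cone_profile, grid_deg)))
  x_r <- log10(density_to_icd(10^eval_genexp_profile(rpe_profile, grid_deg)))
  total <- sigma^2 / (split[["residual"]] / 100)
  shape_lmm_params(beta0 = beta0, beta_c = beta_c, beta_r = beta_r,
                   sd_b0 = sqrt(split[["intercept"]] / 100 * total),
                   sd_bc = sqrt(split[["cone"]] / 100 * total / mean(x_c^2)),
                   sd_br = sqrt(split[["rpe"]] / 100 * total / mean(x_r^2)),
                   sigma = sigma)
}

#' Draw participant random effects
#'
#' Independent zero-mean Gaussian draws for every random effect declared in
#' a parameter object, as a pure function of `(seed, index)`: the same seed
#' and participant index always give the same draws.
#'
#' @param params a [power_law_params()], [genexp_params()] or
#'   [shape_lmm_params()] (the `sd_*` fields are the effect SDs; they are
#'   validated as non-negative by the constructors).
#' @param index participant index (>= 1).
#' @param seed integer seed.
#' @return Named list of realized effects in the parameterization expected
#'   by the matching `eval_*` function (offset/scale effects on the log
#'   scale).
#' @export
draw_participant_effects <- function(params, index, seed = 1) {
  set.seed(stream_seed(seed, index, salt = 11L))
  if (inherits(params, "power_law_params")) {
    list(kappa = rnorm(1, 0, params$sd_kappa),
         pi_n = rnorm(1, 0, params$sd_pi_n),
         pi_t = rnorm(1, 0, params$sd_pi_t),
         log_rho = rnorm(1, 0, params$sd_log_rho))
  } else if (inherits(params, "genexp_params")) {
    list(kappa = rnorm(1, 0, params$sd_kappa),
         log_lambda_n = rnorm(1, 0, params$sd_log_lambda_n),
         log_lambda_t = rnorm(1, 0, params$sd_log_lambda_t),
         log_pi_n = rnorm(1, 0, params$sd_log_pi_n),
         log_pi_t = rnorm(1, 0, params$sd_log_pi_t))
  } else if (inherits(params, "shape_lmm_params")) {
    list(b0 = rnorm(1, 0, params$sd_b0),
         bc = rnorm(1, 0, params$sd_bc),
         br = rnorm(1, 0, params$sd_br))
  } else {
    stop("unsupported parameter object")
  }
}

#' Generate a quasi-hexagonal cell mosaic with a target density profile
#'
#' Lays down a spacing-modulated hexagonal lattice whose local spacing
#' `s(x)` satisfies the hexagonal-packing relation against the requested
#' density profile (`s = density_to_icd(density)`), i.e. columns spaced
#' `s cos(pi/6)` horizontally with in-column spacing `s` and alternating
#' half-spacing vertical offsets, then perturbs every cell by isotropic
#' Gaussian jitter of SD `jitter_sd_frac * s(x)`.  Pairs closer than
#' `0.25 s` have their jitter redrawn (finally reset) so no two cells come
#' closer than a quarter of the local spacing, which protects the Voronoi
#' statistics from degenerate slivers.
#'
#' @param density_fn function of signed eccentricity (deg) returning
#'   cells/mm^2; must be strictly positive and finite over the window.
#' @param window_deg `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param jitter_sd_frac jitter SD as fraction of local spacing, `[0, 0.5]`.
#' @param seed integer seed (bit-identical mosaics for identical seeds).
#' @param um_per_deg retinal magnification.
#' @param participant_id,cell_type passed to [cell_mosaic()].
#' @return A [cell_mosaic()].
#' @examples
#' m <- generate_mosaic(function(e) 10000, c(-1, 1, -0.3, 0.3), seed = 1)
#' @export
generate_mosaic <- function(density_fn, window_deg, jitter_sd_frac = 0.12,
                            seed = 1, um_per_deg = 282,
                            participant_id = "s1",
                            cell_type = c("cone", "rpe")) {
  cell_type <- match.arg(cell_type)
  if (window_deg[1] >= window_deg[2] || window_deg[3] >= window_deg[4]) {
    stop("window has zero or negative area")
  }
  if (jitter_sd_frac < 0 || jitter_sd_frac > 0.5) {
    stop("`jitter_sd_frac` must be in [0, 0.5]")
  }
  win_um <- c(window_deg[1:2] * um_per_deg, window_deg[3:4] * um_per_deg)
  spacing_at <- function(x_um) {
    d <- density_fn(x_um / um_per_deg)
    if (any(!is.finite(d)) || any(d <= 0)) {
      stop("density function must be strictly positive and finite")
    }
    density_to_icd(d)
  }
  # march columns across the window; within a column the spacing is constant
  xs <- list()
  x <- win_um[1]
  colidx <- 0L
  h <- win_um[4] - win_um[3]
  while (x <= win_um[2]) {
    s <- spacing_at(x)
    y0 <- win_um[3] + (if (colidx %% 2L == 1L) s / 2 else 0)
    ys <- seq(y0, win_um[4], by = s)
    if (length(ys)) xs[[length(xs) + 1L]] <- cbind(x, ys, s)
    x <- x + s * cos(pi / 6)
    colidx <- colidx + 1L
    if (length(xs) > 2e5) stop("window too large for the requested density")
  }
  pts <- do.call(rbind, xs)
  colnames(pts) <- c("x", "y", "s")

  set.seed(stream_seed(seed, salt = 23L))
  n <- nrow(pts)
  jit <- matrix(rnorm(2 * n, 0, jitter_sd_frac * pts[, "s"]), ncol = 2)
  xy <- pts[, c("x", "y")] + jit
  # enforce the minimum separation of a quarter of the local spacing
  for (it in seq_len(20)) {
    if (n < 2L) break
    nn <- FNN::get.knn(xy, k = 1)
    bad <- which(nn$nn.dist[, 1] < 0.25 * pts[, "s"])
    if (!length(bad)) break
    if (it == 20L) {
      xy[bad, ] <- pts[bad, c("x", "y")]
      break
    }
    xy[bad, ] <- pts[bad, c("x", "y")] +
      matrix(rnorm(2 * length(bad), 0, jitter_sd_frac * pts[bad, "s"]),
             ncol = 2)
  }
  keep <- xy[, 1] >= win_um[1] & xy[, 1] <= win_um[2] &
    xy[, 2] >= win_um[3] & xy[, 2] <= win_um[4]
  cell_mosaic(xy[keep, 1], xy[keep, 2], participant_id = participant_id,
              cell_type = cell_type, window = win_um,
              um_per_deg = um_per_deg)
}

#' Generate a thickness profile from the shape model
#'
#' Thickness at each grid point is the exact shape-model value
#' ([eval_shape_model()], base-10 logarithms of the ICDs in um) plus
#' Gaussian noise.
#'
#' @param shape a [shape_lmm_params()].
#' @param cone_icd_fn,rpe_icd_fn functions of eccentricity (deg) returning
#'   strictly positive ICDs (um).
#' @param grid_deg eccentricity grid, strictly increasing.
#' @param effects participant shape effects (`b0`, `bc`, `br`).
#' @param noise_sd Gaussian noise SD, mm.
#' @param seed integer seed.
#' @param participant_id identifier.
#' @return A [thickness_profile()].
#' @export
generate_thickness <- function(shape, cone_icd_fn, rpe_icd_fn, grid_deg,
                               effects = list(), noise_sd = 0.005, seed = 1,
                               participant_id = "s1") {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  ci <- cone_icd_fn(grid_deg)
  ri <- rpe_icd_fn(grid_deg)
  if (any(ci <= 0) || any(ri <= 0)) stop("ICD profiles must be > 0")
  mu <- eval_shape_model(shape, ci, ri, effects)
  set.seed(stream_seed(seed, salt = 31L))
  thickness_profile(grid_deg, mu + rnorm(length(grid_deg), 0, noise_sd),
                    participant_id = participant_id)
}

# per-participant density functions (cells/mm^2) implied by the config
participant_density_fns <- function(config, index) {
  ce <- draw_participant_effects(config$cone_profile, index,
                                 stream_seed(config$seed, salt = 1L))
  re <- draw_participant_effects(config$rpe_profile, index,
                                 stream_seed(config$seed, salt = 2L))
  list(
    cone_effects = ce, rpe_effects = re,
    cone_density = function(ecc) {
      10^eval_power_profile(config$cone_profile, ecc, ce)
    },
    rpe_density = function(ecc) {
      10^eval_genexp_profile(config$rpe_profile, ecc, re)
    }
  )
}

#' Generate a complete synthetic study
#'
#' For each participant: draws random effects for the cone, RPE and shape
#' models, builds the participant's density functions, generates cone and
#' RPE mosaics over the meridian strip, and generates a thickness profile
#' on a regular grid.  Realized effects are stored so recovery tests can
#' compare estimates with truth.  Identical configs give bit-identical
#' studies.
#'
#' @param config a [population_config()].
#' @return Object of class `synthetic_study`: list with `participants`
#'   (each: `id`, `cone`, `rpe` mosaics, `thickness`, `effects`) and
#'   `config`.
#' @export
generate_study <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  fe <- config$field_extent_deg
  window_deg <- c(-fe[["nasal_max"]], fe[["temporal_max"]],
                  -fe[["vertical_halfwidth"]], fe[["vertical_halfwidth"]])
  grid <- seq(-fe[["nasal_max"]], fe[["temporal_max"]],
              length.out = config$n_thickness_grid)
  participants <- lapply(seq_len(config$n_participants), function(i) {
    id <- sprintf("s%02d", i)
    fns <- participant_density_fns(config, i)
    se <- draw_participant_effects(config$shape_model, i,
                                   stream_seed(config$seed, salt = 3L))
    cone <- generate_mosaic(fns$cone_density, window_deg,
                            jitter_sd_frac = config$jitter_sd_frac,
                            seed = stream_seed(config$seed, i, salt = 4L),
                            um_per_deg = config$deg_to_um,
                            participant_id = id, cell_type = "cone")
    rpe <- generate_mosaic(fns$rpe_density, window_deg,
                           jitter_sd_frac = config$jitter_sd_frac,
                           seed = stream_seed(config$seed, i, salt = 5L),
                           um_per_deg = config$deg_to_um,
                           participant_id = id, cell_type = "rpe")
    thickness <- generate_thickness(
      config$shape_model,
      cone_icd_fn = function(e) density_to_icd(fns$cone_density(e)),
      rpe_icd_fn = function(e) density_to_icd(fns$rpe_density(e)),
      grid_deg = grid, effects = se,
      noise_sd = config$thickness_noise_sd,
      seed = stream_seed(config$seed, i, salt = 6L), participant_id = id)
    list(id = id, cone = cone, rpe = rpe, thickness = thickness,
         effects = list(cone = fns$cone_effects, rpe = fns$rpe_effects,
                        shape = se))
  })
  structure(list(participants = participants, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  nc <- vapply(x$participants, function(p) length(p$cone$x), numeric(1))
  nr <- vapply(x$participants, function(p) length(p$rpe$x), numeric(1))
  cat(sprintf(
    "<synthetic_study> %d participants; cones/participant %d-%d, RPE %d-%d (seed %d)\n",
    length(x$participants), min(nc), max(nc), min(nr), max(nr),
    x$config$seed))
  invisible(x)
}

#' Simulate density observations directly from a profile model
#'
#' Draws per-participant random effects, samples eccentricities uniformly
#' over the field, and returns log10-density observations with Gaussian
#' residual noise — the idealized per-cell meridian dataset used for
#' profile-fit recovery studies (mosaic generation and tessellation are
#' exercised separately).
#'
#' @param params a [power_law_params()] or [genexp_params()] population
#'   truth.
#' @param n_participants,n_per_participant study size (defaults 23 x 300).
#' @param ecc_range sampling range in degrees (default `c(-6, 6)`).
#' @param seed integer seed.
#' @return Data frame with `participant_id`, `ecc_deg`, `log10_density`;
#'   attribute `effects` holds the realized per-participant effects.
#' @export
simulate_density_observations <- function(params, n_participants = 23,
                                          n_per_participant = 300,
                                          ecc_range = c(-6, 6), seed = 1) {
  fam_power <- inherits(params, "power_law_params")
  if (!fam_power && !inherits(params, "genexp_params")) {
    stop("`params` must be power_law_params or genexp_params")
  }
  effects <- lapply(seq_len(n_participants), function(i) {
    draw_participant_effects(params, i, seed)
  })
  set.seed(stream_seed(seed, salt = 47L))
  obs <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    ecc <- runif(n_per_participant, ecc_range[1], ecc_range[2])
    mu <- if (fam_power) eval_power_profile(params, ecc, effects[[i]])
    else eval_genexp_profile(params, ecc, effects[[i]])
    data.frame(participant_id = sprintf("s%02d", i), ecc_deg = ecc,
               log10_density = mu + rnorm(n_per_participant, 0, params$sigma))
  }))
  attr(obs, "effects") <- effects
  attr(obs, "truth") <- params
  obs
}

#' Simulate a foveal-shape recovery study
#'
#' Generates the observation table for shape-model recovery: per
#' participant, cone and RPE ICD profiles on a regular meridian grid
#' (population profiles plus that participant's random effects), and
#' thickness from the shape model with participant shape effects and
#' Gaussian noise.
#'
#' @param shape a [shape_lmm_params()] truth (default: the canonical
#'   variance-split solution of [shape_variance_components()]).
#' @param cone_profile,rpe_profile population ICD profile truths.
#' @param n_participants,n_locations study size (defaults 23 x 200).
#' @param max_ecc_deg meridian half-range (default 5).
#' @param seed integer seed.
#' @return List with `observations` (participant_id, ecc_deg, thickness_mm,
#'   cone_icd_um, rpe_icd_um) and `truth` (parameters and realized
#'   effects).
#' @export
simulate_shape_study <- function(shape = NULL,
                                 cone_profile = power_law_params(),
                                 rpe_profile = genexp_params(),
                                 n_participants = 23, n_locations = 200,
                                 max_ecc_deg = 5, seed = 1) {
  if (is.null(shape)) {
    shape <- shape_variance_components(cone_profile = cone_profile,
                                       rpe_profile = rpe_profile)
  }
  stopifnot(inherits(shape, "shape_lmm_params"))
  grid <- seq(-max_ecc_deg, max_ecc_deg, length.out = n_locations)
  effects <- lapply(seq_len(n_participants), function(i) {
    list(cone = draw_participant_effects(cone_profile, i,
                                         stream_seed(seed, salt = 1L)),
         rpe = draw_participant_effects(rpe_profile, i,
                                        stream_seed(seed, salt = 2L)),
         shape = draw_participant_effects(shape, i,
                                          stream_seed(seed, salt = 3L)))
  })
  set.seed(stream_seed(seed, salt = 53L))
  obs <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    e <- effects[[i]]
    ci <- density_to_icd(10^eval_power_profile(cone_profile, grid, e$cone))
    ri <- density_to_icd(10^eval_genexp_profile(rpe_profile, grid, e$rpe))
    t <- eval_shape_model(shape, ci, ri, e$shape) +
      rnorm(n_locations, 0, shape$sigma)
    data.frame(participant_id = sprintf("s%02d", i), ecc_deg = grid,
               thickness_mm = t, cone_icd_um = ci, rpe_icd_um = ri)
  }))
  list(observations = obs,
       truth = list(shape = shape, cone_profile = cone_profile,
                    rpe_profile = rpe_profile, effects = effects))
}

#' Generate a pair of simulated rater counts
#'
#' Two raters re-counting the same true cell counts with independent
#' Gaussian counting noise, rounded to integers and floored at zero.
#'
#' @param true_counts non-negative true counts (e.g. 35 ROI locations).
#' @param rater_sd counting-noise SD (>= 0).
#' @param seed integer seed.
#' @return List with integer vectors `rater1`, `rater2`.
#' @export
generate_rater_pair <- function(true_counts, rater_sd = 2, seed = 1) {
  if (any(true_counts < 0)) stop("`true_counts` must be non-negative")
  if (rater_sd < 0) stop("`rater_sd` must be >= 0")
  set.seed(stream_seed(seed, salt = 61L))
  n <- length(true_counts)
  r1 <- pmax(0, round(true_counts + rnorm(n, 0, rater_sd)))
  r2 <- pmax(0, round(true_counts + rnorm(n, 0, rater_sd)))
  list(rater1 = as.integer(r1), rater2 = as.integer(r2))
}
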