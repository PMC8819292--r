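test_that("participant effect draws are deterministic and degenerate at 0", {
  p <- power_law_params()
  e1 <- draw_participant_effects(p, 3, seed = 17)
  e2 <- draw_participant_effects(p, 3, seed = 17)
  expect_identical(e1, e2)
  e3 <- draw_participant_effects(p, 4, seed = 17)
  expect_false(identical(e1, e3))
  # all variances zero: every effect is exactly 0
  p0 <- power_law_params(sd_kappa = 0, sd_pi_n = 0, sd_pi_t = 0,
                         sd_log_rho = 0)
  e0 <- draw_participant_effects(p0, 1, seed = 1)
  expect_true(all(unlist(e0) == 0))
  s0 <- shape_lmm_params(sd_b0 = 0, sd_bc = 0, sd_br = 0)
  expect_true(all(unlist(draw_participant_effects(s0, 2, seed = 5)) == 0))
})

test_that("effect draws have the declared first two moments", {
  p <- power_law_params(sd_kappa = 1)
  draws <- vapply(1:10000, function(i) {
    draw_participant_effects(p, i, seed = 23)$kappa
  }, numeric(1))
  expect_lt(abs(mean(draws)), 4 / sqrt(10000))
  expect_lt(abs(var(draws) - 1), 0.1)
})

test_that("generated mosaics match the requested density", {
  m <- generate_mosaic(function(e) 10000, c(-1.773, 1.773, -0.5, 0.5),
                       jitter_sd_frac = 0, seed = 1)
  # window is 1000 x 282 um = 0.282 mm^2
  area_mm2 <- (diff(m$window[1:2]) * diff(m$window[3:4])) / 1e6
  expect_lt(abs(length(m$x) / area_mm2 - 10000) / 10000, 0.05)
  # jitter 0: interior Voronoi ICD equals the hexagonal spacing to < 0.1%
  vs <- mosaic_stats(m)
  s_expected <- density_to_icd(10000)
  expect_lt(abs(mean(vs$icd_um[vs$bounded]) - s_expected) / s_expected,
            0.001)
})

test_that("mosaic generation is deterministic and respects the minimum gap", {
  m1 <- generate_mosaic(function(e) 30000, c(-0.5, 0.5, -0.3, 0.3),
                        jitter_sd_frac = 0.2, seed = 9)
  m2 <- generate_mosaic(function(e) 30000, c(-0.5, 0.5, -0.3, 0.3),
                        jitter_sd_frac = 0.2, seed = 9)
  expect_identical(m1$x, m2$x)
  expect_identical(m1$y, m2$y)
  m3 <- generate_mosaic(function(e) 30000, c(-0.5, 0.5, -0.3, 0.3),
                        jitter_sd_frac = 0.2, seed = 10)
  expect_false(identical(m1$x, m3$x))
  # no two cells closer than a quarter of the local spacing
  d <- FNN::get.knn(cbind(m1$x, m1$y), k = 1)$nn.dist[, 1]
  expect_true(all(d >= 0.25 * density_to_icd(30000) - 1e-9))
  expect_error(generate_mosaic(function(e) 0, c(-1, 1, -1, 1)), "positive")
  expect_error(generate_mosaic(function(e) 1e4, c(1, 1, 0, 1)), "area")
})

test_that("subwindow counts track the integrated density (Poisson bands)", {
  # eccentricity-dependent density over a strip; 60 seeded runs, the count
  # in a fixed 0.05 mm^2 subwindow must sit within 3 Poisson SDs of the
  # integral in at least 95% of runs
  dens <- function(e) 20000 * (1 + 0.5 * abs(e))
  win <- c(-1, 1, -0.25, 0.25)
  um <- 282
  sub <- c(-0.65, 0.65)            # interior slab, ~0.052 mm^2
  h_mm <- diff(win[3:4]) * um / 1000
  expected <- integrate(function(e) dens(e) * (um / 1000) * h_mm,
                        sub[1], sub[2])$value
  hits <- vapply(1:60, function(i) {
    m <- generate_mosaic(dens, win, jitter_sd_frac = 0.12, seed = 1000 + i)
    cnt <- sum(m$ecc_deg >= sub[1] & m$ecc_deg <= sub[2])
    abs(cnt - expected) <= 3 * sqrt(expected)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("thickness generation reproduces the shape model exactly", {
  sp <- shape_lmm_params(beta0 = 0.3, beta_c = 0, beta_r = 0,
                         sd_b0 = 0, sd_bc = 0, sd_br = 0)
  grid <- seq(-4, 4, length.out = 17)
  prof <- generate_thickness(sp, function(e) 3 + abs(e),
                             function(e) 13 + abs(e), grid, noise_sd = 0,
                             seed = 1)
  expect_equal(prof$thickness, rep(0.3, 17), tolerance = 1e-15)
  # hand-computed values for non-trivial coefficients
  sp2 <- shape_lmm_params(beta0 = 0.006, beta_c = 0.291, beta_r = 0.064)
  eff <- list(b0 = 0.002, bc = 0.01, br = -0.003)
  prof2 <- generate_thickness(sp2, function(e) 3 + abs(e),
                              function(e) 13 + abs(e), grid, effects = eff,
                              noise_sd = 0, seed = 1)
  hand <- (0.006 + 0.002) + (0.291 + 0.01) * log10(3 + abs(grid)) +
    (0.064 - 0.003) * log10(13 + abs(grid))
  expect_equal(prof2$thickness, hand, tolerance = 1e-15)
  expect_error(generate_thickness(sp2, function(e) -1, function(e) 13,
                                  grid, noise_sd = 0), "> 0")
})

test_that("full study generation is deterministic with stored truth", {
  pop <- population_config(
    n_participants = 3,
    cone_profile = power_law_params(kappa = 4.0),
    rpe_profile = genexp_params(kappa = 8.3),
    field_extent_deg = c(2, 2, 0.35), n_thickness_grid = 21, seed = 5)
  st1 <- generate_study(pop)
  st2 <- generate_study(pop)
  expect_identical(length(st1$participants), 3L)
  for (i in 1:3) {
    p1 <- st1$participants[[i]]
    p2 <- st2$participants[[i]]
    expect_gt(length(p1$cone$x), 0)
    expect_gt(length(p1$rpe$x), 0)
    expect_identical(p1$cone$x, p2$cone$x)
    expect_identical(p1$thickness$thickness, p2$thickness$thickness)
    expect_identical(p1$effects, p2$effects)
  }
  # mosaics live in the +/- vertical halfwidth strip
  expect_true(all(abs(st1$participants[[1]]$cone$y) <= 0.35 * 282))
})

test_that("noise-free thickness is reproduced by the shape-model evaluator", {
  pop <- population_config(
    n_participants = 2,
    cone_profile = power_law_params(kappa = 4.0),
    rpe_profile = genexp_params(kappa = 8.3),
    field_extent_deg = c(1.5, 1.5, 0.3), n_thickness_grid = 15,
    thickness_noise_sd = 1e-12, seed = 8)
  st <- generate_study(pop)
  p <- st$participants[[1]]
  grid <- p$thickness$grid
  ci <- density_to_icd(10^eval_power_profile(pop$cone_profile, grid,
                                             p$effects$cone))
  ri <- density_to_icd(10^eval_genexp_profile(pop$rpe_profile, grid,
                                              p$effects$rpe))
  expect_equal(p$thickness$thickness,
               eval_shape_model(pop$shape_model, ci, ri, p$effects$shape),
               tolerance = 1e-9)
})

test_that("measured central densities straddle the population peak", {
  pop <- population_config(n_participants = 6,
                           field_extent_deg = c(0.6, 0.6, 0.25),
                           n_thickness_grid = 11, seed = 3)
  st <- generate_study(pop)
  central <- vapply(st$participants, function(p) {
    vs <- mosaic_stats(p$cone)
    roi_density(vs, roi_spec(c(0, 0), "square", 40, "unbounded"))$density_mm2
  }, numeric(1))
  peak_truth <- 10^eval_power_profile(pop$cone_profile, 0)
  expect_gt(max(central), peak_truth * 0.85)
  expect_lt(min(central), peak_truth * 1.15)
  expect_gt(peak_truth, 9e4)   # study-like cone peak scale
  expect_lt(peak_truth, 1.8e5)
})

test_that("rater pairs are reproducible, sized, and degrade the ICC", {
  counts <- round(runif(35, 200, 400))
  r0 <- generate_rater_pair(counts, rater_sd = 0, seed = 2)
  expect_identical(r0$rater1, r0$rater2)
  expect_length(r0$rater1, 35)
  r1 <- generate_rater_pair(counts, rater_sd = 5, seed = 2)
  r2 <- generate_rater_pair(counts, rater_sd = 5, seed = 2)
  expect_identical(r1, r2)
  expect_error(generate_rater_pair(counts, rater_sd = -1), ">= 0")
  expect_error(generate_rater_pair(c(-5, 2), 1), "non-negative")
  # noise much larger than the between-location spread kills the ICC
  flat <- rep(100, 40)
  iccs <- vapply(1:100, function(i) {
    r <- generate_rater_pair(flat + rnorm(40, 0, 1), rater_sd = 25,
                             seed = i)
    icc_oneway(cbind(r$rater1, r$rater2))$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs)), 0.1)
})

test_that("simulated density observations carry their ground truth", {
  obs <- simulate_density_observations(power_law_params(),
                                       n_participants = 4,
                                       n_per_participant = 50, seed = 6)
  expect_identical(nrow(obs), 200L)
  expect_length(attr(obs, "effects"), 4)
  obs2 <- simulate_density_observations(power_law_params(),
                                        n_participants = 4,
                                        n_per_participant = 50, seed = 6)
  expect_identical(obs, obs2)
  expect_error(simulate_density_observations(list(), 4, 50), "params")
})
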