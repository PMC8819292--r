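# shape_fit skeleton for decomposition arithmetic checks
fake_shape_fit <- function(varcomp, x_c, x_r) {
  structure(list(include = "both", varcomp = varcomp,
                 data = data.frame(x_c = x_c, x_r = x_r)),
            class = "shape_fit")
}

test_that("thickness spline interpolates knots and reproduces lines", {
  grid <- seq(-5, 5, length.out = 21)
  prof <- thickness_profile(grid, 0.25 + 0.01 * grid, "p1")
  f <- interp_thickness(prof)
  expect_equal(f(grid), prof$thickness, tolerance = 1e-12)
  dense <- seq(-5, 5, length.out = 501)
  expect_equal(f(dense), 0.25 + 0.01 * dense, tolerance = 1e-10)
  expect_error(f(5.5), "outside")
  expect_error(interp_thickness(thickness_profile(1:3, c(1, 2, 3) / 10)),
               "4 grid points")
})

test_that("spline minimum of a pit-like profile sits near the true minimum", {
  grid <- seq(-5, 5, by = 0.5)
  # smooth foveal-pit-like profile with its minimum at 0
  prof <- thickness_profile(grid, 0.35 - 0.15 * exp(-(grid / 1.5)^2), "p1")
  f <- interp_thickness(prof)
  dense <- seq(-5, 5, length.out = 4001)
  expect_lt(abs(dense[which.min(f(dense))]), 0.5)
})

test_that("degenerate LMM (no noise, no random effects) equals OLS", {
  truth <- shape_lmm_params(sd_b0 = 0, sd_bc = 0, sd_br = 0, sigma = 1e-4)
  st <- simulate_shape_study(shape = truth, n_participants = 5,
                             n_locations = 60, seed = 2)
  obs <- st$observations
  fit <- suppressMessages(fit_foveal_shape(obs))
  ols <- lm(thickness_mm ~ log10(cone_icd_um) + log10(rpe_icd_um),
            data = obs)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-4)
})

test_that("shape fits are invariant to observation order", {
  st <- simulate_shape_study(n_participants = 6, n_locations = 50, seed = 5)
  f1 <- suppressMessages(fit_foveal_shape(st$observations))
  set.seed(1)
  f2 <- suppressMessages(
    fit_foveal_shape(st$observations[sample(nrow(st$observations)), ]))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-3)
})

test_that("cohort-scale fit recovers the generating fixed effects", {
  st <- simulate_shape_study(seed = 1)           # 23 x 200 study conditions
  fit <- suppressMessages(fit_foveal_shape(st$observations))
  truth <- st$truth$shape
  cf <- coef(fit)
  # within 2 cohort-scale standard errors of the generating coefficients
  expect_lt(abs(cf[["(Intercept)"]] - truth$beta0), 2 * 0.021)
  expect_lt(abs(cf[["x_c"]] - truth$beta_c), 2 * 0.016)
  expect_lt(abs(cf[["x_r"]] - truth$beta_r), 2 * 0.015)
  # t-values are reported, p-values are not
  expect_true(all(c("estimate", "se", "t_value") %in%
                    names(fit$coefficients)))
  expect_false("p_value" %in% names(fit$coefficients))
})

test_that("variance shares normalize, bound and degenerate correctly", {
  x_c <- runif(50, 0.5, 1)
  x_r <- runif(50, 1, 1.2)
  only_int <- fake_shape_fit(c(intercept = 0.01, cone = 0, rpe = 0,
                               residual = 0), x_c, x_r)
  d <- variance_decomposition(only_int)
  expect_equal(unname(d$shares["intercept"]), 100)
  mixed <- fake_shape_fit(c(intercept = 2e-4, cone = 1e-4, rpe = 5e-5,
                            residual = 1e-5), x_c, x_r)
  dm <- variance_decomposition(mixed)
  expect_equal(sum(dm$shares[c("intercept", "cone", "rpe", "residual")]),
               100, tolerance = 1e-9)
  expect_equal(unname(dm$shares["cone_rpe"]),
               unname(dm$shares["cone"] + dm$shares["rpe"]),
               tolerance = 1e-12)
  expect_true(all(dm$shares >= 0 & dm$shares <= 100))
  zero <- fake_shape_fit(c(intercept = 0, cone = 0, rpe = 0, residual = 0),
                         x_c, x_r)
  expect_error(variance_decomposition(zero), "undefined")
})

test_that("per-participant regressions behave on perfect and null relations", {
  set.seed(8)
  t_mm <- runif(60, 0.2, 0.35)
  d_perfect <- data.frame(participant_id = rep(c("a", "b"), each = 30),
                          thickness_mm = t_mm,
                          value = 10^(0.3 + 2 * t_mm))
  r <- suppressWarnings(per_participant_regressions(d_perfect))
  expect_equal(r$per_participant$r_squared, c(1, 1), tolerance = 1e-10)
  expect_equal(r$per_participant$slope, c(2, 2), tolerance = 1e-8)
  expect_equal(r$median_r2, 1, tolerance = 1e-10)
  # R^2 is invariant to affine rescaling of the metric (log10 scale offset)
  d_scaled <- d_perfect
  d_scaled$value <- d_perfect$value * 37
  r2 <- suppressWarnings(per_participant_regressions(d_scaled))
  expect_equal(r2$per_participant$r_squared,
               r$per_participant$r_squared, tolerance = 1e-10)
  # independent predictor: R^2 near zero at large n
  set.seed(9)
  d_null <- data.frame(participant_id = "a",
                       thickness_mm = runif(1000, 0.2, 0.35),
                       value = 10^rnorm(1000, 1, 0.2))
  rn <- per_participant_regressions(d_null)
  expect_lt(rn$per_participant$r_squared, 0.02)
  # constant metric is skipped with a warning
  d_const <- data.frame(participant_id = "a", thickness_mm = (1:5) / 10,
                        value = 2)
  expect_warning(try(per_participant_regressions(d_const), silent = TRUE),
                 "skipped")
  expect_error(suppressWarnings(per_participant_regressions(d_const)),
               "fittable")
})

test_that("folding nasal/temporal equals mirror-averaging for symmetric data", {
  ecc <- seq(0.2, 5, by = 0.2)
  thick <- 0.2 + 0.02 * ecc
  val <- 10^(0.4 + 0.5 * thick + 0.01 * sin(ecc))
  both <- data.frame(participant_id = "a",
                     thickness_mm = c(thick, thick),
                     value = c(val, val))  # nasal and temporal mirrored
  folded <- suppressWarnings(per_participant_regressions(both))
  single <- suppressWarnings(per_participant_regressions(
    data.frame(participant_id = "a", thickness_mm = thick, value = val)))
  expect_equal(folded$per_participant$slope, single$per_participant$slope,
               tolerance = 1e-10)
  expect_equal(folded$per_participant$r_squared,
               single$per_participant$r_squared, tolerance = 1e-10)
})

test_that("shape prediction round-trips the generator and is monotone", {
  truth <- shape_lmm_params()
  grid <- seq(-5, 5, length.out = 41)
  ci <- function(e) 3 + 1.5 * abs(e)
  ri <- function(e) 12 + 0.8 * abs(e)
  eff <- list(b0 = 0.01, bc = -0.02, br = 0.005)
  prof <- generate_thickness(truth, ci, ri, grid, effects = eff,
                             noise_sd = 0, seed = 1)
  expect_equal(prof$thickness,
               eval_shape_model(truth, ci(grid), ri(grid), eff),
               tolerance = 1e-15)
  # beta_c > 0 with ICD increasing in |ecc|: thickness increases off-center
  pos <- grid >= 0
  expect_true(all(diff(prof$thickness[pos]) > 0))
  # a fitted model predicts its own fitted values
  st <- simulate_shape_study(n_participants = 5, n_locations = 40, seed = 3)
  fit <- suppressMessages(fit_foveal_shape(st$observations))
  expect_equal(predict(fit, st$observations, level = 1),
               unname(fitted(fit)), tolerance = 1e-9)
  expect_error(predict(fit, data.frame(cone_icd_um = -1, rpe_icd_um = 2)),
               "> 0")
})

test_that("dropping the RPE term from RPE-dependent data is detected", {
  st <- simulate_shape_study(seed = 4)    # full 23 x 200 study conditions
  full <- suppressMessages(fit_foveal_shape(st$observations))
  nc <- suppressMessages(fit_foveal_shape(st$observations, include = "cone"))
  lrt <- lr_test(nc, full)
  expect_lt(lrt$p.value, 1e-6)
  expect_gt(lrt$statistic, 40)
})

test_that("LMM slope estimates are unbiased on generated data", {
  ests <- vapply(1:12, function(i) {
    st <- simulate_shape_study(n_participants = 10, n_locations = 60,
                               seed = 300 + i)
    coef(suppressMessages(fit_foveal_shape(st$observations)))[["x_c"]]
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.291), 3 * mc_se + 1e-3)
})
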