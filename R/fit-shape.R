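#' Foveal shape model parameters
#'
#' Parameters of the linear mixed-effects model of retinal thickness (mm,
#' ILM to RPE-BrM) on log10 cone and RPE inter-cell distances (um):
#' `t_i = (beta0 + b_s) + (beta_c + b_cs) log10 d_c + (beta_r + b_rs) log10 d_r + eps_i`,
#' with independent zero-mean Gaussian participant random effects `b_s`,
#' `b_cs`, `b_rs` and residual `eps_i`.  Defaults are the package's
#' synthetic-population truth: the cohort point estimates for the fixed
#' effects and random-effect SDs that realize the canonical
#' between-individual variance split (see [shape_variance_components()]).
#'
#' @param beta0 intercept, mm.
#' @param beta_c cone coefficient, mm per log10 um.
#' @param beta_r RPE coefficient, mm per log10 um.
#' @param sd_b0,sd_bc,sd_br random-effect SDs (>= 0).
#' @param sigma residual SD, mm (> 0).
#' @return List of class `shape_lmm_params`.
#' @export
shape_lmm_params <- function(beta0 = 0.006, beta_c = 0.291, beta_r = 0.064,
                             sd_b0 = 0.0278, sd_bc = 0.0385, sd_br = 0.0124,
                             sigma = 0.005) {
  if (any(c(sd_b0, sd_bc, sd_br) < 0)) stop("random-effect SDs must be >= 0")
  if (sigma <= 0) stop("`sigma` must be > 0")
  structure(list(beta0 = beta0, beta_c = beta_c, beta_r = beta_r,
                 sd_b0 = sd_b0, sd_bc = sd_bc, sd_br = sd_br, sigma = sigma),
            class = "shape_lmm_params")
}

#' Evaluate the foveal shape model
#'
#' Pointwise evaluation of the thickness model for given ICD profiles and
#' participant effects (no noise).
#'
#' @param params a [shape_lmm_params()].
#' @param cone_icd_um,rpe_icd_um positive ICDs in um.
#' @param effects list with `b0`, `bc`, `br` (defaults 0).
#' @return thickness in mm.
#' @export
eval_shape_model <- function(params, cone_icd_um, rpe_icd_um,
                             effects = list()) {
  stopifnot(inherits(params, "shape_lmm_params"))
  if (any(cone_icd_um <= 0) || any(rpe_icd_um <= 0)) {
    stop("ICDs must be > 0 (log10 undefined otherwise)")
  }
  e <- modifyList(list(b0 = 0, bc = 0, br = 0), effects)
  (params$beta0 + e$b0) +
    (params$beta_c + e$bc) * log10(cone_icd_um) +
    (params$beta_r + e$br) * log10(rpe_icd_um)
}

#' Cubic-spline interpolation of a thickness profile
#'
#' C2 cubic spline through all knots ([stats::splinefun()]); evaluating
#' outside the grid range is an error, not extrapolation.
#'
#' @param profile a [thickness_profile()] (>= 4 grid points).
#' @return A function of eccentricity (deg) returning thickness (mm).
#' @export
interp_thickness <- function(profile) {
  stopifnot(inherits(profile, "thickness_profile"))
  if (length(profile$grid) < 4L) stop("need at least 4 grid points")
  if (anyDuplicated(profile$grid)) stop("duplicate grid points")
  f <- splinefun(profile$grid, profile$thickness, method = "fmm")
  rng <- range(profile$grid)
  function(ecc_deg) {
    if (any(ecc_deg < rng[1] - 1e-12 | ecc_deg > rng[2] + 1e-12)) {
      stop("evaluation outside the thickness grid [", rng[1], ", ", rng[2],
           "] deg is not supported")
    }
    f(ecc_deg)
  }
}

#' Fit the foveal shape linear mixed-effects model
#'
#' Regresses retinal thickness on log10 cone and RPE ICDs with independent
#' participant random effects on the intercept and both slopes (no
#' covariances), using [lme4::lmer()].  ML is the default so that
#' likelihood-ratio tests on fixed effects ([lr_test()]) are valid; no
#' p-values are reported for the fixed effects, only t-values.
#'
#' @param data data frame with columns `participant_id`, `thickness_mm`,
#'   `cone_icd_um`, `rpe_icd_um` (matched at the same retinal locations), at
#'   least 2 participants.
#' @param REML use REML instead of ML (default FALSE).
#' @param include which predictors to include: `"both"` (default),
#'   `"cone"`, or `"rpe"` — the reduced variants are the nested models for
#'   term-dropping likelihood-ratio tests.
#' @return Object of class `shape_fit` with methods `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `fitted`, `residuals`, `plot`, plus
#'   [variance_decomposition()].
#' @examples
#' study <- simulate_shape_study(seed = 1, n_participants = 6,
#'                               n_locations = 40)
#' fit <- fit_foveal_shape(study$observations)
#' coef(fit)
#' @export
fit_foveal_shape <- function(data, REML = FALSE,
                             include = c("both", "cone", "rpe")) {
  include <- match.arg(include)
  need <- c("participant_id", "thickness_mm", "cone_icd_um", "rpe_icd_um")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns: ", paste(need, collapse = ", "))
  }
  if (any(data$cone_icd_um <= 0) || any(data$rpe_icd_um <= 0)) {
    stop("ICDs must be > 0")
  }
  if (length(unique(data$participant_id)) < 2L) {
    stop("need at least 2 participants")
  }
  d <- data.frame(id = factor(data$participant_id),
                  t = data$thickness_mm,
                  x_c = log10(data$cone_icd_um),
                  x_r = log10(data$rpe_icd_um))
  X <- switch(include,
              both = cbind(1, d$x_c, d$x_r),
              cone = cbind(1, d$x_c),
              rpe = cbind(1, d$x_r))
  kap <- kappa(X, exact = TRUE)
  if (kap > 1e8) {
    warning(sprintf("predictors nearly collinear (condition number %.3g)",
                    kap))
  }
  form <- switch(include,
                 both = t ~ x_c + x_r + (1 | id) + (0 + x_c | id) + (0 + x_r | id),
                 cone = t ~ x_c + (1 | id) + (0 + x_c | id),
                 rpe = t ~ x_r + (1 | id) + (0 + x_r | id))
  fit <- lme4::lmer(form, data = d, REML = REML,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  coefs <- data.frame(estimate = unname(cf), se = unname(se),
                      t_value = unname(cf / se),
                      row.names = names(cf))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(v) {
    i <- which(vc$grp != "Residual" & vc$var1 == v)
    if (length(i)) vc$vcov[i[1]] else 0
  }
  varcomp <- c(intercept = getvar("(Intercept)"),
               cone = getvar("x_c"), rpe = getvar("x_r"),
               residual = vc$vcov[vc$grp == "Residual"])
  ll <- logLik(fit)
  structure(list(fit = fit, include = include, REML = REML,
                 coefficients = coefs, varcomp = varcomp,
                 data = d, n_obs = nrow(d), n_participants = nlevels(d$id),
                 logLik = as.numeric(ll), df = attr(ll, "df"),
                 AIC = AIC(fit)),
            class = "shape_fit")
}

#' @export
coef.shape_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' @export
logLik.shape_fit <- function(object, ...) logLik(object$fit)

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf("<shape_fit> thickness ~ %s (%s)\n",
              switch(x$include, both = "log10 cone ICD + log10 RPE ICD",
                     cone = "log10 cone ICD", rpe = "log10 RPE ICD"),
              ifelse(x$REML, "REML", "ML")))
  cat(sprintf("  %d observations, %d participants; logLik %.2f, AIC %.2f\n",
              x$n_obs, x$n_participants, x$logLik, x$AIC))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.shape_fit <- function(object, ...) {
  out <- list(include = object$include, REML = object$REML,
              coefficients = object$coefficients,
              varcomp = object$varcomp,
              decomposition = try(variance_decomposition(object),
                                  silent = TRUE),
              logLik = object$logLik, AIC = object$AIC,
              n_obs = object$n_obs, n_participants = object$n_participants)
  class(out) <- "summary.shape_fit"
  out
}

#' @export
print.summary.shape_fit <- function(x, ...) {
  cat("Foveal shape LMM (", ifelse(x$REML, "REML", "ML"), ")\n", sep = "")
  cat(sprintf("  %d observations from %d participants\n",
              x$n_obs, x$n_participants))
  cat("Fixed effects (no p-values; see t):\n")
  print(round(x$coefficients, 4))
  cat("Variance components:\n")
  print(signif(x$varcomp, 4))
  if (!inherits(x$decomposition, "try-error")) {
    cat("Between-individual variance shares (%):\n")
    print(round(x$decomposition$shares, 1))
  }
  invisible(x)
}

#' @export
predict.shape_fit <- function(object, newdata = NULL, level = 1, ...) {
  if (is.null(newdata)) return(fitted(object$fit))
  if (any(newdata$cone_icd_um <= 0) ||
      (object$include != "cone" && any(newdata$rpe_icd_um <= 0))) {
    stop("ICDs must be > 0")
  }
  cf <- coef(object)
  pred <- rep(cf[["(Intercept)"]], nrow(newdata))
  if (object$include != "rpe") pred <- pred + cf[["x_c"]] * log10(newdata$cone_icd_um)
  if (object$include != "cone") pred <- pred + cf[["x_r"]] * log10(newdata$rpe_icd_um)
  if (level > 0 && !is.null(newdata$participant_id)) {
    re <- lme4::ranef(object$fit)$id
    ids <- as.character(newdata$participant_id)
    if (!all(ids %in% rownames(re))) stop("unknown participant_id in `newdata`")
    pred <- pred + re[ids, "(Intercept)"]
    if (object$include != "rpe") {
      pred <- pred + re[ids, "x_c"] * log10(newdata$cone_icd_um)
    }
    if (object$include != "cone") {
      pred <- pred + re[ids, "x_r"] * log10(newdata$rpe_icd_um)
    }
  }
  unname(pred)
}

#' @export
fitted.shape_fit <- function(object, ...) fitted(object$fit)

#' @export
residuals.shape_fit <- function(object, ...) residuals(object$fit)

#' @export
plot.shape_fit <- function(x, ...) {
  plot(fitted(x), resid(x), pch = 16, cex = 0.4,
       xlab = "fitted thickness (mm)", ylab = "residual (mm)", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}

#' Between-individual variance decomposition of a shape fit
#'
#' Decomposes the model's between-individual variance, evaluated at the
#' observed covariate values, into the contributions of the random
#' intercept, the cone-slope and RPE-slope random effects, plus the
#' residual.  The convention is: at observation i the between-individual
#' variance is `sd_b0^2 + sd_bc^2 x_c,i^2 + sd_br^2 x_r,i^2`; each term is
#' averaged over observations, the residual variance is added, and shares
#' are normalized to 100%.
#'
#' @param fit a `shape_fit`.
#' @param data optional data frame with `cone_icd_um`, `rpe_icd_um` at which
#'   to evaluate the covariates (defaults to the fitting data).
#' @return List with `shares` (named percentages: intercept, cone, rpe,
#'   cone_rpe, residual), `components` (absolute variances, mm^2) and
#'   `total`.
#' @export
variance_decomposition <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "shape_fit"))
  if (fit$include != "both") {
    stop("variance decomposition is defined for the full (both-term) model")
  }
  if (is.null(data)) {
    x_c <- fit$data$x_c
    x_r <- fit$data$x_r
  } else {
    x_c <- log10(data$cone_icd_um)
    x_r <- log10(data$rpe_icd_um)
  }
  comp <- c(intercept = unname(fit$varcomp["intercept"]),
            cone = unname(fit$varcomp["cone"]) * mean(x_c^2),
            rpe = unname(fit$varcomp["rpe"]) * mean(x_r^2),
            residual = unname(fit$varcomp["residual"]))
  total <- sum(comp)
  if (total <= 0) stop("total variance is zero; shares undefined")
  shares <- 100 * comp / total
  shares <- c(shares[c("intercept", "cone", "rpe")],
              cone_rpe = unname(shares["cone"] + shares["rpe"]),
              residual = unname(shares["residual"]))
  list(shares = shares, components = comp, total = total)
}

#' Per-participant regressions of cell metrics on retinal thickness
#'
#' For each participant, ordinary least squares of the log10 of a cell
#' metric (cone ICD, RPE ICD, or cones per RPE cell) on retinal thickness,
#' with nasal and temporal data folded together by the caller having matched
#' thickness at each cell's absolute eccentricity.  Returns per-participant
#' slopes and R^2 and the cohort median and IQR of R^2.
#'
#' @param data data frame with columns `participant_id`, `thickness_mm` and
#'   `value` (the metric, linear scale).
#' @param log10_value regress on log10 of the metric (default TRUE);
#'   non-positive values are dropped.
#' @return List with `per_participant` (id, n, slope, intercept, r_squared),
#'   `median_r2`, `iqr_r2`.
#' @export
per_participant_regressions <- function(data, log10_value = TRUE) {
  need <- c("participant_id", "thickness_mm", "value")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(split(data, data$participant_id), function(d) {
    if (log10_value) {
      keep <- d$value > 0
      if (!all(keep)) warning("dropping non-positive metric values")
      d <- d[keep, , drop = FALSE]
      d$value <- log10(d$value)
    }
    if (nrow(d) < 3L) {
      warning("participant ", d$participant_id[1], " has < 3 points; skipped")
      return(NULL)
    }
    if (sd(d$value) == 0 || sd(d$thickness_mm) == 0) {
      warning("constant metric or thickness for participant ",
              d$participant_id[1], "; skipped")
      return(NULL)
    }
    f <- lm(value ~ thickness_mm, data = d)
    data.frame(participant_id = d$participant_id[1], n = nrow(d),
               slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
               r_squared = summary(f)$r.squared)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no participant with a fittable regression")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  q <- quantile(per$r_squared, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_participant = per, median_r2 = q[2], iqr_r2 = c(q[1], q[3]))
}

#' Join tessellated mosaics and a thickness profile into shape observations
#'
#' Builds the observation table for [fit_foveal_shape()]: for every cone in
#' the meridian strip within `max_ecc_deg`, the thickness is the spline
#' interpolant of the participant's profile evaluated at the cone's
#' eccentricity, the cone ICD is the cell's own ICD, and the RPE ICD is that
#' of the nearest RPE cell.
#'
#' @param cone_stats,rpe_stats `voronoi_stats` for the two mosaics (same
#'   coordinate frame).
#' @param profile the participant's [thickness_profile()].
#' @param max_ecc_deg restrict to |ecc| <= this (default 5).
#' @param vertical_halfwidth_deg meridian strip half-height (default 0.5).
#' @return Data frame with `participant_id`, `ecc_deg`, `thickness_mm`,
#'   `cone_icd_um`, `rpe_icd_um`.
#' @export
build_shape_observations <- function(cone_stats, rpe_stats, profile,
                                     max_ecc_deg = 5,
                                     vertical_halfwidth_deg = 0.5) {
  stopifnot(inherits(cone_stats, "voronoi_stats"),
            inherits(rpe_stats, "voronoi_stats"))
  tfun <- interp_thickness(profile)
  half_um <- vertical_halfwidth_deg * attr(cone_stats, "um_per_deg")
  keep <- abs(cone_stats$y_um) <= half_um &
    abs(cone_stats$ecc_deg) <= max_ecc_deg
  cones <- cone_stats[keep, , drop = FALSE]
  if (nrow(cones) == 0L) stop("no cones in the requested strip")
  nn <- FNN::get.knnx(cbind(rpe_stats$x_um, rpe_stats$y_um),
                      cbind(cones$x_um, cones$y_um), k = 1)
  data.frame(participant_id = attr(cone_stats, "participant_id"),
             ecc_deg = cones$ecc_deg,
             thickness_mm = tfun(cones$ecc_deg),
             cone_icd_um = cones$icd_um,
             rpe_icd_um = rpe_stats$icd_um[nn$nn.index[, 1]])
}
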