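#' Fit a nonlinear mixed-effects density profile
#'
#' Fits the asymmetric power-law or generalized-exponential model of log10
#' cell density versus signed eccentricity with participant-nested Gaussian
#' random effects on every parameter (independent variances, no
#' covariances), maximizing the marginal likelihood with [nlme::nlme()].
#' Starting values come from a two-stage initializer: a profiled linear fit
#' (the power model is linear in its amplitude and exponents given the
#' offset `rho`; the genexp model is linearized per side given the peak)
#' followed by the mixed fit.  Positivity of `rho` and of the genexp
#' `lambda`/`pi` parameters is enforced by optimizing them on the log scale,
#' so their random effects act multiplicatively.
#'
#' Symmetric variants (`asymmetric = FALSE`) constrain the nasal and
#' temporal parameters to be equal, with correspondingly fewer random
#' effects, and are the nested models for the asymmetry likelihood-ratio
#' test ([lr_test()]).
#'
#' @param data data frame with columns `participant_id`, `ecc_deg` (signed,
#'   negative = nasal) and `log10_density`.
#' @param family `"power"` or `"genexp"`.
#' @param asymmetric allow separate nasal/temporal parameters (default TRUE).
#' @param method `"ML"` (default; valid for likelihood-ratio tests) or
#'   `"REML"`.
#' @param start optional named numeric vector of starting values on the
#'   internal scale (power: `K, pn, pt, lrho`; genexp: `K, lln, llt, lpn,
#'   lpt`; symmetric variants drop the temporal entries).
#' @param control a [nlme::nlmeControl()] list.
#' @return An object of class `density_fit` with methods `print`, `summary`,
#'   `coef` (natural-scale fixed effects), `logLik`, `AIC`, `predict`,
#'   `fitted`, `residuals`, `plot`, plus [peak_density()].
#' @examples
#' obs <- simulate_density_observations(power_law_params(), n_participants = 6,
#'                                      n_per_participant = 80, seed = 1)
#' fit <- fit_density_profile(obs, family = "power")
#' coef(fit)
#' @export
fit_density_profile <- function(data, family = c("power", "genexp"),
                                asymmetric = TRUE,
                                method = c("ML", "REML"),
                                start = NULL, control = NULL) {
  family <- match.arg(family)
  method <- match.arg(method)
  data <- check_density_obs(data, asymmetric)
  if (is.null(control)) {
    control <- nlme::nlmeControl(maxIter = 200, msMaxIter = 200,
                                 pnlsMaxIter = 15, tolerance = 1e-6,
                                 returnObject = FALSE)
  }
  if (is.null(start)) {
    start <- density_start_values(data, family, asymmetric)
  }
  dat <- data.frame(id = factor(data$participant_id),
                    ecc_deg = data$ecc_deg, y = data$log10_density)

  spec <- density_model_spec(family, asymmetric)
  # do.call inlines the evaluated formula into the stored call, which keeps
  # predict() working outside this function's evaluation frame
  fit <- try(do.call(nlme::nlme,
                     list(model = spec$model, fixed = spec$fixed,
                          random = spec$random, groups = ~id, data = dat,
                          start = start[spec$pars], method = method,
                          control = control)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # one retry from a perturbed start with a damped optimizer
    fit <- try(do.call(nlme::nlme,
                       list(model = spec$model, fixed = spec$fixed,
                            random = spec$random, groups = ~id, data = dat,
                            start = start[spec$pars] * 0.95 - 0.02,
                            method = method,
                            control = utils::modifyList(
                              control, list(pnlsMaxIter = 25,
                                            minScale = 1e-6)))),
               silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    stop("density profile fit did not converge (", family,
         ifelse(asymmetric, ", asymmetric", ", symmetric"), "): ",
         attr(fit, "condition")$message, call. = FALSE)
  }

  structure(list(
    fit = fit, family = family, asymmetric = asymmetric, method = method,
    pars = spec$pars,
    n_obs = nrow(dat), n_participants = nlevels(dat$id),
    fingerprint = data_fingerprint(dat),
    logLik = as.numeric(logLik(fit)),
    df = attr(logLik(fit), "df"),
    AIC = AIC(fit)
  ), class = "density_fit")
}

check_density_obs <- function(data, asymmetric) {
  need <- c("participant_id", "ecc_deg", "log10_density")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns: ", paste(need, collapse = ", "))
  }
  data <- data[complete.cases(data[need]), need]
  if (!all(is.finite(data$ecc_deg)) || !all(is.finite(data$log10_density))) {
    stop("non-finite observations")
  }
  tab <- table(data$participant_id)
  if (length(tab) < 2L) stop("need at least 2 participants")
  if (any(tab < 10L)) stop("need at least 10 observations per participant")
  if (length(unique(round(data$ecc_deg, 8))) < 4L) {
    stop("degenerate design: too few distinct eccentricities")
  }
  if (asymmetric && (!any(data$ecc_deg > 0) || !any(data$ecc_deg < 0))) {
    stop("asymmetric fits need eccentricities of both signs")
  }
  data
}

data_fingerprint <- function(dat) {
  round(c(n = nrow(dat), sy = sum(dat$y), se = sum(dat$ecc_deg),
          syy = sum(dat$y^2), g = nlevels(dat$id)), 8)
}

density_model_spec <- function(family, asymmetric) {
  if (family == "power") {
    if (asymmetric) {
      list(model = y ~ foveatopo::power_mu(ecc_deg, K, pn, pt, lrho),
           fixed = K + pn + pt + lrho ~ 1,
           random = nlme::pdDiag(K + pn + pt + lrho ~ 1),
           pars = c("K", "pn", "pt", "lrho"))
    } else {
      list(model = y ~ foveatopo::power_mu(ecc_deg, K, pn, pn, lrho),
           fixed = K + pn + lrho ~ 1,
           random = nlme::pdDiag(K + pn + lrho ~ 1),
           pars = c("K", "pn", "lrho"))
    }
  } else {
    if (asymmetric) {
      list(model = y ~ foveatopo::genexp_mu(ecc_deg, K, lln, llt, lpn, lpt),
           fixed = K + lln + llt + lpn + lpt ~ 1,
           random = nlme::pdDiag(K + lln + llt + lpn + lpt ~ 1),
           pars = c("K", "lln", "llt", "lpn", "lpt"))
    } else {
      list(model = y ~ foveatopo::genexp_mu(ecc_deg, K, lln, lln, lpn, lpn),
           fixed = K + lln + lpn ~ 1,
           random = nlme::pdDiag(K + lln + lpn ~ 1),
           pars = c("K", "lln", "lpn"))
    }
  }
}

# two-stage starting values from pooled linearized fits
density_start_values <- function(data, family, asymmetric) {
  y <- data$log10_density
  r <- data$ecc_deg
  pos <- r >= 0
  if (family == "power") {
    best <- NULL
    for (rho in c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8, 1.2, 2)) {
      b <- log10(abs(r) + rho)
      lr10 <- log10(rho)
      c1 <- ifelse(pos, b, lr10)
      c2 <- ifelse(pos, 0, b - lr10)
      f <- lm(y ~ c1 + c2)
      if (is.null(best) || deviance(f) < best$rss) {
        best <- list(rss = deviance(f), rho = rho, beta = coef(f))
      }
    }
    K <- unname(best$beta[1])
    pn <- unname(best$beta[2])
    # the c2 coefficient is pt directly; if all data fall on one side the
    # column is dropped and we reuse pn
    pt <- unname(if (is.na(best$beta[3])) pn else best$beta[3])
    if (!asymmetric) pn <- pt <- (pn + pt) / 2
    c(K = K, pn = pn, pt = pt, lrho = log(best$rho))
  } else {
    l10e <- log10(exp(1))
    K0 <- max(y) / l10e + 0.05
    side_start <- function(sel) {
      u <- K0 - y[sel] / l10e
      keep <- u > 0 & abs(r[sel]) > 0.15
      f <- lm(log(u[keep]) ~ log(abs(r[sel][keep])))
      c(ll = unname(coef(f)[1]), lp = log(max(unname(coef(f)[2]), 0.05)))
    }
    sn <- side_start(pos)
    st <- if (any(!pos)) side_start(!pos) else sn
    if (!asymmetric) {
      sn <- st <- (sn + st) / 2
    }
    c(K = K0, lln = sn[["ll"]], llt = st[["ll"]],
      lpn = sn[["lp"]], lpt = st[["lp"]])
  }
}

natural_scale_coefs <- function(object) {
  fe <- nlme::fixef(object$fit)
  se <- sqrt(diag(object$fit$varFix))
  if (object$family == "power") {
    if (object$asymmetric) {
      est <- c(kappa = unname(fe["K"]), pi_n = unname(fe["pn"]),
               pi_t = unname(fe["pt"]), rho = unname(exp(fe["lrho"])))
      ses <- c(se[c("K", "pn", "pt")], exp(fe["lrho"]) * se["lrho"])
    } else {
      est <- c(kappa = unname(fe["K"]), pi = unname(fe["pn"]),
               rho = unname(exp(fe["lrho"])))
      ses <- c(se[c("K", "pn")], exp(fe["lrho"]) * se["lrho"])
    }
  } else {
    if (object$asymmetric) {
      est <- c(kappa = unname(fe["K"]),
               lambda_n = unname(exp(fe["lln"])),
               lambda_t = unname(exp(fe["llt"])),
               pi_n = unname(exp(fe["lpn"])),
               pi_t = unname(exp(fe["lpt"])))
      ses <- c(se["K"], exp(fe["lln"]) * se["lln"], exp(fe["llt"]) * se["llt"],
               exp(fe["lpn"]) * se["lpn"], exp(fe["lpt"]) * se["lpt"])
    } else {
      est <- c(kappa = unname(fe["K"]),
               lambda = unname(exp(fe["lln"])),
               pi = unname(exp(fe["lpn"])))
      ses <- c(se["K"], exp(fe["lln"]) * se["lln"], exp(fe["lpn"]) * se["lpn"])
    }
  }
  data.frame(estimate = unname(est), se = unname(ses),
             t_value = unname(est / ses), row.names = names(est))
}

#' @export
coef.density_fit <- function(object, scale = c("natural", "internal"), ...) {
  scale <- match.arg(scale)
  if (scale == "internal") return(nlme::fixef(object$fit))
  tab <- natural_scale_coefs(object)
  setNames(tab$estimate, rownames(tab))
}

#' @export
logLik.density_fit <- function(object, ...) logLik(object$fit)

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf("<density_fit> %s (%s), %s\n", x$family,
              ifelse(x$asymmetric, "asymmetric", "symmetric"), x$method))
  cat(sprintf("  %d observations, %d participants; logLik %.2f, AIC %.2f (df %d)\n",
              x$n_obs, x$n_participants, x$logLik, x$AIC, x$df))
  print(round(natural_scale_coefs(x), 4))
  invisible(x)
}

#' @export
summary.density_fit <- function(object, ...) {
  vc <- nlme::VarCorr(object$fit)
  out <- list(family = object$family, asymmetric = object$asymmetric,
              method = object$method,
              coefficients = natural_scale_coefs(object),
              random_sd = setNames(as.numeric(vc[, "StdDev"]),
                                   rownames(vc)),
              logLik = object$logLik, AIC = object$AIC, df = object$df,
              n_obs = object$n_obs, n_participants = object$n_participants)
  class(out) <- "summary.density_fit"
  out
}

#' @export
print.summary.density_fit <- function(x, ...) {
  cat(sprintf("Density profile fit: %s (%s), %s\n", x$family,
              ifelse(x$asymmetric, "asymmetric", "symmetric"), x$method))
  cat(sprintf("  %d observations from %d participants\n", x$n_obs,
              x$n_participants))
  cat("Fixed effects (natural scale):\n")
  print(round(x$coefficients, 4))
  cat("Random-effect SDs (internal scale) and residual:\n")
  print(round(x$random_sd, 4))
  cat(sprintf("logLik %.2f  AIC %.2f  (df %d)\n", x$logLik, x$AIC, x$df))
  invisible(x)
}

#' @export
predict.density_fit <- function(object, newdata = NULL, level = 1,
                                ...) {
  if (is.null(newdata)) return(fitted(object$fit, level = level))
  nd <- data.frame(ecc_deg = newdata$ecc_deg)
  if (!is.null(newdata$participant_id) && level > 0) {
    nd$id <- factor(newdata$participant_id,
                    levels = levels(object$fit$groups$id))
    if (anyNA(nd$id)) stop("unknown participant_id in `newdata`")
    as.numeric(predict(object$fit, newdata = nd, level = 1))
  } else {
    as.numeric(predict(object$fit, newdata = nd, level = 0))
  }
}

#' @export
fitted.density_fit <- function(object, ...) fitted(object$fit, ...)

#' @export
residuals.density_fit <- function(object, ...) residuals(object$fit, ...)

#' @export
plot.density_fit <- function(x, n_grid = 201, ...) {
  dat <- nlme::getData(x$fit)
  plot(dat$ecc_deg, dat$y, pch = 16, cex = 0.3, col = "grey60",
       xlab = "eccentricity (deg, negative = nasal)",
       ylab = "log10 density (cells/mm2)", ...)
  grid_ecc <- seq(min(dat$ecc_deg), max(dat$ecc_deg), length.out = n_grid)
  lines(grid_ecc,
        predict(x, data.frame(ecc_deg = grid_ecc), level = 0),
        col = "firebrick", lwd = 2)
  invisible(x)
}

#' Peak density from a fitted profile
#'
#' Evaluates the fitted profile at 0 degrees eccentricity (fixed effects
#' plus the participant's empirical-Bayes random effects) and returns the
#' linear-scale density.  The power-law offset `rho` keeps this finite; for
#' the genexp family the value is `exp(kappa + k_s)`.
#'
#' @param fit a `density_fit`.
#' @param participant participant id(s); `NULL` (default) returns all, and
#'   `"population"` the fixed-effects-only peak.
#' @return Named numeric vector of peak densities (cells/mm^2).  If a
#'   requested participant was not in the fit, the population value is
#'   returned for it with attribute `population_fallback`.
#' @export
peak_density <- function(fit, participant = NULL) {
  stopifnot(inherits(fit, "density_fit"))
  ids <- levels(fit$fit$groups$id)
  pop <- 10^predict(fit, data.frame(ecc_deg = 0), level = 0)
  if (identical(participant, "population")) {
    return(c(population = unname(pop)))
  }
  if (is.null(participant)) participant <- ids
  known <- participant %in% ids
  out <- setNames(rep(unname(pop), length(participant)), participant)
  if (any(known)) {
    nd <- data.frame(ecc_deg = rep(0, sum(known)),
                     participant_id = participant[known])
    out[known] <- 10^predict(fit, nd, level = 1)
  }
  if (any(!known)) attr(out, "population_fallback") <- participant[!known]
  out
}

#' Compare fitted profile models by AIC
#'
#' @param ... two or more `density_fit` objects fitted to the *same*
#'   observations.
#' @param aicc use the small-sample corrected AICc instead of AIC.
#' @return Data frame (class `profile_comparison`) with one row per fit:
#'   family, asymmetry, df, logLik, AIC (or AICc), delta to the best model
#'   and a `selected` flag.  Ties in the minimum are all flagged and noted
#'   in attribute `tie`.
#' @export
compare_profile_models <- function(..., aicc = FALSE) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "density_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "density_fit")))
  fps <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fps, function(f) isTRUE(all.equal(f, fps[[1]])),
                  logical(1)))) {
    stop("fits were not made on identical observations")
  }
  ic <- vapply(fits, function(f) {
    if (aicc) f$AIC + 2 * f$df * (f$df + 1) / (f$n_obs - f$df - 1) else f$AIC
  }, numeric(1))
  out <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    asymmetric = vapply(fits, `[[`, logical(1), "asymmetric"),
    df = vapply(fits, `[[`, numeric(1), "df"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    IC = ic, dIC = ic - min(ic), selected = ic == min(ic)
  )
  names(out)[names(out) == "IC"] <- if (aicc) "AICc" else "AIC"
  names(out)[names(out) == "dIC"] <- if (aicc) "dAICc" else "dAIC"
  if (sum(out$selected) > 1L) attr(out, "tie") <- TRUE
  class(out) <- c("profile_comparison", "data.frame")
  out
}

#' Likelihood-ratio test for nested fits
#'
#' `chi^2 = 2 (logLik_full - logLik_nested)` on `df = df_full - df_nested`
#' degrees of freedom.  Used for the symmetric-versus-asymmetric profile
#' comparison and for dropping terms from the foveal-shape model; both fits
#' must be maximum-likelihood fits on the same data.
#'
#' @param nested,full fitted models with `logLik` methods (e.g.
#'   `density_fit` or `shape_fit` objects); the nested model's parameters
#'   must be a subset of the full model's.
#' @return List (class `lr_test`) with `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(nested, full) {
  ll0 <- logLik_of(nested)
  ll1 <- logLik_of(full)
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 0) stop("`full` must have more parameters than `nested`")
  stat <- 2 * (as.numeric(ll1) - as.numeric(ll0))
  if (stat < -1e-6) {
    warning("full model has lower likelihood than nested model; refit advised")
  }
  stat <- max(stat, 0)
  out <- list(statistic = stat, df = df,
              p.value = if (df == 0) as.numeric(stat <= 0) else
                pchisq(stat, df, lower.tail = FALSE))
  class(out) <- "lr_test"
  out
}

logLik_of <- function(x) {
  if (inherits(x, "density_fit") || inherits(x, "shape_fit")) {
    structure(x$logLik, df = x$df, class = "logLik")
  } else {
    logLik(x)
  }
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi^2(%d) = %.4g, p = %.4g\n",
              x$df, x$statistic, x$p.value))
  invisible(x)
}
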