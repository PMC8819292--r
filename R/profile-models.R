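#' Density-profile parameter sets
#'
#' Population parameters for the two model families of log10 cell density
#' versus signed eccentricity r (degrees, negative = nasal).
#'
#' **Power law** (`power_law_params`): for r >= 0,
#' `log10 d = kappa + pi_n * log10(r + rho)`; for r < 0,
#' `log10 d = kappa + (pi_n - pi_t) * log10(rho) + pi_t * log10(|r| + rho)`.
#' The offset `rho` (> 0, degrees) keeps the density finite at the origin,
#' and the branch construction makes the profile continuous at r = 0 for
#' every parameter draw.  `kappa` is in log10 cells/mm^2 units.
#'
#' **Generalized exponential** (`genexp_params`): for r >= 0,
#' `log10 d = log10(e) * (kappa - lambda_n * r^pi_n)`, and analogously with
#' `lambda_t`, `pi_t` for r < 0 (using |r|).  At r = 0 both branches equal
#' `log10(e) * kappa`, so the peak log10 density is `log10(e) * kappa` and
#' the peak density `exp(kappa)`.
#'
#' `sd_*` entries are the standard deviations of the corresponding
#' zero-mean Gaussian participant random effects; `sigma` is the residual
#' SD of log10 density.  Random effects on `rho` (power) and on the
#' `lambda`/`pi` parameters (genexp) act on the log scale (multiplicatively),
#' which keeps every draw admissible.
#'
#' @param kappa amplitude (power: log10 units; genexp: natural-log units).
#' @param pi_n,pi_t nasal/temporal exponents (power: < 0; genexp: > 0).
#' @param rho power-law eccentricity offset, degrees, > 0.
#' @param lambda_n,lambda_t genexp spatial-scale rates, > 0.
#' @param sd_kappa,sd_pi_n,sd_pi_t,sd_log_rho,sd_log_lambda_n,sd_log_lambda_t,sd_log_pi_n,sd_log_pi_t
#'   random-effect SDs (>= 0).
#' @param sigma residual SD of log10 density (> 0).
#' @return A list of class `power_law_params` or `genexp_params`.
#' @export
power_law_params <- function(kappa = 4.813, pi_n = -1.0, pi_t = -0.9,
                             rho = 0.5,
                             sd_kappa = 0.07, sd_pi_n = 0.08, sd_pi_t = 0.08,
                             sd_log_rho = 0.15, sigma = 0.05) {
  if (rho <= 0) stop("`rho` must be > 0")
  sds <- c(sd_kappa, sd_pi_n, sd_pi_t, sd_log_rho)
  if (any(sds < 0)) stop("random-effect SDs must be >= 0")
  if (sigma <= 0) stop("`sigma` must be > 0")
  structure(list(kappa = kappa, pi_n = pi_n, pi_t = pi_t, rho = rho,
                 sd_kappa = sd_kappa, sd_pi_n = sd_pi_n, sd_pi_t = sd_pi_t,
                 sd_log_rho = sd_log_rho, sigma = sigma),
            class = "power_law_params")
}

#' @rdname power_law_params
#' @export
genexp_params <- function(kappa = 8.92, lambda_n = 0.15, lambda_t = 0.13,
                          pi_n = 0.70, pi_t = 0.75,
                          sd_kappa = 0.15, sd_log_lambda_n = 0.10,
                          sd_log_lambda_t = 0.10, sd_log_pi_n = 0.05,
                          sd_log_pi_t = 0.05, sigma = 0.05) {
  if (lambda_n <= 0 || lambda_t <= 0) stop("`lambda` rates must be > 0")
  if (pi_n <= 0 || pi_t <= 0) stop("genexp exponents must be > 0")
  sds <- c(sd_kappa, sd_log_lambda_n, sd_log_lambda_t, sd_log_pi_n, sd_log_pi_t)
  if (any(sds < 0)) stop("random-effect SDs must be >= 0")
  if (sigma <= 0) stop("`sigma` must be > 0")
  structure(list(kappa = kappa, lambda_n = lambda_n, lambda_t = lambda_t,
                 pi_n = pi_n, pi_t = pi_t,
                 sd_kappa = sd_kappa, sd_log_lambda_n = sd_log_lambda_n,
                 sd_log_lambda_t = sd_log_lambda_t, sd_log_pi_n = sd_log_pi_n,
                 sd_log_pi_t = sd_log_pi_t, sigma = sigma),
            class = "genexp_params")
}

#' Evaluate the asymmetric power-law density profile
#'
#' @param params a [power_law_params()] object.
#' @param ecc_deg signed eccentricities in degrees (negative = nasal).
#' @param effects participant random effects: a list with elements `kappa`,
#'   `pi_n`, `pi_t` (additive) and either `log_rho` (multiplicative offset
#'   effect, default parameterization) or `rho` (the additive form; a draw
#'   with `rho + effects$rho <= 0` is a domain error).  Missing elements are
#'   treated as 0.
#' @return log10 density (cells/mm^2) at each eccentricity.
#' @examples
#' p <- power_law_params()
#' eval_power_profile(p, c(-2, 0, 2))
#' @export
eval_power_profile <- function(params, ecc_deg, effects = list()) {
  stopifnot(inherits(params, "power_law_params"))
  e <- modifyList(list(kappa = 0, pi_n = 0, pi_t = 0, log_rho = 0, rho = 0),
                  effects)
  rho <- params$rho * exp(e$log_rho) + e$rho
  if (rho <= 0) stop("effective rho (rho + effect) must be > 0")
  power_mu(ecc_deg,
           K = params$kappa + e$kappa,
           pn = params$pi_n + e$pi_n,
           pt = params$pi_t + e$pi_t,
           lrho = log(rho))
}

#' Low-level profile mean functions
#'
#' Branch-safe mean functions used inside the nonlinear mixed-effects model
#' formulas (they must be visible where [nlme::nlme()] evaluates its model).
#' `power_mu()` takes the power-law parameters on the internal scale
#' (`lrho` is the natural log of the offset `rho`; all other logs are base
#' 10); `genexp_mu()` takes the generalized-exponential rates and exponents
#' as natural logs (`lln`, `llt`, `lpn`, `lpt`).  Most users want
#' [eval_power_profile()] / [eval_genexp_profile()] instead.
#'
#' @param ecc signed eccentricity, degrees.
#' @param K amplitude.
#' @param pn,pt nasal/temporal exponents (power law).
#' @param lrho log offset (power law).
#' @param lln,llt,lpn,lpt log rates and log exponents (genexp).
#' @return log10 density at each eccentricity.
#' @keywords internal
#' @export
power_mu <- function(ecc, K, pn, pt, lrho) {
  rho <- exp(lrho)
  b <- log10(abs(ecc) + rho)
  pos <- ecc >= 0
  val <- K + (pn - pt) * (lrho / log(10)) + pt * b   # nasal-side branch
  val[pos] <- (K + pn * b)[pos]
  val
}

#' Evaluate the asymmetric generalized-exponential density profile
#'
#' @param params a [genexp_params()] object.
#' @param ecc_deg signed eccentricities in degrees (negative = nasal).
#' @param effects participant random effects: `kappa` (additive),
#'   `log_lambda_n`, `log_lambda_t`, `log_pi_n`, `log_pi_t` (multiplicative,
#'   default) or `lambda_n`, `lambda_t`, `pi_n`, `pi_t` (additive; the
#'   effective values must stay positive).  Missing elements are 0.
#' @return log10 density (cells/mm^2) at each eccentricity; at r = 0 the
#'   value is exactly `log10(e) * (kappa + k_s)` from both sides.
#' @examples
#' g <- genexp_params()
#' eval_genexp_profile(g, 0) / log10(exp(1))  # recovers kappa
#' @export
eval_genexp_profile <- function(params, ecc_deg, effects = list()) {
  stopifnot(inherits(params, "genexp_params"))
  e <- modifyList(list(kappa = 0, log_lambda_n = 0, log_lambda_t = 0,
                       log_pi_n = 0, log_pi_t = 0,
                       lambda_n = 0, lambda_t = 0, pi_n = 0, pi_t = 0),
                  effects)
  ln <- params$lambda_n * exp(e$log_lambda_n) + e$lambda_n
  lt <- params$lambda_t * exp(e$log_lambda_t) + e$lambda_t
  pn <- params$pi_n * exp(e$log_pi_n) + e$pi_n
  pt <- params$pi_t * exp(e$log_pi_t) + e$pi_t
  if (ln <= 0 || lt <= 0) stop("effective lambda must be > 0")
  if (pn <= 0 || pt <= 0) stop("effective genexp exponent must be > 0")
  genexp_mu(ecc_deg, K = params$kappa + e$kappa,
            lln = log(ln), llt = log(lt), lpn = log(pn), lpt = log(pt))
}

#' @rdname power_mu
#' @export
genexp_mu <- function(ecc, K, lln, llt, lpn, lpt) {
  pos <- ecc >= 0
  lam <- ifelse(pos, exp(lln), exp(llt))
  p <- ifelse(pos, exp(lpn), exp(lpt))
  log10(exp(1)) * (K - lam * abs(ecc)^p)
}
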