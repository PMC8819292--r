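#' Deming regression via the first principal component
#'
#' Errors-in-both-variables line fit: the line runs along the first
#' principal component of the centered (x, y) cloud, and R^2 is the fraction
#' of total variance captured by that component.  Confidence intervals for
#' the slope, intercept and R^2 come from a seeded nonparametric bootstrap.
#'
#' @param x,y paired measurements (length >= 3, finite).
#' @param nboot bootstrap resamples (default 2000); 0 disables CIs.
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return List of class `deming_fit`: `slope`, `intercept`, `r_squared`,
#'   and `ci` (matrix of percentile intervals) when `nboot > 0`.
#' @examples
#' d <- deming_fit(1:6, 2 * (1:6))
#' d$slope       # 2
#' d$r_squared   # 1
#' @export
deming_fit <- function(x, y, nboot = 2000, conf = 0.95, seed = 1) {
  p <- check_pairs(x, y, min_n = 3)
  est <- deming_est(p$x, p$y)
  out <- c(est, list(n = length(p$x)))
  if (nboot > 0) {
    set.seed(seed)
    bs <- replicate(nboot, {
      i <- sample.int(length(p$x), replace = TRUE)
      # degenerate resamples (all points identical) carry no information
      tryCatch(unlist(deming_est(p$x[i], p$y[i])),
               error = function(e) c(slope = NA_real_, intercept = NA_real_,
                                     r_squared = NA_real_))
    })
    a <- (1 - conf) / 2
    out$ci <- t(apply(bs, 1, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  }
  structure(out, class = "deming_fit")
}

deming_est <- function(x, y) {
  S <- cov(cbind(x, y))
  if (sum(diag(S)) <= 0) stop("zero total variance")
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (abs(v[1]) < 1e-15) {
    slope <- Inf
  } else {
    slope <- v[2] / v[1]
  }
  list(slope = slope,
       intercept = mean(y) - slope * mean(x),
       r_squared = e$values[1] / sum(e$values))
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (first PC): slope %.4g, intercept %.4g, R^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  if (!is.null(x$ci)) {
    cat("Bootstrap CIs:\n")
    print(signif(x$ci, 4))
  }
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the differences `x - y`; the 95% limits of agreement
#' are bias +/- 1.96 SD of the differences.
#'
#' @param x,y paired measurements from the two methods (length >= 2).
#' @return List of class `bland_altman`: `bias`, `sd_diff`, `loa`
#'   (lower, upper), `n`.
#' @export
bland_altman <- function(x, y) {
  p <- check_pairs(x, y, min_n = 2)
  d <- p$x - p$y
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, 95%% LoA [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' One-way intraclass correlation coefficient
#'
#' ICC(1): the one-way random-effects model in which only the rated targets
#' (participants/locations) are random.  Computed from the one-way ANOVA
#' mean squares, `(MSB - MSW) / (MSB + (k - 1) MSW)` for k raters, with the
#' standard F-based confidence interval.
#'
#' @param ratings numeric matrix, locations x raters (>= 5 locations, >= 2
#'   raters).
#' @param conf confidence level (default 0.95).
#' @return List of class `icc_oneway`: `icc`, `ci`, `F`, `df1`, `df2`,
#'   `ms_between`, `ms_within`.  If the between-location variance is zero
#'   the ICC is reported as `NA` (undefined).
#' @export
icc_oneway <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must be complete")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 5L) stop("need at least 5 locations")
  row_means <- rowMeans(ratings)
  grand <- mean(ratings)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((ratings - row_means)^2) / (n * (k - 1))
  if (msb <= 0) {
    warning("zero between-location variance; ICC undefined")
    return(structure(list(icc = NA_real_, ci = c(NA, NA), F = NA,
                          df1 = n - 1, df2 = n * (k - 1),
                          ms_between = msb, ms_within = msw),
                     class = "icc_oneway"))
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  Fobs <- msb / msw
  a <- 1 - conf
  fl <- Fobs / qf(1 - a / 2, n - 1, n * (k - 1))
  fu <- Fobs * qf(1 - a / 2, n * (k - 1), n - 1)
  ci <- c(lower = (fl - 1) / (fl + k - 1), upper = (fu - 1) / (fu + k - 1))
  structure(list(icc = icc, ci = ci, F = Fobs, df1 = n - 1,
                 df2 = n * (k - 1), ms_between = msb, ms_within = msw),
            class = "icc_oneway")
}

#' @export
print.icc_oneway <- function(x, ...) {
  cat(sprintf("One-way ICC(1): %.4f (95%% CI %.4f-%.4f)\n",
              x$icc, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Pearson and partial correlations
#'
#' Standard Pearson correlation with a two-sided t-test p-value; when a
#' control variable is supplied, the partial correlation is computed by
#' residualizing both variables on it (p-value on n - 3 df).
#'
#' @param x,y paired measurements (length >= 4; >= 5 with a control).
#' @param control optional control variable for a partial correlation.
#' @return List of class `pair_correlation`: `r`, `p.value`, `df`,
#'   `partial` flag.
#' @export
pair_correlation <- function(x, y, control = NULL) {
  p <- check_pairs(x, y, min_n = if (is.null(control)) 4 else 5)
  if (sd(p$x) == 0 || sd(p$y) == 0) stop("constant input")
  if (is.null(control)) {
    r <- cor(p$x, p$y)
    df <- length(p$x) - 2L
  } else {
    if (length(control) != length(p$x)) stop("`control` length mismatch")
    rx <- resid(lm(p$x ~ control))
    ry <- resid(lm(p$y ~ control))
    # perfect confounding: nothing left to correlate once z is removed
    if (sd(rx) < 1e-10 * sd(p$x) || sd(ry) < 1e-10 * sd(p$y)) {
      r <- 0
    } else {
      r <- cor(rx, ry)
    }
    df <- length(p$x) - 3L
  }
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, p.value = 2 * pt(-abs(tstat), df), df = df,
                 partial = !is.null(control)),
            class = "pair_correlation")
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat(sprintf("%s r = %.4f (df %d, p = %.4g)\n",
              if (x$partial) "Partial Pearson" else "Pearson",
              x$r, x$df, x$p.value))
  invisible(x)
}

check_pairs <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < min_n) stop("need at least ", min_n, " pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  list(x = as.numeric(x), y = as.numeric(y))
}
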