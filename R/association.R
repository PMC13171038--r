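#' Spearman rank correlation
#'
#' Pairs with a missing value in either vector are dropped; ties receive
#' midranks. At least 3 complete pairs are required.
#'
#' @param x,y numeric vectors of equal length.
#' @return the Spearman correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("correlation undefined: zero variance in ranks", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Fisher z confidence interval for a correlation
#'
#' Transforms the correlation with `atanh`, builds a normal interval with
#' standard error `1/sqrt(n - 3)`, and back-transforms with `tanh`. This is
#' the construction under which every printed interval of the study is
#' internally consistent with a single sample size per analysis.
#'
#' @param rho correlation in (-1, 1) (|rho| = 1 yields a degenerate interval
#'   with a warning).
#' @param n number of paired observations, > 3.
#' @param level confidence level, default 0.95.
#' @return numeric vector `c(lo, hi)`.
#' @examples
#' fisher_ci(0.507, 35)  # c(0.209, 0.719) to 3 decimals
#' @export
fisher_ci <- function(rho, n, level = 0.95) {
  stopifnot(length(rho) == 1, length(n) == 1)
  if (abs(rho) > 1) stop("`rho` must be in [-1, 1]", call. = FALSE)
  if (abs(rho) == 1) {
    warning("|rho| = 1: degenerate confidence interval", call. = FALSE)
    return(c(rho, rho))
  }
  if (n <= 3) stop("`n` must exceed 3 for a Fisher z interval", call. = FALSE)
  z <- atanh(rho)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Recover the sample size implied by a printed confidence bound
#'
#' Exhaustively searches integers n in [5, 500] for the one whose Fisher z
#' interval endpoint lies closest to `bound`; ties break toward smaller n.
#' Used to reconstruct unreported sample sizes from published correlation
#' intervals.
#'
#' @param rho the reported correlation, |rho| < 1.
#' @param bound one reported interval endpoint (above `rho` for the upper
#'   endpoint, below for the lower).
#' @param level confidence level of the reported interval.
#' @return the implied integer sample size.
#' @export
implied_n <- function(rho, bound, level = 0.95) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (bound == rho) stop("`bound` must differ from `rho`", call. = FALSE)
  side <- if (bound > rho) 2L else 1L
  ns <- 5:500
  diffs <- vapply(ns, function(n) abs(fisher_ci(rho, n, level)[side] - bound),
                  numeric(1))
  best <- which.min(diffs)  # ties resolve to the smaller n
  if (diffs[best] > 0.05) {
    stop("no sample size in [5, 500] brings the interval endpoint within ",
         "0.05 of `bound`", call. = FALSE)
  }
  ns[best]
}

#' Two-sided p-value for a Spearman correlation (t approximation)
#'
#' Uses `t = rho * sqrt((n - 2) / (1 - rho^2))` referred to a Student-t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param rho correlation, |rho| < 1.
#' @param n number of paired observations, > 2.
#' @return two-sided p-value.
#' @export
spearman_p <- function(rho, n) {
  if (n <= 2) stop("`n` must exceed 2", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t_stat), df = n - 2)
}

#' Ordinary least-squares fit with classical standard errors
#'
#' A thin wrapper around [stats::lm()] returning a compact `evt_fit` record:
#' coefficient names (intercept first), estimates, classical standard
#' errors, R-squared relative to the intercept-only model, and two-sided
#' t p-values.
#'
#' @param y numeric response.
#' @param X data frame (or named matrix) of predictors.
#' @param add_intercept include an intercept term (default `TRUE`).
#' @return an `evt_fit` object.
#' @export
ols_fit <- function(y, X, add_intercept = TRUE) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(names(X) == "")) {
    stop("all predictor columns must be named", call. = FALSE)
  }
  n <- length(y)
  k <- ncol(X) + as.integer(add_intercept)
  if (n <= k) stop("too few observations (n = ", n, ") for ", k,
                   " coefficients", call. = FALSE)
  dat <- cbind(data.frame(.y = y), X)
  fml <- if (add_intercept) .y ~ . else .y ~ . - 1
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  # a perfect fit (noiseless oracle data) is legitimate here; silence
  # summary.lm's "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))
  est <- coef(sm)
  nm <- rownames(est)
  nm[nm == "(Intercept)"] <- "intercept"
  # R^2 always relative to the intercept-only model
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  new_evt_fit(
    names = nm, coef = unname(est[, 1]), se = unname(est[, 2]),
    r2 = r2, n = n, df_resid = fit$df.residual,
    p_values = unname(est[, 4]), lm = fit
  )
}

new_evt_fit <- function(names, coef, se, r2, n, df_resid, p_values,
                        lm = NULL, se_type = "classical") {
  structure(list(names = names, coef = setNames(coef, names),
                 se = setNames(se, names), r2 = r2, n = n,
                 df_resid = df_resid, p_values = setNames(p_values, names),
                 se_type = se_type, lm = lm),
            class = "evt_fit")
}

#' @export
print.evt_fit <- function(x, ...) {
  cat(sprintf("<evt_fit> n = %d, R^2 = %.4f, %s SEs\n", x$n, x$r2, x$se_type))
  print(data.frame(coef = x$coef, se = x$se, p = x$p_values,
                   row.names = x$names))
  invisible(x)
}

#' Rank correlation between two panel variables
#'
#' Builds complete-case pairs over all country-years of the panel (the
#' derived `"density"` is computed on the fly) and returns the Spearman
#' correlation with its Fisher z interval and t-approximation p-value.
#'
#' @param panel an `evt_panel`.
#' @param x_var,y_var panel variable names (any schema column or
#'   `"density"`).
#' @param level confidence level for the interval.
#' @return an `association_result`: list with `x_var`, `y_var`, `rho`, `n`,
#'   `ci_lo`, `ci_hi`, `p_value`, `level`.
#' @export
associate_panel <- function(panel, x_var, y_var, level = 0.95) {
  stopifnot(inherits(panel, "evt_panel"))
  x <- panel_var(panel, x_var)
  y <- panel_var(panel, y_var)
  ok <- complete.cases(x, y)
  rho <- spearman_rho(x, y)
  n <- sum(ok)
  ci <- if (abs(rho) == 1) c(rho, rho) else fisher_ci(rho, n, level)
  p <- if (abs(rho) == 1) 0 else spearman_p(rho, n)
  structure(list(x_var = x_var, y_var = y_var, rho = rho, n = n,
                 ci_lo = ci[1], ci_hi = ci[2], p_value = p, level = level),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association> %s ~ %s: rho = %.3f (%.0f%% CI %.3f to %.3f), n = %d, p = %.4g\n",
    x$y_var, x$x_var, x$rho, 100 * x$level, x$ci_lo, x$ci_hi, x$n, x$p_value))
  invisible(x)
}
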