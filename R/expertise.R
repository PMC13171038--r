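#' Parameters of the cumulative expertise index
#'
#' The index is a [floor, ceiling]-bounded proxy for accumulated procedural
#' experience. It starts in the first panel year at the country's density
#' relative to the maximum first-year density, then grows each year by a
#' base learning rate `beta0` plus `beta1` per additional
#' neurointerventionalist recruited that year.
#'
#' @param beta0 base learning rate per year (default 0.005).
#' @param beta1 increment per unit annual change in the absolute
#'   neurointerventionalist head count (default 0.001).
#' @param ceiling maximum index value (default 1).
#' @param floor minimum index value (default 0); workforce attrition can
#'   erode the index but never below the floor.
#' @return an `expertise_params` list.
#' @export
expertise_params <- function(beta0 = 0.005, beta1 = 0.001,
                             ceiling = 1, floor = 0) {
  if (beta0 < 0) stop("`beta0` must be >= 0", call. = FALSE)
  if (floor < 0 || ceiling <= floor) {
    stop("need ceiling > floor >= 0", call. = FALSE)
  }
  structure(list(beta0 = beta0, beta1 = beta1,
                 ceiling = ceiling, floor = floor),
            class = "expertise_params")
}

#' Cumulative expertise index and effective supply per country-year
#'
#' For each country present in the first panel year, the index is
#' initialised as that country's density divided by the maximum first-year
#' density across countries, then updated along consecutive years as
#' `clamp(E[t-1] + beta0 + beta1 * (N[t] - N[t-1]), floor, ceiling)` where N
#' is the absolute neurointerventionalist count. Countries absent from the
#' first year (or after a gap in their series) are excluded with a warning;
#' the initialisation is defined only at the first year.
#'
#' @param panel an `evt_panel`.
#' @param params an [expertise_params()].
#' @return a tibble (`expertise_series`) with columns `country`, `year`,
#'   `index`, `effective_supply` (density times index).
#' @export
expertise_index <- function(panel, params = expertise_params()) {
  stopifnot(inherits(panel, "evt_panel"), inherits(params, "expertise_params"))
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  t0 <- min(panel$year)
  first <- panel[panel$year == t0, , drop = FALSE]
  dens0 <- workforce_density(first$n_nir, first$population)
  if (max(dens0) <= 0) {
    stop("all first-year densities are zero; index initialisation undefined",
         call. = FALSE)
  }
  absent <- setdiff(unique(panel$country), first$country)
  if (length(absent)) {
    warning("excluding country(ies) absent from first year ", t0, ": ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  dmax <- max(dens0)
  out <- lapply(seq_len(nrow(first)), function(i) {
    cc <- first$country[i]
    sub <- panel[panel$country == cc, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    # keep only the consecutive run starting at t0
    run <- cumsum(c(0, diff(sub$year) != 1)) == 0
    if (!all(run)) {
      warning("country ", cc, ": dropping year(s) after a gap in its series",
              call. = FALSE)
      sub <- sub[run, , drop = FALSE]
    }
    dens <- workforce_density(sub$n_nir, sub$population)
    e <- numeric(nrow(sub))
    e[1] <- dens[1] / dmax
    if (nrow(sub) > 1) {
      for (t in 2:nrow(sub)) {
        dn <- sub$n_nir[t] - sub$n_nir[t - 1]
        e[t] <- min(params$ceiling,
                    max(params$floor, e[t - 1] + params$beta0 + params$beta1 * dn))
      }
    }
    tibble::tibble(country = cc, year = sub$year, index = e,
                   effective_supply = dens * e)
  })
  res <- dplyr::bind_rows(out)
  res <- res[order(res$country, res$year), , drop = FALSE]
  structure(res, class = c("expertise_series", class(tibble::tibble())))
}

#' Effective supply: density scaled by the expertise index
#'
#' @param series an `expertise_series` from [expertise_index()].
#' @param panel the `evt_panel` the series was computed from; every
#'   (country, year) of the series must be present.
#' @return the series with `effective_supply` recomputed as
#'   `density * index`.
#' @export
effective_supply <- function(series, panel) {
  stopifnot(inherits(series, "expertise_series"), inherits(panel, "evt_panel"))
  key_s <- paste(series$country, series$year)
  key_p <- paste(panel$country, panel$year)
  if (!all(key_s %in% key_p)) {
    stop("year mismatch: series contains (country, year) pairs absent from ",
         "the panel", call. = FALSE)
  }
  idx <- match(key_s, key_p)
  dens <- workforce_density(panel$n_nir[idx], panel$population[idx])
  series$effective_supply <- dens * series$index
  series
}

#' Within-series z-scores
#'
#' Standardises a numeric series to mean 0, sample (n-1) SD 1. A constant
#' series maps to all zeros with a warning.
#'
#' @param values numeric vector, length >= 2, no missing values.
#' @return z-scores of the same length.
#' @export
within_zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (anyNA(values)) stop("missing values in series", call. = FALSE)
  s <- sd(values)
  if (s == 0) {
    warning("constant series: z-scores set to 0", call. = FALSE)
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' Within-country standardised effective supply and EVT rate
#'
#' Convenience builder for the trend analyses: joins the expertise series to
#' the panel's EVT rates and standardises both effective supply and EVT
#' rate to within-country z-scores (`z_eff`, `z_rate`).
#'
#' @param panel an `evt_panel` (complete on `n_nir`, `population`,
#'   `evt_rate` for the years analysed).
#' @param params an [expertise_params()].
#' @return tibble with columns `country`, `year`, `index`,
#'   `effective_supply`, `evt_rate`, `z_eff`, `z_rate`.
#' @export
standardize_within <- function(panel, params = expertise_params()) {
  series <- expertise_index(panel, params)
  key_p <- paste(panel$country, panel$year)
  series$evt_rate <- panel$evt_rate[match(paste(series$country, series$year),
                                          key_p)]
  if (anyNA(series$evt_rate)) {
    stop("missing evt_rate in the trend panel; apply complete_cases() first",
         call. = FALSE)
  }
  dplyr::mutate(dplyr::group_by(series, .data$country),
                z_eff = within_zscore(.data$effective_supply),
                z_rate = within_zscore(.data$evt_rate)) |>
    dplyr::ungroup()
}

#' Pooled first-difference regression of EVT-rate z-scores
#'
#' Computes year-over-year changes of `z_rate` and `z_eff` within each
#' country (consecutive years only), pools them, and fits OLS of
#' `delta z_rate` on `delta z_eff`. Removes time-invariant country effects
#' by differencing.
#'
#' @param panel_z tibble with columns `country`, `year`, `z_eff`, `z_rate`
#'   (e.g. from [standardize_within()]).
#' @param intercept include an intercept in the pooled difference
#'   regression (default `TRUE`).
#' @return an `evt_fit` for the pooled difference regression.
#' @export
first_diff_regression <- function(panel_z, intercept = TRUE) {
  stopifnot(all(c("country", "year", "z_eff", "z_rate") %in% names(panel_z)))
  diffs <- dplyr::group_by(panel_z, .data$country) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(d_rate = .data$z_rate - dplyr::lag(.data$z_rate),
                  d_eff = .data$z_eff - dplyr::lag(.data$z_eff),
                  consec = .data$year - dplyr::lag(.data$year) == 1) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$d_rate), .data$consec)
  if (nrow(diffs) == 0) stop("no consecutive-year difference pairs",
                             call. = FALSE)
  if (nrow(diffs) < 3) stop("need at least 3 pooled difference pairs",
                            call. = FALSE)
  ols_fit(diffs$d_rate, data.frame(d_eff = diffs$d_eff),
          add_intercept = intercept)
}

#' Country fixed-effects (within) estimator with robust standard errors
#'
#' Demeans `z_rate` and `z_eff` within each country and regresses the
#' demeaned response on the demeaned predictor, which is numerically
#' identical to OLS with explicit country dummies. The standard error is
#' heteroskedasticity-robust (HC1), with the absorbed country effects
#' counted in the degrees-of-freedom correction.
#'
#' @param panel_z tibble with columns `country`, `year`, `z_eff`, `z_rate`;
#'   at least 2 countries with 2 years each.
#' @return an `evt_fit` with the single slope coefficient `z_eff`.
#' @export
fixed_effects_fit <- function(panel_z) {
  stopifnot(all(c("country", "z_eff", "z_rate") %in% names(panel_z)))
  g <- factor(panel_z$country)
  if (nlevels(g) < 2) {
    stop("fixed-effects model needs at least 2 countries", call. = FALSE)
  }
  if (any(table(g) < 2)) {
    stop("every country needs at least 2 years", call. = FALSE)
  }
  demean <- function(v) v - ave(v, g)
  x <- demean(panel_z$z_eff)
  y <- demean(panel_z$z_rate)
  if (sum(x^2) < 1e-12) {
    stop("no within-country variation in z_eff; design degenerate",
         call. = FALSE)
  }
  n <- length(y)
  ngrp <- nlevels(g)
  beta <- sum(x * y) / sum(x^2)
  e <- y - beta * x
  df_resid <- n - ngrp - 1L
  if (df_resid < 1) stop("too few observations for the fixed-effects model",
                         call. = FALSE)
  # HC1 sandwich on the within regression; k counts slope + absorbed effects
  vcov_hc1 <- (n / df_resid) * sum(x^2 * e^2) / sum(x^2)^2
  se <- sqrt(vcov_hc1)
  r2_within <- 1 - sum(e^2) / sum(y^2)
  p <- 2 * pt(-abs(beta / se), df = df_resid)
  new_evt_fit(names = "z_eff", coef = beta, se = se, r2 = r2_within,
              n = n, df_resid = df_resid, p_values = p,
              se_type = "HC1 (within)")
}
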