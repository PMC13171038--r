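#' Benchmark EVT rate
#'
#' The best-in-class target: the maximum observed national EVT rate across
#' the panel's country-years, or an explicit override (e.g. the 15% policy
#' target).
#'
#' @param panel an `evt_panel` with at least one non-missing `evt_rate`.
#' @param override if non-`NULL`, returned as the benchmark regardless of
#'   the data.
#' @return benchmark EVT rate (%).
#' @export
benchmark_rate <- function(panel, override = NULL) {
  if (!is.null(override)) return(as.numeric(override))
  stopifnot(inherits(panel, "evt_panel"))
  if (nrow(panel) == 0 || all(is.na(panel$evt_rate))) {
    stop("no evt_rate values in panel", call. = FALSE)
  }
  max(panel$evt_rate, na.rm = TRUE)
}

#' Fit the linear EVT-rate model used for the gap inversion
#'
#' OLS of EVT rate on neurointerventionalist density, optionally adjusted
#' for GDP per capita (`evt_rate ~ density + gdp_pc`). Fitted on
#' complete cases of the involved variables.
#'
#' @param panel an `evt_panel`.
#' @param adjust_gdp include GDP per capita as a covariate.
#' @return an `evt_fit`.
#' @export
fit_gap_model <- function(panel, adjust_gdp = FALSE) {
  stopifnot(inherits(panel, "evt_panel"))
  dens <- workforce_density(panel$n_nir, panel$population)
  dat <- data.frame(evt_rate = panel$evt_rate, density = dens,
                    gdp_pc = panel$gdp_pc)
  if (adjust_gdp && all(is.na(dat$gdp_pc))) {
    stop("adjust_gdp = TRUE but column `gdp_pc` has no data", call. = FALSE)
  }
  vars <- if (adjust_gdp) c("density", "gdp_pc") else "density"
  dat <- dat[complete.cases(dat[c("evt_rate", vars)]), , drop = FALSE]
  fit <- ols_fit(dat$evt_rate, dat[vars], add_intercept = TRUE)
  fit$model <- if (adjust_gdp) "gdp_adjusted" else "unadjusted"
  fit
}

#' Invert the fitted EVT model for the needed workforce density
#'
#' Solves `target = a + b * density + c * gdp_pc` for density at each
#' country's own GDP per capita: `(target - a - c * gdp_pc) / b`. For the
#' unadjusted model `c = 0`. Requires a positive density coefficient;
#' otherwise the inversion is meaningless and refused.
#'
#' @param fit an `evt_fit` from [fit_gap_model()].
#' @param gdp_pc GDP per capita (ignored by the unadjusted model; may be
#'   vectorised).
#' @param target_rate benchmark EVT rate (%).
#' @return needed density per million (may be below a country's current
#'   density).
#' @export
needed_density <- function(fit, gdp_pc, target_rate) {
  stopifnot(inherits(fit, "evt_fit"))
  b <- fit$coef[["density"]]
  if (b <= 0) {
    stop("inversion refused: density coefficient is ", signif(b, 4),
         " (must be > 0 for a meaningful workforce target)", call. = FALSE)
  }
  a <- if ("intercept" %in% fit$names) fit$coef[["intercept"]] else 0
  cg <- if ("gdp_pc" %in% fit$names) fit$coef[["gdp_pc"]] else 0
  if (cg != 0 && any(is.na(gdp_pc))) {
    stop("gdp_pc required by the GDP-adjusted model but missing",
         call. = FALSE)
  }
  gterm <- if (cg == 0) 0 else cg * gdp_pc
  (target_rate - a - gterm) / b
}

#' Per-country workforce gap table
#'
#' For each country's reference year (latest year with workforce data, and
#' GDP data if the model is GDP-adjusted), computes the needed density to
#' reach `target_rate` under the fitted model, the non-negative per-million
#' gap, and the headcount gap (`ceiling(gap * population / 1e6)` - a
#' fractional person cannot staff a call rota). Negative raw gaps are
#' truncated to 0 in `gap_per_million` but preserved in `needed_density`.
#'
#' @param panel an `evt_panel`.
#' @param fit an `evt_fit` from [fit_gap_model()].
#' @param target_rate benchmark EVT rate (%).
#' @param ref_year reference year for "current" density; default is each
#'   country's latest usable year.
#' @return a tibble sorted by descending `gap_per_million` with columns
#'   `country`, `ref_year`, `current_density`, `needed_density`,
#'   `gap_per_million`, `headcount_gap`, `benchmark_rate`, `model`.
#' @export
gap_table <- function(panel, fit, target_rate, ref_year = NULL) {
  stopifnot(inherits(panel, "evt_panel"), inherits(fit, "evt_fit"))
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  adjusted <- "gdp_pc" %in% fit$names
  rows <- lapply(unique(panel$country), function(cc) {
    sub <- panel[panel$country == cc, , drop = FALSE]
    if (adjusted) sub <- sub[!is.na(sub$gdp_pc), , drop = FALSE]
    if (!is.null(ref_year)) sub <- sub[sub$year == ref_year, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop("country ", cc, " has no usable reference-year record",
           if (adjusted) " with gdp_pc" else "", call. = FALSE)
    }
    sub <- sub[which.max(sub$year), , drop = FALSE]
    cur <- workforce_density(sub$n_nir, sub$population)
    need <- needed_density(fit, sub$gdp_pc, target_rate)
    gap <- max(0, need - cur)
    if (gap < 1e-9) gap <- 0  # do not let float dust become a headcount
    tibble::tibble(
      country = cc, ref_year = sub$year, current_density = cur,
      needed_density = need, gap_per_million = gap,
      headcount_gap = as.integer(ceiling(gap * sub$population / 1e6)),
      benchmark_rate = target_rate,
      model = if (adjusted) "gdp_adjusted" else "unadjusted"
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$gap_per_million, out$country), , drop = FALSE]
}
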