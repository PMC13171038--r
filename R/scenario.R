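#' Log-linear model of stroke mortality on EVT rate
#'
#' OLS of the natural log of ischaemic-stroke mortality (per 100,000) on
#' the EVT rate, pooled over all complete country-years. The slope gamma is
#' the proportional change in mortality per EVT percentage point.
#'
#' @param panel an `evt_panel`.
#' @return an `evt_fit` with coefficients `intercept` and `evt_rate`.
#' @export
fit_log_linear <- function(panel) {
  stopifnot(inherits(panel, "evt_panel"))
  ok <- complete.cases(panel$mortality, panel$evt_rate)
  bad <- which(!is.na(panel$mortality) & panel$mortality <= 0)
  if (length(bad)) {
    stop("non-positive mortality for (", panel$country[bad[1]], ", ",
         panel$year[bad[1]], "); log-linear model undefined", call. = FALSE)
  }
  if (sum(ok) < 3) stop("need at least 3 complete (mortality, evt_rate) pairs",
                        call. = FALSE)
  ols_fit(log(panel$mortality[ok]),
          data.frame(evt_rate = panel$evt_rate[ok]))
}

#' Relative mortality reduction under an EVT-rate counterfactual
#'
#' Under the fitted log-linear model, raising a country's EVT rate from its
#' observed value to `target` multiplies its mortality by
#' `exp(gamma * (target - observed))`; the relative reduction is one minus
#' that factor. Countries already at or above the target, or a
#' non-negative gamma, yield exactly 0 - the projection reports reductions
#' only.
#'
#' @param gamma fitted log-mortality slope per EVT percentage point.
#' @param evt_observed observed EVT rate(s) (%).
#' @param target counterfactual EVT rate (%), >= 0.
#' @return relative reduction(s) in [0, 1).
#' @export
relative_reduction <- function(gamma, evt_observed, target) {
  if (any(target < 0)) stop("`target` must be >= 0", call. = FALSE)
  ifelse(evt_observed < target & gamma < 0,
         1 - exp(gamma * (target - evt_observed)),
         0)
}

#' Per-country mortality projection under a uniform EVT target
#'
#' Fits gamma once on the pooled panel, then projects each country's
#' relative mortality reduction if its EVT rate rose from the latest
#' observed value to `target` (default 15%, the best-in-class policy
#' scenario). The projection is descriptive alignment, not a causal effect.
#'
#' @param panel an `evt_panel`.
#' @param target counterfactual EVT rate (%), default 15.
#' @return a tibble sorted by descending `relative_reduction` with columns
#'   `country`, `evt_rate_observed`, `gamma`, `relative_reduction`,
#'   `target_rate`.
#' @export
scenario_table <- function(panel, target = 15) {
  stopifnot(inherits(panel, "evt_panel"))
  fit <- fit_log_linear(panel)
  gamma <- fit$coef[["evt_rate"]]
  obs <- panel[!is.na(panel$evt_rate), , drop = FALSE]
  rows <- lapply(unique(obs$country), function(cc) {
    sub <- obs[obs$country == cc, , drop = FALSE]
    sub <- sub[which.max(sub$year), , drop = FALSE]
    tibble::tibble(country = cc, evt_rate_observed = sub$evt_rate,
                   gamma = gamma,
                   relative_reduction = relative_reduction(
                     gamma, sub$evt_rate, target),
                   target_rate = target)
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$relative_reduction, out$country), , drop = FALSE]
}
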