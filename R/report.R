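config_defaults <- list(
  year_window = c(2020L, 2024L),
  inclusion_years = 2020:2022,
  gap_target = "auto",
  scenario_target = 15,
  out_dir = "evtgap_output",
  seed = 1L,
  log_level = "info"
)

#' Read and validate a YAML run configuration
#'
#' Exactly one of `panel_path` (a CSV panel to load) or `synthetic` (a block
#' of [synthetic_config()] arguments) must be present. Unknown keys -
#' including unknown keys inside the `synthetic` block - are rejected.
#' Missing optional keys are filled with defaults: year window 2020-2024,
#' inclusion years 2020-2022, gap target `"auto"` (observed maximum),
#' scenario target 15%.
#'
#' @param path path to a YAML file.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("panel_path", "synthetic", names(config_defaults))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  has_path <- !is.null(raw$panel_path)
  has_syn <- !is.null(raw$synthetic)
  if (has_path == has_syn) {
    stop("exactly one of `panel_path` and `synthetic` must be given",
         call. = FALSE)
  }
  cfg <- utils::modifyList(config_defaults, raw)
  if (length(cfg$year_window) != 2L) {
    stop("`year_window`: need two years", call. = FALSE)
  }
  if (!cfg$log_level %in% c("info", "quiet")) {
    stop("`log_level` must be \"info\" or \"quiet\"", call. = FALSE)
  }
  if (!identical(cfg$gap_target, "auto") && !is.numeric(cfg$gap_target)) {
    stop("`gap_target` must be \"auto\" or a number", call. = FALSE)
  }
  if (!is.numeric(cfg$scenario_target) || cfg$scenario_target < 0) {
    stop("`scenario_target` must be a non-negative number", call. = FALSE)
  }
  if (has_syn) {
    syn_known <- names(formals(synthetic_config))
    syn_unknown <- setdiff(names(cfg$synthetic), syn_known)
    if (length(syn_unknown)) {
      stop("unknown key(s) under `synthetic`: ",
           paste(syn_unknown, collapse = ", "), call. = FALSE)
    }
    cfg$synthetic <- do.call(synthetic_config,
                             utils::modifyList(cfg$synthetic,
                                               list(seed = cfg$seed)))
  }
  structure(cfg, class = "run_config")
}

# Flatten an evt_fit for JSON serialisation at 6 significant digits.
fit_to_list <- function(fit) {
  list(names = fit$names, coef = signif(unname(fit$coef), 6),
       se = signif(unname(fit$se), 6), r2 = signif(fit$r2, 6),
       n = fit$n, df_resid = fit$df_resid,
       p_values = signif(unname(fit$p_values), 6), se_type = fit$se_type)
}

assoc_to_list <- function(a) {
  list(x_var = a$x_var, y_var = a$y_var, rho = signif(a$rho, 6), n = a$n,
       ci_lo = signif(a$ci_lo, 6), ci_hi = signif(a$ci_hi, 6),
       p_value = signif(a$p_value, 6), level = a$level)
}

signif_df <- function(df, digits = 6) {
  df[] <- lapply(df, function(v) if (is.double(v)) signif(v, digits) else v)
  df
}

# Row-restrict a panel to given years, preserving class and window.
restrict_years <- function(panel, years) {
  out <- panel[panel$year %in% years, , drop = FALSE]
  structure(out, year_window = attr(panel, "year_window"),
            class = class(panel))
}

#' Run the full workforce-capacity analysis
#'
#' Wires every stage together: panel ingestion (or synthetic generation),
#' the density/EVT/outcome rank correlations, the expertise-index trend
#' analyses (first-difference and country fixed-effects), the workforce-gap
#' inversion under both the unadjusted and GDP-adjusted models, and the
#' uniform-EVT-target mortality projection. Outputs are written to
#' `config$out_dir`: `assoc.json`, `expertise.csv`, `trend_fits.json`,
#' `gap.csv`, `scenario.csv` and `run_manifest.json`. Floats are serialised
#' at 6 significant digits, so an identical config and seed reproduces a
#' byte-identical bundle. Any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' @param config a `run_config` from [validate_config()], or a path to a
#'   YAML config file.
#' @return invisibly, a list with the panel, fitted objects, tables and the
#'   manifest.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  log_msg <- function(stage, txt) {
    if (config$log_level != "quiet") {
      message(sprintf("[%s] %s", stage, txt))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(file) written <<- c(written, file.path(out_dir, file))

  panel <- stage("panel_model", {
    if (!is.null(config$panel_path)) {
      log_msg("panel_model", paste("loading", config$panel_path))
      read_panel(config$panel_path, year_window = config$year_window)
    } else {
      log_msg("panel_model", sprintf("generating synthetic panel (seed %d)",
                                     config$seed))
      suppressMessages(generate_panel(config$synthetic))$panel
    }
  })

  assoc <- stage("association_stats", {
    outcomes <- list(c("density", "mortality"), c("density", "daly"),
                     c("density", "yld"), c("evt_rate", "mortality"),
                     c("evt_rate", "daly"), c("evt_rate", "yld"))
    res <- list(
      main = assoc_to_list(associate_panel(panel, "density", "evt_rate")),
      outcomes = lapply(outcomes, function(p) {
        assoc_to_list(associate_panel(panel, p[1], p[2]))
      })
    )
    jsonlite::write_json(res, file.path(out_dir, "assoc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("assoc.json")
    res
  })

  trend <- stage("expertise_dynamics", {
    sub <- restrict_years(
      complete_cases(panel, c("n_nir", "population", "evt_rate"),
                     config$inclusion_years),
      config$inclusion_years)
    log_msg("expertise_dynamics",
            sprintf("%d countries complete for %s",
                    length(unique(sub$country)),
                    paste(range(config$inclusion_years), collapse = "-")))
    z <- standardize_within(sub)
    readr::write_csv(signif_df(tibble::as_tibble(z)),
                     file.path(out_dir, "expertise.csv"))
    emit("expertise.csv")
    fits <- list(first_difference = fit_to_list(first_diff_regression(z)),
                 fixed_effects = fit_to_list(fixed_effects_fit(z)))
    jsonlite::write_json(fits, file.path(out_dir, "trend_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("trend_fits.json")
    list(z = z, fits = fits)
  })

  gaps <- stage("capacity_gap", {
    sub <- restrict_years(
      complete_cases(panel, c("n_nir", "population", "evt_rate"),
                     config$inclusion_years),
      config$inclusion_years)
    target <- if (identical(config$gap_target, "auto")) {
      benchmark_rate(sub)
    } else {
      as.numeric(config$gap_target)
    }
    fit_u <- fit_gap_model(sub, adjust_gdp = FALSE)
    sub_g <- complete_cases(sub, c("n_nir", "population", "evt_rate", "gdp_pc"),
                            config$inclusion_years)
    if (nrow(sub_g) == 0) {
      stop("no countries with complete gdp_pc for the GDP-adjusted model",
           call. = FALSE)
    }
    fit_g <- fit_gap_model(sub_g, adjust_gdp = TRUE)
    tab <- dplyr::bind_rows(gap_table(sub, fit_u, target),
                            gap_table(sub_g, fit_g, target))
    readr::write_csv(signif_df(tibble::as_tibble(tab)),
                     file.path(out_dir, "gap.csv"))
    emit("gap.csv")
    list(target = target, unadjusted = fit_u, gdp_adjusted = fit_g, table = tab)
  })

  scen <- stage("mortality_scenario", {
    tab <- scenario_table(panel, target = config$scenario_target)
    readr::write_csv(signif_df(tibble::as_tibble(tab)),
                     file.path(out_dir, "scenario.csv"))
    emit("scenario.csv")
    tab
  })

  manifest <- stage("report", {
    input_md5 <- if (!is.null(config$panel_path)) {
      unname(tools::md5sum(config$panel_path))
    } else {
      sprintf("synthetic-seed-%d", config$seed)
    }
    m <- list(
      package = "evtgap",
      version = as.character(utils::packageVersion("evtgap")),
      seed = config$seed,
      config = unclass(config)[setdiff(names(config), "synthetic")],
      synthetic = if (!is.null(config$synthetic)) unclass(config$synthetic),
      input = input_md5,
      outputs = as.list(setNames(unname(tools::md5sum(written)),
                                 basename(written))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(m, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })
  log_msg("report", paste("bundle written to", out_dir))
  invisible(list(panel = panel, associations = assoc, trend = trend,
                 gaps = gaps, scenario = scen, manifest = manifest))
}
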