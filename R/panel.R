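#' @importFrom rlang .data
#' @importFrom stats ave coef complete.cases lm pt qnorm rnorm rpois runif sd setNames
NULL

# Canonical column order of a country-year panel; the first five are mandatory.
panel_columns <- c(
  "country", "year", "n_nir", "population", "evt_rate", "ivt_rate",
  "mortality", "daly", "yld", "gdp_pc", "n_centres", "work_hours", "source"
)
mandatory_columns <- c("country", "year", "n_nir", "population", "evt_rate")

# Smallest population admitted: microstates below this are excluded from
# country-level stroke-care comparisons.
MIN_POPULATION <- 1e5

#' Construct and validate a country-year panel
#'
#' An `evt_panel` is a tibble with one row per (country, year) holding
#' neurointerventionalist workforce counts, population, EVT treatment rates
#' and stroke outcome rates. Columns absent from `x` are added as missing.
#' Rows for countries with fewer than 100,000 inhabitants are dropped with a
#' warning, since microstates are excluded from country-level comparisons.
#'
#' @param x data frame with at least columns `country` (ISO-3166 alpha-3
#'   code), `year`, `n_nir` (count of practising neurointerventionalists),
#'   `population`, `evt_rate` (% of ischaemic strokes treated with EVT).
#'   Optional columns: `ivt_rate`, `mortality` (ischaemic-stroke deaths per
#'   100,000), `daly`, `yld` (rates per 100,000), `gdp_pc` (current US $),
#'   `n_centres`, `work_hours`, `source`.
#' @param year_window length-2 integer vector, inclusive span of admissible
#'   years. Defaults to `c(2020, 2024)`.
#' @return a validated `evt_panel` tibble, ordered by country then year.
#' @export
as_panel <- function(x, year_window = c(2020L, 2024L)) {
  stopifnot(is.data.frame(x))
  if (length(year_window) != 2L || any(is.na(year_window)) ||
      year_window[1] > year_window[2]) {
    stop("`year_window` must be two ordered years", call. = FALSE)
  }
  missing_cols <- setdiff(mandatory_columns, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  for (col in setdiff(panel_columns, names(x))) {
    x[[col]] <- if (col == "source") NA_character_ else NA_real_
  }
  x <- x[panel_columns]

  x$source <- as.character(x$source)
  x$source[!is.na(x$source) & trimws(x$source) %in% c("", "NA")] <- NA_character_
  x$country <- toupper(trimws(as.character(x$country)))
  bad <- which(!grepl("^[A-Z]{3}$", x$country))
  if (length(bad)) {
    stop("row ", bad[1], ": `country` must be an ISO-3166 alpha-3 code, got \"",
         x$country[bad[1]], "\"", call. = FALSE)
  }

  num_cols <- setdiff(panel_columns, c("country", "source"))
  for (col in num_cols) {
    v <- x[[col]]
    if (is.character(v)) {
      v <- trimws(v)
      v[v %in% c("", "NA")] <- NA
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) {
        row <- which(is.na(vn) & !is.na(v))[1]
        stop("row ", row, ", column `", col, "`: non-numeric value \"",
             v[row], "\"", call. = FALSE)
      }
      v <- vn
    }
    x[[col]] <- as.numeric(v)
  }

  check_range <- function(col, ok, what) {
    v <- x[[col]]
    bad <- which(!is.na(v) & !ok(v))
    if (length(bad)) {
      stop("row ", bad[1], ", column `", col, "`: value ", v[bad[1]], " ",
           what, call. = FALSE)
    }
  }
  for (col in c("year", "n_nir", "population")) {
    if (anyNA(x[[col]])) {
      stop("column `", col, "` contains missing values (row ",
           which(is.na(x[[col]]))[1], ")", call. = FALSE)
    }
  }
  check_range("year", function(v) v == round(v) &
                v >= year_window[1] & v <= year_window[2],
              sprintf("outside year window [%d, %d]",
                      year_window[1], year_window[2]))
  check_range("n_nir", function(v) v >= 0 & v == round(v),
              "must be a non-negative integer count")
  check_range("population", function(v) v > 0, "must be > 0")
  check_range("evt_rate", function(v) v >= 0 & v <= 100,
              "outside [0, 100]")
  check_range("ivt_rate", function(v) v >= 0 & v <= 100,
              "outside [0, 100]")
  check_range("mortality", function(v) v > 0, "must be > 0")
  check_range("daly", function(v) v >= 0, "must be >= 0")
  check_range("yld", function(v) v >= 0, "must be >= 0")
  check_range("gdp_pc", function(v) v > 0, "must be > 0")
  check_range("n_centres", function(v) v >= 0 & v == round(v),
              "must be a non-negative integer count")
  check_range("work_hours", function(v) v > 0, "must be > 0")

  small <- x$population < MIN_POPULATION
  if (any(small)) {
    warning("dropping ", sum(small), " row(s) for countries with population ",
            "below 100,000 (", paste(unique(x$country[small]), collapse = ", "),
            ")", call. = FALSE)
    x <- x[!small, , drop = FALSE]
  }

  key <- paste(x$country, x$year)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (country, year) key: (",
         sub(" ", ", ", d), ")", call. = FALSE)
  }

  x$year <- as.integer(x$year)
  x <- x[order(x$country, x$year), , drop = FALSE]
  structure(x, year_window = as.integer(year_window),
            class = c("evt_panel", class(tibble::tibble())))
}

#' Read a country-year panel from CSV
#'
#' The CSV must be headered, UTF-8, one row per (country, year), with at
#' least the mandatory columns `country, year, n_nir, population, evt_rate`.
#' Empty cells and the literal string `NA` are both read as missing.
#'
#' @param path path to a CSV file.
#' @inheritParams as_panel
#' @return an `evt_panel`.
#' @export
read_panel <- function(path, year_window = c(2020L, 2024L)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  as_panel(raw, year_window = year_window)
}

#' Write a panel to CSV
#'
#' Writes the canonical column order; missing cells become empty strings, so
#' `read_panel(write_panel(p, f))` round-trips all non-missing values.
#'
#' @param panel an `evt_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "evt_panel"))
  readr::write_csv(tibble::as_tibble(panel)[panel_columns], path, na = "")
  invisible(path)
}

#' Neurointerventionalist density per million inhabitants
#'
#' @param n_nir count(s) of practising neurointerventionalists.
#' @param population population(s) served; must be positive.
#' @return `n_nir * 1e6 / population`.
#' @examples
#' workforce_density(30, 6e6)  # 5 per million
#' @export
workforce_density <- function(n_nir, population) {
  if (any(is.na(population)) || any(population <= 0)) {
    stop("`population` must be > 0", call. = FALSE)
  }
  n_nir * 1e6 / population
}

# Extract a named variable from a panel, computing density on the fly.
panel_var <- function(panel, var) {
  if (var == "density") {
    return(workforce_density(panel$n_nir, panel$population))
  }
  if (!var %in% panel_columns) {
    stop("unknown panel variable: `", var, "`", call. = FALSE)
  }
  panel[[var]]
}

#' Restrict a panel to countries with complete data
#'
#' Keeps only countries that have a row with non-missing values for every
#' variable in `required_vars` in every year of `required_years`, mirroring
#' the inclusion rule that a country enters the trend and gap analyses only
#' if workforce and EVT data are available for all years of the window.
#' All rows of qualifying countries are retained.
#'
#' @param panel an `evt_panel`.
#' @param required_vars character vector of panel variables (the derived
#'   `"density"` is accepted and means `n_nir` and `population`).
#' @param required_years integer vector of years, a subset of the panel's
#'   year window.
#' @return the sub-panel of complete countries, ordered by country then year.
#' @export
complete_cases <- function(panel, required_vars, required_years) {
  stopifnot(inherits(panel, "evt_panel"))
  if (length(required_vars) == 0) {
    stop("`required_vars` must not be empty", call. = FALSE)
  }
  required_vars <- unique(as.character(required_vars))
  unknown <- setdiff(required_vars, c(panel_columns, "density"))
  if (length(unknown)) {
    stop("unknown required variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  required_vars[required_vars == "density"] <- NA
  required_vars <- unique(c(required_vars[!is.na(required_vars)],
                            if (anyNA(required_vars)) c("n_nir", "population")))
  yw <- attr(panel, "year_window")
  required_years <- as.integer(required_years)
  if (any(required_years < yw[1] | required_years > yw[2])) {
    stop("`required_years` outside the panel year window", call. = FALSE)
  }
  ok_country <- vapply(unique(panel$country), function(cc) {
    sub <- panel[panel$country == cc & panel$year %in% required_years, , drop = FALSE]
    if (nrow(sub) < length(required_years)) return(FALSE)
    all(vapply(required_vars, function(v) !anyNA(sub[[v]]), logical(1)))
  }, logical(1))
  keep <- names(ok_country)[ok_country]
  out <- panel[panel$country %in% keep, , drop = FALSE]
  out <- out[order(out$country, out$year), , drop = FALSE]
  structure(out, year_window = yw, class = class(panel))
}

#' @export
print.evt_panel <- function(x, ...) {
  yw <- attr(x, "year_window")
  cat(sprintf("<evt_panel> %d record(s), %d country(ies), years %d-%d\n",
              nrow(x), length(unique(x$country)), yw[1], yw[2]))
  NextMethod()
}
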