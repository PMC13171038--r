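# Builders for small deterministic panels used across the test files.

# A panel from per-country densities: evt_rate follows the exact linear law
# a + b * density unless noise is supplied.
linear_panel <- function(densities, years = 2020L, a = 2.5, b = 1.17,
                         population = 1e7, gdp_pc = NA_real_,
                         mortality = NULL, noise = 0) {
  codes <- sprintf("A%s%s", LETTERS[(seq_along(densities) - 1) %/% 26 + 1],
                   LETTERS[(seq_along(densities) - 1) %% 26 + 1])
  grid <- expand.grid(i = seq_along(densities), year = years)
  dens <- densities[grid$i]
  pop <- if (length(population) == 1) rep(population, nrow(grid)) else population[grid$i]
  gdp <- if (length(gdp_pc) == 1) rep(gdp_pc, nrow(grid)) else gdp_pc[grid$i]
  evt <- pmin(pmax(a + b * dens + noise, 0), 100)
  df <- data.frame(
    country = codes[grid$i], year = grid$year,
    n_nir = round(dens * pop / 1e6), population = pop,
    evt_rate = evt, gdp_pc = gdp
  )
  if (!is.null(mortality)) df$mortality <- mortality
  as_panel(df, year_window = range(c(2020L, years)))
}

# A tiny hand-written multi-year panel for trend / completeness tests.
toy_trend_panel <- function() {
  df <- data.frame(
    country = rep(c("CHE", "DNK", "EST"), each = 3),
    year = rep(2020:2022, 3),
    n_nir = c(40, 44, 50, 20, 22, 26, 5, 6, 8),
    population = rep(c(8.7e6, 5.8e6, 1.3e6), each = 3),
    evt_rate = c(8, 9, 10.5, 6, 6.5, 7.5, 2, 2.4, 3.1),
    mortality = c(30, 29, 28, 35, 34, 33, 60, 58, 55),
    gdp_pc = rep(c(85000, 65000, 27000), each = 3)
  )
  as_panel(df, year_window = c(2020L, 2024L))
}

write_panel_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  f
}
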