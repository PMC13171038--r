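test_that("benchmark_rate takes the observed maximum unless overridden", {
  p <- linear_panel(c(0.5, 2, 4))
  p$evt_rate <- c(0.05, 7.3, 14.96)
  expect_equal(benchmark_rate(p), 14.96)
  single <- linear_panel(3)
  expect_equal(benchmark_rate(single), single$evt_rate)
  expect_equal(benchmark_rate(p, override = 15), 15)
  p$evt_rate <- NA_real_
  expect_error(benchmark_rate(p), "no evt_rate")
})

test_that("fit_gap_model recovers a noiseless linear law exactly", {
  p <- linear_panel(c(0.5, 1.5, 3, 5, 7), a = 2.5, b = 1.17)
  f <- fit_gap_model(p)
  expect_equal(unname(f$coef), c(2.5, 1.17), tolerance = 1e-9)
  expect_equal(f$model, "unadjusted")
  expect_error(fit_gap_model(p, adjust_gdp = TRUE), "gdp_pc")
  # with GDP in the design and no GDP effect, its coefficient is ~0
  p2 <- linear_panel(c(0.5, 1.5, 3, 5, 7),
                     gdp_pc = c(2e4, 5e4, 3e4, 8e4, 1e4))
  f2 <- fit_gap_model(p2, adjust_gdp = TRUE)
  expect_equal(unname(f2$coef[["gdp_pc"]]), 0, tolerance = 1e-12)
  expect_equal(f2$model, "gdp_adjusted")
})

test_that("needed_density inverts the fitted equation", {
  p <- linear_panel(c(0.5, 1.5, 3, 5, 7), a = 2.5, b = 1.17)
  f <- fit_gap_model(p)
  expect_equal(needed_density(f, NA, 15), (15 - 2.5) / 1.17, tolerance = 1e-9)
  expect_equal(round(needed_density(f, NA, 15), 3), 10.684)
  # fixed point: the fitted value at a country's own density needs no change
  d <- 3
  fitted_rate <- f$coef[["intercept"]] + f$coef[["density"]] * d
  expect_equal(needed_density(f, NA, fitted_rate), d, tolerance = 1e-9)
  bad <- f; bad$coef[["density"]] <- -0.5
  expect_error(needed_density(bad, NA, 15), "inversion refused")
})

test_that("inversion is self-consistent and monotone", {
  g <- suppressMessages(generate_panel(synthetic_config(
    seed = 2, true_gdp_coef = 5e-5)))
  f <- fit_gap_model(g$panel, adjust_gdp = TRUE)
  gdp <- g$panel$gdp_pc
  need <- needed_density(f, gdp, 15)
  back <- f$coef[["intercept"]] + f$coef[["density"]] * need +
    f$coef[["gdp_pc"]] * gdp
  expect_equal(back, rep(15, length(gdp)), tolerance = 1e-9)
  # raising the target raises needed density; richer countries need less
  expect_true(all(needed_density(f, gdp, 20) > need))
  if (f$coef[["gdp_pc"]] > 0) {
    expect_true(all(needed_density(f, gdp + 1000, 15) < need))
  }
})

test_that("gap_table truncates satisfied countries and rounds headcounts up", {
  # densities 1, 4, 10 with evt = 2.5 + 1.25 * density; target 15 needs
  # density (15 - 2.5) / 1.25 = 10 exactly
  df <- data.frame(country = c("AAA", "BBB", "CCC"), year = 2022,
                   n_nir = c(9, 16, 20),
                   population = c(9e6, 4e6, 2e6),
                   evt_rate = 2.5 + 1.25 * c(1, 4, 10))
  p <- as_panel(df)
  f <- fit_gap_model(p)
  tab <- gap_table(p, f, 15)
  expect_equal(nrow(tab), 3L)
  # the country already at the needed density has zero gap
  sat <- tab[tab$country == "CCC", ]
  expect_equal(sat$gap_per_million, 0, tolerance = 1e-9)
  expect_equal(sat$headcount_gap, 0L)
  # headcount = ceiling(gap * population / 1e6)
  row1 <- tab[tab$country == "AAA", ]
  expect_equal(row1$gap_per_million, 9, tolerance = 1e-9)
  expect_equal(row1$headcount_gap, 81L)
  # sorted by descending gap
  expect_true(all(diff(tab$gap_per_million) <= 0))
  # a literal worked case: gap 2 per million, 8.7M people -> 18 heads
  expect_equal(as.integer(ceiling(2 * 8.7e6 / 1e6)), 18L)
})

test_that("gap_table matches a hand-computed inversion row by row", {
  df <- data.frame(country = c("AAA", "BBB", "CCC", "DDD"), year = 2022,
                   n_nir = c(10, 60, 30, 8),
                   population = c(5e6, 1e7, 4e6, 2e6),
                   evt_rate = c(3, 9, 7, 4.5),
                   gdp_pc = c(20000, 70000, 40000, 30000))
  p <- as_panel(df)
  f <- fit_gap_model(p, adjust_gdp = TRUE)
  a <- f$coef[["intercept"]]; b <- f$coef[["density"]]; cg <- f$coef[["gdp_pc"]]
  tab <- gap_table(p, f, 15)
  for (i in seq_len(4)) {
    row <- tab[tab$country == df$country[i], ]
    cur <- df$n_nir[i] * 1e6 / df$population[i]
    need <- (15 - a - cg * df$gdp_pc[i]) / b
    expect_equal(row$current_density, cur, tolerance = 1e-12)
    expect_equal(row$needed_density, need, tolerance = 1e-9)
    expect_equal(row$gap_per_million, max(0, need - cur), tolerance = 1e-9)
    expect_equal(row$headcount_gap,
                 as.integer(ceiling(max(0, need - cur) * df$population[i] / 1e6)))
  }
})

test_that("slope recovery on the default synthetic panel", {
  g <- suppressMessages(generate_panel(synthetic_config(
    n_countries = 200, years = 2020, seed = 17)))
  f <- fit_gap_model(g$panel)
  expect_lt(abs(f$coef[["density"]] - 1.17), 3 * f$se[["density"]])
})
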