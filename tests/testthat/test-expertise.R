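test_that("the expertise index initialises from relative first-year density", {
  df <- data.frame(country = rep(c("AAA", "BBB"), each = 2),
                   year = rep(2020:2021, 2),
                   n_nir = c(50, 50, 25, 25),
                   population = 1e7, evt_rate = 5)
  p <- as_panel(df)
  s <- expertise_index(p)
  expect_equal(s$index[s$country == "AAA" & s$year == 2020], 1.0)
  expect_equal(s$index[s$country == "BBB" & s$year == 2020], 0.5)
  # unchanged head count: increment is exactly beta0
  expect_equal(s$index[s$country == "BBB" & s$year == 2021], 0.505)
  # at the ceiling, gains cannot push the index above 1
  df2 <- df; df2$n_nir <- c(50, 60, 25, 25)
  s2 <- expertise_index(as_panel(df2))
  expect_equal(s2$index[s2$country == "AAA" & s2$year == 2021], 1.0)
})

test_that("the index never leaves [floor, ceiling] for adversarial counts", {
  set.seed(3)
  for (i in 1:10) {
    n0 <- sample(5:100, 1)
    steps <- sample(c(-80, -20, -5, 0, 5, 50, 200), 6, replace = TRUE)
    counts <- pmax(0, cumsum(c(n0, steps)))
    df <- data.frame(country = c(rep("AAA", 7), rep("BBB", 7)),
                     year = rep(2020:2026, 2),
                     n_nir = c(counts, rep(10, 7)),
                     population = 1e7, evt_rate = 5)
    s <- expertise_index(as_panel(df, year_window = c(2020, 2026)))
    expect_true(all(s$index >= 0 & s$index <= 1))
  }
})

test_that("the index is non-decreasing when increments stay above -beta0", {
  df <- data.frame(country = rep(c("AAA", "BBB"), each = 5),
                   year = rep(2020:2024, 2),
                   n_nir = c(10, 12, 12, 15, 20, 40, 40, 41, 43, 43),
                   population = 1e7, evt_rate = 5)
  s <- expertise_index(as_panel(df))
  for (cc in c("AAA", "BBB")) {
    expect_true(all(diff(s$index[s$country == cc]) >= 0))
  }
})

test_that("countries absent from the first year are excluded with a warning", {
  df <- data.frame(country = c("AAA", "AAA", "BBB"),
                   year = c(2020, 2021, 2021),
                   n_nir = c(10, 12, 20), population = 1e7, evt_rate = 5)
  expect_warning(s <- expertise_index(as_panel(df)), "absent from first year")
  expect_setequal(unique(s$country), "AAA")
  df0 <- data.frame(country = c("AAA", "BBB"), year = 2020, n_nir = 0,
                    population = 1e7, evt_rate = 5)
  expect_error(expertise_index(as_panel(df0)), "first-year densities are zero")
})

test_that("effective supply is density scaled by the index", {
  df <- data.frame(country = rep(c("AAA", "BBB"), each = 2),
                   year = rep(2020:2021, 2),
                   n_nir = c(40, 40, 20, 20), population = 1e7, evt_rate = 5)
  p <- as_panel(df)
  s <- expertise_index(p)
  s2 <- effective_supply(s, p)
  expect_equal(s2$effective_supply, s$index * workforce_density(
    c(40, 40, 20, 20)[match(paste(s$country, s$year),
                            paste(df$country, df$year))], 1e7))
  # index 1 throughout means effective supply equals raw density
  expect_equal(s2$effective_supply[s2$country == "AAA" & s2$year == 2020], 4)
  bad <- s; bad$year <- bad$year + 10L
  expect_error(effective_supply(bad, p), "mismatch")
})

test_that("within_zscore standardises and flags degenerate series", {
  expect_equal(within_zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_warning(z <- within_zscore(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_error(within_zscore(5), "at least 2")
  set.seed(8)
  for (i in 1:10) {
    v <- rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 4))
    z <- within_zscore(v)
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("first-difference regression recovers perfect and null coupling", {
  z <- tibble::tibble(
    country = rep(c("AAA", "BBB", "CCC"), each = 3),
    year = rep(2020:2022, 3),
    z_eff = c(-1, 0, 1, -1.2, 0.2, 1, -1, 0.1, 0.9)
  )
  z$z_rate <- z$z_eff
  f <- first_diff_regression(z)
  expect_equal(unname(f$coef[["d_eff"]]), 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  z2 <- z; z2$z_rate <- rep(c(0.3, 0.3, 0.3), 3)
  f2 <- first_diff_regression(z2)
  expect_equal(unname(f2$coef[["d_eff"]]), 0, tolerance = 1e-12)
  # only consecutive years are differenced
  z3 <- z; z3$year <- rep(c(2020, 2022, 2024), 3)
  expect_error(first_diff_regression(z3), "no consecutive-year")
})

test_that("first-difference regression is invariant to per-country affine maps", {
  set.seed(21)
  raw <- tibble::tibble(
    country = rep(sprintf("A%s%s", LETTERS[1:8], LETTERS[1:8]), each = 4),
    year = rep(2020:2023, 8),
    eff = rnorm(32, 5, 2), rate = rnorm(32, 6, 3)
  )
  zs <- function(d) dplyr::mutate(
    dplyr::group_by(d, country),
    z_eff = within_zscore(eff), z_rate = within_zscore(rate)) |>
    dplyr::ungroup()
  f0 <- first_diff_regression(zs(raw))
  warped <- raw
  for (cc in unique(raw$country)) {
    i <- warped$country == cc
    warped$eff[i] <- runif(1, 0.5, 3) * warped$eff[i] + runif(1, -10, 10)
    warped$rate[i] <- runif(1, 0.5, 3) * warped$rate[i] + runif(1, -10, 10)
  }
  f1 <- first_diff_regression(zs(warped))
  expect_equal(unname(f1$coef), unname(f0$coef), tolerance = 1e-10)
})

test_that("pooled first differences recover a generating slope of 0.8", {
  set.seed(14)
  ncty <- 11
  rows <- lapply(seq_len(ncty), function(i) {
    z_eff <- within_zscore(rnorm(3))
    d_rate <- 0.8 * diff(z_eff) + rnorm(2, 0, 0.2)
    tibble::tibble(country = sprintf("A%s%s", LETTERS[i], LETTERS[i]),
                   year = 2020:2022, z_eff = z_eff,
                   z_rate = cumsum(c(rnorm(1, 0, 0.3), d_rate)))
  })
  f <- first_diff_regression(dplyr::bind_rows(rows))
  b <- f$coef[["d_eff"]]; se <- f$se[["d_eff"]]
  expect_lt(abs(b - 0.8), 3 * se)
})

test_that("the within estimator strips country offsets exactly", {
  z <- tibble::tibble(
    country = rep(c("AAA", "BBB", "CCC"), each = 4),
    year = rep(2020:2023, 3),
    z_eff = rnorm(12)
  )
  offsets <- c(AAA = 5, BBB = -2, CCC = 0.4)
  z$z_rate <- 0.6 * z$z_eff + offsets[z$country]
  f <- fixed_effects_fit(z)
  expect_equal(unname(f$coef[["z_eff"]]), 0.6, tolerance = 1e-12)
})

test_that("within estimator equals country-dummy OLS with HC1 errors", {
  skip_if_not_installed("sandwich")
  skip_if_not_installed("lmtest")
  set.seed(33)
  for (i in 1:5) {
    z <- tibble::tibble(
      country = rep(sprintf("A%s%s", LETTERS[1:6], LETTERS[1:6]), each = 4),
      year = rep(2020:2023, 6),
      z_eff = rnorm(24)
    )
    z$z_rate <- 0.5 * z$z_eff + rnorm(24, sd = 0.7) +
      rep(rnorm(6, sd = 2), each = 4)
    f <- fixed_effects_fit(z)
    m <- lm(z_rate ~ z_eff + factor(country), data = z)
    ct <- lmtest::coeftest(m, vcov = sandwich::vcovHC(m, type = "HC1"))
    expect_equal(unname(f$coef[["z_eff"]]), unname(coef(m)[["z_eff"]]),
                 tolerance = 1e-10)
    expect_equal(unname(f$se[["z_eff"]]), ct["z_eff", "Std. Error"],
                 tolerance = 1e-10)
  }
})

test_that("degenerate fixed-effects designs are refused", {
  z <- tibble::tibble(country = rep("AAA", 4), year = 2020:2023,
                      z_eff = rnorm(4), z_rate = rnorm(4))
  expect_error(fixed_effects_fit(z), "at least 2 countries")
  z2 <- tibble::tibble(country = rep(c("AAA", "BBB"), each = 3),
                       year = rep(2020:2022, 2),
                       z_eff = rep(c(1, 2), each = 3), z_rate = rnorm(6))
  expect_error(fixed_effects_fit(z2), "no within-country variation")
})
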