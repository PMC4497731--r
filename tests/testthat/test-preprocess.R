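# preprocessing: lambda formation and exclusion rules, day-weighted seasonal
# aggregation, long-term means, density proxy, mast coding, standardization,
# mass conversion

bags_df <- function(bag, area = 1, years = seq_along(bag) + 1989,
                    region = "A", country = "X") {
  data.frame(country = country, region = region, year = years, bag = bag,
             area_km2 = area)
}

test_that("lambda is the ratio of consecutive bags", {
  out <- compute_lambda(bags_df(c(10, 20, 30)))
  expect_equal(out$lambda$lambda, c(2.0, 1.5))
  expect_equal(out$lambda$year, c(1991, 1992))
  expect_equal(nrow(out$exclusions), 0)
})

test_that("low-density bags drop both adjacent growth rates", {
  out <- compute_lambda(bags_df(c(5, 40, 60), area = 1000))
  # year-1 density 0.005 < 0.01: removed; only 60/40 survives
  expect_equal(out$lambda$lambda, 1.5)
  expect_equal(out$lambda$year, 1992)
  expect_setequal(out$exclusions$rule, "low_density_prior")
})

test_that("no growth rate spans a gap in the years", {
  out <- compute_lambda(bags_df(c(10, 20), years = c(1990, 1992)))
  expect_equal(nrow(out$lambda), 0)
  expect_equal(out$exclusions$rule, "non_consecutive")
})

test_that("listed census years are removed with accounting and warnings", {
  rows <- compute_lambda(bags_df(c(10, 20, 30, 40, 50)))$lambda
  expect_identical(suppressMessages(
    exclude_years(rows, NULL))[, names(rows)], rows)
  out <- suppressMessages(
    exclude_years(rows, data.frame(region = "A", year = c(1991, 1993))))
  expect_equal(nrow(out), nrow(rows) - 2)
  expect_warning(
    suppressMessages(
      exclude_years(rows, data.frame(region = "ZZ", year = 1991))),
    "matched no data row")
})

test_that("seasonal means are day-weighted, with leap-year February", {
  clim <- data.frame(region = "A",
                     year = rep(c(1990, 1991), each = 12) - c(1, 0),
                     month = 1:12, tmean_c = 0, precip_mm = 10)
  clim <- expand.grid(region = "A", year = 1989:1992, month = 1:12)
  clim$tmean_c <- 0
  clim$precip_mm <- 10
  set_t <- function(y, m, v) clim$tmean_c[clim$year == y & clim$month == m] <<- v
  set_t(1990, 12, -2); set_t(1991, 1, -4); set_t(1991, 2, 0)
  expect_equal(seasonal_mean(clim, "A", "winter", 1991),
               (31 * -2 + 31 * -4 + 28 * 0) / 90)   # -2.0667: 1991 not leap
  set_t(1991, 12, -2); set_t(1992, 1, -4); set_t(1992, 2, 0)
  expect_equal(seasonal_mean(clim, "A", "winter", 1992),
               (31 * -2 + 31 * -4 + 29 * 0) / 91)   # 1992 leap: Feb weight 29
  # constant season
  expect_equal(seasonal_mean(clim, "A", "summer", 1991), 0)
  # missing month flags the record
  clim2 <- clim[!(clim$year == 1991 & clim$month == 1), ]
  expect_true(is.na(seasonal_mean(clim2, "A", "winter", 1991)))
  # precipitation sums
  expect_equal(seasonal_precip_sum(clim, "A", "spring", 1991), 30)
  expect_true(is.na(seasonal_precip_sum(clim2, "A", "winter", 1991)))
})

test_that("season day-weights tile the calendar year", {
  defs <- boargrowth:::.season_defs
  total_nonleap <- sum(vapply(defs, function(d)
    sum(boargrowth:::days_in_month(d$month, 1991 + d$offset)), numeric(1)))
  total_leap <- sum(vapply(defs, function(d)
    sum(boargrowth:::days_in_month(d$month, 1992 + d$offset)), numeric(1)))
  expect_equal(total_nonleap, 365)
  expect_equal(total_leap, 366)
})

test_that("long-term means handle constant, alternating and missing series", {
  clim <- expand.grid(region = "A", year = 1972:2003, month = 1:12)
  clim$tmean_c <- 5
  clim$precip_mm <- 0
  expect_equal(longterm_mean(clim, "summer_t", region = "A"), 5)
  # alternating -1/+1 summers over the even 30-year window
  clim$tmean_c <- ifelse(clim$year %% 2 == 0, -1, 1)
  expect_equal(longterm_mean(clim, "summer_t", region = "A"), 0)
  clim2 <- clim[clim$year != 1990, ]
  expect_error(longterm_mean(clim2, "summer_t", region = "A"),
               "missing year\\(s\\) 1990")
})

test_that("density proxy averages the five preceding years", {
  s <- bags_df(c(1, 1, 1, 1, 2, 3), years = 1990:1995)
  expect_equal(density_proxy(s, "A", 1995), 1.2)
  expect_equal(density_proxy(s, "A", 1994), NA_real_)  # only 4 prior years
  s2 <- bags_df(rep(7, 6), years = 1990:1995)
  expect_equal(density_proxy(s2, "A", 1995), 7)
})

test_that("mast coding follows the category inequalities", {
  ranks <- data.frame(region = "A", year = c(1990, 1991, 1992, 1992, 1993),
                      rank = c(3, 2, 2, 3, 1))
  expect_equal(code_mast(ranks, 1991)$mast_prev, 1)      # rank 3 -> mast
  cm <- code_mast(ranks, 1993)                           # 1992 averaged: 2.5
  expect_equal(cm$mast_prev, 0)
  expect_equal(cm$category, "moderate")                  # 1 < 2.5 <= 3
  cats <- mast_categories(ranks)
  r1 <- cats[cats$year == 1993, ]                        # rank 1: failure
  expect_equal(c(r1$failure, r1$moderate, r1$full), c(1, 0, 0))
  expect_error(mast_categories(data.frame(region = "A", year = 1,
                                          rank = 5)), "0, 4")
})

test_that("standardization gives SD 0.5 for continuous, centering for binary", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$values, c(-0.5, 0, 0.5))
  x <- rnorm(50)
  expect_equal(sd(standardize(x)$values), 0.5)
  b <- standardize(c(0, 0, 0, 1), binary = TRUE)
  expect_equal(b$values, c(-0.25, -0.25, -0.25, 0.75))
  expect_error(standardize(rep(2, 5)), "zero-variance")
})

test_that("standardization is invertible: raw slope = std slope / (2 sd)", {
  set.seed(1)
  d <- data.frame(x = rnorm(40, 10, 3))
  d$y <- 2 + 0.7 * d$x + rnorm(40, 0, 0.1)
  raw <- coef(lm(y ~ x, d))["x"]
  rec <- standardize(d$x)
  d$xs <- rec$values
  std <- coef(lm(y ~ xs, d))["xs"]
  expect_equal(unname(unstandardize_slope(std, rec)), unname(raw),
               tolerance = 1e-10)
})

test_that("dressed masses convert by zone factor, live masses pass through", {
  expect_equal(dressed_to_live(80, "central", TRUE), 100)
  expect_equal(dressed_to_live(80, "eastern", TRUE), 92)
  expect_equal(dressed_to_live(80, "central", FALSE), 80)
  expect_error(dressed_to_live(80, "western", TRUE), "unknown zone")
  expect_error(dressed_to_live(-1, "central", TRUE), "positive")
})

test_that("growth-table accounting balances candidates, rows and exclusions", {
  gt <- small_growth()
  expect_equal(gt$n_candidates, nrow(gt$growth) + nrow(gt$exclusions))
  # per region too
  b <- small_europe_bundle()
  cand <- table(b$bags$region) - 1
  got <- table(factor(gt$growth$region, levels = names(cand))) +
    table(factor(gt$exclusions$region, levels = names(cand)))
  expect_equal(as.vector(got), as.vector(cand))
})

test_that("observed growth rates equal generated ones up to bag rounding", {
  cfg <- generator_config(n_regions = 4, n_countries = 2,
                          years = c(1980, 1995), density_init = 20,
                          area_km2 = 5000, seed = 15)
  bags <- simulate_population(cfg, simulate_climate(cfg))
  lat <- attr(bags, "latent")
  lam <- compute_lambda(bags)$lambda
  m <- merge(lam, lat[c("region", "year", "lambda")], by = c("region", "year"))
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m$lambda.x - m$lambda.y)), 1e-4)
})
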