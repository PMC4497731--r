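# synthetic-data generator: determinism, degenerate noise, ground-truth
# structure of the simulated climate, population, mast, accident and
# body-mass series

test_that("all generator components are deterministic under a fixed seed", {
  cfg <- generator_config(n_regions = 4, n_countries = 2,
                          years = c(1980, 1995), seed = 31)
  expect_identical(simulate_climate(cfg), simulate_climate(cfg))
  expect_identical(simulate_mast(cfg), simulate_mast(cfg))
  cl <- simulate_climate(cfg)
  expect_identical(simulate_population(cfg, cl),
                   simulate_population(cfg, cl))
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$bags, b2$bags)
  expect_identical(b1$accidents, b2$accidents)
})

test_that("zero annual anomaly makes every winter equal the long-term mean", {
  cfg <- generator_config(n_regions = 3, n_countries = 1,
                          years = c(1980, 1995), annual_temp_sd = 0,
                          longterm_winter_range = c(-3, 3), seed = 5)
  cl <- simulate_climate(cfg)
  st <- boargrowth:::season_table(cl)
  st <- st[!is.na(st$winter_t), ]
  for (r in unique(st$region)) {
    w <- st$winter_t[st$region == r]
    expect_equal(max(w) - min(w), 0, tolerance = 1e-12)
  }
  # the three regions span the configured range
  lt <- longterm_mean(cl, "winter_t")
  expect_equal(unname(max(lt) - min(lt)), 6, tolerance = 1e-9)
})

test_that("long-term winter means across regions reproduce the configured range", {
  cfg <- generator_config(n_regions = 2, n_countries = 1,
                          years = c(1980, 1995),
                          longterm_winter_range = c(-4, 4), seed = 8)
  cl <- simulate_climate(cfg)
  lt <- longterm_mean(cl, "winter_t")   # day-weighted, via the pipeline
  # empirical 30-year means differ by 8 up to sampling error of the annual
  # anomalies (sd 1.5 / sqrt(30) per region mean)
  expect_equal(unname(diff(lt)), 8, tolerance = 4 * 1.5 / sqrt(30) * sqrt(2))
})

test_that("null coefficients and zero noise give constant bags and lambda 1", {
  cfg <- generator_config(n_regions = 3, n_countries = 1,
                          years = c(1980, 1995), coefficients = c(winter_t = 0),
                          region_sd = 0, country_sd = 0, residual_sd = 1e-9,
                          base_lambda = 1, seed = 4)
  bags <- simulate_population(cfg, simulate_climate(cfg))
  lat <- attr(bags, "latent")
  expect_true(all(abs(lat$lambda - 1) < 1e-6))
  for (r in unique(bags$region)) {
    expect_true(max(bags$bag[bags$region == r]) -
                  min(bags$bag[bags$region == r]) <= 1)  # rounding only
  }
})

test_that("a positive winter coefficient raises lambda in warm winters", {
  cfg <- generator_config(n_regions = 2, n_countries = 1,
                          years = c(1975, 2010),
                          coefficients = c(winter_t = 0.4),
                          residual_sd = 0.1, seed = 12)
  bags <- simulate_population(cfg, simulate_climate(cfg))
  lat <- attr(bags, "latent")
  slope <- coef(lm(lambda ~ winter_t, lat))["winter_t"]
  expect_gt(slope, 0)
})

test_that("unrecognized coefficient names are rejected with the valid list", {
  expect_error(generator_config(coefficients = c(warmth = 0.1)),
               "unrecognized term")
  expect_error(generator_config(coefficients = c(0.1)), "named")
})

test_that("generator invariants hold: bags non-negative, ranks in 0..4, climate complete", {
  b <- small_europe_bundle()
  expect_true(all(b$bags$bag >= 0))
  expect_true(all(b$mast$rank %in% 0:4))
  # every (region, year) in bags has complete monthly climate
  need <- expand.grid(region = unique(b$bags$region),
                      year = seq(min(b$bags$year) - 1, max(b$bags$year)),
                      month = 1:12)
  key <- paste(b$climate$region, b$climate$year, b$climate$month)
  expect_true(all(paste(need$region, need$year, need$month) %in% key))
})

test_that("latent residuals match the configured residual SD", {
  cfg <- generator_config(n_regions = 56, n_countries = 8,
                          years = c(1970, 2012), seed = 90)
  bags <- simulate_population(cfg, simulate_climate(cfg))
  lat <- attr(bags, "latent")         # > 2000 rows
  expect_gt(nrow(lat), 2000)
  co <- cfg$coefficients
  eta <- cfg$base_lambda + lat$u_country + lat$u_region +
    co[["winter_t"]] * lat$winter_t +
    co[["lt_winter_t"]] * lat$lt_winter_t +
    co[["prior_autumn_t"]] * lat$prior_autumn_t +
    co[["density5"]] * lat$density5_z +
    co[["summer_t"]] * lat$summer_t +
    co[["lt_winter_t:winter_t"]] * lat$winter_t * lat$lt_winter_t
  res <- lat$lambda - eta
  keep <- lat$lambda > 0.05            # floored rows deviate by construction
  expect_lt(abs(sd(res[keep]) / cfg$residual_sd - 1), 0.10)
})

test_that("mast trend shapes decade frequencies and a null trend is flat", {
  cfg0 <- generator_config(n_regions = 40, n_countries = 4,
                           years = c(1976, 2013), mast_trend = 0, seed = 3)
  m0 <- simulate_mast(cfg0)
  high <- m0$rank >= 3
  first <- m0$year <= 1985; last <- m0$year >= 2004
  p1 <- mean(high[first]); p2 <- mean(high[last])
  se <- sqrt(0.3 * 0.7 * (1 / sum(first) + 1 / sum(last)))
  expect_lt(abs(p2 - p1), 4 * se)
  cfgT <- generator_config(n_regions = 40, n_countries = 4,
                           years = c(1976, 2013), mast_trend = 0.1, seed = 3)
  mT <- simulate_mast(cfgT)
  highT <- mT$rank >= 3
  expect_gt(mean(highT[mT$year >= 2004]), mean(highT[mT$year <= 1985]))
})

test_that("noise-free accidents track bags exactly; moderate noise stays strong", {
  b <- small_europe_bundle()
  acc0 <- simulate_accidents(b$bags, noise_sd = 0, seed = 1)
  nat <- national_totals(b$bags)
  m <- merge(nat, acc0, by = c("country", "year"))
  for (ctry in unique(m$country)) {
    d <- m[m$country == ctry, ]
    expect_equal(cor(d$bag, d$accidents / d$vehicles), 1, tolerance = 1e-12)
  }
  accN <- simulate_accidents(b$bags, noise_sd = 0.1, seed = 1)
  rep <- validate_bags(nat, accN)
  expect_true(all(rep$r_level > 0.9))
})

test_that("noise-free body masses lie exactly on the configured cline", {
  cfg <- generator_config(seed = 2)
  bm <- simulate_bodymass(cfg, slope = -3.9, sex_offset = 25.7, noise_sd = 0)
  f <- bm[bm$sex == "F", ]
  fit <- lm(mass_kg ~ longterm_winter_c, f)
  expect_equal(unname(coef(fit)["longterm_winter_c"]), -3.9, tolerance = 1e-10)
  # male - female at fixed temperature equals the sex offset
  m <- bm[bm$sex == "M", ]
  expect_equal(unique(round(m$mass_kg - f$mass_kg, 10)), 25.7)
})

test_that("written bundles round-trip through the delimited schemas", {
  b <- small_europe_bundle()
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  tabs <- read_input_tables(dir)
  expect_equal(tabs$bags$bag, b$bags$bag)
  expect_equal(tabs$climate$tmean_c, b$climate$tmean_c, tolerance = 1e-12)
  expect_equal(tabs$mast$rank, b$mast$rank)
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$seed, b$truth$seed)
  expect_equal(truth$coefficients$winter_t,
               unname(b$truth$coefficients["winter_t"]))
  unlink(dir, recursive = TRUE)
})
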