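# synthetic-data generator: region-structured hunting-bag, climate, mast,
# accident, crop and body-mass series with known ground-truth parameters, so
# every downstream stage has a parameter-recovery test

#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions under which region-structured series are
#' simulated. Growth rates follow
#' `lambda = base_lambda + sum_k beta_k x_k + u_country + u_region + eps`,
#' with the predictors `x_k` standardized internally exactly as the pipeline
#' standardizes them (continuous: SD 0.5; binary mast: centered), so that
#' generating and recovered coefficients are directly comparable.
#'
#' @param n_regions number of regions (>= 2).
#' @param n_countries number of countries; regions are assigned round-robin.
#' @param years inclusive range of hunting-bag years. The first five years
#'   are burn-in for the 5-year density proxy; analysis census years run from
#'   `years[1] + 5` to `years[2]` (the span must therefore be >= 8 years).
#' @param longterm_winter_range range (degrees C) across regions of the
#'   long-term mean winter temperature.
#' @param annual_temp_sd SD (degrees C) of the i.i.d. monthly temperature
#'   anomalies that drive inter-annual variability; a seasonal (3-month)
#'   mean then varies between years with SD about `annual_temp_sd / sqrt(3)`,
#'   and seasonal predictors of the same year are uncorrelated, as in
#'   observed European series.
#' @param seasonal_amplitude amplitude (degrees C) of the within-year
#'   temperature cycle; per-region continentality noise
#'   (`amplitude_sd`) decorrelates long-term summer from long-term winter
#'   temperature.
#' @param amplitude_sd SD of the per-region seasonal amplitude.
#' @param coefficients named vector of generating coefficients on the
#'   standardized scale; names must come from the model vocabulary (mains or
#'   `"a:b"` interactions).
#' @param region_sd,country_sd SDs of the nested random intercepts on the
#'   lambda scale.
#' @param residual_sd residual SD of lambda (> 0).
#' @param base_lambda baseline growth rate (intercept).
#' @param mast_base_prob probability of moderate-or-full mast
#'   (rank >= 3) at the reference (middle) year; must be < 0.55 so the
#'   cumulative-logit cutpoints stay ordered.
#' @param mast_trend per-year log-odds increment of mast probability.
#' @param mast_ref_year anchor year at which `mast_base_prob` holds
#'   (default 1976, the first year of the Austrian mast records).
#' @param density_init initial hunting-bag density (animals shot per km^2).
#' @param area_km2 region area (km^2), recycled over regions.
#' @param longterm_window year window of the long-term climate means; climate
#'   is generated to cover it even when the bag years do not.
#' @param seed integer seed governing the whole bundle; per-component
#'   sub-streams are derived deterministically.
#' @return object of class `"generator_config"`.
#' @export
generator_config <- function(n_regions = 60, n_countries = 12,
                             years = c(1972, 2012),
                             longterm_winter_range = c(-4, 4),
                             annual_temp_sd = 2.5,
                             seasonal_amplitude = 9, amplitude_sd = 2,
                             coefficients = c(
                               winter_t = 0.180, lt_winter_t = -0.252,
                               prior_autumn_t = 0.179, density5 = -0.065,
                               summer_t = -0.050,
                               "lt_winter_t:winter_t" = -0.059),
                             region_sd = 0.02, country_sd = 0.01,
                             residual_sd = 0.30, base_lambda = 1.05,
                             mast_base_prob = 0.30, mast_trend = 0.054,
                             mast_ref_year = 1976,
                             density_init = 2.0, area_km2 = 1000,
                             longterm_window = c(1973, 2002), seed = 1) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_countries = as.integer(n_countries),
              years = as.integer(years),
              longterm_winter_range = longterm_winter_range,
              annual_temp_sd = annual_temp_sd,
              seasonal_amplitude = seasonal_amplitude,
              amplitude_sd = amplitude_sd,
              coefficients = coefficients,
              region_sd = region_sd, country_sd = country_sd,
              residual_sd = residual_sd, base_lambda = base_lambda,
              mast_base_prob = mast_base_prob, mast_trend = mast_trend,
              mast_ref_year = as.integer(mast_ref_year),
              density_init = density_init, area_km2 = area_km2,
              longterm_window = as.integer(longterm_window),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_regions < 2) stop("n_regions must be >= 2")
  if (cfg$n_countries < 1 || cfg$n_countries > cfg$n_regions) {
    stop("n_countries must be between 1 and n_regions")
  }
  if (diff(cfg$years) < 8) {
    stop("the year span must cover at least 8 years (5 burn-in years for ",
         "the density proxy plus growth-rate formation)")
  }
  if (cfg$residual_sd <= 0) stop("residual_sd must be positive")
  if (cfg$mast_base_prob <= 0 || cfg$mast_base_prob >= 0.55) {
    stop("mast_base_prob must lie in (0, 0.55)")
  }
  if (cfg$density_init <= 0.01) {
    stop("density_init must exceed the 0.01 animals/km^2 exclusion threshold")
  }
  if (length(cfg$coefficients) > 0) {
    if (is.null(names(cfg$coefficients)) || any(names(cfg$coefficients) == "")) {
      stop("coefficients must be a named vector")
    }
    check_term_names(names(cfg$coefficients))
  }
  invisible(cfg)
}

# region/country labels shared by all components
region_frame <- function(cfg) {
  data.frame(
    region = sprintf("R%02d", seq_len(cfg$n_regions)),
    country = sprintf("C%02d", rep_len(seq_len(cfg$n_countries),
                                       cfg$n_regions)),
    area_km2 = rep_len(cfg$area_km2, cfg$n_regions),
    stringsAsFactors = FALSE
  )
}

# years for which monthly climate must exist: one year before the first bag
# year (winter straddles the boundary) through the end, plus the long-term
# window
climate_years <- function(cfg) {
  seq(min(cfg$years[1], cfg$longterm_window[1]) - 1,
      max(cfg$years[2], cfg$longterm_window[2]))
}

#' Simulate monthly climate series
#'
#' Monthly mean temperature is the sum of a region-specific level (long-term
#' winter means spread evenly over `longterm_winter_range`), a smooth
#' seasonal cycle that is flat over December-February (so a region's
#' deterministic winter mean equals its long-term winter level exactly, leap
#' years included) and i.i.d. monthly anomalies. Because the four seasons
#' share no months, the seasonal means of a year are mutually independent
#' given the region, mirroring the weak observed coupling between seasonal
#' anomalies. Monthly precipitation is positive gamma noise, uncorrelated
#' with the growth-rate process.
#'
#' @param cfg a [generator_config()].
#' @return climate table (`region`, `year`, `month`, `tmean_c`, `precip_mm`).
#' @export
simulate_climate <- function(cfg) {
  validate_generator_config(cfg)
  if (diff(cfg$years) + 1 < 1) stop("empty year range")
  set.seed(component_seed(cfg$seed, "climate"))
  rf <- region_frame(cfg)
  yrs <- climate_years(cfg)
  w_r <- seq(cfg$longterm_winter_range[1], cfg$longterm_winter_range[2],
             length.out = cfg$n_regions)
  amp_r <- cfg$seasonal_amplitude + rnorm(cfg$n_regions, 0, cfg$amplitude_sd)
  # clipped cosine: zero over Dec-Feb, peaking in July
  cyc <- pmax(0, cos(2 * pi * ((1:12) - 7) / 12) + cos(2 * pi * 5 / 12) * -1)
  grid <- expand.grid(month = 1:12, year = yrs, region = rf$region,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ri <- match(grid$region, rf$region)
  grid$tmean_c <- w_r[ri] + amp_r[ri] * cyc[grid$month] +
    rnorm(nrow(grid), 0, cfg$annual_temp_sd)
  # regional precipitation level, mild summer peak
  p_r <- runif(cfg$n_regions, 50, 110)
  mu <- p_r[ri] * (1 + 0.3 * cyc[grid$month] / max(cyc))
  grid$precip_mm <- rgamma(nrow(grid), shape = 4, rate = 4 / mu)
  grid[c("region", "year", "month", "tmean_c", "precip_mm")]
}

#' Simulate beech-mast rank series
#'
#' Ranks 0-4 are drawn from a cumulative-logit (proportional-odds) model with
#' a common per-year log-odds trend, so that the binary mast indicator
#' (rank >= 3), the failure indicator (rank <= 1) and the full-mast
#' indicator (rank 4) are each exactly logistic in year with slope
#' `+/- mast_trend`. Regions are independent given the year.
#'
#' @param cfg a [generator_config()].
#' @param years optional year range (default: one year before the first bag
#'   year through the last bag year).
#' @return rank table (`region`, `year`, `rank`).
#' @export
simulate_mast <- function(cfg, years = NULL) {
  validate_generator_config(cfg)
  set.seed(component_seed(cfg$seed, "mast"))
  rf <- region_frame(cfg)
  yrs <- if (is.null(years)) seq(cfg$years[1] - 1, cfg$years[2]) else
    seq(years[1], years[2])
  ref <- cfg$mast_ref_year
  # cutpoints at the reference year: P(rank >= k), k = 1..4
  p_ref <- c(0.85, 0.55, cfg$mast_base_prob, cfg$mast_base_prob / 2.5)
  alpha <- qlogis(p_ref)
  grid <- expand.grid(region = rf$region, year = yrs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u <- runif(nrow(grid))
  yc <- grid$year - ref
  rank <- integer(nrow(grid))
  for (k in 1:4) {
    rank <- rank + as.integer(u < plogis(alpha[k] + cfg$mast_trend * yc))
  }
  grid$rank <- rank
  grid[order(grid$region, grid$year), c("region", "year", "rank")]
}

#' Simulate crop-area series
#'
#' Slowly drifting percentages of region area under corn and potato
#' cultivation; by default they do not enter the growth-rate process (null
#' covariates for the Austrian food-availability model).
#'
#' @param cfg a [generator_config()].
#' @return table (`region`, `year`, `crop_corn`, `crop_potato`).
#' @export
simulate_crops <- function(cfg) {
  validate_generator_config(cfg)
  set.seed(component_seed(cfg$seed, "crops"))
  rf <- region_frame(cfg)
  yrs <- seq(cfg$years[1] - 1, cfg$years[2])
  grid <- expand.grid(region = rf$region, year = yrs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ri <- match(grid$region, rf$region)
  base_c <- runif(cfg$n_regions, 5, 15)
  base_p <- runif(cfg$n_regions, 1, 5)
  t <- grid$year - yrs[1]
  grid$crop_corn <- pmin(pmax(base_c[ri] + 0.08 * t +
                                rnorm(nrow(grid), 0, 0.5), 0), 40)
  grid$crop_potato <- pmin(pmax(base_p[ri] - 0.02 * t +
                                  rnorm(nrow(grid), 0, 0.25), 0), 20)
  grid[order(grid$region, grid$year), ]
}

#' Simulate hunting-bag series from the growth-rate model
#'
#' Builds the standardized predictors for all analysis census years by
#' running the generated climate (and mast/crop) tables through the same
#' preprocessing code the pipeline uses, forms
#' `lambda = base_lambda + sum beta_k x_k + u_country + u_region + eps`
#' (floored at 0.05), and updates bags multiplicatively,
#' `bag_t = round(bag_(t-1) * lambda_t)`. Because the 5-year density proxy
#' depends on the bags being generated, its standardization is calibrated by
#' a short fixed-point iteration with common random numbers.
#'
#' @param cfg a [generator_config()].
#' @param climate climate table from [simulate_climate()].
#' @param mast optional rank table (required when the coefficients involve
#'   `mast_prev`).
#' @param crops optional crop table (required for `crop_*` coefficients).
#' @return hunting-bag table (`country`, `region`, `year`, `bag`,
#'   `area_km2`) with attribute `"latent"`: one row per analysis census year
#'   carrying the true lambda, the standardized predictors and the random
#'   intercepts, and attribute `"density_scaling"` (center/scale used for the
#'   density term).
#' @export
simulate_population <- function(cfg, climate, mast = NULL, crops = NULL) {
  validate_generator_config(cfg)
  beta <- cfg$coefficients
  if (length(beta) > 0) names(beta) <- canonical_terms(names(beta))
  mains <- unique(unlist(strsplit(names(beta), ":", fixed = TRUE)))
  if (any(grepl("mast_prev", mains)) && is.null(mast)) {
    stop("coefficients involve mast_prev but no mast table was supplied")
  }
  if (any(grepl("^crop_", mains)) && is.null(crops)) {
    stop("coefficients involve crop terms but no crop table was supplied")
  }

  rf <- region_frame(cfg)
  y0 <- cfg$years[1]; y1 <- cfg$years[2]
  ay <- seq(y0 + 5, y1)                       # analysis census years
  if (max(climate$year) < y1 || min(climate$year) > y0 - 1) {
    stop("climate table does not cover the hunting-bag years")
  }

  # predictor table over analysis rows, via the pipeline's own aggregation
  st <- season_table(climate)
  key_st <- paste(st$region, st$year)
  X <- expand.grid(region = rf$region, year = ay,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cur <- match(paste(X$region, X$year), key_st)
  prv <- match(paste(X$region, X$year - 1), key_st)
  X$winter_t <- st$winter_t[cur]
  X$spring_t <- st$spring_t[cur]
  X$summer_t <- st$summer_t[cur]
  X$prior_spring_t <- st$spring_t[prv]
  X$prior_summer_t <- st$summer_t[prv]
  X$prior_autumn_t <- st$autumn_t[prv]
  lt <- function(v) {
    vals <- longterm_mean(climate, v, cfg$longterm_window)
    unname(vals[as.character(X$region)])
  }
  X$lt_winter_t <- lt("winter_t")
  X$lt_summer_t <- lt("summer_t")
  X$lt_summer_precip <- lt("summer_p")
  X$lt_yearly_precip <- lt("yearly_p")
  if (!is.null(mast)) {
    cats <- mast_categories(mast)
    X$mast_prev <- cats$mast_binary[match(paste(X$region, X$year - 1),
                                          paste(cats$region, cats$year))]
    if (anyNA(X$mast_prev)) stop("mast table does not cover all prior years")
  }
  if (!is.null(crops)) {
    idx <- match(paste(X$region, X$year - 1),
                 paste(crops$region, crops$year))
    X$crop_corn <- crops$crop_corn[idx]
    X$crop_potato <- crops$crop_potato[idx]
    if (anyNA(X$crop_corn)) stop("crop table does not cover all prior years")
  }

  # standardize every non-density main exactly as the pipeline will
  for (v in setdiff(mains, "density5")) {
    X[[v]] <- standardize(X[[v]], binary = (v == "mast_prev"))$values
  }

  set.seed(component_seed(cfg$seed, "population"))
  u_country <- setNames(rnorm(cfg$n_countries, 0, cfg$country_sd),
                        sprintf("C%02d", seq_len(cfg$n_countries)))
  u_region <- setNames(rnorm(cfg$n_regions, 0, cfg$region_sd), rf$region)
  n_years_all <- y1 - y0                       # census years y0+1 .. y1
  eps <- matrix(rnorm(cfg$n_regions * n_years_all, 0, cfg$residual_sd),
                nrow = cfg$n_regions,
                dimnames = list(rf$region, as.character(seq(y0 + 1, y1))))

  # fixed-effect part excluding the density term
  ri <- match(X$region, rf$region)
  eta0 <- rep(0, nrow(X))
  for (tr in names(beta)) {
    if ("density5" %in% interaction_parents(tr)) next
    parents <- interaction_parents(tr)
    xv <- Reduce(`*`, lapply(parents, function(p) X[[p]]))
    eta0 <- eta0 + beta[[tr]] * xv
  }
  dens_terms <- names(beta)[vapply(names(beta), function(tr)
    "density5" %in% interaction_parents(tr), logical(1))]

  run_once <- function(d_center, d_scale, use_density) {
    bags <- matrix(NA_real_, nrow = cfg$n_regions, ncol = y1 - y0 + 1,
                   dimnames = list(rf$region, as.character(y0:y1)))
    lam_store <- matrix(NA_real_, nrow = cfg$n_regions, ncol = length(ay),
                        dimnames = list(rf$region, as.character(ay)))
    dens_store <- lam_store
    bags[, 1] <- round(cfg$density_init * rf$area_km2)
    for (y in seq(y0 + 1, y1)) {
      j <- y - y0 + 1
      lam <- cfg$base_lambda + u_country[rf$country] + u_region +
        eps[, as.character(y)]
      if (y >= y0 + 5) {
        rows <- match(paste(rf$region, y), paste(X$region, X$year))
        lam <- lam + eta0[rows]
        d5 <- rowMeans(bags[, (j - 5):(j - 1), drop = FALSE] / rf$area_km2)
        if (use_density && length(dens_terms) > 0) {
          zd <- (d5 - d_center) / d_scale
          for (tr in dens_terms) {
            others <- setdiff(interaction_parents(tr), "density5")
            xv <- zd
            for (p in others) xv <- xv * X[[p]][rows]
            lam <- lam + beta[[tr]] * xv
          }
        }
        lam_store[, as.character(y)] <- pmax(lam, 0.05)
        dens_store[, as.character(y)] <- d5
        lam <- lam_store[, as.character(y)]
      } else {
        lam <- pmax(lam, 0.05)
      }
      bags[, j] <- round(bags[, j - 1] * lam)
    }
    list(bags = bags, lambda = lam_store, density = dens_store)
  }

  if (length(dens_terms) > 0) {
    # the density predictor must be standardized by the moments of the very
    # densities being generated; iterate the deterministic map (common
    # random numbers) to its fixed point so the generator's scaling agrees
    # with what the pipeline will recompute from the realized data
    r <- run_once(0, 1, use_density = FALSE)
    d_center <- NA_real_; d_scale <- NA_real_
    for (pass in 1:25) {
      d <- as.vector(r$density)
      if (pass > 1 && abs(2 * sd(d) / d_scale - 1) < 0.005 &&
          abs(mean(d) - d_center) < 0.005 * d_scale) break
      d_center <- mean(d); d_scale <- 2 * sd(d)
      r <- run_once(d_center, d_scale, use_density = TRUE)
    }
  } else {
    r <- run_once(0, 1, use_density = FALSE)
    d_center <- NA_real_; d_scale <- NA_real_
  }

  bags_long <- expand.grid(region = rf$region, year = y0:y1,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bags_long$country <- rf$country[match(bags_long$region, rf$region)]
  bags_long$area_km2 <- rf$area_km2[match(bags_long$region, rf$region)]
  bags_long$bag <- r$bags[cbind(match(bags_long$region, rf$region),
                                bags_long$year - y0 + 1)]
  bags_long <- bags_long[order(bags_long$region, bags_long$year),
                         c("country", "region", "year", "bag", "area_km2")]
  rownames(bags_long) <- NULL

  latent <- X
  latent$country <- rf$country[ri]
  latent$u_country <- unname(u_country[latent$country])
  latent$u_region <- unname(u_region[latent$region])
  latent$lambda <- r$lambda[cbind(ri, match(X$year, ay))]
  if (length(dens_terms) > 0) {
    latent$density5_z <- (r$density[cbind(ri, match(X$year, ay))] - d_center) /
      d_scale
  }
  attr(bags_long, "latent") <- latent
  attr(bags_long, "density_scaling") <- c(center = d_center, scale = d_scale)
  bags_long
}

#' Simulate wild-boar traffic-accident counts
#'
#' National accident counts proportional to the national hunting-bag total
#' and to the (geometrically growing) vehicle stock, with multiplicative
#' lognormal observation noise.
#'
#' @param bags hunting-bag table (`country`, `region`, `year`, `bag`).
#' @param detectability accidents per shot animal per registered vehicle
#'   share (> 0).
#' @param noise_sd SD of the lognormal observation noise (0 = noise-free).
#' @param vehicle_growth annual geometric growth rate of registered vehicles.
#' @param vehicles0 vehicle stock in the first year.
#' @param seed integer seed.
#' @return accident table (`country`, `year`, `accidents`, `vehicles`).
#' @export
simulate_accidents <- function(bags, detectability = 0.002, noise_sd = 0.1,
                               vehicle_growth = 0.03, vehicles0 = 2e6,
                               seed = 1) {
  if (detectability <= 0) stop("detectability must be positive")
  set.seed(component_seed(seed, "accidents"))
  nat <- aggregate(bag ~ country + year, data = bags, FUN = sum)
  nat <- nat[order(nat$country, nat$year), ]
  y0 <- min(nat$year)
  nat$vehicles <- vehicles0 * (1 + vehicle_growth)^(nat$year - y0)
  noise <- exp(rnorm(nrow(nat), 0, noise_sd))
  nat$accidents <- detectability * nat$bag * (nat$vehicles / vehicles0) * noise
  rownames(nat) <- NULL
  nat[c("country", "year", "accidents", "vehicles")]
}

#' Simulate the body-mass cline
#'
#' Adult body mass as a linear function of the regional long-term winter
#' temperature with a sex offset:
#' `mass = baseline + slope * lt_winter + sex_offset * male + noise`.
#'
#' @param cfg a [generator_config()]; supplies the winter-temperature range
#'   and the seed.
#' @param slope kg per degree C (default -3.9).
#' @param sex_offset male-minus-female offset in kg (default 25.7).
#' @param noise_sd residual SD in kg (default 0: exact cline).
#' @param n_regions number of body-mass regions (>= 5; default 22).
#' @param baseline female mass at 0 degrees C long-term winter temperature.
#' @return table (`region`, `sex`, `mass_kg`, `dressed`, `zone`,
#'   `longterm_winter_c`), one male and one female record per region.
#' @export
simulate_bodymass <- function(cfg, slope = -3.9, sex_offset = 25.7,
                              noise_sd = 0, n_regions = 22, baseline = 75) {
  validate_generator_config(cfg)
  if (n_regions < 5) stop("at least 5 regions are needed for a meaningful fit")
  set.seed(component_seed(cfg$seed, "bodymass"))
  ltw <- seq(cfg$longterm_winter_range[1], cfg$longterm_winter_range[2],
             length.out = n_regions)
  out <- data.frame(
    region = rep(sprintf("BM%02d", seq_len(n_regions)), each = 2),
    sex = rep(c("F", "M"), n_regions),
    longterm_winter_c = rep(ltw, each = 2),
    stringsAsFactors = FALSE
  )
  out$mass_kg <- baseline + slope * out$longterm_winter_c +
    sex_offset * (out$sex == "M") + rnorm(nrow(out), 0, noise_sd)
  out$dressed <- FALSE
  out$zone <- "central"
  out[c("region", "sex", "mass_kg", "dressed", "zone", "longterm_winter_c")]
}

#' Simulate a complete synthetic bundle
#'
#' Generates climate, mast, crops, hunting bags, traffic accidents and body
#' masses under one seed, with deterministic per-component sub-streams.
#'
#' @param cfg a [generator_config()].
#' @param accidents_args,bodymass_args optional argument lists forwarded to
#'   [simulate_accidents()] / [simulate_bodymass()].
#' @return object of class `"boar_bundle"`: list with `bags`, `climate`,
#'   `mast`, `crops`, `accidents`, `bodymass`, `latent` (ground-truth rows)
#'   and `truth` (the configuration).
#' @export
simulate_bundle <- function(cfg, accidents_args = list(),
                            bodymass_args = list()) {
  validate_generator_config(cfg)
  climate <- simulate_climate(cfg)
  mast <- simulate_mast(cfg)
  crops <- simulate_crops(cfg)
  bags <- simulate_population(cfg, climate, mast = mast, crops = crops)
  accidents <- do.call(simulate_accidents,
                       c(list(bags = bags, seed = cfg$seed), accidents_args))
  bodymass <- do.call(simulate_bodymass, c(list(cfg = cfg), bodymass_args))
  out <- list(bags = bags, climate = climate, mast = mast, crops = crops,
              accidents = accidents, bodymass = bodymass,
              latent = attr(bags, "latent"), truth = cfg)
  attr(out$bags, "latent") <- NULL
  class(out) <- "boar_bundle"
  out
}

#' Write a synthetic bundle as delimited text tables
#'
#' Writes `bags.csv`, `climate.csv`, `mast.csv`, `crops.csv`,
#' `accidents.csv`, `bodymass.csv` (the input schemas of the preprocessing
#' module) plus `truth.yaml` echoing the generator configuration.
#'
#' @param bundle a `"boar_bundle"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "boar_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("bags", "climate", "mast", "crops", "accidents", "bodymass")) {
    write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  truth <- unclass(bundle$truth)
  truth$coefficients <- as.list(truth$coefficients)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
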