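# preprocessing: lambda construction with exclusion rules, day-weighted
# seasonal climate aggregation, long-term means, density proxy, mast coding,
# two-SD standardization, dressed-to-live mass conversion

# season windows relative to a census year t; winter straddles the year
# boundary and is assigned to the census year of its January/February
.season_defs <- list(
  winter = data.frame(month = c(12L, 1L, 2L), offset = c(-1L, 0L, 0L)),
  spring = data.frame(month = 3:5, offset = 0L),
  summer = data.frame(month = 6:8, offset = 0L),
  autumn = data.frame(month = 9:11, offset = 0L)
)

.climate_key <- function(region, year, month) paste(region, year, month, sep = "\r")

#' Annual population growth rates from hunting-bag series
#'
#' Computes lambda = bag_t / bag_(t-1) per region after removing bag-years
#' with fewer than `min_density` animals shot per square kilometre. A removed
#' bag-year invalidates both the growth rate that would use it as numerator
#' and the one that would use it as denominator. Growth rates are only formed
#' across consecutive calendar years.
#'
#' @param series data frame with columns `country`, `region`, `year`, `bag`,
#'   `area_km2` (one row per region-year).
#' @param min_density exclusion threshold in animals shot per km^2
#'   (default 0.01).
#' @return list with `lambda`: data frame (`country`, `region`, `year`,
#'   `lambda`, `bag`, `bag_prev`, `area_km2`) where `year` is the census year,
#'   and `exclusions`: data frame (`region`, `year`, `rule`) logging every
#'   candidate census year that could not be formed.
#' @export
compute_lambda <- function(series, min_density = 0.01) {
  stopifnot(all(c("region", "year", "bag", "area_km2") %in% names(series)))
  if (any(series$bag < 0)) stop("negative hunting bags are invalid")
  if (any(series$area_km2 <= 0)) stop("region areas must be positive")
  if (anyDuplicated(series[c("region", "year")])) {
    stop("duplicate (region, year) rows in hunting-bag series")
  }
  if (!"country" %in% names(series)) series$country <- NA_character_
  series <- series[order(series$region, series$year), , drop = FALSE]
  series$density <- series$bag / series$area_km2
  series$kept <- series$density >= min_density

  out <- vector("list", length(unique(series$region)))
  excl <- vector("list", length(out))
  for (i in seq_along(out)) {
    reg <- unique(series$region)[i]
    s <- series[series$region == reg, , drop = FALSE]
    if (nrow(s) < 2) next
    cand <- s$year[-1]                      # candidate census years
    prev_in <- (cand - 1L) %in% s$year
    kept_t <- s$kept[match(cand, s$year)]
    kept_p <- s$kept[match(cand - 1L, s$year)]
    rule <- rep(NA_character_, length(cand))
    rule[!prev_in] <- "non_consecutive"
    rule[is.na(rule) & !kept_t] <- "low_density"
    rule[is.na(rule) & !kept_p] <- "low_density_prior"
    ok <- is.na(rule)
    bag_t <- s$bag[match(cand, s$year)]
    bag_p <- s$bag[match(cand - 1L, s$year)]
    if (any(ok)) {
      out[[i]] <- data.frame(
        country = s$country[1], region = reg, year = cand[ok],
        lambda = bag_t[ok] / bag_p[ok],
        bag = bag_t[ok], bag_prev = bag_p[ok],
        area_km2 = s$area_km2[1], stringsAsFactors = FALSE
      )
    }
    if (any(!ok)) {
      excl[[i]] <- data.frame(region = reg, year = cand[!ok],
                              rule = rule[!ok], stringsAsFactors = FALSE)
    }
  }
  empty_lambda <- data.frame(
    country = character(), region = character(), year = integer(),
    lambda = numeric(), bag = numeric(), bag_prev = numeric(),
    area_km2 = numeric())
  list(
    lambda = do.call(rbind, out[!vapply(out, is.null, logical(1))]) %||%
      empty_lambda,
    exclusions = do.call(rbind, excl[!vapply(excl, is.null, logical(1))]) %||%
      data.frame(region = character(), year = integer(), rule = character())
  )
}

#' Remove listed census years (e.g. war-affected data points)
#'
#' @param rows growth-rate rows with `region` and `year` (census year).
#' @param exclusion_list data frame with columns `region`, `year`.
#' @return `rows` without the listed census years; the removed rows are
#'   attached as attribute `"exclusion_log"`. List entries matching nothing
#'   raise a warning, not an error.
#' @export
exclude_years <- function(rows, exclusion_list) {
  if (is.null(exclusion_list) || nrow(exclusion_list) == 0) {
    attr(rows, "exclusion_log") <- data.frame(
      region = character(), year = integer(), rule = character())
    return(rows)
  }
  key_rows <- paste(rows$region, rows$year)
  key_list <- paste(exclusion_list$region, exclusion_list$year)
  unmatched <- !(key_list %in% key_rows)
  if (any(unmatched)) {
    warning(sum(unmatched), " exclusion-list entr",
            if (sum(unmatched) == 1) "y" else "ies",
            " matched no data row", call. = FALSE)
  }
  hit <- key_rows %in% key_list
  message(sum(hit), " data point(s) removed by the exclusion list")
  out <- rows[!hit, , drop = FALSE]
  attr(out, "exclusion_log") <- .excl_rows(rows$region[hit], rows$year[hit],
                                           "listed_exclusion")
  out
}

# all seasonal values for every (region, year) on a complete grid; used both
# by the pipeline and by the synthetic generator so the two always agree
season_table <- function(climate) {
  stopifnot(all(c("region", "year", "month", "tmean_c", "precip_mm") %in%
                  names(climate)))
  if (anyDuplicated(climate[c("region", "year", "month")])) {
    stop("duplicate (region, year, month) rows in climate table")
  }
  key <- .climate_key(climate$region, climate$year, climate$month)
  regions <- unique(climate$region)
  years <- seq(min(climate$year), max(climate$year))
  grid <- expand.grid(region = regions, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (season in names(.season_defs)) {
    def <- .season_defs[[season]]
    num_t <- 0; num_p <- 0; den <- 0
    for (j in seq_len(nrow(def))) {
      yy <- grid$year + def$offset[j]
      idx <- match(.climate_key(grid$region, yy, def$month[j]), key)
      w <- days_in_month(def$month[j], yy)
      num_t <- num_t + w * climate$tmean_c[idx]
      num_p <- num_p + climate$precip_mm[idx]
      den <- den + w
    }
    grid[[paste0(season, "_t")]] <- num_t / den
    grid[[paste0(season, "_p")]] <- num_p
  }
  # calendar-year precipitation sum (needs all 12 months)
  yp <- 0
  for (m in 1:12) {
    idx <- match(.climate_key(grid$region, grid$year, m), key)
    yp <- yp + climate$precip_mm[idx]
  }
  grid$yearly_p <- yp
  grid
}

#' Day-weighted seasonal mean temperature
#'
#' Seasonal (3-month) mean temperature, weighted by the number of days per
#' month (29 for February of leap years). Winter of census year t comprises
#' December of t-1 and January/February of t.
#'
#' @param climate climate table (`region`, `year`, `month`, `tmean_c`,
#'   `precip_mm`).
#' @param region region label.
#' @param season one of `"winter"`, `"spring"`, `"summer"`, `"autumn"`.
#' @param census_year calendar year of the census.
#' @return mean temperature in degrees C; `NA` if any of the three months is
#'   missing (the record is then flagged incomplete downstream).
#' @export
seasonal_mean <- function(climate, region, season, census_year) {
  def <- .season_defs[[match.arg(season, names(.season_defs))]]
  key <- .climate_key(climate$region, climate$year, climate$month)
  yy <- census_year + def$offset
  idx <- match(.climate_key(region, yy, def$month), key)
  if (anyNA(idx)) return(NA_real_)
  w <- days_in_month(def$month, yy)
  sum(w * climate$tmean_c[idx]) / sum(w)
}

#' Seasonal precipitation sum
#'
#' Sum of the three monthly precipitation values for the same season windows
#' as [seasonal_mean()].
#'
#' @inheritParams seasonal_mean
#' @return precipitation sum in mm; `NA` if any month is missing.
#' @export
seasonal_precip_sum <- function(climate, region, season, census_year) {
  def <- .season_defs[[match.arg(season, names(.season_defs))]]
  key <- .climate_key(climate$region, climate$year, climate$month)
  yy <- census_year + def$offset
  idx <- match(.climate_key(region, yy, def$month), key)
  if (anyNA(idx)) return(NA_real_)
  sum(climate$precip_mm[idx])
}

#' Long-term (30-year) climate means
#'
#' Mean of the seasonal values (day-weighted temperature means, or seasonal /
#' calendar-year precipitation sums) over a fixed window of years, by default
#' 1973-2002.
#'
#' @param climate climate table.
#' @param variable one of `"winter_t"`, `"summer_t"`, `"spring_t"`,
#'   `"autumn_t"` (temperature), `"winter_p"`, `"spring_p"`, `"summer_p"`,
#'   `"autumn_p"` (seasonal precipitation sums) or `"yearly_p"`
#'   (calendar-year precipitation sum).
#' @param window inclusive year range, default `c(1973, 2002)`.
#' @param region optional region label; if omitted, a named vector over all
#'   regions is returned.
#' @return long-term mean (scalar or named vector). Errors if the window is
#'   not fully covered, naming the missing years.
#' @export
longterm_mean <- function(climate, variable, window = c(1973, 2002),
                          region = NULL) {
  st <- season_table(climate)
  valid <- c("winter_t", "spring_t", "summer_t", "autumn_t",
             "winter_p", "spring_p", "summer_p", "autumn_p", "yearly_p")
  variable <- match.arg(variable, valid)
  st <- st[st$year >= window[1] & st$year <= window[2], , drop = FALSE]
  regions <- if (is.null(region)) unique(st$region) else region
  res <- setNames(numeric(length(regions)), regions)
  for (r in regions) {
    s <- st[st$region == r, , drop = FALSE]
    miss <- setdiff(seq(window[1], window[2]), s$year[!is.na(s[[variable]])])
    if (length(miss) > 0) {
      stop("long-term window ", window[1], "-", window[2],
           " incomplete for region ", r, ": missing year(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    res[[r]] <- mean(s[[variable]])
  }
  if (is.null(region)) res else unname(res[region])
}

#' Five-year density proxy
#'
#' Arithmetic mean of hunting-bag density (animals shot per km^2) over the
#' five years preceding the census year. All five prior years must be present
#' after the low-density filter; otherwise the record is excluded.
#'
#' @param series hunting-bag series after filtering (columns `region`,
#'   `year`, `bag`, `area_km2`).
#' @param region region label.
#' @param census_year census year t; uses years t-5 ... t-1.
#' @return density in animals shot per km^2, or `NA` if any prior year is
#'   missing.
#' @export
density_proxy <- function(series, region, census_year) {
  s <- series[series$region == region, , drop = FALSE]
  idx <- match(census_year - (5:1), s$year)
  if (anyNA(idx)) return(NA_real_)
  mean(s$bag[idx] / s$area_km2[idx])
}

#' Beech-mast coding
#'
#' Averages multiple measurements per region-year and codes (i) the binary
#' mast indicator used as predictor (1 if mean rank >= 3, i.e. pollination
#' >= 70 %) and (ii) the three trend categories: mast failure (rank <= 1),
#' moderate (1 < rank <= 3) and full mast (rank > 3).
#'
#' @param ranks data frame with columns `region`, `year`, `rank`
#'   (rank in \[0, 4\]; multiple rows per region-year are averaged).
#' @return data frame with one row per (region, year): `rank_mean`,
#'   `mast_binary`, `failure`, `moderate`, `full`.
#' @export
mast_categories <- function(ranks) {
  stopifnot(all(c("region", "year", "rank") %in% names(ranks)))
  if (any(ranks$rank < 0 | ranks$rank > 4)) {
    stop("mast ranks must lie in [0, 4]")
  }
  agg <- aggregate(rank ~ region + year, data = ranks, FUN = mean)
  names(agg)[names(agg) == "rank"] <- "rank_mean"
  agg$mast_binary <- as.integer(agg$rank_mean >= 3)
  agg$failure <- as.integer(agg$rank_mean <= 1)
  agg$moderate <- as.integer(agg$rank_mean > 1 & agg$rank_mean <= 3)
  agg$full <- as.integer(agg$rank_mean > 3)
  agg
}

#' Previous-year binary mast for a census year
#'
#' @param ranks rank table as for [mast_categories()].
#' @param census_year census year t; the binary code uses the (averaged) rank
#'   of year t-1.
#' @param region optional region label.
#' @return named list with `mast_prev` (binary) and `category` (the trend
#'   category label of year t-1).
#' @export
code_mast <- function(ranks, census_year, region = NULL) {
  cats <- mast_categories(ranks)
  if (!is.null(region)) cats <- cats[cats$region == region, , drop = FALSE]
  row <- cats[cats$year == census_year - 1, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("no unique mast rank for year ", census_year - 1,
         "; supply a region label or check the rank table")
  }
  lab <- c("failure", "moderate", "full")[which(
    c(row$failure, row$moderate, row$full) == 1)]
  list(mast_prev = row$mast_binary, category = lab)
}

#' Two-standard-deviation standardization
#'
#' Continuous inputs are centered and divided by twice their sample standard
#' deviation (so the result has SD 0.5); binary inputs are centered to mean 0
#' but not rescaled. The transform parameters are recorded so standardized
#' coefficients can be back-converted to the raw scale.
#'
#' @param x numeric vector.
#' @param binary logical; treat `x` as a binary indicator.
#' @return list with `values`, `center`, `scale` (2 * sd, or 1 for binary)
#'   and `binary`.
#' @export
standardize <- function(x, binary = FALSE) {
  if (binary) {
    ctr <- mean(x)
    return(list(values = x - ctr, center = ctr, scale = 1, binary = TRUE))
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a zero-variance variable", call. = FALSE)
  }
  list(values = (x - mean(x)) / (2 * s), center = mean(x), scale = 2 * s,
       binary = FALSE)
}

#' Back-convert a standardized slope to the raw scale
#'
#' For a continuous predictor standardized to SD 0.5 the raw-scale slope is
#' `estimate / (2 * sd)`; binary (centered-only) predictors are unchanged.
#'
#' @param estimate standardized-scale coefficient.
#' @param record a record returned by [standardize()] (or a row of a scaling
#'   table with `scale`).
#' @return raw-scale slope.
#' @export
unstandardize_slope <- function(estimate, record) {
  estimate / record$scale
}

# standardize a set of predictor columns in place; scaling recorded in attr
standardize_predictors <- function(data, cols, binary_cols = "mast_prev") {
  scaling <- data.frame(variable = cols, center = NA_real_, scale = NA_real_,
                        binary = cols %in% binary_cols,
                        stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    rec <- tryCatch(standardize(data[[cols[i]]], binary = scaling$binary[i]),
                    error = function(e) stop("variable '", cols[i], "': ",
                                             conditionMessage(e), call. = FALSE))
    data[[cols[i]]] <- rec$values
    scaling$center[i] <- rec$center
    scaling$scale[i] <- rec$scale
  }
  attr(data, "scaling") <- scaling
  data
}

#' Dressed-to-live body-mass conversion
#'
#' Dressed masses are converted to live mass with the zone factor 1.25
#' (Central Europe) or 1.15 (Eastern Europe); live masses pass through.
#'
#' @param mass_kg positive mass in kg (vectorized).
#' @param zone `"central"` or `"eastern"` (required for dressed records).
#' @param dressed logical; is the record a dressed mass?
#' @return live mass in kg.
#' @export
dressed_to_live <- function(mass_kg, zone, dressed) {
  if (any(mass_kg <= 0)) stop("masses must be positive")
  n <- length(mass_kg)
  zone <- rep_len(as.character(zone), n)
  dressed <- rep_len(as.logical(dressed), n)
  factor <- ifelse(zone == "central", 1.25,
                   ifelse(zone == "eastern", 1.15, NA_real_))
  if (any(dressed & is.na(factor))) {
    stop("unknown zone for a dressed record; use 'central' or 'eastern'")
  }
  ifelse(dressed, mass_kg * factor, mass_kg)
}

.excl_rows <- function(region, year, rule) {
  data.frame(region = as.character(region), year = as.integer(year),
             rule = rep_len(rule, length(region)), stringsAsFactors = FALSE)
}

#' Build the analysis-ready growth table
#'
#' Runs the full preprocessing chain: growth rates with the low-density rule,
#' listed-year exclusions, day-weighted seasonal temperatures and
#' precipitation sums (census year and previous year), long-term climate
#' means, the 5-year density proxy, and (optionally) previous-year binary
#' mast, census-year mast category and previous-year crop areas. Every
#' candidate census year that does not reach the final table is logged with
#' its exclusion rule.
#'
#' @param bags hunting-bag series (`country`, `region`, `year`, `bag`,
#'   `area_km2`).
#' @param climate climate table (`region`, `year`, `month`, `tmean_c`,
#'   `precip_mm`).
#' @param mast optional mast rank table (`region`, `year`, `rank`).
#' @param crops optional crop table (`region`, `year`, `crop_corn`,
#'   `crop_potato`; percentages of region area). Census year t uses the
#'   values of year t-1.
#' @param exclusion_list optional data frame (`region`, `year`) of census
#'   years to drop (e.g. war-affected).
#' @param min_density low-density threshold (animals shot per km^2).
#' @param longterm_window inclusive year range for long-term means.
#' @return list with `growth` (one row per retained census year),
#'   `exclusions` (`region`, `year`, `rule`) and `n_candidates` (number of
#'   candidate census years before any exclusion).
#' @export
build_growth_table <- function(bags, climate, mast = NULL, crops = NULL,
                               exclusion_list = NULL, min_density = 0.01,
                               longterm_window = c(1973, 2002)) {
  lam <- compute_lambda(bags, min_density = min_density)
  logs <- list(lam$exclusions)
  g <- lam$lambda
  n_candidates <- nrow(g) + nrow(lam$exclusions)

  g <- exclude_years(g, exclusion_list)
  logs <- c(logs, list(attr(g, "exclusion_log")))

  # seasonal climate, census year and previous year
  st <- season_table(climate)
  key_st <- paste(st$region, st$year)
  cur <- match(paste(g$region, g$year), key_st)
  prv <- match(paste(g$region, g$year - 1), key_st)
  g$winter_t <- st$winter_t[cur]
  g$spring_t <- st$spring_t[cur]
  g$summer_t <- st$summer_t[cur]
  g$prior_spring_t <- st$spring_t[prv]
  g$prior_summer_t <- st$summer_t[prv]
  g$prior_autumn_t <- st$autumn_t[prv]
  g$winter_p <- st$winter_p[cur]
  g$spring_p <- st$spring_p[cur]
  g$summer_p <- st$summer_p[cur]
  g$prior_spring_p <- st$spring_p[prv]
  g$prior_summer_p <- st$summer_p[prv]
  g$prior_autumn_p <- st$autumn_p[prv]

  # long-term means per region (named vector indexed by region label)
  lt_all <- function(v) {
    vals <- longterm_mean(climate, v, longterm_window)
    unname(vals[as.character(g$region)])
  }
  g$lt_winter_t <- lt_all("winter_t")
  g$lt_summer_t <- lt_all("summer_t")
  g$lt_summer_precip <- lt_all("summer_p")
  g$lt_yearly_precip <- lt_all("yearly_p")

  clim_cols <- c("winter_t", "spring_t", "summer_t", "prior_spring_t",
                 "prior_summer_t", "prior_autumn_t", "winter_p", "spring_p",
                 "summer_p", "prior_spring_p", "prior_summer_p",
                 "prior_autumn_p")
  bad_clim <- !stats::complete.cases(g[clim_cols])
  logs <- c(logs, list(.excl_rows(g$region[bad_clim], g$year[bad_clim],
                                  "incomplete_climate")))
  g <- g[!bad_clim, , drop = FALSE]

  # 5-year density proxy from post-filter bags
  kept_bags <- bags[bags$bag / bags$area_km2 >= min_density, , drop = FALSE]
  key_b <- paste(kept_bags$region, kept_bags$year)
  dens <- 0
  ok <- rep(TRUE, nrow(g))
  for (off in 1:5) {
    idx <- match(paste(g$region, g$year - off), key_b)
    ok <- ok & !is.na(idx)
    dens <- dens + kept_bags$bag[idx] / kept_bags$area_km2[idx]
  }
  g$density5 <- dens / 5
  logs <- c(logs, list(.excl_rows(g$region[!ok], g$year[!ok],
                                  "no_density_history")))
  g <- g[ok, , drop = FALSE]

  if (!is.null(mast)) {
    cats <- mast_categories(mast)
    key_m <- paste(cats$region, cats$year)
    prv <- match(paste(g$region, g$year - 1), key_m)
    cur <- match(paste(g$region, g$year), key_m)
    g$mast_prev <- cats$mast_binary[prv]
    g$mast_cat <- factor(round(cats$rank_mean[cur]), levels = 0:4)
    bad <- is.na(g$mast_prev) | is.na(g$mast_cat)
    logs <- c(logs, list(.excl_rows(g$region[bad], g$year[bad],
                                    "missing_mast")))
    g <- g[!bad, , drop = FALSE]
  }

  if (!is.null(crops)) {
    key_c <- paste(crops$region, crops$year)
    prv <- match(paste(g$region, g$year - 1), key_c)
    g$crop_corn <- crops$crop_corn[prv]
    g$crop_potato <- crops$crop_potato[prv]
    bad <- is.na(g$crop_corn) | is.na(g$crop_potato)
    logs <- c(logs, list(.excl_rows(g$region[bad], g$year[bad],
                                    "missing_crops")))
    g <- g[!bad, , drop = FALSE]
  }

  exclusions <- do.call(rbind, logs[vapply(logs, nrow, integer(1)) > 0]) %||%
    data.frame(region = character(), year = integer(), rule = character())
  rownames(g) <- NULL
  list(growth = g, exclusions = exclusions, n_candidates = n_candidates)
}

#' Read the delimited input tables of the pipeline
#'
#' Convenience readers for the five input schemas: `bags.csv`
#' (country,region,year,bag,area_km2), `climate.csv`
#' (region,year,month,tmean_c,precip_mm), `mast.csv` (region,year,rank),
#' `accidents.csv` (country,year,accidents,vehicles) and `bodymass.csv`
#' (region,sex,mass_kg,dressed,zone,longterm_winter_c).
#'
#' @param dir directory containing the tables.
#' @return named list of data frames (missing optional files are `NULL`).
#' @export
read_input_tables <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  list(bags = rd("bags.csv"), climate = rd("climate.csv"),
       mast = rd("mast.csv"), accidents = rd("accidents.csv"),
       bodymass = rd("bodymass.csv"), crops = rd("crops.csv"))
}
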