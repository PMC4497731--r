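# diagnostics and validation: empirical semivariograms of model residuals,
# climate-station distances, hunting-bag validation against traffic
# accidents, and residual normality summaries

#' Empirical semivariogram
#'
#' `gamma(h) = 1 / (2 |N(h)|) * sum over pairs in N(h) of (z_i - z_j)^2`
#' per lag bin. Supply spatial coordinates (planar km), temporal coordinates
#' (years), or both for the spatio-temporal variant binned jointly on
#' distance and year lag.
#'
#' @param values numeric vector of residuals.
#' @param space optional n x 2 matrix of planar coordinates in km.
#' @param time optional numeric vector of years.
#' @param space_width spatial bin width in km (default 50).
#' @param cutoff maximum spatial distance (default: half the maximum
#'   pairwise distance).
#' @param time_width temporal bin width in years (default 1).
#' @param max_n guard against accidental quadratic blow-up (default 3000
#'   observations).
#' @return object of class `"boar_semivariogram"`: data frame with
#'   `gamma` and `n_pairs` per bin plus `dist_mid` and/or `lag_mid`;
#'   attribute `direction` is `"spatial"`, `"temporal"` or
#'   `"spatiotemporal"`. Empty bins carry `gamma = NA`, `n_pairs = 0`.
#' @export
empirical_semivariogram <- function(values, space = NULL, time = NULL,
                                    space_width = 50, cutoff = NULL,
                                    time_width = 1, max_n = 3000) {
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  if (n > max_n) stop("more than ", max_n, " observations; subsample first")
  if (is.null(space) && is.null(time)) stop("supply space and/or time")
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  sq <- (values[ii] - values[jj])^2

  dist_s <- lag_t <- NULL
  if (!is.null(space)) {
    space <- as.matrix(space)
    stopifnot(nrow(space) == n, ncol(space) == 2)
    dist_s <- sqrt((space[ii, 1] - space[jj, 1])^2 +
                     (space[ii, 2] - space[jj, 2])^2)
    if (is.null(cutoff)) cutoff <- max(dist_s) / 2
  }
  if (!is.null(time)) {
    stopifnot(length(time) == n)
    lag_t <- abs(time[ii] - time[jj])
  }

  bin_stats <- function(f, sq) {
    keep <- !is.na(f)
    agg_n <- tapply(sq[keep], f[keep], length)
    agg_g <- tapply(sq[keep], f[keep], function(v) sum(v) / (2 * length(v)))
    list(n = agg_n, g = agg_g)
  }

  if (!is.null(space) && is.null(time)) {
    breaks <- seq(0, cutoff + space_width, by = space_width)
    f <- cut(dist_s, breaks, include.lowest = TRUE)
    f[dist_s > cutoff] <- NA
    mids <- (head(breaks, -1) + breaks[-1]) / 2
    bs <- bin_stats(f, sq)
    out <- data.frame(dist_mid = mids,
                      gamma = as.numeric(bs$g[levels(f)]),
                      n_pairs = ifelse(is.na(bs$n[levels(f)]), 0,
                                       bs$n[levels(f)]))
    direction <- "spatial"
  } else if (is.null(space) && !is.null(time)) {
    breaks <- seq(0, max(lag_t) + time_width, by = time_width)
    f <- cut(lag_t, breaks, include.lowest = TRUE, right = FALSE)
    mids <- (head(breaks, -1) + breaks[-1]) / 2
    bs <- bin_stats(f, sq)
    out <- data.frame(lag_mid = mids,
                      gamma = as.numeric(bs$g[levels(f)]),
                      n_pairs = ifelse(is.na(bs$n[levels(f)]), 0,
                                       bs$n[levels(f)]))
    direction <- "temporal"
  } else {
    sbreaks <- seq(0, cutoff + space_width, by = space_width)
    fs <- cut(dist_s, sbreaks, include.lowest = TRUE)
    fs[dist_s > cutoff] <- NA
    tbreaks <- seq(0, max(lag_t) + time_width, by = time_width)
    ft <- cut(lag_t, tbreaks, include.lowest = TRUE, right = FALSE)
    f <- interaction(fs, ft, drop = FALSE)
    bs <- bin_stats(f, sq)
    grid <- expand.grid(s = levels(fs), t = levels(ft),
                        KEEP.OUT.ATTRS = FALSE)
    lv <- paste(grid$s, grid$t, sep = ".")
    smids <- (head(sbreaks, -1) + sbreaks[-1]) / 2
    tmids <- (head(tbreaks, -1) + tbreaks[-1]) / 2
    out <- data.frame(dist_mid = smids[match(grid$s, levels(fs))],
                      lag_mid = tmids[match(grid$t, levels(ft))],
                      gamma = as.numeric(bs$g[lv]),
                      n_pairs = ifelse(is.na(bs$n[lv]), 0, bs$n[lv]))
    direction <- "spatiotemporal"
  }
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  class(out) <- c("boar_semivariogram", "data.frame")
  out
}

#' Great-circle distance matrix between climate stations
#'
#' Symmetric haversine distances on a sphere of radius 6371 km.
#'
#' @param stations data frame or matrix with columns `lon`, `lat` in
#'   degrees.
#' @return n x n matrix of distances in km (zero diagonal).
#' @export
station_distance_matrix <- function(stations) {
  x <- as.matrix(as.data.frame(stations)[, c("lon", "lat")])
  if (any(abs(x[, "lat"]) > 90) || any(abs(x[, "lon"]) > 180)) {
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  }
  # distHaversine is linear in the sphere radius; rescale its default
  # (6378.137 km) to the conventional mean earth radius of 6371 km
  m <- geosphere::distm(x, fun = geosphere::distHaversine)
  m * (6371 / 6378.137) / 1000
}

#' Validate hunting bags against traffic-accident counts
#'
#' Per country: Pearson correlation between the national hunting bag and
#' the accident count corrected for registered vehicles
#' (accidents / vehicles), and between the year-to-year relative changes of
#' the two series (the growth-rate scale). Two-sided p-values from the t
#' transform of r.
#'
#' @param bags_national data frame (`country`, `year`, `bag`) of national
#'   totals (see [national_totals()]).
#' @param accidents data frame (`country`, `year`, `accidents`,
#'   `vehicles`).
#' @return object of class `"boar_validation"`: per-country data frame with
#'   `r_level`, `p_level`, `r_change`, `p_change`, `n`. Zero-variance series
#'   give `NA` correlations.
#' @export
validate_bags <- function(bags_national, accidents) {
  merged <- merge(bags_national, accidents, by = c("country", "year"))
  merged$corrected <- merged$accidents / merged$vehicles
  rows <- lapply(split(merged, merged$country), function(d) {
    d <- d[order(d$year), ]
    if (nrow(d) < 3) stop("fewer than 3 overlapping years for country ",
                          d$country[1])
    safe_cor <- function(a, b) {
      if (sd(a) == 0 || sd(b) == 0) return(c(r = NA_real_, p = NA_real_))
      ct <- cor.test(a, b)
      c(r = unname(ct$estimate), p = ct$p.value)
    }
    lev <- safe_cor(d$bag, d$corrected)
    consec <- which(diff(d$year) == 1)
    lam_b <- d$bag[consec + 1] / d$bag[consec]
    lam_a <- d$corrected[consec + 1] / d$corrected[consec]
    chg <- if (length(consec) >= 3) safe_cor(lam_b, lam_a) else
      c(r = NA_real_, p = NA_real_)
    data.frame(country = d$country[1], n = nrow(d),
               r_level = lev["r"], p_level = lev["p"],
               r_change = chg["r"], p_change = chg["p"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("boar_validation", "data.frame")
  out
}

#' National hunting-bag totals
#'
#' @param bags regional hunting-bag table.
#' @return data frame (`country`, `year`, `bag`).
#' @export
national_totals <- function(bags) {
  out <- aggregate(bag ~ country + year, data = bags, FUN = sum)
  out[order(out$country, out$year), ]
}

#' Residual normality summary
#'
#' Advisory summary of residual shape: skewness, excess kurtosis and the
#' maximum absolute deviation between the empirical and the fitted-normal
#' quantiles. Never gates the pipeline.
#'
#' @param residuals numeric vector (>= 10 values).
#' @return list with `n`, `skewness`, `kurtosis_excess`, `qq_deviation`,
#'   `degenerate`.
#' @export
normality_report <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 10) stop("need at least 10 residuals")
  if (sd(residuals) == 0) {
    return(list(n = length(residuals), skewness = NA_real_,
                kurtosis_excess = NA_real_, qq_deviation = NA_real_,
                degenerate = TRUE))
  }
  z <- (residuals - mean(residuals)) / sd(residuals)
  qq <- max(abs(sort(z) - qnorm(ppoints(length(z)))))
  list(n = length(residuals),
       skewness = e1071::skewness(residuals, type = 2),
       kurtosis_excess = e1071::kurtosis(residuals, type = 2),
       qq_deviation = qq, degenerate = FALSE)
}
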