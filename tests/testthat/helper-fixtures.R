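# shared fixtures, generated once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small European-style bundle: 12 regions in 4 countries, 17 analysis years
small_europe_bundle <- function() {
  fixture("small_europe", simulate_bundle(
    generator_config(n_regions = 12, n_countries = 4,
                     years = c(1977, 1998), seed = 77)))
}

# growth table of the small bundle
small_growth <- function() {
  fixture("small_growth", {
    b <- small_europe_bundle()
    build_growth_table(b$bags, b$climate, mast = b$mast, crops = b$crops)
  })
}

# Austrian-style configuration: one country, climatically close regions,
# stationary mast availability
austria_config <- function(years = c(1907, 2012), seed = 1) {
  generator_config(
    n_regions = 6, n_countries = 1, years = years,
    longterm_winter_range = c(-0.5, 0.5), residual_sd = 0.2,
    mast_trend = 0,
    coefficients = c(winter_t = 0.237, mast_prev = 0.284,
                     "mast_prev:winter_t" = -0.926,
                     prior_autumn_t = 0.173),
    seed = seed)
}

# a fitted gaussian model set on fast-to-fit body-mass style data
small_lm_set <- function() {
  fixture("small_lm_set", {
    set.seed(42)
    n <- 60
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 1 + 0.8 * d$x1 - 0.3 * d$x2 + 0.4 * d$x1 * d$x2 + rnorm(n, 0, 0.7)
    fit_model_set(d, "y", c("x1", "x2", "x1:x2"), random = character())
  })
}

# brute-force marginality filter: oracle for model enumeration
brute_force_subsets <- function(terms) {
  m <- length(terms)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    subset <- terms[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0]
    ok <- TRUE
    for (tr in subset) {
      if (grepl(":", tr) &&
          !all(strsplit(tr, ":")[[1]] %in% subset)) ok <- FALSE
    }
    if (ok) out <- c(out, list(subset))
  }
  out
}

term_set_key <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1)))
}
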