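# end-to-end analyses: the European lambda model, the Austrian
# food-availability model, the mast-frequency trends, the body-mass cline
# and the hunting-bag validation

#' Default term vocabularies
#'
#' `europe_terms()`: the full European growth-rate model — six seasonal
#' temperatures, long-term winter and summer temperature with their
#' interactions with the current winter and summer temperature, long-term
#' summer and yearly precipitation, the 5-year density proxy and its
#' interaction with winter temperature (11 mains + 3 interactions).
#' `austria_terms()`: the Austrian food-availability model — the important
#' European terms plus previous-year binary beech mast, its interactions
#' with winter temperature, long-term winter temperature and density, and
#' previous-year corn and potato cultivation areas.
#'
#' @return character vector of term names.
#' @export
europe_terms <- function() {
  canonical_terms(c(
    "winter_t", "summer_t", "spring_t", "prior_spring_t", "prior_summer_t",
    "prior_autumn_t", "lt_winter_t", "lt_summer_t", "lt_summer_precip",
    "lt_yearly_precip", "density5",
    "winter_t:lt_winter_t", "winter_t:density5", "summer_t:lt_summer_t"))
}

#' @rdname europe_terms
#' @export
austria_terms <- function() {
  canonical_terms(c(
    "winter_t", "summer_t", "prior_spring_t", "prior_autumn_t",
    "lt_winter_t", "density5", "mast_prev", "crop_corn", "crop_potato",
    "mast_prev:winter_t", "winter_t:lt_winter_t",
    "mast_prev:lt_winter_t", "mast_prev:density5"))
}

# shared pipeline for the two growth-rate analyses: growth table,
# standardization, model-set fit, conditional natural average + zero method
run_lambda_analysis <- function(bags, climate, mast = NULL, crops = NULL,
                                terms, random, alpha = 0.05,
                                min_density = 0.01, exclusion_list = NULL,
                                longterm_window = c(1973, 2002),
                                cap = 5000) {
  terms <- canonical_terms(terms)
  check_term_names(terms)
  gt <- build_growth_table(bags, climate, mast = mast, crops = crops,
                           exclusion_list = exclusion_list,
                           min_density = min_density,
                           longterm_window = longterm_window)
  mains <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(mains, names(gt$growth))
  if (length(missing_cols) > 0) {
    stop("growth table lacks column(s): ",
         paste(missing_cols, collapse = ", "),
         " (supply the mast/crop tables they require)")
  }
  data <- standardize_predictors(gt$growth, mains)
  scaling <- attr(data, "scaling")
  set <- fit_model_set(data, response = "lambda", base_terms = terms,
                       random = random, family = "gaussian", cap = cap)
  natural <- conditional_average(set, alpha = alpha)
  zero <- zero_average_table(set)
  out <- list(table = build_table(natural), natural = natural, zero = zero,
              set = set, growth = data, scaling = scaling,
              exclusions = gt$exclusions, n = set$n,
              n_candidates = gt$n_candidates)
  class(out) <- "boar_analysis"
  out
}

#' @export
print.boar_analysis <- function(x, ...) {
  cat("<boar_analysis> n = ", x$n, " growth rates (",
      nrow(x$exclusions), " of ", x$n_candidates,
      " candidate data points excluded), ",
      length(x$set$members), " models averaged\n\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}

#' European growth-rate analysis
#'
#' Fits the full European model set on a hunting-bag / climate bundle:
#' growth rates with exclusion rules, day-weighted seasonal temperatures,
#' long-term climate, density proxy, two-SD standardization, ML linear
#' mixed models with country/region nested random intercepts, and AICc
#' multi-model averaging with the interaction-conditional rule (natural
#' average) plus the zero method.
#'
#' @param bundle a `"boar_bundle"` (or any list with `bags` and `climate`
#'   tables).
#' @param terms fixed-term vocabulary (default [europe_terms()]; the full
#'   set enumerates 4160 models — pass a reduced set for quick runs).
#' @param random random-intercept structure (default nested
#'   `"country/region"`).
#' @param alpha significance level of the conditional rule.
#' @param min_density low-density exclusion threshold.
#' @param exclusion_list optional (`region`, `year`) census years to drop.
#' @param longterm_window window of the long-term climate means.
#' @param cap model-count guard (see [enumerate_models()]).
#' @return a `"boar_analysis"`: report table, natural/zero averaging
#'   results, the fitted model set, the standardized growth table, the
#'   scaling record and the exclusion log.
#' @export
run_europe <- function(bundle, terms = europe_terms(),
                       random = c("country/region"), alpha = 0.05,
                       min_density = 0.01, exclusion_list = NULL,
                       longterm_window = c(1973, 2002), cap = 5000) {
  run_lambda_analysis(bundle$bags, bundle$climate, mast = NULL, crops = NULL,
                      terms = terms, random = random, alpha = alpha,
                      min_density = min_density,
                      exclusion_list = exclusion_list,
                      longterm_window = longterm_window, cap = cap)
}

#' Austrian food-availability analysis
#'
#' As [run_europe()], restricted to the Austrian term vocabulary: adds
#' previous-year binary beech mast, its interaction with winter
#' temperature (mast compensating cold winters), and previous-year crop
#' areas. The census-year mast category enters as an additional random
#' factor (hunting success may depend on mast intensity).
#'
#' @inheritParams run_europe
#' @param regions optional subset of region labels to analyse.
#' @param random default `c("region", "mast_cat")`: region intercepts plus
#'   the census-year mast-category intercept.
#' @return a `"boar_analysis"`.
#' @export
run_austria <- function(bundle, terms = austria_terms(),
                        random = c("region", "mast_cat"), alpha = 0.05,
                        min_density = 0.01, exclusion_list = NULL,
                        longterm_window = c(1973, 2002), cap = 5000,
                        regions = NULL) {
  bags <- bundle$bags
  if (!is.null(regions)) bags <- bags[bags$region %in% regions, , drop = FALSE]
  run_lambda_analysis(bags, bundle$climate, mast = bundle$mast,
                      crops = bundle$crops, terms = terms, random = random,
                      alpha = alpha, min_density = min_density,
                      exclusion_list = exclusion_list,
                      longterm_window = longterm_window, cap = cap)
}

#' Mast-frequency trend models
#'
#' Tests whether the frequencies of mast failure (rank <= 1), moderate mast
#' (1 < rank <= 3) and full mast (rank > 3) have changed over the years:
#' three binomial random-intercept models, each with year as fixed and
#' region as random effect, fitted by adaptive Gauss-Hermite quadrature.
#'
#' @param mast rank table (`region`, `year`, `rank`).
#' @param start_year first year of the trend window (default 1976).
#' @param end_year last year (default: last year in the data).
#' @param nagq quadrature nodes (default 15).
#' @return data frame with one row per category: `slope` (per-year
#'   log-odds change), `se`, `z`, `p`, `n`; skipped categories (never or
#'   always observed) are reported with `NA` and a message.
#' @export
run_mast_trends <- function(mast, start_year = 1976, end_year = NULL,
                            nagq = 15) {
  cats <- mast_categories(mast)
  if (is.null(end_year)) end_year <- max(cats$year)
  cats <- cats[cats$year >= start_year & cats$year <= end_year, , drop = FALSE]
  cats$year_c <- cats$year - mean(cats$year)
  rows <- lapply(c("failure", "moderate", "full"), function(cat) {
    y <- cats[[cat]]
    if (all(y == 0) || all(y == 1)) {
      message("category '", cat, "' is ", if (all(y == 0)) "never" else
        "always", " observed; model skipped")
      return(data.frame(category = cat, slope = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_, n = length(y)))
    }
    d <- cats
    d$outcome <- y
    fit <- fit_glmm_binomial(d, model_spec("outcome", "year_c",
                                           random = "region",
                                           family = "binomial"),
                             nagq = nagq)
    sl <- unname(fit$beta["year_c"]); se <- unname(fit$se["year_c"])
    data.frame(category = cat, slope = sl, se = se, z = sl / se,
               p = 2 * pnorm(-abs(sl / se)), n = fit$n)
  })
  out <- do.call(rbind, rows)
  attr(out, "years") <- c(start_year, end_year)
  out
}

#' Body-mass cline analysis
#'
#' Multi-model average of a linear model of adult body mass as a function
#' of the regional long-term winter temperature, sex and their interaction.
#' Dressed masses are converted to live mass first.
#'
#' @param bodymass table (`region`, `sex`, `mass_kg`, `dressed`, `zone`,
#'   `longterm_winter_c`).
#' @param alpha significance level of the conditional rule.
#' @return a `"boar_analysis"`-like list with the averaged table, the model
#'   set and the prepared data.
#' @export
run_bodymass <- function(bodymass, alpha = 0.05) {
  d <- bodymass
  if (length(unique(d$region)) < 5) {
    stop("fewer than 5 regions: too few for the body-mass cline")
  }
  d$mass_live <- dressed_to_live(d$mass_kg, d$zone, d$dressed)
  d$sex_male <- as.integer(d$sex %in% c("M", "male", "m"))
  terms <- c("longterm_winter_c", "sex_male",
             "longterm_winter_c:sex_male")
  if (length(unique(d$sex_male)) == 1) {
    warning("only one sex present; sex terms dropped", call. = FALSE)
    terms <- "longterm_winter_c"
  }
  d$longterm_winter_c <- as.numeric(d$longterm_winter_c)
  set <- fit_model_set(d, response = "mass_live", base_terms = terms,
                       random = character(), family = "gaussian")
  natural <- conditional_average(set, alpha = alpha)
  zero <- zero_average_table(set)
  out <- list(table = build_table(natural), natural = natural, zero = zero,
              set = set, data = d, n = set$n,
              exclusions = data.frame(), n_candidates = nrow(d))
  class(out) <- "boar_analysis"
  out
}

#' Hunting-bag validation against traffic accidents
#'
#' @param bundle a `"boar_bundle"` (or list with `bags` and `accidents`).
#' @return a `"boar_validation"` per-country correlation report.
#' @export
run_validation <- function(bundle) {
  validate_bags(national_totals(bundle$bags), bundle$accidents)
}
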