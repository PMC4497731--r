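# shared internal helpers: term vocabulary, interaction parsing, seed streams

# recognized main-effect names for growth-rate models; interactions are "a:b"
.term_vocabulary <- c(
  "winter_t", "summer_t", "spring_t",
  "prior_spring_t", "prior_summer_t", "prior_autumn_t",
  "lt_winter_t", "lt_summer_t", "lt_summer_precip", "lt_yearly_precip",
  "density5", "mast_prev", "crop_corn", "crop_potato"
)

is_interaction <- function(term) grepl(":", term, fixed = TRUE)

interaction_parents <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Canonicalize model term names
#'
#' Interactions are written with their parent main effects in alphabetical
#' order ("a:b"), so that term labels agree between model enumeration and the
#' coefficient names of fitted models.
#'
#' @param terms character vector of main-effect and interaction names.
#' @return character vector of the same length.
#' @keywords internal
canonical_terms <- function(terms) {
  vapply(terms, function(tr) {
    if (!is_interaction(tr)) return(tr)
    paste(sort(interaction_parents(tr)), collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

check_term_names <- function(terms, extra = character()) {
  vocab <- c(.term_vocabulary, extra)
  mains <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  bad <- setdiff(mains, vocab)
  if (length(bad) > 0) {
    stop("unrecognized term(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(vocab, collapse = ", "),
         call. = FALSE)
  }
  invisible(terms)
}

# deterministic sub-stream seeds: one bundle seed governs all components, and
# adding a component never perturbs the draws of another
component_seed <- function(seed, component) {
  offsets <- c(climate = 101L, mast = 211L, population = 307L,
               accidents = 401L, bodymass = 503L, crops = 601L)
  if (!component %in% names(offsets)) {
    stop("unknown generator component: ", component)
  }
  (as.integer(seed) + offsets[[component]]) %% .Machine$integer.max
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

days_in_month <- function(month, year) {
  n <- max(length(month), length(year))
  month <- rep_len(month, n)
  year <- rep_len(year, n)
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  d[month == 2 & is_leap_year(year)] <- 29L
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
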