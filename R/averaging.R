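# the statistical core: enumeration of all nested fixed-effect structures
# under marginality, AICc weighting, natural-average and zero-method
# model-averaged estimates, relative variable importance, and the
# interaction-conditional model-subset rule for main effects

#' Enumerate all nested fixed-effect structures
#'
#' All subsets of the base terms such that an interaction is only included
#' together with both of its parent main effects (marginality). The
#' intercept-only model (empty subset) is included. Random effects are not
#' part of the enumeration: they are identical across members.
#'
#' @param terms character vector of base terms (mains and `"a:b"`
#'   interactions); at most 20 terms.
#' @param cap maximum admissible subset count (default 5000); exceeded
#'   counts raise an error advising term reduction.
#' @return list of character vectors (term subsets), in deterministic order.
#' @export
enumerate_models <- function(terms, cap = 5000) {
  terms <- canonical_terms(terms)
  if (anyDuplicated(terms)) stop("duplicate base terms")
  m <- length(terms)
  if (m > 20) stop("more than 20 base terms; reduce the model vocabulary")
  inter <- which(is_interaction(terms))
  for (i in inter) {
    if (!all(interaction_parents(terms[i]) %in% terms)) {
      stop("interaction ", terms[i],
           " lacks a parent main effect in the base terms")
    }
  }
  masks <- 0:(2^m - 1)
  keep <- rep(TRUE, length(masks))
  bit <- function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0
  for (i in inter) {
    par_idx <- match(interaction_parents(terms[i]), terms)
    keep <- keep & (!bit(i) | (bit(par_idx[1]) & bit(par_idx[2])))
  }
  masks <- masks[keep]
  if (length(masks) > cap) {
    stop(length(masks), " admissible models exceed the cap of ", cap,
         "; reduce the term set or raise `cap`")
  }
  lapply(masks, function(ms) terms[bitwAnd(ms, bitwShiftL(1L, seq_len(m) - 1L)) > 0])
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`; the min-shift makes the computation
#' numerically stable and the weights invariant to adding a constant to all
#' AICcs. If some models fit exactly (AICc of `-Inf`), the weight is shared
#' equally among them.
#'
#' @param aiccs numeric vector of AICc values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) == 0) stop("empty AICc vector")
  if (anyNA(aiccs)) stop("AICc values must not be NA")
  if (any(aiccs == -Inf)) {
    w <- as.numeric(aiccs == -Inf)
    return(w / sum(w))
  }
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit every model of an enumerated set
#'
#' Enumerates all admissible fixed-term subsets of `base_terms` under
#' marginality and fits each with the requested fitter. Non-converged
#' members are dropped with a warning and the Akaike weights renormalized.
#'
#' @param data model data frame (predictors already standardized).
#' @param response response column name.
#' @param base_terms maximal fixed-term set.
#' @param random random-intercept groupings (see [model_spec()]); empty for
#'   ordinary linear models.
#' @param family `"gaussian"` or `"binomial"`.
#' @param cap forwarded to [enumerate_models()].
#' @param nagq quadrature nodes for binomial fits.
#' @return object of class `"boar_model_set"`: list with `base_terms`,
#'   `term_sets`, `members` (list of `boar_fit`), `aicc`, `delta`, `weight`,
#'   `n`, `dropped` (term sets of non-converged members).
#' @export
fit_model_set <- function(data, response, base_terms,
                          random = c("country/region"),
                          family = "gaussian", cap = 5000, nagq = 15) {
  base_terms <- canonical_terms(base_terms)
  subsets <- enumerate_models(base_terms, cap = cap)
  fitter <- if (family == "binomial") {
    function(sp) fit_glmm_binomial(data, sp, nagq = nagq)
  } else if (length(random) > 0) {
    function(sp) fit_lmm(data, sp)
  } else {
    function(sp) fit_lm(data, sp)
  }
  members <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sp <- model_spec(response, subsets[[i]], random = random,
                     family = family)
    members[[i]] <- fitter(sp)
  }
  conv <- vapply(members, `[[`, logical(1), "converged")
  dropped <- subsets[!conv]
  if (any(!conv)) {
    warning(sum(!conv), " model(s) did not converge and were dropped from ",
            "the set", call. = FALSE)
    members <- members[conv]
    subsets <- subsets[conv]
  }
  if (length(members) == 0) stop("no model in the set converged")
  aiccs <- vapply(members, `[[`, numeric(1), "aicc")
  w <- akaike_weights(aiccs)
  out <- list(base_terms = base_terms, term_sets = subsets,
              members = members, aicc = aiccs,
              delta = aiccs - min(aiccs), weight = w,
              n = members[[1]]$n, response = response, dropped = dropped)
  class(out) <- "boar_model_set"
  out
}

#' @export
print.boar_model_set <- function(x, ...) {
  cat("<boar_model_set> ", length(x$members), " models over ",
      length(x$base_terms), " base terms, n = ", x$n, "\n", sep = "")
  print(head(model_set_ledger(x), 5), digits = 4)
  if (length(x$members) > 5) cat("... (", length(x$members) - 5,
                                 " more models)\n", sep = "")
  invisible(x)
}

#' Per-member audit ledger of a model set
#'
#' @param set a `"boar_model_set"`.
#' @return data frame with one row per member: terms, k, logLik, AICc,
#'   delta-AICc and Akaike weight, sorted by AICc.
#' @export
model_set_ledger <- function(set) {
  df <- data.frame(
    model = vapply(set$term_sets, function(tt)
      if (length(tt) == 0) "(intercept only)" else
        paste(tt, collapse = " + "), character(1)),
    k = vapply(set$members, `[[`, numeric(1), "k"),
    loglik = vapply(set$members, `[[`, numeric(1), "loglik"),
    aicc = set$aicc, delta = set$delta, weight = set$weight,
    stringsAsFactors = FALSE)
  df[order(df$aicc), ]
}

has_term <- function(set, term) {
  vapply(set$term_sets, function(tt) term %in% tt, logical(1))
}

member_beta <- function(set, idx, term) {
  vapply(set$members[idx], function(m) unname(m$beta[term]), numeric(1))
}

member_se <- function(set, idx, term) {
  vapply(set$members[idx], function(m) unname(m$se[term]), numeric(1))
}

member_p <- function(set, idx, term) {
  b <- member_beta(set, idx, term)
  s <- member_se(set, idx, term)
  p <- 2 * pnorm(-abs(b / s))
  p[s == 0 & b == 0] <- NA_real_
  p[s == 0 & b != 0] <- 0
  p
}

#' Relative variable importance
#'
#' Sum of the Akaike weights of the models containing the term.
#'
#' @param set a `"boar_model_set"`.
#' @param term base term name.
#' @return RVI in \[0, 1\].
#' @export
rvi <- function(set, term) {
  term <- canonical_terms(term)
  if (!term %in% set$base_terms) stop("unknown term: ", term)
  sum(set$weight[has_term(set, term)])
}

.avg_core <- function(beta, se, w) {
  w <- w / sum(w)
  est <- sum(w * beta)
  se_u <- sum(w * sqrt(se^2 + (beta - est)^2))
  c(estimate = est, se = se_u)
}

#' Natural-average model-averaged estimate
#'
#' Averages only over the models that contain the term, with the Akaike
#' weights renormalized over that subset (avoiding shrinkage towards zero).
#' The unconditional standard error is
#' `sum_i w_i * sqrt(se_i^2 + (beta_i - beta_bar)^2)`.
#'
#' @param set a `"boar_model_set"`.
#' @param term base term name; must appear in at least one member.
#' @return named vector `c(estimate, se)`.
#' @export
average_natural <- function(set, term) {
  term <- canonical_terms(term)
  idx <- which(has_term(set, term))
  if (length(idx) == 0) stop("term ", term, " is absent from all models")
  .avg_core(member_beta(set, idx, term), member_se(set, idx, term),
            set$weight[idx])
}

#' Zero-method model-averaged estimate
#'
#' Models not containing the term contribute an estimate of 0 with a
#' standard error of 0; weights are not renormalized. By construction the
#' zero-method estimate equals the natural-average estimate times the RVI.
#'
#' @inheritParams average_natural
#' @return named vector `c(estimate, se)`.
#' @export
average_zero <- function(set, term) {
  term <- canonical_terms(term)
  idx <- has_term(set, term)
  if (!any(idx)) stop("term ", term, " is absent from all models")
  beta <- se <- numeric(length(set$members))
  beta[idx] <- member_beta(set, which(idx), term)
  se[idx] <- member_se(set, which(idx), term)
  est <- sum(set$weight * beta)
  c(estimate = est,
    se = sum(set$weight * sqrt(se^2 + (beta - est)^2)))
}

.zp <- function(est, se) {
  est <- unname(est); se <- unname(se)
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  if (se == 0) {
    z <- if (est == 0) NA_real_ else sign(est) * Inf
    p <- if (est == 0) NA_real_ else 0
  }
  c(z = z, p = p)
}

#' Interaction-conditional multi-model average
#'
#' Two-pass averaging. Pass 1 computes the full-set natural average for all
#' terms and classifies every interaction as significant or not by its
#' averaged p-value. Pass 2 re-averages the main effects involved in
#' interactions: a main whose interaction is significant is averaged only
#' over models where that interaction is itself significant (within-model
#' Wald p < alpha); a main whose interaction is not significant is averaged
#' over models not containing the interaction plus models where it is not
#' significant. Weights are renormalized within each selected subset. If a
#' selection is empty the full-set average is kept with a warning.
#'
#' @param set a `"boar_model_set"`.
#' @param alpha significance level (default 0.05).
#' @return object of class `"boar_averaging"`: data frame with one row per
#'   base term (`term`, `estimate`, `se`, `z`, `p`, `rvi`, `n_models`,
#'   `selection`), attributes `method = "natural"` and `alpha`.
#' @export
conditional_average <- function(set, alpha = 0.05) {
  terms <- set$base_terms
  full <- lapply(terms, function(tr) average_natural(set, tr))
  names(full) <- terms
  full_p <- vapply(terms, function(tr) {
    .zp(full[[tr]]["estimate"], full[[tr]]["se"])["p"]
  }, numeric(1))
  inters <- terms[is_interaction(terms)]
  sig_inter <- inters[!is.na(full_p[inters]) & full_p[inters] < alpha]

  rows <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    tr <- terms[i]
    related <- inters[vapply(inters, function(it)
      tr %in% interaction_parents(it), logical(1))]
    if (is_interaction(tr) || length(related) == 0) {
      est <- full[[tr]]
      sel_note <- "all models containing the term"
      idx <- which(has_term(set, tr))
    } else {
      idx <- which(has_term(set, tr))
      notes <- character()
      for (it in related) {
        in_it <- has_term(set, it)
        p_it <- rep(NA_real_, length(set$members))
        p_it[in_it] <- member_p(set, which(in_it), it)
        if (it %in% sig_inter) {
          keep <- in_it & !is.na(p_it) & p_it < alpha
          notes <- c(notes, paste0(it, " significant: models with ", it,
                                   " significant"))
        } else {
          # models containing the interaction with undefined p (degenerate
          # se = 0, beta = 0) count as non-significant
          keep <- !in_it | (!is.na(p_it) & p_it >= alpha) |
            (is.na(p_it) & in_it)
          notes <- c(notes, paste0(it, " not significant: models without ",
                                   it, " or with it non-significant"))
        }
        idx <- intersect(idx, which(keep))
      }
      if (length(idx) == 0) {
        warning("empty conditional selection for term ", tr,
                "; falling back to the full-set average", call. = FALSE)
        est <- full[[tr]]
        sel_note <- "fallback: full set (empty conditional selection)"
        idx <- which(has_term(set, tr))
      } else {
        est <- .avg_core(member_beta(set, idx, tr), member_se(set, idx, tr),
                         set$weight[idx])
        sel_note <- paste(notes, collapse = "; ")
      }
    }
    zp <- .zp(est["estimate"], est["se"])
    rows[[i]] <- data.frame(
      term = tr, estimate = unname(est["estimate"]), se = unname(est["se"]),
      z = unname(zp["z"]), p = unname(zp["p"]), rvi = rvi(set, tr),
      n_models = length(idx), selection = sel_note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "method") <- "natural"
  attr(out, "alpha") <- alpha
  attr(out, "n") <- set$n
  class(out) <- c("boar_averaging", "data.frame")
  out
}

#' Zero-method averaging table for a whole set
#'
#' @param set a `"boar_model_set"`.
#' @return `"boar_averaging"` data frame (method `"zero"`).
#' @export
zero_average_table <- function(set) {
  rows <- lapply(set$base_terms, function(tr) {
    est <- average_zero(set, tr)
    zp <- .zp(est["estimate"], est["se"])
    data.frame(term = tr, estimate = unname(est["estimate"]),
               se = unname(est["se"]), z = unname(zp["z"]),
               p = unname(zp["p"]), rvi = rvi(set, tr),
               n_models = length(set$members),
               selection = "zero method: all models",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- "zero"
  attr(out, "n") <- set$n
  class(out) <- c("boar_averaging", "data.frame")
  out
}

#' Format an averaging result as a report table
#'
#' Rows ordered by RVI (descending), ties broken by absolute estimate;
#' interactions rendered `"a: b"`; significant terms flagged.
#'
#' @param result a `"boar_averaging"` data frame.
#' @param alpha significance level for the flag (default: the result's).
#' @return data frame with columns `term`, `estimate`, `SE`, `P`, `RVI`,
#'   `significant`.
#' @export
build_table <- function(result, alpha = attr(result, "alpha") %||% 0.05) {
  if (nrow(result) == 0) {
    return(data.frame(term = character(), estimate = numeric(),
                      SE = numeric(), P = numeric(), RVI = numeric(),
                      significant = logical()))
  }
  ord <- order(-result$rvi, -abs(result$estimate))
  r <- result[ord, ]
  data.frame(term = gsub(":", ": ", r$term, fixed = TRUE),
             estimate = r$estimate, SE = r$se, P = r$p, RVI = r$rvi,
             significant = !is.na(r$p) & r$p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.boar_averaging <- function(x, ...) {
  cat("<boar_averaging> method = ", attr(x, "method"),
      ", n = ", attr(x, "n") %||% NA, "\n", sep = "")
  print(build_table(x), digits = 3)
  invisible(x)
}

#' Model-averaged conditional residuals
#'
#' Akaike-weighted average of the members' conditional residuals, used for
#' the semivariogram diagnostics.
#'
#' @param set a `"boar_model_set"`.
#' @return numeric vector of length `n`.
#' @export
averaged_residuals <- function(set) {
  res <- vapply(set$members, `[[`, numeric(set$n), "residuals")
  as.vector(res %*% set$weight)
}
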