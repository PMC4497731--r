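# model fitting: ML linear mixed models with nested random intercepts
# (lme4), random-intercept binomial models (adaptive Gauss-Hermite), and
# ordinary linear models; all reduced to a common fitted-model record with
# AICc

#' Model specification
#'
#' @param response response column name.
#' @param fixed_terms character vector of fixed-effect terms; interactions
#'   are written `"a:b"` (canonicalized to alphabetical parent order).
#' @param random character vector of random-intercept groupings; each element
#'   becomes one `(1 | g)` term and may use `/` for nesting (e.g.
#'   `"country/region"`). Empty for ordinary linear models.
#' @param family `"gaussian"` or `"binomial"`.
#' @return object of class `"boar_model_spec"`.
#' @export
model_spec <- function(response, fixed_terms = character(),
                       random = character(),
                       family = c("gaussian", "binomial")) {
  spec <- list(response = response,
               fixed_terms = canonical_terms(fixed_terms),
               random = random, family = match.arg(family))
  class(spec) <- "boar_model_spec"
  spec
}

spec_formula <- function(spec) {
  rhs <- c("1", spec$fixed_terms,
           if (length(spec$random) > 0) sprintf("(1 | %s)", spec$random))
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

fixed_formula <- function(spec) {
  as.formula(paste(spec$response, "~",
                   paste(c("1", spec$fixed_terms), collapse = " + ")))
}

# check the fixed-effect design for rank deficiency, naming collinear terms
check_full_rank <- function(spec, data) {
  mm <- model.matrix(fixed_formula(spec), data)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient fixed-effect design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects plus variance
#'   components plus, for gaussian models, the residual variance).
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

new_boar_fit <- function(spec, beta, se, vcov, sigma2, tau2, loglik, k, n,
                         converged, residuals, messages = character()) {
  # coefficient labels use canonical (alphabetical-parent) interaction names
  # so they match the enumerated term sets regardless of formula order
  relabel <- function(nm) ifelse(nm == "(Intercept)", nm, canonical_terms(nm))
  names(beta) <- relabel(names(beta))
  names(se) <- relabel(names(se))
  dimnames(vcov) <- list(relabel(rownames(vcov)), relabel(colnames(vcov)))
  out <- list(spec = spec, beta = beta, se = se, vcov = vcov,
              sigma2 = sigma2, tau2 = tau2, loglik = loglik, k = k, n = n,
              aicc = aicc(loglik, k, n), converged = converged,
              residuals = residuals, messages = messages)
  class(out) <- "boar_fit"
  out
}

#' @export
print.boar_fit <- function(x, ...) {
  cat("<boar_fit> ", x$spec$family, " model, n = ", x$n, ", k = ", x$k,
      ", logLik = ", format(x$loglik, digits = 6),
      ", AICc = ", format(x$aicc, digits = 6),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  z <- x$beta / x$se
  print(data.frame(estimate = x$beta, se = x$se, z = z,
                   p = 2 * pnorm(-abs(z))), digits = 4)
  invisible(x)
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Gaussian linear mixed model with nested random intercepts, fitted by ML
#' (not REML) so that AICc values are comparable across fixed-effect
#' structures. Fitting is delegated to [lme4::lmer()]; estimates, standard
#' errors, variance components, the ML log-likelihood and AICc (with `k`
#' counting fixed effects, variance components and the residual variance)
#' are collected into a compact record. Singular (boundary) fits are
#' retained; genuine non-convergence is flagged.
#'
#' @param data model data frame.
#' @param spec a [model_spec()] with `family = "gaussian"` and at least one
#'   random grouping.
#' @return object of class `"boar_fit"`.
#' @export
fit_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "boar_model_spec"), spec$family == "gaussian",
            length(spec$random) > 0)
  check_full_rank(spec, data)
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(spec_formula(spec), data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  ll <- logLik(fit)
  vc <- lme4::VarCorr(fit)
  tau2 <- setNames(vapply(vc, function(m) m[1, 1], numeric(1)), names(vc))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  new_boar_fit(
    spec = spec,
    beta = lme4::fixef(fit),
    se = sqrt(diag(as.matrix(vcov(fit)))),
    vcov = as.matrix(vcov(fit)),
    sigma2 = stats::sigma(fit)^2, tau2 = tau2,
    loglik = as.numeric(ll), k = attr(ll, "df"), n = stats::nobs(fit),
    converged = conv, residuals = residuals(fit), messages = msgs)
}

#' Fit a random-intercept binomial model
#'
#' Logistic mixed model with a single random intercept, fitted by maximizing
#' the marginal likelihood with adaptive Gauss-Hermite quadrature
#' ([lme4::glmer()]; `nagq = 1` is the Laplace approximation).
#'
#' @param data model data frame; the response must be 0/1.
#' @param spec a [model_spec()] with `family = "binomial"` and exactly one
#'   (non-nested) random grouping.
#' @param nagq number of quadrature nodes (default 15).
#' @return object of class `"boar_fit"` (with `sigma2 = NA`).
#' @export
fit_glmm_binomial <- function(data, spec, nagq = 15) {
  stopifnot(inherits(spec, "boar_model_spec"), spec$family == "binomial",
            length(spec$random) == 1, !grepl("/", spec$random))
  y <- data[[spec$response]]
  if (!all(y %in% c(0, 1))) stop("binomial response must be coded 0/1")
  check_full_rank(spec, data)
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::glmer(spec_formula(spec), data = data, family = stats::binomial(),
                nAGQ = nagq,
                control = lme4::glmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  ll <- logLik(fit)
  vc <- lme4::VarCorr(fit)
  tau2 <- setNames(vapply(vc, function(m) m[1, 1], numeric(1)), names(vc))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    !any(grepl("failed to converge", msgs))
  new_boar_fit(
    spec = spec,
    beta = lme4::fixef(fit),
    se = sqrt(diag(as.matrix(vcov(fit)))),
    vcov = as.matrix(vcov(fit)),
    sigma2 = NA_real_, tau2 = tau2,
    loglik = as.numeric(ll), k = attr(ll, "df"), n = stats::nobs(fit),
    converged = conv, residuals = residuals(fit, type = "response"),
    messages = msgs)
}

#' Fit an ordinary linear model
#'
#' Least-squares fit with the usual standard errors; `k` counts the
#' coefficients plus the residual variance so AICc is comparable with the
#' mixed-model fits. An exact (zero-residual) fit yields an infinite
#' log-likelihood and zero standard errors, which the averaging layer treats
#' as total support for the exactly fitting models.
#'
#' @param data model data frame.
#' @param spec a [model_spec()] with empty `random`.
#' @return object of class `"boar_fit"`.
#' @export
fit_lm <- function(data, spec) {
  stopifnot(inherits(spec, "boar_model_spec"), length(spec$random) == 0,
            spec$family == "gaussian")
  check_full_rank(spec, data)
  n <- nrow(data)
  p <- length(spec$fixed_terms) + 1
  if (n < p + 2) stop("too few observations for the linear model")
  fit <- lm(fixed_formula(spec), data = data)
  ll <- logLik(fit)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  se <- sm$coefficients[, "Std. Error"]
  # exact fits: summary() reports NaN standard errors; they are exactly 0
  if (sm$sigma == 0) se[] <- 0
  new_boar_fit(
    spec = spec, beta = coef(fit), se = se,
    vcov = if (sm$sigma == 0) matrix(0, p, p, dimnames = list(names(coef(fit)),
                                                              names(coef(fit))))
           else suppressWarnings(vcov(fit)),
    sigma2 = sm$sigma^2, tau2 = numeric(),
    loglik = as.numeric(ll), k = attr(ll, "df"), n = n,
    converged = TRUE, residuals = residuals(fit))
}
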