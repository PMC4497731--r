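# random-forest regression pre-screen: ranks climatic variables by
# out-of-bag permutation importance to decide which enter the mixed models
# (the step that discarded seasonal precipitation)

#' Random-forest screening configuration
#'
#' @param n_trees trees in the forest (default 2000, the analysis setting;
#'   tests use fewer for speed).
#' @param mtry predictors sampled as split candidates (default 4, i.e. the
#'   number of the twelve seasonal climate predictors divided by 3).
#' @param min_node minimum terminal-node size.
#' @param bootstrap draw bootstrap samples per tree (sampling with
#'   replacement, sample size n); `FALSE` grows every tree on the full data
#'   (no out-of-bag rows, so no permutation importance).
#' @param seed integer seed.
#' @return object of class `"forest_config"`.
#' @export
forest_config <- function(n_trees = 2000, mtry = 4, min_node = 5,
                          bootstrap = TRUE, seed = 1) {
  cfg <- list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
              min_node = as.integer(min_node), bootstrap = bootstrap,
              seed = as.integer(seed))
  if (cfg$n_trees < 1) stop("n_trees must be >= 1")
  if (cfg$mtry < 1) stop("mtry must be >= 1")
  class(cfg) <- "forest_config"
  cfg
}

#' Fit the screening forest
#'
#' Regression random forest (bootstrapped binary trees, `mtry` random split
#' candidates per node) via [randomForest::randomForest()]. Rows with
#' missing predictor values are dropped with a message. A constant response
#' yields all-leaf trees and zero importances, with a warning.
#'
#' @param x data frame or matrix of predictors.
#' @param y numeric response (lambda).
#' @param cfg a [forest_config()].
#' @return a `randomForest` object with attribute `"n_dropped"`.
#' @export
fit_forest <- function(x, y, cfg = forest_config()) {
  x <- as.data.frame(x)
  cc <- stats::complete.cases(x) & !is.na(y)
  if (any(!cc)) {
    message(sum(!cc), " row(s) with missing values dropped before the forest")
    x <- x[cc, , drop = FALSE]
    y <- y[cc]
  }
  if (cfg$mtry > ncol(x)) stop("mtry exceeds the number of predictors")
  if (var(y) == 0) warning("constant response: all importances will be zero",
                           call. = FALSE)
  set.seed(cfg$seed)
  fo <- randomForest::randomForest(
    x = x, y = y, ntree = cfg$n_trees, mtry = cfg$mtry,
    nodesize = cfg$min_node, replace = cfg$bootstrap,
    sampsize = nrow(x), importance = cfg$bootstrap, keep.inbag = TRUE)
  attr(fo, "n_dropped") <- sum(!cc)
  fo
}

#' Permutation and impurity importance report
#'
#' Permutation importance is the mean increase in out-of-bag MSE after
#' permuting a predictor (unscaled), the primary screening metric; impurity
#' importance (total variance reduction at splits) is reported secondarily.
#'
#' @param forest a forest from [fit_forest()].
#' @return object of class `"importance_report"`: data frame (`predictor`,
#'   `permutation`, `impurity`, `rank`), ranked by permutation importance.
#' @export
importance_report <- function(forest) {
  imp <- randomForest::importance(forest, scale = FALSE)
  perm <- if ("%IncMSE" %in% colnames(imp)) imp[, "%IncMSE"] else
    rep(NA_real_, nrow(imp))
  out <- data.frame(predictor = rownames(imp), permutation = unname(perm),
                    impurity = unname(imp[, "IncNodePurity"]),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$permutation, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Variable screening rule
#'
#' `"group"` (default): keep the `keep` group (temperature predictors) when
#' every importance in the `drop` group (precipitation) lies strictly below
#' every importance in the `keep` group; if the groups interleave, all
#' predictors are retained with a message (the screen is inconclusive).
#' `"top_k"`: keep the k best-ranked predictors. `"threshold"`: keep
#' predictors at or above a permutation-importance threshold.
#'
#' @param report an [importance_report()].
#' @param rule screening rule.
#' @param groups for `"group"`: list with character vectors `keep` and
#'   `drop`.
#' @param k for `"top_k"`.
#' @param threshold for `"threshold"`.
#' @return character vector of kept predictors; errors if the rule would
#'   remove all predictors or (group rule) if all importances are zero.
#' @export
screen_variables <- function(report, rule = c("group", "top_k", "threshold"),
                             groups = NULL, k = NULL, threshold = NULL) {
  rule <- match.arg(rule)
  kept <- switch(rule,
    group = {
      stopifnot(!is.null(groups), all(c("keep", "drop") %in% names(groups)))
      if (all(report$permutation == 0)) {
        stop("all importances are zero; the screen is uninformative")
      }
      imp <- setNames(report$permutation, report$predictor)
      if (max(imp[groups$drop]) < min(imp[groups$keep])) {
        groups$keep
      } else {
        message("importance groups interleave; screen inconclusive, ",
                "keeping all predictors")
        report$predictor
      }
    },
    top_k = {
      stopifnot(!is.null(k))
      report$predictor[report$rank <= k]
    },
    threshold = {
      stopifnot(!is.null(threshold))
      report$predictor[report$permutation >= threshold]
    })
  if (length(kept) == 0) stop("screening rule removed all predictors")
  kept
}

# the twelve seasonal climate predictors of the screening step
.screen_predictors <- c(
  "winter_t", "spring_t", "summer_t", "prior_spring_t", "prior_summer_t",
  "prior_autumn_t", "winter_p", "spring_p", "summer_p", "prior_spring_p",
  "prior_summer_p", "prior_autumn_p")

#' Run the climate-variable pre-screen on a growth table
#'
#' Fits the screening forest of lambda on the twelve seasonal temperature
#' and precipitation variables and applies the group rule (temperatures vs
#' precipitation sums).
#'
#' @param growth growth table from [build_growth_table()].
#' @param cfg a [forest_config()].
#' @return list with `forest`, `report` and `kept`.
#' @export
run_screen <- function(growth, cfg = forest_config()) {
  x <- growth[.screen_predictors]
  fo <- fit_forest(x, growth$lambda, cfg)
  rep <- importance_report(fo)
  temps <- grep("_t$", .screen_predictors, value = TRUE)
  precs <- grep("_p$", .screen_predictors, value = TRUE)
  kept <- screen_variables(rep, "group", groups = list(keep = temps,
                                                       drop = precs))
  list(forest = fo, report = rep, kept = kept)
}
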