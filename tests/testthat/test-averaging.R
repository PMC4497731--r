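# model averaging: enumeration under marginality, Akaike weights, RVI,
# natural and zero methods, the interaction-conditional rule, and report
# formatting

test_that("enumeration respects marginality and matches the brute-force oracle", {
  got <- enumerate_models(c("A", "B", "A:B"))
  expect_length(got, 5)
  expect_setequal(term_set_key(got),
                  term_set_key(list(character(), "A", "B", c("A", "B"),
                                    c("A", "B", "A:B"))))
  # no interactions: 2^m subsets
  expect_length(enumerate_models(c("A", "B", "C")), 8)
  # shared parents and several interactions, versus the oracle
  for (base in list(c("A", "B", "C", "A:B", "A:C"),
                    c("A", "B", "C", "D", "A:B", "C:D"),
                    c("A", "B", "A:B", "C"))) {
    expect_setequal(term_set_key(enumerate_models(base)),
                    term_set_key(brute_force_subsets(base)))
  }
  expect_error(enumerate_models(c("A", "A:B")), "lacks a parent")
  expect_error(enumerate_models(LETTERS[1:10], cap = 100), "exceed the cap")
})

test_that("Akaike weights are normalized, symmetric and shift-invariant", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)))
  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(c(3, 7, 9) + 1000),
               akaike_weights(c(3, 7, 9)))
  expect_equal(sum(akaike_weights(rnorm(20, 100, 5))), 1, tolerance = 1e-12)
  expect_error(akaike_weights(numeric()), "empty")
  # exact fits absorb all weight
  expect_equal(akaike_weights(c(-Inf, 10, -Inf)), c(0.5, 0, 0.5))
})

test_that("RVI sums the weights of models containing the term", {
  set <- small_lm_set()
  for (tr in set$base_terms) {
    manual <- sum(set$weight[vapply(set$term_sets, function(tt)
      tr %in% tt, logical(1))])
    expect_equal(rvi(set, tr), manual)
    expect_gte(rvi(set, tr), 0)
    expect_lte(rvi(set, tr), 1)
  }
  expect_error(rvi(set, "nope"), "unknown term")
})

test_that("the natural average reproduces single members and the SE formula", {
  set <- small_lm_set()
  # a term present in exactly one member keeps that member's estimate and se
  only_full <- "x1:x2"
  idx <- which(vapply(set$term_sets, function(tt) only_full %in% tt,
                      logical(1)))
  expect_length(idx, 1)
  av <- average_natural(set, only_full)
  expect_equal(unname(av["estimate"]),
               unname(set$members[[idx]]$beta[only_full]))
  expect_equal(unname(av["se"]), unname(set$members[[idx]]$se[only_full]))
  # two members, equal weights, beta 1 and 3, se 0: estimate 2, SE 1
  est <- boargrowth:::.avg_core(beta = c(1, 3), se = c(0, 0), w = c(0.5, 0.5))
  expect_equal(unname(est), c(2, 1))
  # invariance under duplicating a member at half weight
  est2 <- boargrowth:::.avg_core(beta = c(1, 3, 3), se = c(0, 0, 0),
                                 w = c(0.5, 0.25, 0.25))
  expect_equal(est, est2)
})

test_that("the zero method equals the natural average times RVI", {
  set <- small_lm_set()
  for (tr in set$base_terms) {
    nat <- average_natural(set, tr)
    zer <- average_zero(set, tr)
    expect_equal(unname(zer["estimate"]),
                 unname(nat["estimate"]) * rvi(set, tr), tolerance = 1e-10)
  }
  # rvi 1 makes the methods identical
  set.seed(8)
  d <- data.frame(x = rnorm(80))
  d$y <- 3 * d$x + rnorm(80, 0, 0.2)
  strong <- fit_model_set(d, "y", "x", random = character())
  expect_gt(rvi(strong, "x"), 0.999999)
  expect_equal(average_zero(strong, "x")["estimate"],
               average_natural(strong, "x")["estimate"], tolerance = 1e-6)
})

test_that("the conditional rule is vacuous without interactions", {
  set.seed(11)
  d <- data.frame(a = rnorm(70), b = rnorm(70))
  d$y <- 0.5 * d$a + rnorm(70)
  set <- fit_model_set(d, "y", c("a", "b"), random = character())
  cond <- conditional_average(set)
  for (tr in c("a", "b")) {
    nat <- average_natural(set, tr)
    row <- cond[cond$term == tr, ]
    expect_equal(row$estimate, unname(nat["estimate"]))
    expect_equal(row$se, unname(nat["se"]))
  }
})

test_that("a significant interaction restricts its mains to models where it is significant", {
  # strong interaction: significant in the averaged result and in every
  # member containing it
  set.seed(21)
  n <- 300
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$y <- 0.5 * d$a + 0.3 * d$b + 1.5 * d$a * d$b + rnorm(n, 0, 0.5)
  set <- fit_model_set(d, "y", c("a", "b", "a:b"), random = character())
  cond <- conditional_average(set)
  full_idx <- which(vapply(set$term_sets, function(tt) "a:b" %in% tt,
                           logical(1)))
  expect_lt(cond[cond$term == "a:b", "p"], 0.05)
  # mains then average only over the (single) member with the significant
  # interaction: the full model
  for (tr in c("a", "b")) {
    row <- cond[cond$term == tr, ]
    expect_equal(row$n_models, length(full_idx))
    expect_equal(row$estimate,
                 unname(set$members[[full_idx]]$beta[tr]))
    expect_match(row$selection, "significant")
  }
})

test_that("a non-significant interaction excludes itself from its mains' averages", {
  set.seed(31)
  n <- 250
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$y <- 0.8 * d$a + 0.4 * d$b + rnorm(n, 0, 0.6)   # no real interaction
  set <- fit_model_set(d, "y", c("a", "b", "a:b"), random = character())
  cond <- conditional_average(set)
  int_p <- cond[cond$term == "a:b", "p"]
  if (int_p >= 0.05) {
    # mains averaged over models lacking the interaction or where it is ns
    in_int <- vapply(set$term_sets, function(tt) "a:b" %in% tt, logical(1))
    p_int <- rep(NA_real_, length(set$members))
    p_int[in_int] <- boargrowth:::member_p(set, which(in_int), "a:b")
    keep <- !in_int | p_int >= 0.05
    for (tr in c("a", "b")) {
      has <- vapply(set$term_sets, function(tt) tr %in% tt, logical(1))
      idx <- which(has & keep)
      manual <- boargrowth:::.avg_core(
        boargrowth:::member_beta(set, idx, tr),
        boargrowth:::member_se(set, idx, tr), set$weight[idx])
      row <- cond[cond$term == tr, ]
      expect_equal(row$estimate, unname(manual["estimate"]), tolerance = 1e-12)
      expect_equal(row$n_models, length(idx))
    }
  } else {
    succeed("interaction happened to be significant in this draw")
  }
})

test_that("report tables order by RVI then effect size and flag significance", {
  set <- small_lm_set()
  tab <- build_table(conditional_average(set))
  expect_named(tab, c("term", "estimate", "SE", "P", "RVI", "significant"))
  expect_true(all(diff(tab$RVI) <= 1e-12))
  ties <- which(abs(diff(tab$RVI)) < 1e-12)
  for (i in ties) expect_gte(abs(tab$estimate[i]), abs(tab$estimate[i + 1]))
  expect_true(all(grepl(": ", tab$term[grepl(":", tab$term)])))
  empty <- build_table(conditional_average(set)[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("restricting to low-delta subsets changes averages only slightly", {
  # well-behaved set: averaged estimates stable under delta-AICc < 4 / < 10
  set.seed(55)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 0.9 * d$a + 0.5 * d$b + rnorm(n)
  set <- fit_model_set(d, "y", c("a", "b", "c"), random = character())
  for (cut in c(4, 10)) {
    keep <- set$delta < cut
    sub <- set
    sub$members <- set$members[keep]
    sub$term_sets <- set$term_sets[keep]
    sub$aicc <- set$aicc[keep]
    sub$delta <- sub$aicc - min(sub$aicc)
    sub$weight <- akaike_weights(sub$aicc)
    for (tr in c("a", "b")) {
      full <- average_natural(set, tr)["estimate"]
      part <- average_natural(sub, tr)["estimate"]
      expect_lt(abs(part - full) / abs(full), 0.10)
    }
  }
})

test_that("model-averaged residuals are the weighted member residuals", {
  set <- small_lm_set()
  res <- averaged_residuals(set)
  manual <- Reduce(`+`, Map(function(m, w) w * m$residuals,
                            set$members, set$weight))
  expect_equal(res, unname(manual))
})
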