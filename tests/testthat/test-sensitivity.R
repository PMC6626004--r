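test_that("factorial designs enumerate the full cross with stable ids", {
  expect_equal(nrow(toy_design(1)$design), 2)
  d6 <- toy_design(6)
  expect_equal(nrow(d6$design), 64)
  expect_identical(d6$design$id, sprintf("S%03d", 1:64))
  # default specification: six analysis factors over seven design columns
  d <- build_factorial_design()
  expect_equal(nrow(d$design), 128)
  expect_equal(length(d$factors), 6)
  expect_equal(length(d$col_factor), 7)
  # every scenario parameter set validates and ids are in deterministic order
  expect_identical(d$design$id, sprintf("S%03d", 1:128))
})

test_that("conflicting factor patches are rejected", {
  sets <- default_parameter_sets()
  f1 <- factor_spec("a", "policy", list(cap = 100), list(cap = 200))
  f2 <- factor_spec("b", "policy", list(cap = 300), list(cap = 400))
  expect_error(build_factorial_design(list(f1, f2), base = sets[["2013"]]),
               "conflicting|duplicate")
})

test_that("logistic contrast models recover known coefficients in sign and rank", {
  design <- toy_design(6)
  X <- wolfpva:::factor_predictors(design)
  beta <- c(2, -1, 0, 0, 0, 0)
  eta <- -1 + as.matrix(X) %*% beta
  set.seed(42)
  n_iter <- 500
  ev <- rbinom(nrow(X), n_iter, plogis(eta))
  fac <- fake_results(design, ev, n_iter)
  m <- fit_contrast_model(fac, "extinction")
  expect_false(m$degenerate)
  expect_gt(m$coefficients[["f1"]], 0)
  expect_lt(m$coefficients[["f2"]], 0)
  # rank order of |z|: the two true effects dominate the four null factors
  ranks <- rank(-abs(m$standardized))
  expect_setequal(names(ranks)[ranks <= 2], c("f1", "f2"))
  expect_true(all(abs(m$standardized[c("f3", "f4", "f5", "f6")]) < 3))
  # coefficient estimates close to truth
  expect_lt(abs(m$coefficients[["f1"]] - 2), 0.3)
  expect_lt(abs(m$coefficients[["f2"]] + 1), 0.3)
})

test_that("a single-factor additive effect on diversity is recovered by the linear model", {
  design <- toy_design(6)
  X <- wolfpva:::factor_predictors(design)
  delta <- 0.04
  set.seed(9)
  gd <- 0.7 + delta * X$f1 + rnorm(nrow(X), 0, 0.005)
  fac <- design
  fac$results <- data.frame(id = design$design$id, n_ext = 0L, n_quasi = 0L,
                            p_ext = 0, p_quasi = 0, mean_GD = gd,
                            n_iter = 100L, seed = 1L)
  class(fac) <- c("pva_factorial", "pva_design")
  m <- fit_contrast_model(fac, "genetic_diversity")
  expect_equal(m$family, "linear")
  se_pred <- 0.005 / sqrt(nrow(X) / 4)
  expect_lt(abs(m$coefficients[["f1"]] - delta), 3 * se_pred)
})

test_that("degenerate responses are flagged and excluded", {
  fac <- fake_results(toy_design(3), rep(0L, 8))
  m <- fit_contrast_model(fac, "extinction")
  expect_true(m$degenerate)
  expect_true(all(is.na(m$standardized)))
  expect_error(contrast_shares(m), "no defined")
})

test_that("separation triggers the Firth fallback with finite estimates", {
  design <- toy_design(3)
  X <- wolfpva:::factor_predictors(design)
  ev <- ifelse(X$f1 == 1, 200L, 0L)   # perfectly separated
  fac <- fake_results(design, ev, 200)
  m <- fit_contrast_model(fac, "extinction")
  expect_true(m$firth)
  expect_true(all(is.finite(m$standardized)))
  expect_true(any(grepl("Firth", m$notes)))
  expect_gt(m$coefficients[["f1"]], 1)
})

test_that("shares split standardized coefficients proportionally and sum to 100", {
  m <- structure(list(
    response = "extinction", family = "binomial_logistic",
    coefficients = c(a = 1, b = 1), se = c(a = 1, b = 1),
    standardized = c(a = 3, b = -1),
    categories = c(a = "biological", b = "policy"),
    degenerate = FALSE, firth = FALSE, notes = character(0)),
    class = "contrast_model")
  s <- contrast_shares(m)
  expect_equal(s$factor_shares$share_pct, c(75, 25))
  expect_equal(sum(s$category_shares$share_pct), 100)
  # equal magnitudes share equally
  m$standardized <- stats::setNames(rep(2, 6), letters[1:6])
  m$categories <- stats::setNames(rep("mixed", 6), letters[1:6])
  m$coefficients <- m$se <- m$standardized
  expect_true(all(abs(contrast_shares(m)$factor_shares$share_pct - 100 / 6) < 1e-9))
  # invariance to rescaling all standardized coefficients
  m2 <- m
  m2$standardized <- m$standardized * 7.3
  expect_equal(contrast_shares(m2)$factor_shares$share_pct,
               contrast_shares(m)$factor_shares$share_pct)
})

test_that("the quartile coefficient of dispersion follows interpolated quartiles", {
  expect_equal(qcd(rep(3, 10)), 0)
  expect_equal(qcd(c(0, 0, 1, 1)), 1)
  # hand arithmetic with type-7 quartiles: Q1 = 2.75, Q3 = 6.25
  expect_equal(qcd(1:8), (6.25 - 2.75) / (6.25 + 2.75))
  # scale invariance and bounds
  x <- c(0.2, 0.9, 1.4, 3.3, 5.1, 0.05)
  expect_equal(qcd(x * 13), qcd(x))
  expect_true(qcd(x) >= 0 && qcd(x) <= 1)
  expect_error(qcd(c(-1, 2, 3, 4)), "nonnegative")
  expect_error(qcd(c(1, 2, 3)), "at least 4")
  expect_message(v <- qcd(c(0, 0, 0, 0)), "undefined")
  expect_true(is.na(v))
})

test_that("balanced designs give orthogonal main-effect estimates", {
  design <- toy_design(4)
  X <- wolfpva:::factor_predictors(design)
  set.seed(77)
  est <- replicate(60, {
    gd <- 0.7 + 0.03 * X$f1 - 0.02 * X$f2 + rnorm(nrow(X), 0, 0.01)
    fac <- design
    fac$results <- data.frame(id = design$design$id, n_ext = 0L, n_quasi = 0L,
                              p_ext = 0, p_quasi = 0, mean_GD = gd,
                              n_iter = 100L, seed = 1L)
    class(fac) <- c("pva_factorial", "pva_design")
    fit_contrast_model(fac, "genetic_diversity")$coefficients[c("f1", "f2")]
  })
  expect_lt(abs(cor(est[1, ], est[2, ])), 0.35)
})
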