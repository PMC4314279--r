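# Expression -> alkene regressions: exact fits, term selection, prediction.

test_that("noise-free data are fit exactly with R^2 = 1", {
  p <- ground_truth_params(alkene_resid_sd = 0)
  d <- generate_expression_scent(p, n_per_species = 60, seed = 2)
  fit <- fit_alkene_models(d)
  g <- glance(fit)
  expect_true(all(g$r.squared > 1 - 1e-9))
  # selected coefficients match the generating values
  td <- tidy(fit)
  m9 <- td[td$class == "alkene_9", ]
  expect_equal(
    m9$estimate[m9$term == "sqrt_sad2a"],
    p$alkene_coeffs$alkene_9[["sqrt_sad2a"]],
    tolerance = 1e-6
  )
  m7 <- td[td$class == "alkene_7", ]
  expect_equal(
    m7$estimate[m7$term == "sqrt_sad5a"],
    p$alkene_coeffs$alkene_7[["sqrt_sad5a"]],
    tolerance = 1e-6
  )
})

test_that("term selection recovers the generating structure at low noise", {
  p <- ground_truth_params(alkene_resid_sd = 0.3)
  d <- generate_expression_scent(p, n_per_species = 500, seed = 31)
  fit <- fit_alkene_models(d)
  # 7-alkenes depend only on SAD5A expression
  expect_setequal(fit$classes$alkene_7$terms, c("intercept", "sqrt_sad5a"))
  # 9-alkenes only on SAD2A
  expect_setequal(fit$classes$alkene_9$terms, c("intercept", "sqrt_sad2a"))
  # 12-alkenes on SAD2A and the SAD2A x SAD5A interaction
  expect_true(all(c("sqrt_sad2a", "interaction") %in% fit$classes$alkene_12$terms))
})

test_that("term selection equals an independent exhaustive best-AIC oracle", {
  # Random generating structures and noise levels; the candidate space has
  # only eight subsets per class, so exhaustive search is a complete oracle.
  for (s in 1:20) {
    set.seed(400 + s)
    coefs <- function() {
      c(intercept = runif(1, 0.5, 3),
        sqrt_sad2a = sample(c(0, runif(1, -1, 1.5)), 1),
        sqrt_sad5a = sample(c(0, runif(1, -1, 1.5)), 1),
        interaction = sample(c(0, 0, runif(1, -0.4, 0.4)), 1))
    }
    p <- ground_truth_params(
      alkene_coeffs = list(alkene_7 = coefs(), alkene_9 = coefs(), alkene_12 = coefs()),
      alkene_resid_sd = runif(1, 0.2, 1.2)
    )
    d <- generate_expression_scent(p, n_per_species = sample(15:60, 1), seed = 600 + s)
    fit <- fit_alkene_models(d)
    for (cl in c("alkene_7", "alkene_9", "alkene_12")) {
      oracle <- oracle_best_alkene_terms(d, cl)
      expect_setequal(fit$classes[[cl]]$terms, oracle$terms)
      expect_equal(fit$classes[[cl]]$aic, oracle$aic, tolerance = 1e-8)
    }
  }
})

test_that("greedy stepwise agrees with the exhaustive optimum on clear signal", {
  p <- ground_truth_params(alkene_resid_sd = 0.3)
  for (s in 1:5) {
    d <- generate_expression_scent(p, n_per_species = 200, seed = 800 + s)
    ex <- fit_alkene_models(d, method = "exhaustive")
    sw <- fit_alkene_models(d, method = "stepwise")
    for (cl in c("alkene_7", "alkene_9", "alkene_12")) {
      expect_setequal(sw$classes[[cl]]$terms, ex$classes[[cl]]$terms)
    }
  }
})

test_that("predictions are nonnegative, baselined, and monotone", {
  truth <- ophrys_ground_truth()
  fit <- alkene_model_from_truth(truth)
  # zero expression returns the back-transformed intercepts
  base <- predict_alkenes(fit, tibble::tibble(sad2a_expr = 0, sad5a_expr = 0))
  expect_equal(base$alkene_7, exp(truth$alkene_coeffs$alkene_7[["intercept"]]) - 1)
  expect_equal(base$alkene_9, exp(truth$alkene_coeffs$alkene_9[["intercept"]]) - 1)
  # O. sphegodes pattern: high SAD2A, no SAD5A -> 9-/12-alkenes dominate
  sph <- predict_alkenes(fit, tibble::tibble(sad2a_expr = 4, sad5a_expr = 0))
  expect_gt(sph$alkene_9, 10 * sph$alkene_7)
  expect_gt(sph$alkene_12, 10 * sph$alkene_7)
  # positive sqrt_sad5a slope: alkene_7 nondecreasing in sad5a expression
  grid <- tibble::tibble(sad2a_expr = 0, sad5a_expr = seq(0, 8, length.out = 30))
  pred <- predict_alkenes(fit, grid)
  expect_true(all(diff(pred$alkene_7) >= 0))
  # all-finite, nonnegative over a wide nonnegative input range
  wide <- tidyr::expand_grid(sad2a_expr = seq(0, 50, 5), sad5a_expr = seq(0, 50, 5))
  pw <- predict_alkenes(fit, wide)
  expect_true(all(is.finite(as.matrix(pw))) && all(as.matrix(pw) >= 0))
})

test_that("degenerate and invalid inputs raise informative errors", {
  truth <- ophrys_ground_truth()
  d <- generate_expression_scent(truth, n_per_species = 10, seed = 1)
  expect_error(fit_alkene_models(d[1:4, ]), class = "ophrysim_underdetermined_fit")
  expect_error(predict_alkenes(list(), tibble::tibble()), "alkene_fit")
  fit <- alkene_model_from_truth(truth)
  expect_error(
    predict_alkenes(fit, tibble::tibble(sad2a_expr = -1, sad5a_expr = 0)),
    "nonnegative"
  )
  # constant response: intercept-only with R^2 reported as 0
  dc <- d
  dc$alkene_7 <- 2
  fc <- fit_alkene_models(dc)
  expect_identical(fc$classes$alkene_7$terms, "intercept")
  expect_identical(fc$classes$alkene_7$r_squared, 0)
})
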