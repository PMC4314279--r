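# Permutation expansion and Poisson attraction models.

make_trials <- function(n_per_group = 10, seed = 77) {
  generate_choice_trials(ophrys_ground_truth(), n_trials_per_group = n_per_group,
                         seed = seed)
}

test_that("permutation conserves group-wise visit multisets and row counts", {
  trials <- make_trials(10)
  expanded <- permute_within_groups(trials, n_perm = 300, seed = 1)
  expect_identical(nrow(expanded), 12000L)
  # per group and round, the multiset of visit counts equals the original
  for (g in unique(trials$group)) {
    orig_cc <- sort(trials$visits_cc[trials$group == g])
    orig_an <- sort(trials$visits_an[trials$group == g])
    sub <- expanded[expanded$group == g, ]
    per_round_ok <- tapply(seq_len(nrow(sub)), sub$perm, function(i) {
      identical(sort(sub$visits_cc[i]), orig_cc) &&
        identical(sort(sub$visits_an[i]), orig_an)
    })
    expect_true(all(per_round_ok))
  }
  # determinism
  expect_identical(expanded, permute_within_groups(trials, n_perm = 300, seed = 1))
})

test_that("a singleton group expands to identical copies of its only pairing", {
  trials <- make_trials(1)
  expanded <- permute_within_groups(trials, n_perm = 25, seed = 2)
  expect_identical(nrow(expanded), 100L)
  for (g in trials$group) {
    sub <- expanded[expanded$group == g, ]
    expect_true(all(sub$visits_cc == trials$visits_cc[trials$group == g]))
  }
})

test_that("an empty treatment group is rejected by name", {
  trials <- make_trials(4)
  crippled <- trials[trials$group != "exaltata_scent", ]
  expect_error(permute_within_groups(crippled, 10),
               "exaltata_scent", class = "ophrysim_empty_group")
})

test_that("constant counts select the intercept-only model at ln(k)", {
  trials <- make_trials(8)
  trials$visits_cc <- 3
  expanded <- permute_within_groups(trials, n_perm = 20, seed = 3)
  fit <- fit_attraction_glm(expanded, "cc")
  expect_identical(fit$terms, "intercept")
  expect_equal(unname(fit$estimate[["intercept"]]), log(3), tolerance = 1e-8)
})

test_that("selection recovers a known single-term Poisson truth", {
  set.seed(88)
  n <- 400
  df <- tibble::tibble(
    group = rep(c("sphegodes_scent", "sphegodes_plus7", "exaltata_scent",
                  "exaltata_plus9_12"), each = n / 4),
    alkene_7 = runif(n, 0, 30),
    alkene_9 = runif(n, 0, 30),
    alkene_12 = runif(n, 0, 30)
  )
  df$visits_cc <- rpois(n, exp(0.5 + 0.1 * df$alkene_7))
  df$visits_an <- rpois(n, 1)
  fit <- fit_attraction_glm(df, "cc")
  expect_setequal(fit$terms, c("intercept", "alkene_7"))
  ci <- fit$ci["alkene_7", ]
  expect_true(ci[["conf.low"]] <= 0.1 && 0.1 <= ci[["conf.high"]])
  # stepwise hierarchy search agrees with the exhaustive search here too
  fit_sw <- fit_attraction_glm(df, "cc", method = "stepwise")
  expect_setequal(fit_sw$terms, fit$terms)
})

test_that("subset selection equals the exhaustive 27-subset oracle", {
  for (s in 1:8) {
    set.seed(900 + s)
    n <- 250
    df <- tibble::tibble(
      alkene_7 = runif(n, 0, 30), alkene_9 = runif(n, 0, 30),
      alkene_12 = runif(n, 0, 30)
    )
    b <- c(runif(1, -0.5, 0.8), runif(3, -0.05, 0.08), runif(3, -0.002, 0.001))
    lp <- b[1] + b[2] * df$alkene_7 + b[3] * df$alkene_9 + b[4] * df$alkene_12 +
      b[5] * df$alkene_7^2 + b[6] * df$alkene_9^2 + b[7] * df$alkene_12^2
    df$visits_cc <- rpois(n, exp(pmin(lp, 4)))
    fit_ex <- fit_attraction_glm(df, "cc", method = "exhaustive")
    oracle <- oracle_best_attraction_terms(df, "visits_cc")
    expect_setequal(fit_ex$terms, oracle$terms)
    expect_equal(fit_ex$aic, oracle$aic, tolerance = 1e-8)
  }
})

test_that("predictions are positive with an interior optimum under concavity", {
  truth <- ophrys_ground_truth()
  # intercept-only model at 0 predicts exactly 1 anywhere
  p0 <- ground_truth_params(attraction_coeffs = list(
    C_cunicularius = c(intercept = 0, alkene_7 = 0, alkene_9 = 0, alkene_12 = 0,
                       alkene_7_sq = 0, alkene_9_sq = 0, alkene_12_sq = 0),
    A_nigroaenea = c(intercept = 0, alkene_7 = 0, alkene_9 = 0, alkene_12 = 0,
                     alkene_7_sq = 0, alkene_9_sq = 0, alkene_12_sq = 0)
  ))
  m0 <- attraction_model_from_truth(p0, "cc")
  amounts <- tibble::tibble(alkene_7 = c(0, 5, 50), alkene_9 = 0, alkene_12 = 0)
  expect_equal(predict_attraction(m0, amounts), rep(1, 3))

  # fixture C. cunicularius model: positive linear, negative quadratic in
  # 7-alkenes -> interior maximum along the alkene_7 axis
  mcc <- attraction_model_from_truth(truth, "cc")
  grid <- tibble::tibble(alkene_7 = seq(0, 80, 0.5), alkene_9 = 0, alkene_12 = 0)
  pred <- predict_attraction(mcc, grid)
  expect_true(all(pred > 0) && all(is.finite(pred)))
  peak <- which.max(pred)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(grid))
})

test_that("count validation rejects negative or fractional visits", {
  trials <- make_trials(5)
  bad <- trials
  bad$visits_cc[3] <- 1.5
  expect_error(fit_attraction_glm(bad, "cc"), "integer")
  bad2 <- trials
  bad2$visits_an[1] <- -2
  expect_error(fit_attraction_glm(bad2, "an"), "nonnegative")
})
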