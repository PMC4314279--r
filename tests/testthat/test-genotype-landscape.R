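# Genotype enumeration, dosage/suppression, scaling, CI perturbation.

test_that("genotype enumeration covers the diploid space exactly once", {
  g9 <- enumerate_genotypes()
  expect_identical(nrow(g9), 9L)
  expect_identical(anyDuplicated(g9$label), 0L)
  expect_identical(sum(g9$label == "++/--"), 1L)
  expect_identical(sum(g9$label == "--/++"), 1L)
  expect_identical(g9$label[1], "++/--")   # canonical order starts sphegodes-like
  expect_identical(g9$label[9], "--/++")

  g27 <- enumerate_genotypes(include_sus = TRUE)
  expect_identical(nrow(g27), 27L)
  expect_identical(anyDuplicated(g27$label), 0L)
  # matches brute-force enumeration of unordered diploid combinations
  expect_setequal(
    g27$label,
    as.vector(outer(
      as.vector(outer(c("++", "+-", "--"), c("++", "+-", "--"), paste, sep = "/")),
      c("SS", "Ss", "ss"), paste, sep = "/"
    ))
  )
})

test_that("dosage is additive and SUS suppression is dominant", {
  refs <- c(sad2a = 4, sad5a = 6.25)
  g <- tibble::tibble(
    sad2 = c(2L, 1L, 0L, 1L, 2L),
    sad5 = c(0L, 2L, 1L, 2L, 2L),
    sus = c(0L, 1L, 0L, 0L, 2L)
  )
  e <- genotype_expression(g, refs)
  expect_equal(e$sad2a_expr, c(4, 2, 0, 2, 4))
  # row 2: one S allele silences SAD5 despite the ++ genotype; row 5: SS too
  expect_equal(e$sad5a_expr, c(0, 0, 3.125, 6.25, 0))
  expect_error(genotype_expression(g, c(sad2a = 0, sad5a = 1)), "positive")
})

test_that("attraction scaling is relative to the pure-species reference", {
  expect_equal(scale_attraction(c(0, 2, 4, 8), 4), c(0, 0.5, 1, 2))
  expect_error(scale_attraction(1, 0), "positive")
  land <- fixture_point_landscape(include_sus = FALSE)
  expect_equal(land$attraction_cc_point[land$label == "--/++"], 1)
  expect_equal(land$attraction_an_point[land$label == "++/--"], 1)
  expect_equal(land$attraction_cc_mean[land$label == "--/++"], 1)
})

test_that("point CIs collapse the perturbation to the plug-in prediction", {
  truth <- ophrys_ground_truth()
  args <- list(
    enumerate_genotypes(), alkene_model_from_truth(truth),
    attraction_model_from_truth(truth, "cc"),
    attraction_model_from_truth(truth, "an"),
    reference_expression(truth)
  )
  land <- do.call(predict_genotype_landscape, c(args, n_perturb = 5, seed = 2))
  expect_equal(land$attraction_cc_mean, land$attraction_cc_point, tolerance = 1e-12)
  expect_equal(land$attraction_an_mean, land$attraction_an_point, tolerance = 1e-12)
  expect_lt(max(land$attraction_cc_sd), 1e-10)
  expect_lt(max(land$alkene_7_sd), 1e-10)

  # intervals widen monotonically with the CI width
  args_narrow <- list(
    enumerate_genotypes(), alkene_model_from_truth(truth, ci_rel_halfwidth = 0.02),
    attraction_model_from_truth(truth, "cc", ci_rel_halfwidth = 0.02),
    attraction_model_from_truth(truth, "an", ci_rel_halfwidth = 0.02),
    reference_expression(truth)
  )
  args_wide <- list(
    enumerate_genotypes(), alkene_model_from_truth(truth, ci_rel_halfwidth = 0.2),
    attraction_model_from_truth(truth, "cc", ci_rel_halfwidth = 0.2),
    attraction_model_from_truth(truth, "an", ci_rel_halfwidth = 0.2),
    reference_expression(truth)
  )
  narrow <- do.call(predict_genotype_landscape, c(args_narrow, n_perturb = 200, seed = 3))
  wide <- do.call(predict_genotype_landscape, c(args_wide, n_perturb = 200, seed = 3))
  expect_true(mean(narrow$attraction_cc_hi - narrow$attraction_cc_lo) <
                mean(wide$attraction_cc_hi - wide$attraction_cc_lo))
  # the reference genotype still scales to exactly 1 in every round
  expect_equal(wide$attraction_cc_mean[wide$label == "--/++"], 1)
  expect_lt(wide$attraction_cc_sd[wide$label == "--/++"], 1e-10)
})

test_that("suppressor genotypes share 7-alkene predictions with sad5-null ones", {
  land <- fixture_point_landscape(include_sus = TRUE)
  for (i in which(land$sus >= 1)) {
    counterpart <- land[land$sad2 == land$sad2[i] & land$sad5 == 0 & land$sus == 0, ]
    expect_equal(land$alkene_7_mean[i], counterpart$alkene_7_mean)
  }
})

test_that("net allele-gain effects average one-step landscape differences", {
  flat <- flat_landscape(0.4, include_sus = FALSE)
  expect_identical(net_allele_gain_effect(flat, "SAD2", "an"), 0)
  expect_identical(net_allele_gain_effect(flat, "SAD5", "cc"), 0)

  # telescoping over a single SAD2-background column
  land <- fixture_point_landscape(include_sus = FALSE)
  col0 <- land[land$sad2 == 0, ]
  v <- setNames(col0$attraction_cc_mean, col0$sad5)
  expect_equal(
    net_allele_gain_effect(col0, "SAD5", "cc"),
    unname((v[["2"]] - v[["0"]]) / 2)
  )
  # missing gain targets are detected
  expect_error(net_allele_gain_effect(land[land$sad5 != 2, ], "SAD5", "cc"),
               "cover")
})
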