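# Model step 3: enumerate SAD2/SAD5 (and optionally SUS) genotypes, push them
# through the fitted models with confidence-interval perturbation, and report
# scaled pollinator attraction and net allele-gain effects.

#' Enumerate diploid genotypes at the SAD loci
#'
#' Enumerates all unordered diploid combinations of the functional ("+") and
#' nonfunctional ("-") allele at *SAD2* and *SAD5*: nine two-locus genotypes.
#' With `include_sus = TRUE` the dominant suppressor locus *SUS* (alleles "S"
#' dominant suppressor / "s" inactive) is added, giving 27 three-locus
#' genotypes. The order is stable and canonical: *SAD2* count descending
#' (so "++/--", the *O. sphegodes*-like genotype, comes first), then *SAD5*
#' count ascending, then *SUS* count ascending.
#'
#' @param include_sus Include the suppressor locus? Default `FALSE`.
#' @return A tibble with integer allele counts `sad2`, `sad5`, `sus` and the
#'   conventional `label` (e.g. `"++/--"`, `"+-/+-/Ss"`).
#' @examples
#' enumerate_genotypes()               # 9 rows
#' nrow(enumerate_genotypes(TRUE))     # 27
#' @export
enumerate_genotypes <- function(include_sus = FALSE) {
  sus_levels <- if (include_sus) 0:2 else 0L
  g <- expand.grid(sus = sus_levels, sad5 = 0:2, sad2 = 2:0)
  g <- as_tibble(g[, c("sad2", "sad5", "sus")])
  g$label <- if (include_sus) {
    genotype_label(g$sad2, g$sad5, g$sus)
  } else {
    genotype_label(g$sad2, g$sad5)
  }
  g
}

#' Allelic expression implied by a genotype
#'
#' Applies additive dosage (each "+" allele contributes half the homozygote
#' reference expression) and dominant suppression: any genotype carrying at
#' least one "S" allele at *SUS* has its *SAD5A* expression forced to zero
#' regardless of the *SAD5* genotype.
#'
#' @param genotypes Tibble from [enumerate_genotypes()] (columns `sad2`,
#'   `sad5`, and optionally `sus`).
#' @param ref_expr Named vector `c(sad2a=, sad5a=)` of positive homozygote
#'   reference expression (raw scale), e.g. [reference_expression()].
#' @return The input with raw-scale `sad2a_expr` and `sad5a_expr` columns
#'   appended.
#' @examples
#' genotype_expression(enumerate_genotypes(), c(sad2a = 4, sad5a = 6.25))
#' @export
genotype_expression <- function(genotypes, ref_expr) {
  assert_columns(genotypes, c("sad2", "sad5"), "`genotypes`")
  if (!all(c("sad2a", "sad5a") %in% names(ref_expr)) ||
      any(!is.finite(ref_expr)) || any(ref_expr <= 0)) {
    abort("`ref_expr` must be positive values named sad2a and sad5a")
  }
  sus <- genotypes$sus %||% rep(0L, nrow(genotypes))
  genotypes %>%
    mutate(
      sad2a_expr = .data$sad2 / 2 * ref_expr[["sad2a"]],
      sad5a_expr = ifelse(sus >= 1, 0, .data$sad5 / 2 * ref_expr[["sad5a"]])
    )
}

#' Scale raw attraction to the pure-species reference
#'
#' Pollinator attraction is reported relative to the raw predicted attraction
#' of the pure-species genotype for that pollinator ("--/++" for
#' *C. cunicularius*, "++/--" for *A. nigroaenea*), so the reference genotype
#' maps to exactly 1. Values above 1 are reported unclipped; clipping to
#' \[0, 1\] happens only inside the simulator's visitation weights.
#'
#' @param raw Nonnegative raw attraction value(s).
#' @param reference_raw Positive raw attraction of the reference genotype.
#' @return `raw / reference_raw`.
#' @examples
#' scale_attraction(c(0, 2, 4), 4)
#' @export
scale_attraction <- function(raw, reference_raw) {
  if (any(!is.finite(reference_raw)) || any(reference_raw <= 0)) {
    abort("`reference_raw` must be positive")
  }
  raw / reference_raw
}

check_model_cis <- function(object, what) {
  if (is.null(object$ci) || any(!is.finite(object$ci))) {
    abort(sprintf("%s has missing confidence intervals; refit or use a plug-in model", what))
  }
  invisible(object)
}

# One coefficient-draw matrix per alkene class / pollinator model.
draw_alkene_coefs <- function(alkene_fit, n) {
  lapply(alkene_fit$classes, function(m) {
    draws <- draw_within_ci(m$ci, n)
    colnames(draws) <- names(m$estimate)
    draws
  })
}

draw_attraction_coefs <- function(fit, n) {
  draws <- draw_within_ci(fit$ci, n)
  colnames(draws) <- names(fit$estimate)
  draws
}

# n x 3 matrix of alkene amounts for one genotype across coefficient draws.
perturbed_amounts <- function(alkene_draws, s2, s5) {
  vals <- vapply(names(alkene_draws), function(cl) {
    draws <- alkene_draws[[cl]]
    term_vals <- c(intercept = 1, sqrt_sad2a = s2, sqrt_sad5a = s5,
                   interaction = s2 * s5)
    lp <- as.vector(draws %*% term_vals[colnames(draws)])
    pmax(expm1(lp), 0)
  }, numeric(nrow(alkene_draws[[1]])))
  matrix(vals, ncol = 3, dimnames = list(NULL, ALKENE_CLASSES))
}

# n-vector of raw attraction across coefficient draws, given an n x 3 amounts
# matrix from the same draws.
perturbed_attraction <- function(attr_draws, amounts) {
  term_mat <- cbind(
    intercept = 1,
    alkene_7 = amounts[, 1], alkene_9 = amounts[, 2], alkene_12 = amounts[, 3],
    alkene_7_sq = amounts[, 1]^2, alkene_9_sq = amounts[, 2]^2,
    alkene_12_sq = amounts[, 3]^2
  )
  lp <- rowSums(attr_draws * term_mat[, colnames(attr_draws), drop = FALSE])
  exp(lp)
}

#' Predict the genotype attraction landscape with CI perturbation
#'
#' For each genotype, computes allelic expression (additive dosage, dominant
#' *SUS* suppression), predicted alkene amounts and raw attraction to both
#' pollinators, repeating the calculation `n_perturb` times with every model
#' coefficient drawn independently and uniformly within its 95% confidence
#' interval. Within each perturbation round, raw attraction is scaled to that
#' round's pure-species reference ("--/++" for *C. cunicularius*, "++/--" for
#' *A. nigroaenea*; both computed with `sus = 0`), so the reference genotype
#' scales to exactly 1 in every round. Plug-in (unperturbed point-estimate)
#' predictions are reported alongside; these are what the population
#' simulator caches.
#'
#' @param genotypes Tibble from [enumerate_genotypes()].
#' @param alkene_fit An [fit_alkene_models()] or [alkene_model_from_truth()]
#'   object.
#' @param attraction_cc,attraction_an Fitted [fit_attraction_glm()] (or
#'   plug-in) models for *C. cunicularius* and *A. nigroaenea*.
#' @param ref_expr Homozygote reference expression, as in
#'   [genotype_expression()].
#' @param n_perturb Number of perturbation rounds (default 500).
#' @param seed RNG seed for the coefficient draws.
#' @return An `ophrys_landscape` tibble: one row per genotype with alkene
#'   means/SDs over rounds, scaled attraction mean and 95% percentile
#'   interval per pollinator, and `attraction_cc_point` /
#'   `attraction_an_point` plug-in values.
#' @examples
#' truth <- ophrys_ground_truth()
#' land <- predict_genotype_landscape(
#'   enumerate_genotypes(), alkene_model_from_truth(truth),
#'   attraction_model_from_truth(truth, "cc"),
#'   attraction_model_from_truth(truth, "an"),
#'   ref_expr = reference_expression(truth), n_perturb = 10, seed = 1
#' )
#' land[, c("label", "attraction_cc_mean", "attraction_an_mean")]
#' @export
predict_genotype_landscape <- function(genotypes, alkene_fit,
                                       attraction_cc, attraction_an,
                                       ref_expr, n_perturb = 500, seed = NULL) {
  stopifnot(inherits(alkene_fit, "alkene_fit"),
            inherits(attraction_cc, "attraction_fit"),
            inherits(attraction_an, "attraction_fit"))
  n_perturb <- as.integer(n_perturb)
  if (!is.finite(n_perturb) || n_perturb < 1) abort("`n_perturb` must be >= 1")
  for (m in alkene_fit$classes) {
    if (any(!is.finite(m$ci))) abort("alkene model has missing confidence intervals")
  }
  check_model_cis(attraction_cc, "C. cunicularius attraction model")
  check_model_cis(attraction_an, "A. nigroaenea attraction model")

  geno <- genotype_expression(genotypes, ref_expr)
  # Reference genotypes for scaling, always evaluated without suppression.
  refs <- genotype_expression(
    tibble(sad2 = c(0L, 2L), sad5 = c(2L, 0L), sus = c(0L, 0L)), ref_expr
  )

  with_seed_or_not(seed, {
    alkene_draws <- draw_alkene_coefs(alkene_fit, n_perturb)
    cc_draws <- draw_attraction_coefs(attraction_cc, n_perturb)
    an_draws <- draw_attraction_coefs(attraction_an, n_perturb)

    eval_geno <- function(s2expr, s5expr) {
      amounts <- perturbed_amounts(alkene_draws, sqrt(s2expr), sqrt(s5expr))
      list(
        amounts = amounts,
        cc = perturbed_attraction(cc_draws, amounts),
        an = perturbed_attraction(an_draws, amounts)
      )
    }

    ref_cc <- eval_geno(refs$sad2a_expr[1], refs$sad5a_expr[1])$cc
    ref_an <- eval_geno(refs$sad2a_expr[2], refs$sad5a_expr[2])$an

    # Plug-in references from point estimates.
    point <- plugin_predictions(geno, refs, alkene_fit, attraction_cc, attraction_an)

    rows <- purrr::map_dfr(seq_len(nrow(geno)), function(i) {
      ev <- eval_geno(geno$sad2a_expr[i], geno$sad5a_expr[i])
      cc_scaled <- scale_attraction(ev$cc, ref_cc)
      an_scaled <- scale_attraction(ev$an, ref_an)
      tibble(
        alkene_7_mean = mean(ev$amounts[, 1]), alkene_7_sd = sd_or_zero(ev$amounts[, 1]),
        alkene_9_mean = mean(ev$amounts[, 2]), alkene_9_sd = sd_or_zero(ev$amounts[, 2]),
        alkene_12_mean = mean(ev$amounts[, 3]), alkene_12_sd = sd_or_zero(ev$amounts[, 3]),
        attraction_cc_mean = mean(cc_scaled),
        attraction_cc_lo = unname(quantile(cc_scaled, 0.025)),
        attraction_cc_hi = unname(quantile(cc_scaled, 0.975)),
        attraction_cc_sd = sd_or_zero(cc_scaled),
        attraction_an_mean = mean(an_scaled),
        attraction_an_lo = unname(quantile(an_scaled, 0.025)),
        attraction_an_hi = unname(quantile(an_scaled, 0.975)),
        attraction_an_sd = sd_or_zero(an_scaled)
      )
    })

    out <- dplyr::bind_cols(geno, rows, point)
    attr(out, "n_perturb") <- n_perturb
    attr(out, "ref_expr") <- ref_expr
    class(out) <- c("ophrys_landscape", class(out))
    out
  })
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

plugin_predictions <- function(geno, refs, alkene_fit, attraction_cc, attraction_an) {
  amounts <- predict_alkenes(alkene_fit, geno)
  ref_amounts <- predict_alkenes(alkene_fit, refs)
  raw_cc <- predict_attraction(attraction_cc, amounts)
  raw_an <- predict_attraction(attraction_an, amounts)
  ref_cc <- predict_attraction(attraction_cc, ref_amounts[1, ])
  ref_an <- predict_attraction(attraction_an, ref_amounts[2, ])
  tibble(
    attraction_cc_point = scale_attraction(raw_cc, ref_cc),
    attraction_an_point = scale_attraction(raw_an, ref_an)
  )
}

#' Net change in scaled attraction on gaining a functional allele
#'
#' For every genotype in the landscape with fewer than two functional alleles
#' at the focal locus, computes the change in mean scaled attraction when one
#' "-" allele is replaced by "+" (holding the other locus and the *SUS*
#' genotype fixed), and returns the unweighted mean over those background
#' genotypes. This is the per-locus "net allele-gain effect" summarising the
#' fitness landscape's sensitivity to each desaturase.
#'
#' @param landscape An `ophrys_landscape` tibble.
#' @param locus `"SAD2"` or `"SAD5"`.
#' @param pollinator `"C_cunicularius"`/`"cc"` or `"A_nigroaenea"`/`"an"`.
#' @param column Which landscape column to difference: `"mean"` (perturbation
#'   mean, default) or `"point"` (plug-in).
#' @return A single number: the average change in scaled attraction.
#' @examples
#' truth <- ophrys_ground_truth()
#' land <- predict_genotype_landscape(
#'   enumerate_genotypes(), alkene_model_from_truth(truth),
#'   attraction_model_from_truth(truth, "cc"),
#'   attraction_model_from_truth(truth, "an"),
#'   reference_expression(truth), n_perturb = 1
#' )
#' net_allele_gain_effect(land, "SAD5", "cc")
#' @export
net_allele_gain_effect <- function(landscape, locus = c("SAD2", "SAD5"),
                                   pollinator = c("C_cunicularius", "A_nigroaenea"),
                                   column = c("mean", "point")) {
  locus <- match.arg(locus)
  pollinator <- normalize_pollinator(pollinator)
  column <- match.arg(column)
  suffix <- if (pollinator == "C_cunicularius") "cc" else "an"
  col <- paste0("attraction_", suffix, "_", column)
  assert_columns(landscape, c("sad2", "sad5", col), "`landscape`")
  focal <- if (locus == "SAD2") "sad2" else "sad5"
  other <- if (locus == "SAD2") "sad5" else "sad2"
  sus <- landscape$sus %||% rep(0L, nrow(landscape))

  key <- paste(landscape[[focal]], landscape[[other]], sus)
  val <- setNames(landscape[[col]], key)
  backgrounds <- landscape[landscape[[focal]] < 2, ]
  bg_sus <- sus[landscape[[focal]] < 2]
  gains <- vapply(seq_len(nrow(backgrounds)), function(i) {
    from <- paste(backgrounds[[focal]][i], backgrounds[[other]][i], bg_sus[i])
    to <- paste(backgrounds[[focal]][i] + 1L, backgrounds[[other]][i], bg_sus[i])
    if (!to %in% names(val)) {
      abort("landscape must cover all genotypes reachable by a single allele gain")
    }
    val[[to]] - val[[from]]
  }, numeric(1))
  mean(gains)
}
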