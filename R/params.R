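# Ground-truth parameter sets for the synthetic-data generator.

ALKENE_CLASSES <- c("alkene_7", "alkene_9", "alkene_12")
ALKENE_TERMS <- c("intercept", "sqrt_sad2a", "sqrt_sad5a", "interaction")
ATTRACTION_TERMS <- c(
  "intercept",
  "alkene_7", "alkene_9", "alkene_12",
  "alkene_7_sq", "alkene_9_sq", "alkene_12_sq"
)
POLLINATORS <- c("C_cunicularius", "A_nigroaenea")
CHOICE_GROUPS <- c(
  "sphegodes_scent", "sphegodes_plus7", "exaltata_scent", "exaltata_plus9_12"
)

#' Construct a ground-truth parameter set for the synthetic-data generator
#'
#' The generator draws species-level allelic expression of the functional
#' alleles *SAD2A* and *SAD5A* on the square-root scale, converts expression to
#' ln(amount + 1) alkene amounts through a linear model with an optional
#' expression interaction, and converts alkene amounts to Poisson visit counts
#' of the two pollinators through a log-quadratic attraction model. All
#' coefficients live on those transformed scales.
#'
#' Defaults are the calibrated constants of [ophrys_ground_truth()]; pass
#' individual arguments to deviate from them.
#'
#' @param expr_means Named list with elements `sphegodes` and `exaltata`, each
#'   a named vector `c(sad2a=, sad5a=)` of mean allelic expression on the
#'   sqrt scale. A mean of exactly 0 encodes an unexpressed allele class.
#' @param expr_sd Standard deviation of sqrt-scale expression around the
#'   species mean (truncated at zero).
#' @param alkene_coeffs Named list over `alkene_7`, `alkene_9`, `alkene_12`;
#'   each element a named vector over terms `intercept`, `sqrt_sad2a`,
#'   `sqrt_sad5a`, `interaction`, giving coefficients of the ln(amount + 1)
#'   response.
#' @param alkene_resid_sd Residual SD of the ln(amount + 1) alkene response.
#' @param attraction_coeffs Named list over pollinators `C_cunicularius` and
#'   `A_nigroaenea`; each element a named vector over `intercept`, the three
#'   linear alkene terms and the three `_sq` quadratic terms, giving the
#'   log-mean visit count as a function of absolute alkene amounts.
#' @param n_per_species Number of individuals generated per species.
#' @param seed Default RNG seed used by the generators.
#' @return A validated list of class `ophrys_truth`.
#' @seealso [generate_expression_scent()], [generate_choice_trials()],
#'   [alkene_model_from_truth()], [attraction_model_from_truth()]
#' @export
ground_truth_params <- function(expr_means = NULL,
                                expr_sd = 0.4,
                                alkene_coeffs = NULL,
                                alkene_resid_sd = 1.1,
                                attraction_coeffs = NULL,
                                n_per_species = 30,
                                seed = 101) {
  if (is.null(expr_means)) {
    expr_means <- list(
      sphegodes = c(sad2a = 2.0, sad5a = 0.4),
      exaltata  = c(sad2a = 0.4, sad5a = 2.5)
    )
  }
  if (is.null(alkene_coeffs)) {
    alkene_coeffs <- list(
      alkene_7  = c(intercept = 0.1, sqrt_sad2a = 0.0, sqrt_sad5a = 1.4, interaction = 0.00),
      alkene_9  = c(intercept = 0.1, sqrt_sad2a = 1.5, sqrt_sad5a = 0.0, interaction = 0.00),
      alkene_12 = c(intercept = 0.1, sqrt_sad2a = 1.2, sqrt_sad5a = 0.0, interaction = -0.35)
    )
  }
  if (is.null(attraction_coeffs)) {
    attraction_coeffs <- list(
      C_cunicularius = c(
        intercept = -1.35,
        alkene_7 = 0.16, alkene_9 = -0.08, alkene_12 = -0.05,
        alkene_7_sq = -0.002, alkene_9_sq = 0, alkene_12_sq = 0
      ),
      A_nigroaenea = c(
        intercept = 1.62,
        alkene_7 = -0.12, alkene_9 = 0.00065, alkene_12 = -0.00175,
        alkene_7_sq = 0, alkene_9_sq = 0, alkene_12_sq = 0.001536
      )
    )
  }

  params <- structure(
    list(
      expr_means = expr_means,
      expr_sd = expr_sd,
      alkene_coeffs = alkene_coeffs,
      alkene_resid_sd = alkene_resid_sd,
      attraction_coeffs = attraction_coeffs,
      n_per_species = as.integer(n_per_species),
      seed = as.integer(seed)
    ),
    class = "ophrys_truth"
  )
  validate_ground_truth(params)
}

validate_ground_truth <- function(params) {
  if (!setequal(names(params$expr_means), c("sphegodes", "exaltata"))) {
    abort("`expr_means` must have elements 'sphegodes' and 'exaltata'")
  }
  for (sp in names(params$expr_means)) {
    m <- params$expr_means[[sp]]
    if (!setequal(names(m), c("sad2a", "sad5a")) || any(!is.finite(m)) || any(m < 0)) {
      abort(sprintf("expression means for '%s' must be finite, nonnegative and named sad2a/sad5a", sp))
    }
  }
  assert_scalar_number(params$expr_sd, "expr_sd", lower = 1e-12)
  assert_scalar_number(params$alkene_resid_sd, "alkene_resid_sd", lower = 0)
  if (!setequal(names(params$alkene_coeffs), ALKENE_CLASSES)) {
    abort("`alkene_coeffs` must be named alkene_7/alkene_9/alkene_12")
  }
  for (cl in ALKENE_CLASSES) {
    v <- params$alkene_coeffs[[cl]]
    if (!setequal(names(v), ALKENE_TERMS) || any(!is.finite(v))) {
      abort(sprintf("alkene coefficients for '%s' must be finite and named %s",
                    cl, paste(ALKENE_TERMS, collapse = "/")))
    }
    params$alkene_coeffs[[cl]] <- v[ALKENE_TERMS]
  }
  if (!setequal(names(params$attraction_coeffs), POLLINATORS)) {
    abort("`attraction_coeffs` must be named C_cunicularius/A_nigroaenea")
  }
  for (p in POLLINATORS) {
    v <- params$attraction_coeffs[[p]]
    if (!setequal(names(v), ATTRACTION_TERMS) || any(!is.finite(v))) {
      abort(sprintf("attraction coefficients for '%s' must be finite and named %s",
                    p, paste(ATTRACTION_TERMS, collapse = "/")))
    }
    params$attraction_coeffs[[p]] <- v[ATTRACTION_TERMS]
  }
  if (!is.finite(params$n_per_species) || params$n_per_species < 3) {
    abort("`n_per_species` must be at least 3")
  }
  assert_scalar_number(params$seed, "seed")
  params
}

#' Calibrated ground truth mimicking the O. sphegodes / O. exaltata system
#'
#' Returns the package's fixed, versioned ground-truth parameter set. It is a
#' pure function: every call returns identical values. The constants were
#' chosen once so that the full pipeline reproduces the qualitative structure
#' of the real system:
#'
#' * 7-alkene amounts depend only on *SAD5A* expression; 9-alkenes only on
#'   *SAD2A*; 12-alkenes on *SAD2A* and a negative *SAD2A x SAD5A*
#'   interaction (substrate competition between the two desaturases);
#' * *C. cunicularius* is attracted by 7-alkenes (with an interior optimum)
#'   and repelled by 9-/12-alkenes; *A. nigroaenea* the converse, with a much
#'   smaller marginal benefit of gaining a functional *SAD2* allele
#'   (net gain ~3%) than *C. cunicularius* derives from gaining *SAD5*
#'   (~20-27%);
#' * no genotype is more than 50% attractive to both pollinators at once, and
#'   the F1 genotype +-/+- is below 50% for both.
#'
#' @return An `ophrys_truth` parameter set (see [ground_truth_params()]).
#' @examples
#' p <- ophrys_ground_truth()
#' p$alkene_coeffs$alkene_7
#' @export
ophrys_ground_truth <- function() {
  ground_truth_params()
}

#' Homozygote reference expression implied by a ground truth
#'
#' The homozygous ++ reference expression of each functional allele is taken
#' to be the (squared) larger of the two species means on the sqrt scale:
#' *SAD2A* from *O. sphegodes*, *SAD5A* from *O. exaltata*.
#'
#' @param params An `ophrys_truth` parameter set.
#' @return Named vector `c(sad2a=, sad5a=)` of raw-scale expression.
#' @export
reference_expression <- function(params) {
  stopifnot(inherits(params, "ophrys_truth"))
  c(
    sad2a = max(params$expr_means$sphegodes["sad2a"], params$expr_means$exaltata["sad2a"])^2,
    sad5a = max(params$expr_means$sphegodes["sad5a"], params$expr_means$exaltata["sad5a"])^2
  )
}

#' @export
print.ophrys_truth <- function(x, ...) {
  cat("<ophrys_truth> ground-truth parameter set\n")
  cat("  n_per_species:", x$n_per_species, " seed:", x$seed, "\n")
  cat("  expr means (sqrt scale):\n")
  for (sp in names(x$expr_means)) {
    cat(sprintf("    %-10s sad2a=%.3g sad5a=%.3g\n", sp,
                x$expr_means[[sp]]["sad2a"], x$expr_means[[sp]]["sad5a"]))
  }
  cat("  expr_sd:", x$expr_sd, " alkene_resid_sd:", x$alkene_resid_sd, "\n")
  invisible(x)
}
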