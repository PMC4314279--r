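# Synthetic-data generator: expression/scent tables and pollinator-choice
# trials with the statistical structure the downstream analysis assumes.

# Linear predictor of ln(amount + 1) for one alkene class, given sqrt-scale
# expression of the two functional alleles.
alkene_linpred <- function(coefs, s2, s5) {
  coefs[["intercept"]] +
    coefs[["sqrt_sad2a"]] * s2 +
    coefs[["sqrt_sad5a"]] * s5 +
    coefs[["interaction"]] * s2 * s5
}

# Log-mean visit count for one pollinator given absolute alkene amounts.
attraction_linpred <- function(coefs, a7, a9, a12) {
  coefs[["intercept"]] +
    coefs[["alkene_7"]] * a7 + coefs[["alkene_9"]] * a9 + coefs[["alkene_12"]] * a12 +
    coefs[["alkene_7_sq"]] * a7^2 + coefs[["alkene_9_sq"]] * a9^2 +
    coefs[["alkene_12_sq"]] * a12^2
}

# Ground-truth alkene amounts (raw scale) at given sqrt-scale expression.
truth_alkene_amounts <- function(params, s2, s5) {
  out <- lapply(params$alkene_coeffs, function(co) {
    pmax(expm1(alkene_linpred(co, s2, s5)), 0)
  })
  tibble(
    alkene_7 = out$alkene_7, alkene_9 = out$alkene_9, alkene_12 = out$alkene_12
  )
}

#' Generate a per-individual allelic expression and floral scent table
#'
#' Draws, for each individual, sqrt-scale expression of the functional alleles
#' *SAD2A* and *SAD5A* from a truncated-at-zero normal around its species mean,
#' computes ln(amount + 1) of the 7-, 9- and 12-alkene class sums from the
#' ground-truth linear model plus normal residual noise, and back-transforms to
#' absolute amounts. With `alkene_resid_sd = 0` and an unexpressed allele class
#' (species mean 0) the amounts hit the zero-expression baseline
#' `exp(intercept) - 1` exactly.
#'
#' @param params An `ophrys_truth` parameter set.
#' @param n_per_species Individuals per species; defaults to the value stored
#'   in `params`.
#' @param seed RNG seed (defaults to `params$seed`); identical seeds give
#'   identical tables.
#' @return A tibble with columns `individual_id`, `species`, `sad2a_expr`,
#'   `sad5a_expr` (raw-scale relative expression), `alkene_7`, `alkene_9`,
#'   `alkene_12` (absolute amounts). The ln-scale latent amounts are attached
#'   as attribute `"latent"`.
#' @examples
#' d <- generate_expression_scent(ophrys_ground_truth(), n_per_species = 5)
#' d
#' @export
generate_expression_scent <- function(params, n_per_species = NULL, seed = params$seed) {
  stopifnot(inherits(params, "ophrys_truth"))
  n <- as.integer(n_per_species %||% params$n_per_species)
  if (!is.finite(n) || n < 3) abort("`n_per_species` must be at least 3")

  with_seed_or_not(seed, {
    rows <- lapply(c("sphegodes", "exaltata"), function(sp) {
      m <- params$expr_means[[sp]]
      s2 <- rtruncnorm0(n, m[["sad2a"]], params$expr_sd)
      s5 <- rtruncnorm0(n, m[["sad5a"]], params$expr_sd)
      latent <- vapply(ALKENE_CLASSES, function(cl) {
        alkene_linpred(params$alkene_coeffs[[cl]], s2, s5) +
          rnorm(n, 0, params$alkene_resid_sd)
      }, numeric(n))
      latent <- matrix(latent, nrow = n,
                       dimnames = list(NULL, ALKENE_CLASSES))
      list(
        df = tibble(
          individual_id = sprintf("%s_%03d", substr(sp, 1, 3), seq_len(n)),
          species = sp,
          sad2a_expr = s2^2,
          sad5a_expr = s5^2,
          alkene_7 = pmax(expm1(latent[, "alkene_7"]), 0),
          alkene_9 = pmax(expm1(latent[, "alkene_9"]), 0),
          alkene_12 = pmax(expm1(latent[, "alkene_12"]), 0)
        ),
        latent = latent
      )
    })
    out <- bind_rows(rows[[1]]$df, rows[[2]]$df)
    attr(out, "latent") <- rbind(rows[[1]]$latent, rows[[2]]$latent)
    out
  })
}

# Prototype scent blends of the four behavioral-experiment treatment groups.
# Pure-species blends evaluate the ground truth at the species mean
# expression; the "+7" and "+9/12" groups add the other species' class sums.
choice_group_prototypes <- function(params) {
  sph <- params$expr_means$sphegodes
  exa <- params$expr_means$exaltata
  base <- truth_alkene_amounts(
    params,
    s2 = c(sph[["sad2a"]], exa[["sad2a"]]),
    s5 = c(sph[["sad5a"]], exa[["sad5a"]])
  )
  sph_amt <- unlist(base[1, ])
  exa_amt <- unlist(base[2, ])
  tibble(
    group = CHOICE_GROUPS,
    alkene_7 = c(sph_amt[["alkene_7"]], sph_amt[["alkene_7"]] + exa_amt[["alkene_7"]],
                 exa_amt[["alkene_7"]], exa_amt[["alkene_7"]]),
    alkene_9 = c(sph_amt[["alkene_9"]], sph_amt[["alkene_9"]],
                 exa_amt[["alkene_9"]], exa_amt[["alkene_9"]] + sph_amt[["alkene_9"]]),
    alkene_12 = c(sph_amt[["alkene_12"]], sph_amt[["alkene_12"]],
                  exa_amt[["alkene_12"]], exa_amt[["alkene_12"]] + sph_amt[["alkene_12"]])
  )
}

#' Generate pollinator-choice trials for the four scent treatment groups
#'
#' Emulates the behavioral field experiment behind the attraction models: four
#' treatment groups (*O. sphegodes* scent, *O. sphegodes* + 7-alkenes,
#' *O. exaltata* scent, *O. exaltata* + 9-/12-alkenes). Per trial, alkene
#' amounts are drawn log-normally around the group prototype blend, and
#' approach counts of the two pollinators are Poisson draws whose log-mean is
#' the ground-truth quadratic attraction model evaluated at the trial amounts.
#'
#' @param params An `ophrys_truth` parameter set.
#' @param n_trials_per_group Trials per treatment group (>= 1).
#' @param groups Treatment groups to generate; must be a subset of the four
#'   admissible labels.
#' @param jitter_sdlog SD of the log-normal jitter of trial amounts around the
#'   group prototype.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return A tibble with columns `group`, `alkene_7`, `alkene_9`, `alkene_12`,
#'   `visits_cc` (*C. cunicularius*) and `visits_an` (*A. nigroaenea*).
#' @examples
#' generate_choice_trials(ophrys_ground_truth(), n_trials_per_group = 3)
#' @export
generate_choice_trials <- function(params, n_trials_per_group = 10,
                                   groups = CHOICE_GROUPS,
                                   jitter_sdlog = 0.3, seed = params$seed) {
  stopifnot(inherits(params, "ophrys_truth"))
  n <- as.integer(n_trials_per_group)
  if (!is.finite(n) || n < 1) abort("`n_trials_per_group` must be at least 1")
  unknown <- setdiff(groups, CHOICE_GROUPS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown treatment group(s): %s", paste(unknown, collapse = ", ")))
  }
  assert_scalar_number(jitter_sdlog, "jitter_sdlog", lower = 0)

  proto <- choice_group_prototypes(params)
  with_seed_or_not(seed, {
    out <- lapply(groups, function(g) {
      p <- proto[proto$group == g, ]
      amt <- vapply(ALKENE_CLASSES, function(cl) {
        p[[cl]] * exp(rnorm(n, 0, jitter_sdlog))
      }, numeric(n))
      amt <- matrix(amt, nrow = n, dimnames = list(NULL, ALKENE_CLASSES))
      lp_cc <- attraction_linpred(params$attraction_coeffs$C_cunicularius,
                                  amt[, 1], amt[, 2], amt[, 3])
      lp_an <- attraction_linpred(params$attraction_coeffs$A_nigroaenea,
                                  amt[, 1], amt[, 2], amt[, 3])
      tibble(
        group = g,
        alkene_7 = amt[, 1], alkene_9 = amt[, 2], alkene_12 = amt[, 3],
        visits_cc = rpois(n, exp(lp_cc)),
        visits_an = rpois(n, exp(lp_an))
      )
    })
    bind_rows(out)
  })
}

#' Write generator tables as headered CSV
#'
#' UTF-8, comma-separated, "." decimal, one record per row, with exactly the
#' interchange column sets of the two record types.
#'
#' @param data Tibble produced by [generate_expression_scent()] or
#'   [generate_choice_trials()] (or any table with those columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_scent <- function(data, path) {
  cols <- c("individual_id", "species", "sad2a_expr", "sad5a_expr",
            "alkene_7", "alkene_9", "alkene_12")
  assert_columns(data, cols, "expression/scent table")
  readr::write_csv(data[cols], path)
  invisible(path)
}

#' @rdname write_expression_scent
#' @export
write_choice_trials <- function(data, path) {
  cols <- c("group", "alkene_7", "alkene_9", "alkene_12", "visits_cc", "visits_an")
  assert_columns(data, cols, "choice-trial table")
  readr::write_csv(data[cols], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
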