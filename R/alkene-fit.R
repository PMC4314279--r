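# Model step 1: linear models of ln(alkene amount + 1) on sqrt-transformed
# allelic expression, with stepwise AIC term selection.

# Candidate regressors. The expression interaction is treated as a
# free-standing regressor (no marginality constraint), so a model can keep
# sqrt_sad2a and the interaction while dropping sqrt_sad5a -- the selected
# structure for 12-alkenes.
alkene_design <- function(data) {
  tibble(
    s2 = sqrt(data$sad2a_expr),
    s5 = sqrt(data$sad5a_expr)
  ) %>%
    mutate(s2s5 = .data$s2 * .data$s5)
}

TERM_MAP <- c(
  "(Intercept)" = "intercept",
  "s2" = "sqrt_sad2a",
  "s5" = "sqrt_sad5a",
  "s2s5" = "interaction"
)

#' Fit the three expression-to-alkene regressions with AIC term selection
#'
#' For each alkene class (7, 9, 12), regresses `ln(amount + 1)` on the
#' candidate terms `sqrt(sad2a_expr)`, `sqrt(sad5a_expr)` and their product,
#' and selects the AIC-best term subset. The intercept is always retained.
#' The candidate space has only eight subsets per class, so the default
#' `method = "exhaustive"` evaluates all of them and is free of the path
#' dependence of greedy stepwise search; `method = "stepwise"` runs
#' bidirectional [MASS::stepAIC] from the full model instead, which agrees
#' with the exhaustive optimum whenever the data carry a clear signal but can
#' stall in a local AIC optimum under weak signal.
#'
#' @param data A data frame with columns `sad2a_expr`, `sad5a_expr` (raw-scale
#'   nonnegative expression) and `alkene_7`, `alkene_9`, `alkene_12`
#'   (nonnegative absolute amounts); at least 5 rows.
#' @param method Term search: `"exhaustive"` (default) or `"stepwise"`.
#' @return An object of class `alkene_fit`: per class, the selected term
#'   names, OLS estimates with 95% confidence intervals, residual SD, R
#'   squared and the number of observations. Supports [tidy()], [glance()]
#'   and [predict_alkenes()].
#' @examples
#' d <- generate_expression_scent(ophrys_ground_truth(), n_per_species = 50)
#' fit <- fit_alkene_models(d)
#' tidy(fit)
#' glance(fit)
#' @export
fit_alkene_models <- function(data, method = c("exhaustive", "stepwise")) {
  method <- match.arg(method)
  assert_columns(data, c("sad2a_expr", "sad5a_expr", ALKENE_CLASSES),
                 "expression/scent data")
  if (nrow(data) < 5) {
    abort("at least 5 records are needed to fit the alkene models",
          class = "ophrysim_underdetermined_fit")
  }
  num_cols <- c("sad2a_expr", "sad5a_expr", ALKENE_CLASSES)
  vals <- as.matrix(data[num_cols])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("expression and alkene amounts must be finite and nonnegative")
  }

  design <- alkene_design(data)
  classes <- lapply(ALKENE_CLASSES, function(cl) {
    df <- design
    df$y <- log1p(data[[cl]])
    fit_one_alkene_class(df, cl, method)
  })
  names(classes) <- ALKENE_CLASSES
  structure(
    list(classes = classes, n_obs = nrow(data)),
    class = "alkene_fit"
  )
}

fit_one_alkene_class <- function(df, class_name, method = "exhaustive") {
  if (sd(df$y) == 0) {
    # Degenerate constant response: intercept-only model, R^2 reported as 0.
    est <- c(intercept = mean(df$y))
    ci <- matrix(c(est, est), ncol = 2,
                 dimnames = list("intercept", c("conf.low", "conf.high")))
    return(list(
      class = class_name, terms = "intercept", estimate = est, ci = ci,
      sigma = 0, r_squared = 0, n_obs = nrow(df), aic = NA_real_,
      degenerate = TRUE
    ))
  }
  if (method == "stepwise") {
    full <- lm(y ~ s2 + s5 + s2s5, data = df)
    sel <- MASS::stepAIC(full, scope = list(lower = ~1, upper = ~ s2 + s5 + s2s5),
                         direction = "both", trace = 0)
  } else {
    sel <- best_subset_lm(df)
  }
  summarise_lm_fit(sel, class_name, nrow(df))
}

# Exhaustive best-AIC search over the 2^3 candidate term subsets.
best_subset_lm <- function(df) {
  candidates <- c("s2", "s5", "s2s5")
  best <- NULL
  best_aic <- Inf
  for (mask in 0:7) {
    terms <- candidates[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    fit <- lm(stats::as.formula(paste("y ~", rhs)), data = df)
    if (AIC(fit) < best_aic) {
      best_aic <- AIC(fit)
      best <- fit
    }
  }
  best
}

summarise_lm_fit <- function(model, class_name, n_obs) {
  est <- coef(model)
  ci <- suppressWarnings(suppressMessages(confint(model, level = 0.95)))
  names(est) <- TERM_MAP[names(est)]
  rownames(ci) <- TERM_MAP[rownames(ci)]
  colnames(ci) <- c("conf.low", "conf.high")
  # summary.lm warns on zero-residual fits; exact fits are legitimate here
  sm <- suppressWarnings(summary(model))
  list(
    class = class_name,
    terms = names(est),
    estimate = est,
    ci = ci,
    sigma = sm$sigma,
    r_squared = sm$r.squared,
    n_obs = n_obs,
    aic = AIC(model),
    degenerate = FALSE
  )
}

#' @export
print.alkene_fit <- function(x, ...) {
  cat("<alkene_fit> expression -> alkene regressions (n =", x$n_obs, ")\n")
  for (cl in names(x$classes)) {
    m <- x$classes[[cl]]
    cat(sprintf("  %-9s R2=%.3f terms: %s\n", cl, m$r_squared,
                paste(m$terms, collapse = " + ")))
  }
  invisible(x)
}

#' @export
tidy.alkene_fit <- function(x, ...) {
  purrr::map_dfr(x$classes, function(m) {
    tibble(
      class = m$class,
      term = m$terms,
      estimate = unname(m$estimate),
      conf.low = unname(m$ci[, "conf.low"]),
      conf.high = unname(m$ci[, "conf.high"])
    )
  })
}

#' @export
glance.alkene_fit <- function(x, ...) {
  purrr::map_dfr(x$classes, function(m) {
    tibble(
      class = m$class, r.squared = m$r_squared, sigma = m$sigma,
      AIC = m$aic, nobs = m$n_obs
    )
  })
}

# Evaluate one class's selected linear predictor at sqrt-scale expressions.
alkene_class_linpred <- function(model, s2, s5) {
  co <- setNames(rep(0, 4), ALKENE_TERMS)
  co[names(model$estimate)] <- model$estimate
  alkene_linpred(as.list(co), s2, s5)
}

#' Predict alkene amounts from allelic expression
#'
#' Evaluates each selected linear predictor on the transformed inputs and
#' back-transforms via `exp(.) - 1`, floored at zero, so predictions are
#' always finite, nonnegative amounts.
#'
#' @param object An `alkene_fit` (or the alkene element of
#'   [alkene_model_from_truth()]).
#' @param newdata Data frame with columns `sad2a_expr` and `sad5a_expr`
#'   (finite, nonnegative).
#' @return A tibble with columns `alkene_7`, `alkene_9`, `alkene_12`.
#' @examples
#' fit <- alkene_model_from_truth(ophrys_ground_truth())
#' predict_alkenes(fit, tibble::tibble(sad2a_expr = c(0, 4), sad5a_expr = 0))
#' @export
predict_alkenes <- function(object, newdata) {
  if (!inherits(object, "alkene_fit")) {
    abort("`object` must be a fitted `alkene_fit`")
  }
  assert_columns(newdata, c("sad2a_expr", "sad5a_expr"), "`newdata`")
  x2 <- newdata$sad2a_expr
  x5 <- newdata$sad5a_expr
  if (any(!is.finite(x2)) || any(!is.finite(x5)) || any(x2 < 0) || any(x5 < 0)) {
    abort("expression values must be finite and nonnegative")
  }
  s2 <- sqrt(x2)
  s5 <- sqrt(x5)
  out <- lapply(object$classes, function(m) {
    pmax(expm1(alkene_class_linpred(m, s2, s5)), 0)
  })
  tibble(
    alkene_7 = out$alkene_7, alkene_9 = out$alkene_9, alkene_12 = out$alkene_12
  )
}

#' Plug-in alkene model from ground-truth coefficients
#'
#' Wraps a ground-truth parameter set as a fitted-model object, so the exact
#' generating coefficients can be pushed through the genotype landscape and
#' the population simulation without refitting. Zero-coefficient terms are
#' dropped from the term set. Confidence intervals are synthetic: a relative
#' halfwidth around the true coefficient (zero by default, i.e. point CIs).
#'
#' @param params An `ophrys_truth` parameter set.
#' @param ci_rel_halfwidth Relative CI halfwidth (e.g. `0.05` for +/- 5% of
#'   each coefficient's magnitude).
#' @return An `alkene_fit` object.
#' @export
alkene_model_from_truth <- function(params, ci_rel_halfwidth = 0) {
  stopifnot(inherits(params, "ophrys_truth"))
  assert_scalar_number(ci_rel_halfwidth, "ci_rel_halfwidth", lower = 0)
  classes <- lapply(ALKENE_CLASSES, function(cl) {
    co <- params$alkene_coeffs[[cl]]
    keep <- co != 0 | names(co) == "intercept"
    est <- co[keep]
    hw <- abs(est) * ci_rel_halfwidth
    ci <- cbind(conf.low = est - hw, conf.high = est + hw)
    list(
      class = cl, terms = names(est), estimate = est, ci = ci,
      sigma = params$alkene_resid_sd, r_squared = NA_real_,
      n_obs = NA_integer_, aic = NA_real_, degenerate = FALSE
    )
  })
  names(classes) <- ALKENE_CLASSES
  structure(list(classes = classes, n_obs = NA_integer_), class = "alkene_fit")
}
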