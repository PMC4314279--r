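# Model step 2: within-group permutation of scent <-> visitation pairings and
# Poisson log-link regression of visit counts on linear + quadratic alkene
# terms, per pollinator.

#' Permute scent-visitation pairings within treatment groups
#'
#' For each permutation round and each treatment group independently, the
#' visit-count pair (`visits_cc`, `visits_an`) is randomly re-paired with the
#' group's scent rows; all rounds are concatenated. This propagates the
#' observed variance of both scent and attraction into the regression data,
#' and conserves the within-group multiset of visit counts in every round.
#'
#' @param trials Choice-trial table with columns `group`, `alkene_7`,
#'   `alkene_9`, `alkene_12`, `visits_cc`, `visits_an`. All four treatment
#'   groups must be present and nonempty.
#' @param n_perm Number of permutation rounds (default 300).
#' @param seed RNG seed; identical seeds give identical expansions.
#' @return A tibble with `n_perm * nrow(trials)` rows and an additional
#'   `perm` round index; attribute `"n_perm"` records the round count.
#' @examples
#' trials <- generate_choice_trials(ophrys_ground_truth(), n_trials_per_group = 4)
#' expanded <- permute_within_groups(trials, n_perm = 10, seed = 1)
#' nrow(expanded)  # 160
#' @export
permute_within_groups <- function(trials, n_perm = 300, seed = NULL) {
  cols <- c("group", "alkene_7", "alkene_9", "alkene_12", "visits_cc", "visits_an")
  assert_columns(trials, cols, "choice-trial table")
  n_perm <- as.integer(n_perm)
  if (!is.finite(n_perm) || n_perm < 1) abort("`n_perm` must be at least 1")
  missing_groups <- setdiff(CHOICE_GROUPS, unique(trials$group))
  if (length(missing_groups) > 0) {
    abort(sprintf("empty treatment group(s): %s",
                  paste(missing_groups, collapse = ", ")),
          class = "ophrysim_empty_group")
  }
  unknown <- setdiff(unique(trials$group), CHOICE_GROUPS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown treatment group(s): %s", paste(unknown, collapse = ", ")))
  }

  idx_by_group <- split(seq_len(nrow(trials)), trials$group)
  with_seed_or_not(seed, {
    rounds <- lapply(seq_len(n_perm), function(r) {
      shuffled <- trials
      for (idx in idx_by_group) {
        take <- idx[sample.int(length(idx))]
        shuffled[idx, c("visits_cc", "visits_an")] <-
          trials[take, c("visits_cc", "visits_an")]
      }
      shuffled$perm <- r
      shuffled
    })
    out <- bind_rows(rounds)
    attr(out, "n_perm") <- n_perm
    out
  })
}

ATTR_LINEAR <- c("alkene_7", "alkene_9", "alkene_12")
ATTR_QUAD <- paste0(ATTR_LINEAR, "_sq")

# Candidate term subsets under the quadratic-implies-linear hierarchy:
# per alkene class, 0 = absent, 1 = linear, 2 = linear + quadratic.
hierarchy_states <- function() {
  as.matrix(expand.grid(a7 = 0:2, a9 = 0:2, a12 = 0:2))
}

state_terms <- function(state) {
  terms <- character(0)
  for (i in seq_along(ATTR_LINEAR)) {
    if (state[i] >= 1) terms <- c(terms, ATTR_LINEAR[i])
    if (state[i] == 2) terms <- c(terms, ATTR_QUAD[i])
  }
  terms
}

fit_glm_state <- function(df, response, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  fit <- tryCatch(
    suppressWarnings(glm(f, family = poisson(link = "log"), data = df)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) return(NULL)
  fit
}

#' Fit the Poisson attraction model with AIC subset selection
#'
#' Fits a Poisson log-link GLM of one pollinator's visit counts on candidate
#' linear and quadratic terms in the three alkene amounts, selecting the term
#' subset by AIC. Quadratic terms are only admitted together with their linear
#' term, giving 27 admissible subsets which are searched exhaustively by
#' default; `method = "stepwise"` uses a greedy bidirectional search over the
#' same hierarchy (tested to agree with the exhaustive search).
#'
#' The permutation rounds are pooled into one fit, following the procedure of
#' re-using all permuted data points for a single regression. Pooling
#' pseudo-replicates each trial `n_perm` times, so the nominal Wald intervals
#' are anti-conservative; `ci_inflate = TRUE` widens them by `sqrt(n_perm)`.
#'
#' @param expanded Output of [permute_within_groups()] (or any table with the
#'   trial columns; `n_perm` is then taken to be 1).
#' @param pollinator `"C_cunicularius"` (counts `visits_cc`) or
#'   `"A_nigroaenea"` (counts `visits_an`); `"cc"`/`"an"` are accepted.
#' @param method Subset search: `"exhaustive"` (default) or `"stepwise"`.
#' @param ci_inflate If `TRUE`, multiply standard errors by `sqrt(n_perm)`
#'   before forming 95% intervals. Default `FALSE`.
#' @return An object of class `attraction_fit` with the selected terms,
#'   estimates, Wald 95% CIs, deviance-based pseudo R squared and fit size.
#' @examples
#' trials <- generate_choice_trials(ophrys_ground_truth(), n_trials_per_group = 10)
#' expanded <- permute_within_groups(trials, n_perm = 30, seed = 1)
#' fit <- fit_attraction_glm(expanded, "C_cunicularius")
#' tidy(fit)
#' @export
fit_attraction_glm <- function(expanded,
                               pollinator = c("C_cunicularius", "A_nigroaenea"),
                               method = c("exhaustive", "stepwise"),
                               ci_inflate = FALSE) {
  pollinator <- normalize_pollinator(pollinator)
  method <- match.arg(method)
  response <- if (pollinator == "C_cunicularius") "visits_cc" else "visits_an"
  assert_columns(expanded, c(ATTR_LINEAR, response), "expanded choice data")

  y <- expanded[[response]]
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    abort(sprintf("`%s` must contain nonnegative integer counts", response))
  }
  n_perm <- attr(expanded, "n_perm") %||% 1L

  df <- as_tibble(expanded[c(ATTR_LINEAR, response)])
  df$alkene_7_sq <- df$alkene_7^2
  df$alkene_9_sq <- df$alkene_9^2
  df$alkene_12_sq <- df$alkene_12^2

  states <- hierarchy_states()
  aic_of_state <- function(state) {
    fit <- fit_glm_state(df, response, state_terms(state))
    if (is.null(fit)) Inf else AIC(fit)
  }

  if (method == "exhaustive") {
    aics <- apply(states, 1, aic_of_state)
    if (!any(is.finite(aics))) {
      abort("no candidate attraction model converged", class = "ophrysim_fit_failure")
    }
    best_state <- states[which.min(aics), ]
  } else {
    best_state <- stepwise_hierarchy_search(states, aic_of_state)
  }

  sel_terms <- state_terms(best_state)
  fit <- fit_glm_state(df, response, sel_terms)
  if (is.null(fit)) {
    abort(sprintf("attraction model failed to converge for term set: {%s}",
                  paste(c("intercept", sel_terms), collapse = ", ")),
          class = "ophrysim_fit_failure")
  }
  new_attraction_fit(fit, pollinator, n_perm, ci_inflate)
}

# Greedy bidirectional search: from the full hierarchy state, repeatedly take
# the single-class promotion/demotion that most decreases AIC.
stepwise_hierarchy_search <- function(states, aic_of_state) {
  state <- c(a7 = 2, a9 = 2, a12 = 2)
  current <- aic_of_state(state)
  repeat {
    moves <- list()
    for (i in seq_along(state)) {
      for (d in c(-1L, 1L)) {
        cand <- state
        cand[i] <- cand[i] + d
        if (cand[i] >= 0 && cand[i] <= 2) moves <- c(moves, list(cand))
      }
    }
    aics <- vapply(moves, aic_of_state, numeric(1))
    if (min(aics) < current - 1e-10) {
      state <- moves[[which.min(aics)]]
      current <- min(aics)
    } else {
      return(state)
    }
  }
}

normalize_pollinator <- function(pollinator) {
  pollinator <- pollinator[1]
  key <- c(
    "C_cunicularius" = "C_cunicularius", "cc" = "C_cunicularius",
    "A_nigroaenea" = "A_nigroaenea", "an" = "A_nigroaenea"
  )
  if (!pollinator %in% names(key)) {
    abort("`pollinator` must be 'C_cunicularius'/'cc' or 'A_nigroaenea'/'an'")
  }
  unname(key[pollinator])
}

new_attraction_fit <- function(fit, pollinator, n_perm, ci_inflate) {
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (isTRUE(ci_inflate)) se <- se * sqrt(n_perm)
  ci <- cbind(conf.low = est - qnorm(0.975) * se,
              conf.high = est + qnorm(0.975) * se)
  names(est)[names(est) == "(Intercept)"] <- "intercept"
  rownames(ci)[rownames(ci) == "(Intercept)"] <- "intercept"
  structure(
    list(
      pollinator = pollinator,
      terms = names(est),
      estimate = est,
      ci = ci,
      pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
      n_fit_rows = length(fit$y),
      n_perm = n_perm,
      aic = AIC(fit),
      ci_inflated = isTRUE(ci_inflate)
    ),
    class = "attraction_fit"
  )
}

#' @export
print.attraction_fit <- function(x, ...) {
  cat("<attraction_fit>", x$pollinator, "\n")
  cat(sprintf("  terms: %s\n", paste(x$terms, collapse = " + ")))
  cat(sprintf("  pseudo-R2 = %.3f, n = %d (%d permutation rounds)\n",
              x$pseudo_r2, x$n_fit_rows, x$n_perm))
  invisible(x)
}

#' @export
tidy.attraction_fit <- function(x, ...) {
  tibble(
    pollinator = x$pollinator,
    term = x$terms,
    estimate = unname(x$estimate),
    conf.low = unname(x$ci[, "conf.low"]),
    conf.high = unname(x$ci[, "conf.high"])
  )
}

#' @export
glance.attraction_fit <- function(x, ...) {
  tibble(
    pollinator = x$pollinator, pseudo.r.squared = x$pseudo_r2,
    AIC = x$aic, nobs = x$n_fit_rows, n.perm = x$n_perm
  )
}

# Full 7-term coefficient vector (zeros for unselected terms).
attraction_full_coefs <- function(object) {
  co <- setNames(rep(0, length(ATTRACTION_TERMS)), ATTRACTION_TERMS)
  co[names(object$estimate)] <- object$estimate
  co
}

#' Predict expected visit counts from alkene amounts
#'
#' Evaluates `exp(linear predictor)` of a fitted attraction model at the given
#' absolute alkene amounts; the log link guarantees strictly positive, finite
#' predictions.
#'
#' @param object An `attraction_fit`.
#' @param newdata Data frame with columns `alkene_7`, `alkene_9`, `alkene_12`.
#' @return Numeric vector of expected visit counts.
#' @examples
#' fit <- attraction_model_from_truth(ophrys_ground_truth(), "C_cunicularius")
#' predict_attraction(fit, tibble::tibble(alkene_7 = 35, alkene_9 = 0, alkene_12 = 0))
#' @export
predict_attraction <- function(object, newdata) {
  if (!inherits(object, "attraction_fit")) {
    abort("`object` must be a fitted `attraction_fit`")
  }
  assert_columns(newdata, ATTR_LINEAR, "`newdata`")
  co <- as.list(attraction_full_coefs(object))
  lp <- attraction_linpred(co, newdata$alkene_7, newdata$alkene_9, newdata$alkene_12)
  exp(lp)
}

#' Plug-in attraction model from ground-truth coefficients
#'
#' Wraps one pollinator's ground-truth attraction coefficients as an
#' `attraction_fit`, so the exact generating model can drive the genotype
#' landscape and population simulation. Zero coefficients are dropped from the
#' term set; confidence intervals are synthetic relative halfwidths (zero by
#' default).
#'
#' @inheritParams alkene_model_from_truth
#' @param pollinator `"C_cunicularius"` or `"A_nigroaenea"` (or `"cc"`/`"an"`).
#' @return An `attraction_fit` object.
#' @export
attraction_model_from_truth <- function(params, pollinator, ci_rel_halfwidth = 0) {
  stopifnot(inherits(params, "ophrys_truth"))
  pollinator <- normalize_pollinator(pollinator)
  assert_scalar_number(ci_rel_halfwidth, "ci_rel_halfwidth", lower = 0)
  co <- params$attraction_coeffs[[pollinator]]
  keep <- co != 0 | names(co) == "intercept"
  est <- co[keep]
  hw <- abs(est) * ci_rel_halfwidth
  ci <- cbind(conf.low = est - hw, conf.high = est + hw)
  structure(
    list(
      pollinator = pollinator, terms = names(est), estimate = est, ci = ci,
      pseudo_r2 = NA_real_, n_fit_rows = NA_integer_, n_perm = NA_integer_,
      aic = NA_real_, ci_inflated = FALSE
    ),
    class = "attraction_fit"
  )
}
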