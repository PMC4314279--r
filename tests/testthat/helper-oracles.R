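# Independent reference implementations used to cross-check package results.
# These deliberately re-derive everything from first principles (enumeration
# and exhaustive search) instead of calling the package's code paths.

# Exhaustive best-AIC subset search over the 8 candidate alkene models.
# Returns the sorted term names (package naming) of the AIC-minimal subset.
oracle_best_alkene_terms <- function(data, class) {
  df <- data.frame(
    y = log1p(data[[class]]),
    s2 = sqrt(data$sad2a_expr),
    s5 = sqrt(data$sad5a_expr)
  )
  df$s2s5 <- df$s2 * df$s5
  subsets <- expand.grid(s2 = c(FALSE, TRUE), s5 = c(FALSE, TRUE),
                         s2s5 = c(FALSE, TRUE))
  best <- NULL
  best_aic <- Inf
  for (i in seq_len(nrow(subsets))) {
    terms <- names(subsets)[unlist(subsets[i, ])]
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    fit <- lm(as.formula(paste("y ~", rhs)), data = df)
    if (AIC(fit) < best_aic) {
      best_aic <- AIC(fit)
      best <- terms
    }
  }
  map <- c(s2 = "sqrt_sad2a", s5 = "sqrt_sad5a", s2s5 = "interaction")
  list(terms = sort(c("intercept", unname(map[best]))), aic = best_aic)
}

# Exhaustive best-AIC search over the 27 hierarchy-respecting attraction
# subsets (per alkene class: absent / linear / linear + quadratic).
oracle_best_attraction_terms <- function(df, response) {
  lin <- c("alkene_7", "alkene_9", "alkene_12")
  df <- as.data.frame(df)
  for (v in lin) df[[paste0(v, "_sq")]] <- df[[v]]^2
  states <- expand.grid(a7 = 0:2, a9 = 0:2, a12 = 0:2)
  best <- NULL
  best_aic <- Inf
  for (i in seq_len(nrow(states))) {
    terms <- character(0)
    for (k in 1:3) {
      if (states[i, k] >= 1) terms <- c(terms, lin[k])
      if (states[i, k] == 2) terms <- c(terms, paste0(lin[k], "_sq"))
    }
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    fit <- tryCatch(
      suppressWarnings(glm(as.formula(paste(response, "~", rhs)),
                           family = poisson(), data = df)),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$converged && AIC(fit) < best_aic) {
      best_aic <- AIC(fit)
      best <- terms
    }
  }
  list(terms = sort(c("intercept", best)), aic = best_aic)
}

# Brute-force Mendelian oracle: expand each parent's allele count at a locus
# into an explicit ordered allele pair, enumerate the 2 x 2 ordered picks per
# locus and take the Cartesian product across the three loci.
oracle_mate <- function(parent_a, parent_b) {
  pair <- function(count) c(rep(1L, count), rep(0L, 2L - count))
  per_locus <- lapply(1:3, function(l) {
    a <- pair(parent_a[l])
    b <- pair(parent_b[l])
    as.vector(outer(a, b, `+`))  # 4 ordered maternal x paternal transmissions
  })
  grid <- expand.grid(per_locus[[1]], per_locus[[2]], per_locus[[3]])
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, c("sad2", "sad5", "sus"))
  m
}

# Sorted per-locus offspring count distribution, for order-free comparison.
locus_distribution <- function(offspring) {
  apply(offspring, 2, function(col) as.vector(table(factor(col, levels = 0:2))))
}

# A tiny landscape table with constant attraction everywhere, for neutrality
# and net-gain edge cases.
flat_landscape <- function(value = 0.5, include_sus = TRUE) {
  g <- enumerate_genotypes(include_sus = include_sus)
  g$attraction_cc_point <- value
  g$attraction_an_point <- value
  g$attraction_cc_mean <- value
  g$attraction_an_mean <- value
  g
}

# Point-estimate fixture landscape shared by several tests.
fixture_point_landscape <- function(include_sus = TRUE) {
  truth <- ophrys_ground_truth()
  predict_genotype_landscape(
    enumerate_genotypes(include_sus = include_sus),
    alkene_model_from_truth(truth),
    attraction_model_from_truth(truth, "cc"),
    attraction_model_from_truth(truth, "an"),
    reference_expression(truth),
    n_perturb = 1, seed = 1
  )
}
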