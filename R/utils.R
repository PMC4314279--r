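# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# A NULL seed means "use the current RNG stream".
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a stream of child seeds from one master seed; keeps values in integer
# range so downstream set.seed() calls are portable.
spawn_seeds <- function(seed, n) {
  with_seed_or_not(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated-at-zero normal draws on the sqrt-expression scale. A mean of
# exactly zero denotes an unexpressed allele class and returns exact zeros,
# so that "-" backgrounds carry no functional transcript.
rtruncnorm0 <- function(n, mean, sd) {
  if (mean == 0) {
    return(rep(0, n))
  }
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf(
      "`%s` must be a single finite number in [%s, %s], got: %s",
      name, format(lower), format(upper), paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s", what, paste(missing, collapse = ", ")
    ), class = "ophrysim_schema_error")
  }
  invisible(df)
}

allele_pair_label <- function(count, plus = "+", minus = "-") {
  paste0(
    strrep(plus, count),
    strrep(minus, 2L - count)
  )
}

#' Genotype labels in the "++/--" field convention
#'
#' Builds the conventional genotype label listing the SAD2 allele pair first
#' and the SAD5 pair second, separated by a slash ("+" = functional allele,
#' "-" = nonfunctional). When a suppressor allele count is given, the SUS pair
#' ("S" = dominant suppressor, "s" = inactive) is appended as a third field.
#'
#' @param sad2,sad5 Integer counts (0, 1 or 2) of functional alleles.
#' @param sus Optional integer count of suppressor ("S") alleles; `NULL` omits
#'   the SUS field.
#' @return Character vector of labels such as `"++/--"` or `"+-/+-/Ss"`.
#' @examples
#' genotype_label(2, 0)        # "++/--", the O. sphegodes-like genotype
#' genotype_label(1, 1, 1)     # "+-/+-/Ss"
#' @export
genotype_label <- function(sad2, sad5, sus = NULL) {
  stopifnot(all(sad2 %in% 0:2), all(sad5 %in% 0:2))
  lab <- paste0(
    vapply(sad2, allele_pair_label, ""),
    "/",
    vapply(sad5, allele_pair_label, "")
  )
  if (!is.null(sus)) {
    stopifnot(all(sus %in% 0:2))
    lab <- paste0(lab, "/", vapply(sus, allele_pair_label, "", plus = "S", minus = "s"))
  }
  lab
}

# Uniform draws within per-coefficient 95% confidence intervals.
# ci is a k x 2 matrix (lower, upper); returns an n x k matrix.
draw_within_ci <- function(ci, n) {
  k <- nrow(ci)
  m <- matrix(runif(n * k), nrow = n)
  sweep(m, 2, ci[, 2] - ci[, 1], `*`) + matrix(ci[, 1], n, k, byrow = TRUE)
}
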