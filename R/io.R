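# Typed CSV readers with validation and JSON model (de)serialization.

read_validated_csv <- function(path, col_types, what) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, show_col_types = FALSE)
  )
  assert_columns(df, names(col_types$cols), sprintf("%s file '%s'", what, path))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "%s file '%s' has %d malformed value(s); first at row %d, column '%s'",
      what, path, nrow(prob), prob$row[1], names(col_types$cols)[prob$col[1]]
    ))
  }
  if (nrow(df) == 0) {
    warn(sprintf("%s file '%s' has a header but no data rows", what, path))
  }
  df
}

check_nonnegative_rows <- function(df, cols, path) {
  for (col in cols) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "column '%s' of '%s' must be finite and nonnegative; first bad row: %d",
        col, path, bad[1]
      ))
    }
  }
  invisible(df)
}

#' Read expression/scent and choice-trial tables from CSV
#'
#' Typed readers for the two interchange formats written by
#' [write_expression_scent()] and [write_choice_trials()]: comma-separated,
#' UTF-8, "." decimal, header row mandatory. Missing columns raise a schema
#' error naming the column; non-numeric or negative values are rejected with
#' the offending row number.
#'
#' @param path CSV file path.
#' @return A validated tibble of records.
#' @export
read_expression_scent <- function(path) {
  cols <- readr::cols(
    individual_id = readr::col_character(),
    species = readr::col_character(),
    sad2a_expr = readr::col_double(),
    sad5a_expr = readr::col_double(),
    alkene_7 = readr::col_double(),
    alkene_9 = readr::col_double(),
    alkene_12 = readr::col_double()
  )
  df <- read_validated_csv(path, cols, "expression/scent")
  check_nonnegative_rows(
    df, c("sad2a_expr", "sad5a_expr", ALKENE_CLASSES), path
  )
  df
}

#' @rdname read_expression_scent
#' @export
read_choice_trials <- function(path) {
  cols <- readr::cols(
    group = readr::col_character(),
    alkene_7 = readr::col_double(),
    alkene_9 = readr::col_double(),
    alkene_12 = readr::col_double(),
    visits_cc = readr::col_double(),
    visits_an = readr::col_double()
  )
  df <- read_validated_csv(path, cols, "choice-trial")
  check_nonnegative_rows(df, c(ALKENE_CLASSES, "visits_cc", "visits_an"), path)
  for (col in c("visits_cc", "visits_an")) {
    bad <- which(df[[col]] != floor(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("column '%s' of '%s' must contain integer counts; first bad row: %d",
                    col, path, bad[1]))
    }
  }
  unknown <- setdiff(unique(df$group), CHOICE_GROUPS)
  if (length(unknown) > 0 && nrow(df) > 0) {
    abort(sprintf("unknown treatment group(s) in '%s': %s",
                  path, paste(unknown, collapse = ", ")))
  }
  df
}

#' Serialize fitted models to JSON and back
#'
#' Writes an `alkene_fit` or `attraction_fit` to a self-describing JSON file
#' (term names, estimates, confidence intervals, fit statistics) and restores
#' an equivalent object.
#'
#' @param object An `alkene_fit` or `attraction_fit`.
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly; `read_model_json()`
#'   returns the restored model object.
#' @export
write_model_json <- function(object, path) {
  payload <- if (inherits(object, "alkene_fit")) {
    list(
      type = "alkene_fit",
      n_obs = object$n_obs,
      classes = lapply(object$classes, function(m) {
        list(
          class = m$class, terms = as.list(m$terms),
          estimate = as.list(m$estimate),
          conf_low = as.list(setNames(m$ci[, 1], rownames(m$ci))),
          conf_high = as.list(setNames(m$ci[, 2], rownames(m$ci))),
          sigma = m$sigma, r_squared = m$r_squared, n_obs = m$n_obs,
          aic = m$aic, degenerate = m$degenerate
        )
      })
    )
  } else if (inherits(object, "attraction_fit")) {
    list(
      type = "attraction_fit",
      pollinator = object$pollinator,
      terms = as.list(object$terms),
      estimate = as.list(object$estimate),
      conf_low = as.list(setNames(object$ci[, 1], rownames(object$ci))),
      conf_high = as.list(setNames(object$ci[, 2], rownames(object$ci))),
      pseudo_r2 = object$pseudo_r2, n_fit_rows = object$n_fit_rows,
      n_perm = object$n_perm, aic = object$aic, ci_inflated = object$ci_inflated
    )
  } else {
    abort("`object` must be an alkene_fit or attraction_fit")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(x$type, "alkene_fit")) {
    classes <- lapply(x$classes, function(m) {
      est <- unlist(m$estimate)
      ci <- cbind(conf.low = unlist(m$conf_low), conf.high = unlist(m$conf_high))
      rownames(ci) <- names(est)
      list(
        class = m$class, terms = unlist(m$terms), estimate = est, ci = ci,
        sigma = m$sigma, r_squared = null_to_na(m$r_squared),
        n_obs = null_to_na(m$n_obs), aic = null_to_na(m$aic),
        degenerate = isTRUE(m$degenerate)
      )
    })
    names(classes) <- vapply(classes, `[[`, "", "class")
    structure(list(classes = classes, n_obs = null_to_na(x$n_obs)),
              class = "alkene_fit")
  } else if (identical(x$type, "attraction_fit")) {
    est <- unlist(x$estimate)
    ci <- cbind(conf.low = unlist(x$conf_low), conf.high = unlist(x$conf_high))
    rownames(ci) <- names(est)
    structure(
      list(
        pollinator = x$pollinator, terms = unlist(x$terms), estimate = est,
        ci = ci, pseudo_r2 = null_to_na(x$pseudo_r2),
        n_fit_rows = null_to_na(x$n_fit_rows), n_perm = null_to_na(x$n_perm),
        aic = null_to_na(x$aic), ci_inflated = isTRUE(x$ci_inflated)
      ),
      class = "attraction_fit"
    )
  } else {
    abort(sprintf("'%s' is not a recognised model JSON file", path))
  }
}

null_to_na <- function(x) if (is.null(x)) NA_real_ else x
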