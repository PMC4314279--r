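# ggplot2 views of the two result types.

#' Plot a genotype attraction landscape
#'
#' `type = "attraction"` draws the scaled attraction of each genotype to the
#' two pollinators with 95% perturbation intervals; `type = "alkenes"` draws
#' the predicted alkene composition (mean class amounts) per genotype.
#'
#' @param object An `ophrys_landscape`.
#' @param type `"attraction"` or `"alkenes"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ophrys_landscape <- function(object, type = c("attraction", "alkenes"), ...) {
  type <- match.arg(type)
  df <- as_tibble(object)
  df$label <- factor(df$label, levels = df$label)
  if (type == "attraction") {
    long <- dplyr::bind_rows(
      tibble(label = df$label, pollinator = "C. cunicularius",
             mean = df$attraction_cc_mean, lo = df$attraction_cc_lo,
             hi = df$attraction_cc_hi),
      tibble(label = df$label, pollinator = "A. nigroaenea",
             mean = df$attraction_an_mean, lo = df$attraction_an_lo,
             hi = df$attraction_an_hi)
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$mean,
                                       fill = .data$pollinator)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
        position = ggplot2::position_dodge(width = 0.8), width = 0.25
      ) +
      ggplot2::labs(x = "genotype (SAD2/SAD5[/SUS])",
                    y = "scaled pollinator attraction",
                    fill = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  } else {
    long <- tidyr::pivot_longer(
      df[, c("label", "alkene_7_mean", "alkene_9_mean", "alkene_12_mean")],
      -"label", names_to = "class", values_to = "amount"
    )
    long$class <- sub("_mean$", "", long$class)
    ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$amount,
                                       fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "genotype (SAD2/SAD5[/SUS])",
                    y = "predicted alkene amount", fill = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  }
}

#' Plot genotype-class frequencies through time
#'
#' Line plot of the recorded class frequencies of one simulation scenario.
#'
#' @param object An `ophrys_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ophrys_trajectory <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$generation, y = .data$frequency,
                               colour = .data$class)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("%s, An:Cc = %s, SUS %s", cfg$founder_scenario,
                      cfg$pollinator_ratio, cfg$sus_regime),
      x = "generation", y = "genotype-class frequency", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
tidy.ophrys_trajectory <- function(x, type = c("classes", "genotypes"), ...) {
  type <- match.arg(type)
  if (type == "classes") as_tibble(x) else attr(x, "genotypes")
}
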