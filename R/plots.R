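#' Plot per-group stoichiometry estimates
#'
#' Bar plot of the Gbetagamma:channel and Galpha:channel ratios per group.
#'
#' @param object A `girk_stoich` table from [infer_stoichiometry()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot girk_stoich
#' @export
autoplot.girk_stoich <- function(object, ...) {
  dat <- tidy(object) %>%
    dplyr::filter(.data$term %in% c("gbg_per_channel", "ga_per_channel")) %>%
    dplyr::mutate(subunit = ifelse(.data$term == "gbg_per_channel",
                                   "Gbg", "Ga"))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = factor(.data$group, levels = unique(.data$group)),
                 y = .data$estimate, fill = .data$subunit)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "group", y = "subunits per channel", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Gbetagamma dose-response simulation
#'
#' @param data Table from [simulate_gbg_dose_response()] (multiple scenarios
#'   may be row-bound; curves are coloured by `mode`).
#' @param y Which response to draw: the absolute current or the activation
#'   index relative to the zero-dose basal current.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(data, y = c("i_bg", "r_bg")) {
  y <- match.arg(y)
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$added_gbg, y = .data[[y]], colour = .data$mode)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "coexpressed Gbg (molecules/um^2)",
      y = if (y == "i_bg") "current (uA)" else "R_bg",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated R_a vs I_basal relation
#'
#' @param data Table from [simulate_ra_vs_ibasal()], or several such tables
#'   row-bound with a distinguishing `scenario` column.
#' @return A ggplot object.
#' @export
plot_ra_relation <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$i_basal, y = .data$r_a))
  if ("scenario" %in% names(data)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$scenario))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::labs(x = "I_basal (uA)", y = "R_a = I_total / I_basal") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' One line per group, estimate vs swept parameter value.
#'
#' @param data Table from [sensitivity_sweep()].
#' @param estimate Column to draw (default `gbg_per_channel`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(data, estimate = gbg_per_channel) {
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$value, y = {{ estimate }},
                 colour = factor(.data$group))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = unique(data$parameter)[1], colour = "group") +
    ggplot2::theme_minimal()
}
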