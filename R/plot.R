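#' Plot a fitted growth curve over the study-level data
#'
#' Bubble plot of study mean AL against mean age (bubble area proportional to
#' the precision weight) with the fitted curve(s) and delta-method band.
#'
#' @param object An `al_growth_fit`.
#' @param age_range Curve evaluation range in years.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot al_growth_fit
#' @export
autoplot.al_growth_fit <- function(object, age_range = NULL, ...) {
  dat <- object$data
  age_range <- age_range %||% range(dat$age_mean)
  grid <- seq(age_range[1], age_range[2], length.out = 200)
  groups <- if (object$grouped && !object$fix_deltas) c("EA", "nonEA") else "combined"
  curves <- dplyr::bind_rows(purrr::map(groups, predict_with_ci,
                                        fit = object, age = grid))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$age, y = .data$al,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(data = dat,
                        ggplot2::aes(x = .data$age_mean, y = .data$al_mean,
                                     size = .data$weight,
                                     colour = if (object$grouped) .data$group
                                              else "combined"),
                        inherit.aes = FALSE, alpha = 0.5) +
    ggplot2::scale_size_area(name = "study weight", max_size = 8) +
    ggplot2::labs(x = "Mean age (years)", y = "Mean axial length (mm)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an age-specific growth table
#'
#' Line-and-ribbon chart of predicted AL by age and group, with the annual
#' growth rate in a lower panel.
#'
#' @param table A [growth_table] tibble.
#' @return A ggplot object (AL panel); the rate is mapped to a secondary
#'   panel via facetting.
#' @export
plot_growth_table <- function(table) {
  long <- dplyr::bind_rows(
    dplyr::transmute(table, .data$age, .data$group, value = .data$al,
                     lo = .data$ci_low, hi = .data$ci_high,
                     panel = "Axial length (mm)"),
    dplyr::transmute(table, .data$age, .data$group, value = .data$rate,
                     lo = NA_real_, hi = NA_real_,
                     panel = "Annual growth rate (mm/year)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$value,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~ .data$panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = NULL, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
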