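#' Broom-style accessors for stereowound result objects
#'
#' `tidy()` returns the per-comparison or per-visit table; `glance()`
#' returns the one-row-per-test or per-group overview.
#'
#' @param x a `stereo_comparison`, `stereo_table1` or `closure_summary`.
#' @param ... unused.
#' @return a tibble.
#' @name stereowound-tidiers
NULL

#' @rdname stereowound-tidiers
#' @method tidy stereo_comparison
#' @export
tidy.stereo_comparison <- function(x, ...) x$pairwise

#' @rdname stereowound-tidiers
#' @method glance stereo_comparison
#' @export
glance.stereo_comparison <- function(x, ...) x$omnibus

#' @rdname stereowound-tidiers
#' @method tidy stereo_table1
#' @export
tidy.stereo_table1 <- function(x, ...) x$summary

#' @rdname stereowound-tidiers
#' @method glance stereo_table1
#' @export
glance.stereo_table1 <- function(x, ...) x$omnibus

#' @rdname stereowound-tidiers
#' @method tidy closure_summary
#' @export
tidy.closure_summary <- function(x, ...) x$by_visit

#' @rdname stereowound-tidiers
#' @method glance closure_summary
#' @export
glance.closure_summary <- function(x, ...) x$by_group

#' Plot a wound-closure timecourse summary
#'
#' Mean closure percentage by visit day per group with +/- SD error bars,
#' the standard presentation of wound-closure kinetics.
#'
#' @param object a [group_closure_table()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot closure_summary
#' @export
autoplot.closure_summary <- function(object, ...) {
  d <- object$by_visit
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$closure_mean,
                                  colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$closure_mean - .data$closure_sd,
                   ymax = .data$closure_mean + .data$closure_sd),
      width = 0.4
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Day", y = "Wound closure (%)", colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot a group stereology report
#'
#' Group mean +/- SD per quantity, faceted, with stars over groups
#' significant against every reference group.
#'
#' @param object a [table1_report()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot stereo_table1
#' @export
autoplot.stereo_table1 <- function(object, ...) {
  d <- object$summary
  d$facet <- unname(quantity_labels[d$quantity])
  d$facet[is.na(d$facet)] <- d$quantity[is.na(d$facet)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.3
    ) +
    ggplot2::geom_text(
      data = d[d$star, ], label = "*", vjust = -0.8, size = 6,
      ggplot2::aes(y = .data$mean + .data$sd)
    ) +
    ggplot2::facet_wrap(~facet, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Mean (SD)") +
    ggplot2::theme_minimal()
}

#' Plot percent differences from a comparison
#'
#' @param object a [compare_groups()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot stereo_comparison
#' @export
autoplot.stereo_comparison <- function(object, ...) {
  d <- object$pairwise
  d$pair <- paste(d$group_a, "vs", d$group_b)
  d$sig <- d$p_value < object$alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$percent_difference,
                                  fill = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey70"),
                               name = sprintf("p < %g", object$alpha)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Percent difference of means (%)") +
    ggplot2::theme_minimal()
}
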