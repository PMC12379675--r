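# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col facet_wrap labs
#'   scale_y_log10
#' @export
ggplot2::autoplot

#' Plot an excitation function
#'
#' @param object An [excitation_function()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.excitation_function <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$energy_mev, y = .data$sigma_mb)) +
    geom_line() +
    labs(x = "deuteron energy (MeV)", y = "cross section (mb)",
         title = attr(object, "reaction"),
         subtitle = paste0("provenance: ", attr(object, "provenance")))
}

#' Plot the inventory timeline of a scenario run
#'
#' Atom inventories over the irradiation and processing schedule, one line
#' per nuclide, log activity scale.
#'
#' @param object An `ry_scenario_result`.
#' @param quantity `"atoms"` or `"activity_gbq"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ry_scenario_result <- function(object,
                                        quantity = c("atoms", "activity_gbq"),
                                        ...) {
  quantity <- match.arg(quantity)
  df <- dplyr::filter(object$timeline, .data[[quantity]] > 0)
  ggplot(df, aes(x = .data$time_s / 86400, y = .data[[quantity]],
                 colour = .data$nuclide, linetype = .data$phase)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "time (days)",
         y = if (quantity == "atoms") "atoms" else "activity (GBq)",
         title = object$summary$scenario)
}

#' Plot a yield report
#'
#' @param object A tibble from [yield_report()].
#' @param ... Unused.
#' @return A ggplot of per-nuclide activities.
#' @export
plot_yield_report <- function(object, ...) {
  ggplot(object, aes(x = .data$nuclide, y = .data$activity_gbq)) +
    geom_col() +
    scale_y_log10() +
    labs(x = NULL, y = "activity (GBq)")
}
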