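#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated microcosm incubation
#'
#' Measured (noisy) replicate series as points over the noiseless truth as
#' lines, one facet per measured analyte.
#'
#' @param object A [simulate_microcosm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.microcosm_sim <- function(object, ...) {
  measured <- unique(object$series$analyte)
  truth <- dplyr::filter(object$truth, .data$pool %in% measured)
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$day, y = .data$concentration_uM)) +
    ggplot2::geom_line(data = truth,
                       ggplot2::aes(x = .data$day, y = .data$uM),
                       colour = "grey40", inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$replicate), alpha = 0.7) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Day", y = expression("Concentration (" * mu * "M slurry)"),
                  title = sprintf("Microcosm '%s'", object$design$treatment_id)) +
    ggplot2::theme_minimal()
}

#' Plot closed-chamber series with fitted accumulation lines
#'
#' @param object A [chamber_flux()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chamber_flux <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$hour, y = .data$ppmv,
                                            colour = .data$plot)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~gas, scales = "free_y") +
    ggplot2::labs(x = "Hours after chamber closure", y = "Mixing ratio (ppmv)") +
    ggplot2::theme_minimal()
}

#' Bar chart of net carbon and reductant turnover
#'
#' Positive bars are net production, negative net consumption, per compound
#' and time frame — the standard way turnover budgets of anoxic incubations
#' are displayed.
#'
#' @param table A [net_turnover()] table.
#' @param basis `"carbon"` or `"reductant"`.
#' @return A ggplot object.
#' @export
plot_turnover <- function(table, basis = c("carbon", "reductant")) {
  basis <- match.arg(basis)
  col <- paste0(basis, "_uM")
  tbl <- dplyr::mutate(table,
                       frame = sprintf("day %g–%g", .data$t_start, .data$t_end))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$analyte, y = .data[[col]],
                                    fill = .data$analyte)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(treatment ~ frame) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Net %s turnover (µM %s)", basis,
                              if (basis == "carbon") "C" else "e⁻")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
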