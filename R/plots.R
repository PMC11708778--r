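# ggplot2 renderings of the two result types a mechanism report centres
# on: the stepped Gibbs profile and the barrier-contribution vs
# pole-distance scatter.

#' Plot a Gibbs free-energy profile
#'
#' Draws the familiar stepped reaction profile: a horizontal level per
#' stationary state, connected by dashed risers, with the rate-limiting
#' transition state highlighted.
#'
#' @param object A `reaction_profile`.
#' @param level_width Half-width of each state's level on the reaction
#'   coordinate (dimensionless).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' prof <- assemble_profile(make_step_table("stage1-paper"), "acylation")
#' autoplot(prof)
#' @export
autoplot.reaction_profile <- function(object, level_width = 0.3, ...) {
  st <- dplyr::mutate(object$states, pos = dplyr::row_number())
  st$highlight <- st$label == object$rate_limiting$ts_label
  segs <- dplyr::mutate(st,
                        x = .data$pos - level_width,
                        xend = .data$pos + level_width)
  risers <- tibble::tibble(
    x = segs$xend[-nrow(segs)], xend = segs$x[-1],
    y = segs$G[-nrow(segs)], yend = segs$G[-1]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = risers,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend),
      linetype = "dashed", colour = "grey55") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$G,
                   yend = .data$G, colour = .data$highlight),
      linewidth = 1.4) +
    ggplot2::geom_text(
      data = segs,
      ggplot2::aes(x = .data$pos, y = .data$G, label = .data$label),
      vjust = -0.9, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey20",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(
      x = "reaction coordinate",
      y = expression(Delta * G ~ "(kcal/mol)"),
      title = paste0(object$stage, " stage"),
      subtitle = paste0("rate-limiting ", object$rate_limiting$ts_label,
                        ": span ", round(object$rate_limiting$span, 1),
                        " kcal/mol")) +
    ggplot2::theme_minimal()
}

#' Plot a residue scan against the macrodipole axis
#'
#' Scatter of each residue's barrier contribution against its
#' pole-distance difference, coloured by charge class. The top half holds
#' the destabilizers (mutation targets); the left half holds residues
#' closer to the positive pole. Residues beyond the relevance cutoff are
#' labelled.
#'
#' @param object A `residue_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_scan <- function(object, ...) {
  cutoff <- attr(object, "relevance_cutoff") %||% 1.0
  lab <- dplyr::filter(object, .data$relevant)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta_d, y = .data$contribution,
                               fill = .data$charge_class)) +
    ggplot2::geom_hline(yintercept = c(-cutoff, 0, cutoff),
                        linetype = c("dotted", "solid", "dotted"),
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(shape = 21, size = 2.5, colour = "grey20") +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(label = paste0(.data$residue_name, .data$residue_id)),
      vjust = -1, size = 2.8, colour = "grey10") +
    ggplot2::scale_fill_manual(values = c(
      positive = "#4575b4", negative = "#d73027",
      polar = "#66bd63", hydrophobic = "white")) +
    ggplot2::labs(
      x = "d(residue, + pole) - d(residue, - pole)  (Å)",
      y = "barrier contribution (kcal/mol)",
      fill = "charge class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
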