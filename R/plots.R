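#' Histogram of hub APCC values
#'
#' The distribution of the averaged neighbour correlation of hubs; on
#' data with anti-correlated connectors it shows a distinct mode at
#' negative APCC (the fight-club hubs) next to the low- and high-positive
#' date and party modes.
#'
#' @param ct A `cartography_table`.
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot object.
#' @export
plot_apcc_distribution <- function(ct, binwidth = 0.05) {
  stopifnot(inherits(ct, "cartography_table"))
  hubs <- ct[ct$hub, , drop = FALSE]
  ggplot2::ggplot(hubs, ggplot2::aes(x = .data$APCC)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "APCC of hubs", y = "count",
                  title = "Hub co-expression with network neighbours") +
    ggplot2::theme_minimal()
}

#' Heat cartography map
#'
#' Nodes in the `(K_pi, z_g)` plane, coloured red (positive APCC) to blue
#' (negative APCC), with the seven region boundaries drawn and switch
#' genes circled.
#'
#' @param ct A `cartography_table`.
#' @param boundaries The [region_boundaries()] used to build `ct`.
#' @return A ggplot object.
#' @export
plot_heat_cartography <- function(ct, boundaries = region_boundaries()) {
  stopifnot(inherits(ct, "cartography_table"))
  b <- boundaries
  zr <- range(ct$z_g, b$z_cut)
  labels <- data.frame(
    region = c("R1", "R2", "R3", "R4", "R5", "R6", "R7"),
    x = c((0 + b$low[1]) / 2, mean(b$low[1:2]), mean(b$low[2:3]),
          (b$low[3] + 1) / 2,
          b$high[1] / 2, mean(b$high), (b$high[2] + 1) / 2),
    y = c(rep(zr[1], 4L), rep(zr[2], 3L)))
  p <- ggplot2::ggplot(ct, ggplot2::aes(x = .data$K_pi, y = .data$z_g)) +
    ggplot2::geom_hline(yintercept = b$z_cut, linetype = 2) +
    ggplot2::annotate("segment", x = b$low, xend = b$low,
                      y = -Inf, yend = b$z_cut, linetype = 3) +
    ggplot2::annotate("segment", x = b$high, xend = b$high,
                      y = b$z_cut, yend = Inf, linetype = 3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$APCC), size = 1.6) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey85",
                                    high = "red", midpoint = 0,
                                    limits = c(-1, 1)) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$region),
                       inherit.aes = FALSE, size = 3, colour = "grey40") +
    ggplot2::labs(x = expression(K[pi]), y = expression(z[g]),
                  title = "Heat cartography map") +
    ggplot2::theme_minimal()
  if (any(ct$switch))
    p <- p + ggplot2::geom_point(data = ct[ct$switch, , drop = FALSE],
                                 shape = 21, size = 3.2, stroke = 0.7,
                                 colour = "black", fill = NA)
  p
}

#' Degree distribution on log-log axes
#' @param g An igraph graph.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(g) {
  hist <- degree_summary(g)$histogram
  hist <- hist[hist$degree > 0 & hist$count > 0, , drop = FALSE]
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of nodes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Removal curves for all strategies
#'
#' Average shortest path as a function of the fraction of category nodes
#' removed; the matched random baseline of each strategy is drawn dashed.
#'
#' @param curves Output of [compare_strategies()].
#' @return A ggplot object.
#' @export
plot_removal_curves <- function(curves) {
  long <- rbind(
    data.frame(strategy = curves$strategy, fraction = curves$fraction,
               asp = curves$asp, kind = "targeted"),
    data.frame(strategy = curves$strategy, fraction = curves$fraction,
               asp = curves$asp_random, kind = "matched random"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$asp,
                                     colour = .data$strategy,
                                     linetype = .data$kind)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_linetype_manual(values = c(targeted = 1,
                                              `matched random` = 2)) +
    ggplot2::labs(x = "fraction of category removed",
                  y = "average shortest path",
                  title = "Network vulnerability to targeted removal") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a low/high stratification
#' @param records Output of [stratify_by_expression()].
#' @param gene Gene name used in the title.
#' @return A ggplot object.
#' @export
plot_km <- function(records, gene = "") {
  steps <- do.call(rbind, lapply(split(records, records$group), function(part) {
    km <- km_estimate(part)
    data.frame(group = part$group[1L],
               time = c(0, km$time), surv = c(1, km$surv))
  }))
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  title = paste("Kaplan-Meier:", gene)) +
    ggplot2::theme_minimal()
}
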