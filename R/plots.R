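# Figures: deviation heat maps and the cumulative quality stack.

#' Heat map of a deviation surface
#'
#' Diverging palette centered at zero; cells within the experimental error
#' band (the surface's `mask`) are drawn white.  For order parameters, blue
#' (negative) means the simulated chains are too ordered.
#'
#' @param ds a deviation surface from [deviation_surface()].
#' @param coord_lab,title axis label for the first axis and plot title.
#' @return A ggplot object.
#' @export
plot_deviation_map <- function(ds, coord_lab = "carbon", title = NULL) {
  stopifnot(inherits(ds, "deviation_surface"))
  df <- expand.grid(coord = ds$coord, chol = ds$chol_grid)
  df$dev <- as.vector(ds$values)
  df$dev[as.vector(ds$mask)] <- NA_real_
  lim <- max(abs(ds$values), ds$band)
  ggplot2::ggplot(df, ggplot2::aes(x = chol, y = coord, fill = dev)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  midpoint = 0, limits = c(-lim, lim),
                                  na.value = "white", name = "sim - exp") +
    ggplot2::labs(x = "CHOL (mol %)", y = coord_lab, title = title) +
    ggplot2::theme_minimal()
}

#' Stacked-area plot of the cumulative quality report
#'
#' @param report a `quality_report` from [cumulative_quality()].
#' @return A ggplot object.
#' @export
plot_cumulative_quality <- function(report) {
  stopifnot(inherits(report, "quality_report"))
  wide <- report$components
  long <- do.call(rbind, lapply(report$order, function(cmp)
    data.frame(chol = wide$chol_mol_pct, component = cmp, dev = wide[[cmp]])))
  long$component <- factor(long$component, levels = rev(report$order))
  ggplot2::ggplot(long, ggplot2::aes(x = chol, y = dev, fill = component)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "CHOL (mol %)", y = "relative deviation (%)") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("chol", "coord", "dev", "component"))
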