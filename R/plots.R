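# ggplot2 views of the main result types. Each plot_* function takes the
# tabular result; autoplot() methods dispatch on the fitted objects.

#' Plot the photic:aphotic ratio diagnostic
#'
#' Per-dataset log2 photic:aphotic ratios against the reference bands
#' (centre ± halfwidth ribbons); point colour shows the zone call.
#'
#' @param ratios Ratio tibble with `zone_call` (see [classify_zones()]).
#' @param bands A `ratio_bands` object.
#' @return A ggplot.
#' @export
plot_ratio_diagnostic <- function(ratios, bands) {
  b <- tidy(bands)
  ratios <- ratios |> mutate(dataset_id = factor(.data$dataset_id,
                                                 levels = .data$dataset_id))
  ggplot(ratios, aes(x = .data$dataset_id, y = .data$log2_ratio)) +
    geom_rect(data = b, inherit.aes = FALSE,
              aes(xmin = -Inf, xmax = Inf,
                  ymin = .data$center - .data$halfwidth,
                  ymax = .data$center + .data$halfwidth,
                  fill = .data$zone), alpha = 0.15) +
    geom_hline(data = b, aes(yintercept = .data$center, colour = .data$zone),
               linetype = 2, show.legend = FALSE) +
    geom_point(aes(colour = .data$zone_call), size = 2) +
    labs(x = NULL, y = "log2 photic:aphotic core abundance ratio",
         colour = "zone call", fill = "reference band") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.ratio_bands <- function(object, ratios, ...) {
  plot_ratio_diagnostic(ratios, object)
}

#' Plot the group-I oxygen dose-response
#'
#' Mean group-I COG abundance per dataset against dissolved oxygen
#' (log10 axis), with the estimated threshold as a dashed line.
#'
#' @param profile Tibble from [group_i_profile()].
#' @param threshold Optional `threshold_estimate`.
#' @return A ggplot.
#' @export
plot_oxygen_response <- function(profile, threshold = NULL) {
  p <- ggplot(profile, aes(x = .data$do_umol_kg, y = .data$group_i_mean)) +
    geom_point(size = 2, colour = "steelblue") +
    scale_x_log10() +
    labs(x = "dissolved oxygen (µmol/kg)",
         y = "mean group-I COG abundance (reads per common depth)") +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + geom_vline(xintercept = threshold$threshold_o2, linetype = 2)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.threshold_estimate <- function(object, profile, ...) {
  plot_oxygen_response(profile, object)
}

#' Phylum-by-dataset heatmap of core-COG reads
#'
#' Read counts (log10(1+n) fill) of the top phyla across datasets.
#'
#' @param table A `phylum_counts` tibble.
#' @param top Number of phyla shown (ranked as in [top_phyla()]).
#' @return A ggplot.
#' @export
plot_phylum_heatmap <- function(table, top = 10) {
  keep <- top_phyla(table, top)
  dat <- table |>
    filter(.data$phylum %in% keep) |>
    group_by(.data$phylum, .data$dataset_id) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    mutate(phylum = factor(.data$phylum, levels = rev(keep)))
  ggplot(dat, aes(x = .data$dataset_id, y = .data$phylum,
                  fill = log10(1 + .data$n))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10(1+reads)") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.phylum_counts <- function(object, top = 10, ...) {
  plot_phylum_heatmap(object, top = top)
}

#' Plot a bootstrap-supported dendrogram
#'
#' Base-graphics dendrogram with node supports printed above internal
#' nodes that exceed `min_support`.
#'
#' @param x A `boot_dendro`.
#' @param min_support Only supports at or above this value are printed
#'   (default 60).
#' @param ... Passed to [plot.hclust()].
#' @export
plot.boot_dendro <- function(x, min_support = 60, ...) {
  hc <- x$hclust
  graphics::plot(hc, sub = "", xlab = "", ...)
  sup <- x$support$support
  show <- sup >= min_support
  if (any(show)) {
    # x position of each internal node = mean leaf position of its members
    leaf_pos <- setNames(seq_along(hc$labels[hc$order]), hc$labels[hc$order])
    sets <- hclust_leafsets(hc)
    xs <- vapply(sets, function(s) mean(leaf_pos[s]), numeric(1))
    graphics::text(xs[show], hc$height[show], sprintf("%.0f", sup[show]),
                   pos = 3, cex = 0.7, col = "firebrick")
  }
  invisible(x)
}
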