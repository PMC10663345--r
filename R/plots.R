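#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_boxplot
#'   geom_jitter labs theme_bw facet_wrap
#' @export
ggplot2::autoplot

#' Ordination plot of a PCoA embedding
#'
#' Scatter of the two leading real principal coordinates, with points
#' optionally coloured and shaped by metadata factors; axis labels carry
#' the fraction of positive eigenvalue mass explained.
#'
#' @param object A `pcoa_embedding`.
#' @param metadata Optional sample metadata joined on `sample_id`.
#' @param colour,shape Metadata column names for the aesthetics.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_embedding
#' @export
autoplot.pcoa_embedding <- function(object, metadata = NULL,
                                    colour = NULL, shape = NULL, ...) {
  df <- tidy(object, n_axes = 2)
  vexp <- attr(df, "axis_variance")
  if (!is.null(metadata))
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  p <- ggplot(df, aes(x = .data$PCo1, y = .data$PCo2))
  mapping <- list()
  if (!is.null(colour)) mapping$colour <- rlang::sym(colour)
  if (!is.null(shape)) mapping$shape <- rlang::sym(shape)
  if (length(mapping) > 0)
    p <- p + geom_point(do.call(aes, mapping), size = 2)
  else p <- p + geom_point(size = 2)
  p + labs(x = sprintf("PCo1 (%.1f%%)", 100 * vexp[1]),
           y = sprintf("PCo2 (%.1f%%)", 100 * vexp[2])) +
    theme_bw()
}

#' Dispersion plot for a PERMDISP fit
#'
#' Boxplots of per-sample distances to the group centre, one box per
#' group.
#'
#' @param object A `permdisp` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permdisp
#' @export
autoplot.permdisp <- function(object, ...) {
  ggplot(object$distances,
         aes(x = .data$group, y = .data$distance)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    labs(x = NULL, y = "distance to group centre") +
    theme_bw()
}

#' Within-individual homogeneity plot
#'
#' Boxplots of per-plant mean distance-to-median, grouped by genotype and
#' faceted by developmental stage.
#'
#' @param object A `homogeneity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot homogeneity_result
#' @export
autoplot.homogeneity_result <- function(object, ...) {
  ggplot(object$plants,
         aes(x = .data$genotype, y = .data$mean_dist_to_median)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    facet_wrap(~stage) +
    labs(x = NULL, y = "mean distance to plant median community") +
    theme_bw()
}

#' Alpha-diversity plot
#'
#' Boxplots of a chosen per-sample alpha metric across a metadata factor.
#'
#' @param alpha Output of [alpha_diversity()].
#' @param metadata Sample metadata.
#' @param metric Column of `alpha` to plot (e.g. `"shannon"`).
#' @param by Metadata factor on the x axis (default `"genotype"`).
#' @param facet_by Optional metadata factor to facet by.
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha, metadata, metric = "shannon",
                                 by = "genotype", facet_by = NULL) {
  df <- dplyr::left_join(alpha, metadata, by = "sample_id")
  p <- ggplot(df, aes(x = .data[[by]], y = .data[[metric]])) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    labs(x = NULL, y = metric) +
    theme_bw()
  if (!is.null(facet_by)) p <- p + facet_wrap(stats::reformulate(facet_by))
  p
}
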