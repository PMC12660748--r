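#' Dot-track plot of repeat positions along genomes
#'
#' One horizontal lane per genome (ordered by decreasing length), a dot per
#' repeat region at its midpoint — the standard way to compare repeat
#' abundance and distribution across a cohort at a glance.
#'
#' @param object A `repeat_track` from [repeat_track()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot repeat_track
#' @export
autoplot.repeat_track <- function(object, ...) {
  glev <- object$genomes$genome_id  # already ordered by decreasing length
  mids <- dplyr::mutate(
    object$midpoints,
    genome_id = factor(.data$genome_id, levels = rev(glev))
  )
  lens <- dplyr::mutate(
    object$genomes,
    genome_id = factor(.data$genome_id, levels = rev(glev))
  )
  ggplot2::ggplot(mids) +
    ggplot2::geom_segment(
      data = lens,
      ggplot2::aes(x = 0, xend = .data$length, y = .data$genome_id,
                   yend = .data$genome_id),
      linewidth = 0.3, colour = "grey70"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$midpoint, y = .data$genome_id),
      shape = 16, size = 1, alpha = 0.7
    ) +
    ggplot2::scale_x_continuous(labels = function(x) x / 1e3) +
    ggplot2::labs(x = "position (kbp)", y = NULL,
                  title = "Perfect tandem-repeat regions") +
    ggplot2::theme_minimal()
}

#' Heatmap of the subfamily copy-number matrix
#'
#' @param object A `subfamily_matrix` from [subfamily_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subfamily_matrix
#' @export
autoplot.subfamily_matrix <- function(object, ...) {
  df <- tidy(object)
  df$subfamily <- factor(df$subfamily, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_id, y = .data$subfamily,
                                   fill = .data$n_genes)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_genes), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "genes",
                  title = "Gene copies per subfamily and genome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean-versus-SD plot of gene-position conservation
#'
#' Each point is an ortholog group at its mean normalized position and
#' positional SD; the dashed line marks the conservation threshold.
#'
#' @param object A `position_conservation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot position_conservation
#' @export
autoplot.position_conservation <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$mean_position,
                               y = .data$sd_position,
                               colour = .data$conserved)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$sd_threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "mean normalized position", y = "positional SD",
                  colour = paste0("SD ≤ ", object$sd_threshold),
                  title = "Gene-position conservation across genomes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
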