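#' Plot detector traces with detected CAD peaks
#'
#' @param trace A trace tibble (typically the pretreated CAD signal).
#' @param peaks Optional peak tibble; shaded and marked when given.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, peaks = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = time, y = intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "retention time [min]", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    p <- p +
      ggplot2::geom_rect(
        data = peaks,
        ggplot2::aes(xmin = left_bound, xmax = right_bound,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
      ) +
      ggplot2::geom_vline(
        data = peaks, ggplot2::aes(xintercept = apex_time),
        linetype = "dotted", colour = "steelblue4"
      )
  }
  p
}

#' Pseudochromatogram bar plot
#'
#' Bars at each reported peak's apex retention time, height equal to the
#' integrated CAD area, filled by annotation category (taxon level or
#' chemical pathway/superclass).
#'
#' @param bars Bar series tibble from [pseudochromatogram()].
#' @return A ggplot object.
#' @export
plot_pseudochromatogram <- function(bars) {
  ggplot2::ggplot(bars, ggplot2::aes(x = rt, y = value, fill = category)) +
    ggplot2::geom_col(width = 0.12) +
    ggplot2::labs(x = "retention time [min]", y = "CAD peak area",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Treemap-style composition bar
#'
#' Renders the category fractions of [treemap_fractions()] as a single
#' stacked bar (a faithful, dependency-light stand-in for a rectangle
#' treemap: the filled length is proportional to the fraction).
#'
#' @param fractions Tibble from [treemap_fractions()].
#' @return A ggplot object.
#' @export
plot_treemap <- function(fractions) {
  ggplot2::ggplot(
    fractions,
    ggplot2::aes(x = "composition", y = fraction, fill = category)
  ) +
    ggplot2::geom_col(position = "stack", width = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Filter-cascade alluvial bar plot
#'
#' Shows how many CAD peaks fall into each candidate-structure-count bin
#' at each cascade stage.
#'
#' @param alluvial Tibble from [alluvial_counts()].
#' @return A ggplot object.
#' @export
plot_alluvial_counts <- function(alluvial) {
  alluvial$stage <- factor(
    alluvial$stage,
    levels = c("none", "shape", "shape+taxon", "shape+taxon+confidence")
  )
  alluvial$bin <- factor(alluvial$bin, levels = c("0", "1", "2", "3-5", ">5"))
  ggplot2::ggplot(
    alluvial,
    ggplot2::aes(x = stage, y = n_peaks, fill = bin)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "filter stage", y = "CAD peaks",
                  fill = "structures/peak") +
    ggplot2::theme_minimal()
}
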