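# ggplot2 views of scan results.

#' Plot neighborhood heme content
#'
#' Scatter of MHC count against total hemes per neighborhood, colored by
#' whether the neighborhood passes the inclusion criteria — the standard
#' view of a survey's neighborhood landscape (decaheme-dominated clusters
#' show up as horizontal bands at multiples of ten).
#'
#' @param object An `mhc_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mhc_scan <- function(object, ...) {
  nb <- object$neighborhoods
  ggplot(nb, aes(x = .data$n_mhc, y = .data$total_hemes,
                 colour = .data$passes)) +
    geom_point(size = 2, alpha = 0.8) +
    scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "#b2182b"),
                        name = "passes criteria") +
    labs(x = "MHC genes in neighborhood", y = "total hemes in neighborhood") +
    theme_minimal()
}

#' Histogram of per-protein heme counts
#'
#' @param x An `mhc_scan` object or a tibble with a `heme_count` column.
#' @param min_hemes Lowest count shown (default 1 — the heme-free bulk of
#'   the proteome is uninformative).
#' @return A ggplot.
#' @export
plot_heme_counts <- function(x, min_hemes = 1L) {
  df <- if (inherits(x, "mhc_scan")) x$proteins else x
  df <- df[df$heme_count >= min_hemes, , drop = FALSE]
  ggplot(df, aes(x = .data$heme_count)) +
    geom_histogram(binwidth = 1, fill = "#762a83", colour = "white") +
    labs(x = "heme-binding motifs per protein", y = "proteins") +
    theme_minimal()
}

#' Gene map of one neighborhood
#'
#' Draws the member genes of a neighborhood along the contig as bars scaled
#' by heme count, annotated with localization.
#'
#' @param object An `mhc_scan` object.
#' @param neighborhood_id Which neighborhood to draw (default: the first
#'   passing one).
#' @return A ggplot.
#' @export
plot_neighborhood <- function(object, neighborhood_id = NULL) {
  nb <- object$neighborhoods
  if (nrow(nb) == 0L) abort("No neighborhoods to plot.")
  if (is.null(neighborhood_id)) {
    neighborhood_id <- if (any(nb$passes)) nb$neighborhood_id[nb$passes][1]
                       else nb$neighborhood_id[1]
  }
  m <- nb$members[[match(neighborhood_id, nb$neighborhood_id)]]
  ggplot(m, aes(xmin = .data$start, xmax = .data$end, ymin = 0,
                ymax = .data$heme_count, fill = .data$localization)) +
    ggplot2::geom_rect(colour = "grey30") +
    labs(title = neighborhood_id, x = "contig position (bp)",
         y = "heme-binding motifs") +
    theme_minimal()
}
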