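#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a depth histogram
#'
#' @param object A `depth_histogram`.
#' @param trough Optional trough depth to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_histogram <- function(object, trough = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width") %||% 1,
                      fill = "grey35") +
    ggplot2::labs(x = "mean long-read depth", y = "loci") +
    ggplot2::theme_minimal()
  if (!is.null(trough) && !is.na(trough))
    p <- p + ggplot2::geom_vline(xintercept = trough, colour = "orange",
                                 linewidth = 1)
  p
}

#' Plot a depth-tier report (histogram with trough cut)
#'
#' @param object A `depth_tier_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_tier_report <- function(object, ...) {
  if (is.null(object$histogram))
    stop("report carries no histogram", call. = FALSE)
  autoplot(object$histogram, trough = object$trough_depth)
}

#' Bar plot of a region summary
#'
#' @param summary A `region_summary` from [summarize_regions()].
#' @return A ggplot with insertion events and deleted bases per region
#'   class.
#' @export
plot_region_summary <- function(summary) {
  long <- tidyr::pivot_longer(tibble::as_tibble(summary),
                              c("ins_events", "del_bases"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$region_class, levels = region_classes),
    y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Gel-style plot of a predicted band pattern
#'
#' @param object A `band_pattern`.
#' @param ... Unused.
#' @return A ggplot mimicking two gel lanes.
#' @export
autoplot.band_pattern <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(sex = "female", band = object$female),
    tibble::tibble(sex = "male", band = object$male))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sex, y = .data$band)) +
    ggplot2::geom_tile(width = 0.6, height = 8, fill = "white") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "product size (bp)", x = NULL) +
    ggplot2::theme_dark()
}

#' Funnel plot of stage counts
#'
#' @param funnel Tibble from [funnel_stats()].
#' @return A ggplot.
#' @export
plot_funnel <- function(funnel) {
  funnel$stage <- factor(funnel$stage, levels = unique(funnel$stage))
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$stage, y = .data$count,
                                       fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "variant sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
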