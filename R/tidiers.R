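#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bidirectional scan into one variant table
#'
#' @param x A `sexscan` object.
#' @param ... Unused.
#' @return Both direction catalogs bound into one tibble with a
#'   `direction` column.
#' @export
tidy.sexscan <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$catalog_f, direction = "female_ref"),
    dplyr::mutate(x$catalog_m, direction = "male_ref"))
}

#' One-row summary of a bidirectional scan
#'
#' @param x A `sexscan` object.
#' @param ... Unused.
#' @return A one-row tibble of per-direction INS/DEL counts and the
#'   reconciliation rate.
#' @export
glance.sexscan <- function(x, ...) {
  tibble::tibble(
    ins_f = sum(x$catalog_f$type == "INS"),
    del_f = sum(x$catalog_f$type == "DEL"),
    ins_m = sum(x$catalog_m$type == "INS"),
    del_m = sum(x$catalog_m$type == "DEL"),
    n_reconciled = sum(x$reconciliation$matched),
    reconciliation_rate = if (nrow(x$reconciliation) > 0)
      mean(x$reconciliation$matched) else NA_real_)
}

#' Tidy a depth-tier report
#'
#' @param x A `depth_tier_report`.
#' @param ... Unused.
#' @return The per-marker tier tibble.
#' @export
tidy.depth_tier_report <- function(x, ...) x$tiers

#' One-row summary of a depth-tier report
#'
#' @param x A `depth_tier_report`.
#' @param ... Unused.
#' @return A one-row tibble: locus count, trough, high-quality count.
#' @export
glance.depth_tier_report <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$tiers), trough_depth = x$trough_depth,
                 n_high_quality = x$n_high_quality)
}
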