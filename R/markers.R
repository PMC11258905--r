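#' Assemble per-variant evidence into a marker catalog
#'
#' Inner-joins the variant catalog with its annotation, primer, e-PCR and
#' depth-tier evidence by variant id and ranks markers by quality:
#' diagnostic band pattern first, then depth tier (high-quality first),
#' then ascending depth, then primer penalty, then id. The ranking composes
#' the two explicit marker preferences (diagnostic pattern; lower long-read
#' depth) lexicographically rather than with invented numeric weights.
#'
#' @param variants Variant catalog tibble.
#' @param annotations Tibble `id`, `region_class` (and optionally more).
#' @param primers Primer-pair tibble (`variant_id`, `penalty`, ...).
#' @param epcr_results Tibble `id`, `diagnostic`, `band_f`, `band_m` (band
#'   lengths or list columns).
#' @param depth_tiers Tibble `id`, `mean_depth`, `tier` (from a
#'   `depth_tier_report`).
#' @return A tibble of class `marker_catalog`, one row per marker with all
#'   evidence columns and `quality_rank`.
#' @export
build_markers <- function(variants, annotations, primers, epcr_results,
                          depth_tiers) {
  for (d in list(variants, annotations, epcr_results, depth_tiers)) {
    ids <- if (!is.null(d$id)) d$id else d$variant_id
    if (anyDuplicated(ids))
      stop("duplicate variant ids in marker evidence", call. = FALSE)
  }
  if (anyDuplicated(primers$variant_id))
    stop("duplicate variant ids in marker evidence", call. = FALSE)
  out <- variants |>
    dplyr::inner_join(annotations, by = "id") |>
    dplyr::inner_join(dplyr::rename(primers, id = "variant_id"),
                      by = "id") |>
    dplyr::inner_join(epcr_results, by = "id") |>
    dplyr::inner_join(depth_tiers, by = "id")
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$diagnostic),
                   factor(.data$tier,
                          levels = c("high_quality", "standard")),
                   .data$mean_depth, .data$penalty, .data$id) |>
    dplyr::mutate(quality_rank = dplyr::row_number())
  class(out) <- c("marker_catalog", class(out))
  out
}

#' Stage-count funnel statistics
#'
#' @param stage_counts Named integer vector (or tibble with `stage`,
#'   `count`) of per-stage counts in pipeline order, e.g. scanned ->
#'   large-indel -> primer-designed -> single-band -> size-filtered ->
#'   depth-tiered.
#' @param type Optional variant-type label carried through.
#' @return A tibble `stage`, `count`, `type`; a warning is emitted when the
#'   funnel is non-monotone (checked, not enforced).
#' @export
funnel_stats <- function(stage_counts, type = NA_character_) {
  if (is.data.frame(stage_counts)) {
    stages <- stage_counts$stage; counts <- stage_counts$count
  } else {
    stages <- names(stage_counts); counts <- as.integer(stage_counts)
  }
  if (any(diff(counts) > 0))
    warning("funnel counts are not monotone non-increasing: ",
            paste(counts, collapse = " -> "))
  tibble::tibble(stage = stages, count = counts, type = type)
}

#' Shared-call percentage
#'
#' `shared / total x 100`, rounded half-up to two decimals (the convention
#' behind printed figures such as 1,791 / 2,116 = 84.64).
#'
#' @param shared,total Non-negative counts, `shared <= total`, `total > 0`.
#' @return The percentage.
#' @export
overlap_percentage <- function(shared, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(shared < 0 | shared > total))
    stop("need 0 <= shared <= total", call. = FALSE)
  round_half_up(shared / total * 100, 2)
}
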