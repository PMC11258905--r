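#' Mean long-read depth over variant loci
#'
#' For a deletion the window is the deleted reference interval; for an
#' insertion it is the breakpoint extended by `ins_flank_bp` on both sides
#' (clipped to the chromosome when its length is known). Positions missing
#' from the track count as depth 0 -- a deletion with no coverage is the
#' strongest marker signal, not missing data.
#'
#' @param depth_track Tibble with columns `chrom`, `pos` (0-based), `depth`
#'   (see [read_depth_track()]).
#' @param catalog Variant catalog tibble.
#' @param ins_flank_bp Flank around insertion breakpoints, bp.
#' @param chrom_lengths Optional named lengths for window clipping.
#' @return A tibble `id`, `mean_depth`, `n_bases`, ordered as the catalog.
#' @export
locus_depth <- function(depth_track, catalog, ins_flank_bp = 250,
                        chrom_lengths = NULL) {
  if (nrow(catalog) == 0)
    return(tibble::tibble(id = character(), mean_depth = numeric(),
                          n_bases = integer()))
  missing_ch <- setdiff(unique(catalog$ref_chrom), unique(depth_track$chrom))
  if (length(missing_ch) > 0)
    stop("depth track has no positions for chromosome(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  ins <- catalog$type == "INS"
  w_start <- ifelse(ins, pmax(catalog$ref_start - ins_flank_bp, 0),
                    catalog$ref_start)
  w_end <- ifelse(ins, catalog$ref_start + ins_flank_bp, catalog$ref_end)
  if (!is.null(chrom_lengths))
    w_end <- pmin(w_end, unname(chrom_lengths[catalog$ref_chrom]))

  by_ch <- split(seq_len(nrow(depth_track)), depth_track$chrom)
  mean_depth <- numeric(nrow(catalog))
  n_bases <- integer(nrow(catalog))
  for (ch in unique(catalog$ref_chrom)) {
    ti <- by_ch[[ch]]
    pos <- depth_track$pos[ti]
    dep <- depth_track$depth[ti]
    o <- order(pos)
    pos <- pos[o]; dep <- dep[o]
    cs <- c(0, cumsum(dep))
    vi <- which(catalog$ref_chrom == ch)
    lo <- findInterval(w_start[vi] - 0.5, pos)   # positions < w_start
    hi <- findInterval(w_end[vi] - 0.5, pos)     # positions < w_end
    tot <- cs[hi + 1] - cs[lo + 1]
    n_bases[vi] <- as.integer(w_end[vi] - w_start[vi])
    mean_depth[vi] <- tot / pmax(n_bases[vi], 1L)
  }
  tibble::tibble(id = catalog$id, mean_depth = mean_depth,
                 n_bases = n_bases)
}

#' Depth-frequency histogram over loci
#'
#' Right-open bins `[i*w, (i+1)*w)` starting at 0; counts conserve the
#' number of loci.
#'
#' @param loci Tibble with a `mean_depth` column (from [locus_depth()]).
#' @param bin_width Bin width in depth units.
#' @return A tibble `bin_start`, `bin_mid`, `count`; class
#'   `depth_histogram`.
#' @export
depth_histogram <- function(loci, bin_width = 1.0) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  d <- loci$mean_depth
  if (length(d) == 0) {
    out <- tibble::tibble(bin_start = numeric(), bin_mid = numeric(),
                          count = integer())
  } else {
    b <- floor(d / bin_width)
    tab <- table(b)
    bins <- 0:max(b)
    counts <- integer(length(bins))
    counts[match(as.integer(names(tab)), bins)] <- as.integer(tab)
    out <- tibble::tibble(bin_start = bins * bin_width,
                          bin_mid = (bins + 0.5) * bin_width,
                          count = counts)
  }
  attr(out, "bin_width") <- bin_width
  class(out) <- c("depth_histogram", class(out))
  out
}

#' Locate the trough of a depth histogram
#'
#' Counts are smoothed with a centred moving average, then the trough is the
#' centre of the first local minimum after the first local maximum whose
#' depth of dip is at least `min_prominence` of the first peak. A histogram
#' with no qualifying interior minimum (e.g. unimodal) returns `NA`. On real
#' data this is the cut separating the hemizygous low-depth mode (strong
#' sex markers) from the genome-wide coverage mode.
#'
#' @param histogram A [depth_histogram()].
#' @param smooth_window Moving-average window, bins (odd).
#' @param min_prominence Required dip depth as a fraction of the first peak.
#' @return Trough depth (bin centre) or `NA_real_`.
#' @export
find_trough <- function(histogram, smooth_window = 3, min_prominence = 0.05) {
  if (nrow(histogram) == 0) stop("empty histogram", call. = FALSE)
  counts <- histogram$count
  n <- length(counts)
  if (n < 3) return(NA_real_)
  half <- smooth_window %/% 2
  s <- vapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    mean(counts[w])
  }, numeric(1))

  is_max <- function(i) {
    (i == 1 || s[i] >= s[i - 1]) && (i == n || s[i] >= s[i + 1])
  }
  peak <- NA_integer_
  for (i in seq_len(n)) if (is_max(i)) { peak <- i; break }
  if (is.na(peak)) return(NA_real_)
  if (peak + 1 <= n - 1) {
    for (i in (peak + 1):(n - 1)) {
      if (s[i] <= s[i - 1] && s[i] <= s[i + 1]) {
        if (s[peak] - s[i] >= min_prominence * s[peak])
          return(histogram$bin_mid[i])
        # a non-qualifying minimum: keep scanning
      }
    }
  }
  NA_real_
}

#' Tier markers by long-read depth
#'
#' Markers with mean depth strictly below the trough are `high_quality`
#' (the low-depth mode: the locus is absent from the sequenced sex's other
#' haplotype); all others are `standard`. Within each tier markers sort
#' ascending by depth (lower is better), ties by id.
#'
#' @param loci Tibble from [locus_depth()].
#' @param trough_depth Trough from [find_trough()], or a manual override
#'   (the published cuts were 5.48 with the female assembly as reference
#'   and 12.50 with the male); `NA` tiers everything `standard` with a
#'   warning.
#' @param histogram Optional [depth_histogram()] to carry in the report.
#' @return An object of class `depth_tier_report`: `tiers` tibble (`id`,
#'   `mean_depth`, `tier`, `rank`), `trough_depth`, `n_high_quality`,
#'   `histogram`.
#' @export
tier_markers <- function(loci, trough_depth, histogram = NULL) {
  if (is.na(trough_depth)) {
    warning("no trough available; all markers tiered 'standard'")
    trough_depth <- -Inf
  }
  tiers <- loci |>
    dplyr::mutate(tier = ifelse(.data$mean_depth < trough_depth,
                                "high_quality", "standard")) |>
    dplyr::arrange(factor(.data$tier, levels = c("high_quality", "standard")),
                   .data$mean_depth, .data$id) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(
    tiers = tiers,
    trough_depth = if (is.finite(trough_depth)) trough_depth else NA_real_,
    n_high_quality = sum(tiers$tier == "high_quality"),
    histogram = histogram
  ), class = "depth_tier_report")
}

#' Depth histogram, trough and tiers in one step
#'
#' @param loci Tibble from [locus_depth()].
#' @param bin_width,smooth_window,min_prominence Passed through to
#'   [depth_histogram()] and [find_trough()].
#' @param trough_override Use this cut instead of the detected trough.
#' @return A `depth_tier_report`.
#' @export
depth_tier_report <- function(loci, bin_width = 1.0, smooth_window = 3,
                              min_prominence = 0.05,
                              trough_override = NULL) {
  h <- depth_histogram(loci, bin_width)
  trough <- if (!is.null(trough_override)) trough_override
            else if (nrow(h) == 0) NA_real_
            else find_trough(h, smooth_window, min_prominence)
  tier_markers(loci, trough, histogram = h)
}

#' @export
print.depth_tier_report <- function(x, ...) {
  cat("<depth_tier_report>", nrow(x$tiers), "loci; trough at",
      ifelse(is.na(x$trough_depth), "none", format(x$trough_depth)),
      ";", x$n_high_quality, "high-quality\n")
  invisible(x)
}
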