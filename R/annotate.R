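region_classes <- c("five_prime_UTR", "three_prime_UTR", "CDS", "intron",
                    "intergenic")

#' Build an annotation index from a feature table
#'
#' Pre-reduces per-chromosome interval sets for each region class so that
#' point classification and per-base attribution are fast interval queries.
#' Region precedence when features overlap is CDS > 5' UTR > 3' UTR >
#' intron > intergenic; an intron is any base inside a gene span covered by
#' no exon.
#'
#' @param features Feature tibble from [read_gff3()] (may be empty, in which
#'   case everything classifies as intergenic).
#' @return An object of class `annotation_index`.
#' @export
annotation_index <- function(features = NULL) {
  if (is.null(features) || nrow(features) == 0) {
    return(structure(list(by_chrom = list()), class = "annotation_index"))
  }
  mk <- function(df) {
    IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  }
  by_chrom <- lapply(split(features, features$chrom), function(fc) {
    list(
      gene = mk(fc[fc$kind == "gene", ]),
      exon = mk(fc[fc$kind == "exon", ]),
      cds = mk(fc[fc$kind == "CDS", ]),
      utr5 = mk(fc[fc$kind == "five_prime_UTR", ]),
      utr3 = mk(fc[fc$kind == "three_prime_UTR", ])
    )
  })
  structure(list(by_chrom = by_chrom), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("<annotation_index>", length(x$by_chrom), "chromosome(s)\n")
  invisible(x)
}

# precedence-layered interval sets for one chromosome (1-based IRanges)
class_layers <- function(ix, chrom) {
  ch <- ix$by_chrom[[chrom]]
  if (is.null(ch)) return(NULL)
  cds <- ch$cds
  utr5 <- IRanges::setdiff(ch$utr5, cds)
  utr3 <- IRanges::setdiff(IRanges::setdiff(ch$utr3, cds), utr5)
  exonic <- IRanges::union(IRanges::union(cds, utr5),
                           IRanges::union(utr3, ch$exon))
  intron <- IRanges::setdiff(ch$gene, exonic)
  list(CDS = cds, five_prime_UTR = utr5, three_prime_UTR = utr3,
       intron = intron)
}

#' Classify genomic positions into functional region classes
#'
#' @param index An [annotation_index()].
#' @param chrom Chromosome name (scalar or vector recycled against `pos`).
#' @param pos 0-based positions.
#' @param strict Error on a chromosome absent from the index (`TRUE`, the
#'   single-point contract) or classify it intergenic (`FALSE`, useful when
#'   only some chromosomes carry genes).
#' @return Character vector of region classes.
#' @export
classify_point <- function(index, chrom, pos, strict = FALSE) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep("intergenic", n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (!ch %in% names(index$by_chrom)) {
      if (strict && length(index$by_chrom) > 0)
        stop("chromosome '", ch, "' not in annotation index", call. = FALSE)
      next
    }
    layers <- class_layers(index, ch)
    q <- IRanges::IRanges(start = pos[sel] + 1L, width = 1L)
    cls <- rep("intergenic", sum(sel))
    for (nm in rev(names(layers))) {
      hit <- IRanges::overlapsAny(q, layers[[nm]])
      cls[hit] <- nm
    }
    out[sel] <- cls
  }
  out
}

#' Attribute each deleted base to a region class
#'
#' Splits a deletion's reference interval across the region classes under
#' the CDS > UTR > intron > intergenic precedence; the returned totals sum
#' exactly to the deletion length.
#'
#' @param index An [annotation_index()].
#' @param chrom Chromosome name.
#' @param start,end Deletion interval, 0-based half-open.
#' @param chrom_len Optional chromosome length for bounds checking.
#' @return Named numeric vector over all five region classes (bp).
#' @export
attribute_deletion_bases <- function(index, chrom, start, end,
                                     chrom_len = NULL) {
  if (start < 0 || end <= start)
    stop("invalid deletion interval [", start, ", ", end, ")", call. = FALSE)
  if (!is.null(chrom_len) && end > chrom_len)
    stop("deletion interval extends past end of ", chrom, call. = FALSE)
  len <- end - start
  out <- stats::setNames(numeric(length(region_classes)), region_classes)
  layers <- if (chrom %in% names(index$by_chrom)) class_layers(index, chrom)
            else NULL
  q <- IRanges::IRanges(start = start + 1L, end = end)
  acc <- 0
  for (nm in names(layers)) {
    bp <- sum(IRanges::width(IRanges::intersect(q, layers[[nm]])))
    out[[nm]] <- bp
    acc <- acc + bp
  }
  out[["intergenic"]] <- len - acc
  out
}

#' Summarise a catalog by genomic region
#'
#' Insertions are counted per class of their breakpoint (one event each);
#' deletions contribute their deleted bases per class. This is the layout of
#' the positional-distribution table: one row per region class plus totals.
#'
#' @param catalog Variant catalog tibble (one reference direction).
#' @param index An [annotation_index()].
#' @return A tibble with columns `region_class`, `ins_events`, `del_bases`
#'   and an attached `totals` attribute; class `region_summary`.
#' @export
summarize_regions <- function(catalog, index) {
  ins <- catalog[catalog$type == "INS", , drop = FALSE]
  del <- catalog[catalog$type == "DEL", , drop = FALSE]
  ins_cls <- if (nrow(ins)) classify_point(index, ins$ref_chrom,
                                           ins$ref_start)
             else character(0)
  ins_counts <- table(factor(ins_cls, levels = region_classes))
  del_bases <- stats::setNames(numeric(length(region_classes)),
                               region_classes)
  if (nrow(del)) {
    for (i in seq_len(nrow(del))) {
      m <- attribute_deletion_bases(index, del$ref_chrom[i],
                                    del$ref_start[i], del$ref_end[i])
      del_bases <- del_bases + m
    }
  }
  out <- tibble::tibble(
    region_class = region_classes,
    ins_events = as.integer(ins_counts[region_classes]),
    del_bases = as.numeric(del_bases[region_classes])
  )
  attr(out, "totals") <- c(ins_events = sum(out$ins_events),
                           del_bases = sum(out$del_bases))
  class(out) <- c("region_summary", class(out))
  out
}

#' Per-class percentages of a region summary
#'
#' Each value is class / total x 100, rounded half-up to two decimals; the
#' rendered percentages sum to 100 within rounding slack (0.03).
#'
#' @param x Named numeric vector of per-class values, or a `region_summary`
#'   (in which case `measure` picks the column).
#' @param measure `"ins_events"` or `"del_bases"` when `x` is a summary.
#' @return A tibble with `region_class`, `value`, `percent`.
#' @export
percentage_table <- function(x, measure = c("ins_events", "del_bases")) {
  if (inherits(x, "region_summary")) {
    measure <- match.arg(measure)
    x <- stats::setNames(x[[measure]], x$region_class)
  }
  total <- sum(x)
  if (total <= 0) stop("zero total; no percentages to compute", call. = FALSE)
  tibble::tibble(
    region_class = names(x),
    value = as.numeric(x),
    percent = round_half_up(as.numeric(x) / total * 100, 2)
  )
}

#' Attribute variants to repeat classes
#'
#' A variant is attributed to a transposable element when at least
#' `te_threshold` of its allele bases fall inside the supplied repeat
#' intervals; independently, its allele is tested for tandem periodicity.
#' The two categories may overlap. Summary percentages are over the catalog
#' size, half-up to two decimals.
#'
#' @param catalog Variant catalog tibble.
#' @param repeat_intervals Tibble of masked intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open) and optionally `genome` (assembly
#'   label; deletions are measured on the reference, insertions on the
#'   query). `NULL` means no repeat information (all overlaps 0).
#' @param te_threshold Overlap fraction for TE attribution.
#' @param tandem_args List of arguments passed to
#'   [detect_tandem_periodicity()].
#' @return A list of class `repeat_attribution`: `per_variant` tibble
#'   (`id`, `te_overlap`, `te`, `tandem`, `period`) and `summary` (counts
#'   and percentages).
#' @export
attribute_repeats <- function(catalog, repeat_intervals = NULL,
                              te_threshold = 0.5, tandem_args = list()) {
  n <- nrow(catalog)
  te_overlap <- numeric(n)
  if (!is.null(repeat_intervals) && nrow(repeat_intervals) > 0 && n > 0) {
    ri <- repeat_intervals
    if (is.null(ri$genome)) ri$genome <- catalog$ref_label[1] %||% "genome"
    for (i in seq_len(n)) {
      if (catalog$type[i] == "INS") {
        g <- catalog$qry_chrom[i]
        lab <- setdiff(unique(ri$genome), catalog$ref_label[i])
        lab <- if (length(lab)) lab[1] else unique(ri$genome)[1]
        s <- catalog$qry_start[i]; e <- catalog$qry_end[i]; ch <- g
      } else {
        lab <- catalog$ref_label[i]
        s <- catalog$ref_start[i]; e <- catalog$ref_end[i]
        ch <- catalog$ref_chrom[i]
      }
      sel <- ri$genome == lab & ri$chrom == ch
      if (!any(sel) || e <= s) next
      q <- IRanges::IRanges(start = s + 1L, end = e)
      rr <- IRanges::reduce(IRanges::IRanges(start = ri$start[sel] + 1L,
                                             end = ri$end[sel]))
      te_overlap[i] <- sum(IRanges::width(IRanges::intersect(q, rr))) /
        (e - s)
    }
  }
  tandem <- logical(n); period <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    td <- do.call(detect_tandem_periodicity,
                  c(list(catalog$sequence[i]), tandem_args))
    tandem[i] <- td$tandem
    period[i] <- td$period
  }
  per_variant <- tibble::tibble(id = catalog$id, te_overlap = te_overlap,
                                te = te_overlap >= te_threshold,
                                tandem = tandem, period = period)
  summary <- tibble::tibble(
    n = n,
    te_count = sum(per_variant$te),
    te_pct = if (n > 0) round_half_up(sum(per_variant$te) / n * 100, 2)
             else NA_real_,
    tandem_count = sum(per_variant$tandem),
    tandem_pct = if (n > 0)
      round_half_up(sum(per_variant$tandem) / n * 100, 2) else NA_real_
  )
  structure(list(per_variant = per_variant, summary = summary),
            class = "repeat_attribution")
}

#' @export
print.repeat_attribution <- function(x, ...) {
  s <- x$summary
  cat("<repeat_attribution>", s$n, "variants; TE", s$te_count,
      sprintf("(%.2f%%)", s$te_pct), "; tandem", s$tandem_count,
      sprintf("(%.2f%%)", s$tandem_pct), "\n")
  invisible(x)
}

#' Detect tandem periodicity in an allele sequence
#'
#' Lightweight shift-identity test: the sequence is tandem-repetitive if
#' some period `p` (2 to half the length) aligns the sequence with itself
#' shifted by `p` at per-base identity >= `min_identity` over a comparison
#' window of at least `min_span` bp or at least `min_frac` of the allele.
#'
#' @param sequence Nucleotide string (>= 20 bp, otherwise `too_short`).
#' @param min_identity Identity threshold.
#' @param min_span Minimum comparison window, bp.
#' @param min_frac Alternative window floor as a fraction of the allele.
#' @return A list: `tandem` (logical), `period` (best period or `NA`),
#'   `identity` (best identity), `flag` (`"ok"` or `"too_short"`).
#' @export
detect_tandem_periodicity <- function(sequence, min_identity = 0.8,
                                      min_span = 50, min_frac = 0.8) {
  n <- nchar(sequence)
  if (n < 20)
    return(list(tandem = FALSE, period = NA_integer_, identity = NA_real_,
                flag = "too_short"))
  x <- charToRaw(sequence)
  floor_w <- min(min_span, ceiling(min_frac * n))
  best_p <- NA_integer_; best_id <- -Inf
  for (p in 2:(n %/% 2)) {
    w <- n - p
    if (w < floor_w) break
    idy <- mean(x[1:w] == x[(p + 1):n])
    if (idy > best_id) { best_id <- idy; best_p <- p }
  }
  list(tandem = is.finite(best_id) && best_id >= min_identity,
       period = best_p,
       identity = if (is.finite(best_id)) best_id else NA_real_,
       flag = "ok")
}
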