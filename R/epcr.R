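#' Electronic-PCR parameters
#'
#' @param max_mismatches Mismatches tolerated per primer site (3' terminus
#'   excluded). Default 0: primers are screened on the same assemblies they
#'   were designed from.
#' @param three_prime_exact_bp 3'-terminal bases that must match exactly.
#' @param max_product_bp Scan ceiling for amplicon enumeration, bp.
#' @param product_range Size screen applied to bands, bp.
#' @param band_min_bp,band_frac Gel resolution: two lengths merge into one
#'   band when their difference is at most `max(band_min_bp, band_frac x
#'   larger length)`.
#' @return A list of class `epcr_params`.
#' @export
epcr_params <- function(max_mismatches = 0, three_prime_exact_bp = 3,
                        max_product_bp = 5000,
                        product_range = c(100, 2000),
                        band_min_bp = 10, band_frac = 0.02) {
  stopifnot(max_mismatches >= 0, three_prime_exact_bp >= 0,
            product_range[1] <= product_range[2],
            product_range[2] <= max_product_bp)
  structure(list(max_mismatches = max_mismatches,
                 three_prime_exact_bp = three_prime_exact_bp,
                 max_product_bp = max_product_bp,
                 product_range = product_range,
                 band_min_bp = band_min_bp, band_frac = band_frac),
            class = "epcr_params")
}

band_resolution <- function(len, params) {
  pmax(params$band_min_bp, params$band_frac * len)
}

#' Find primer binding sites genome-wide
#'
#' A primer anneals at a position when it matches the sequence with at most
#' `max_mismatches` mismatches and its 3'-terminal `three_prime_exact_bp`
#' bases match exactly; `N` in the genome never matches. Plus-strand sites
#' read the primer left to right; minus-strand sites match its reverse
#' complement. Matching is done with [Biostrings::matchPattern()].
#'
#' @param genome A [genome].
#' @param primer Primer sequence, 5' to 3' (ACGT).
#' @param params An [epcr_params()].
#' @return A tibble: `chrom`, `pos` (0-based footprint start), `strand`,
#'   `mismatches`.
#' @export
find_binding_sites <- function(genome, primer, params = epcr_params()) {
  primer <- toupper(primer)
  if (grepl("[^ACGT]", primer))
    stop("primer contains non-ACGT characters", call. = FALSE)
  m <- nchar(primer)
  if (m < params$three_prime_exact_bp)
    stop("primer shorter than the 3'-exact requirement", call. = FALSE)
  hits <- list()
  for (ch in names(genome$seq)) {
    subj <- Biostrings::DNAString(genome$seq[[ch]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") primer else revcomp(primer)
      mt <- Biostrings::matchPattern(pat, subj,
                                     max.mismatch = params$max_mismatches,
                                     fixed = TRUE)
      if (length(mt) == 0) next
      st0 <- Biostrings::start(mt) - 1L
      seqs <- as.character(mt)
      mm <- vapply(seqs, str_mismatches, numeric(1), b = pat,
                   USE.NAMES = FALSE)
      # exact 3' terminus: rightmost bases on '+', leftmost on '-'
      k <- params$three_prime_exact_bp
      if (k > 0) {
        if (strand == "+") {
          ok <- substr(seqs, m - k + 1, m) == substr(pat, m - k + 1, m)
        } else {
          ok <- substr(seqs, 1, k) == substr(pat, 1, k)
        }
      } else ok <- rep(TRUE, length(seqs))
      ok <- ok & !grepl("N", seqs, fixed = TRUE)
      if (!any(ok)) next
      hits[[length(hits) + 1L]] <- tibble::tibble(
        chrom = ch, pos = st0[ok], strand = strand,
        mismatches = as.integer(mm[ok]))
    }
  }
  if (length(hits) == 0)
    return(tibble::tibble(chrom = character(), pos = integer(),
                          strand = character(), mismatches = integer()))
  dplyr::arrange(dplyr::bind_rows(hits), .data$chrom, .data$pos,
                 .data$strand)
}

#' Enumerate predicted amplicons for a primer pair
#'
#' Every convergent site pair on one chromosome within the scan ceiling
#' yields an amplicon: forward primer on the plus strand upstream of the
#' reverse primer on the minus strand, and the role-swapped orientation
#' (reverse primer on plus, forward on minus). Product length is measured
#' 5' end to 5' end, inclusive of both primer footprints -- the
#' gel-observable size.
#'
#' @param genome A [genome].
#' @param pair One-row primer-pair tibble (needs `fwd_seq`, `rev_seq`).
#' @param params An [epcr_params()].
#' @return A tibble: `genome`, `chrom`, `start`, `end` (0-based half-open
#'   product span), `length`, `fwd_mismatches`, `rev_mismatches`,
#'   `orientation`.
#' @export
predict_amplicons <- function(genome, pair, params = epcr_params()) {
  fs <- find_binding_sites(genome, pair$fwd_seq, params)
  rs <- find_binding_sites(genome, pair$rev_seq, params)
  lens <- c(fwd = nchar(pair$fwd_seq), rev = nchar(pair$rev_seq))
  out <- list()
  emit <- function(left, right, left_len, right_len, orientation) {
    # left: sites on '+', right: sites on '-'
    for (ch in intersect(unique(left$chrom), unique(right$chrom))) {
      a <- left[left$chrom == ch, ]
      b <- right[right$chrom == ch, ]
      for (i in seq_len(nrow(a))) {
        plen <- (b$pos + right_len) - a$pos[i]
        ok <- plen > 0 & plen <= params$max_product_bp
        if (!any(ok)) next
        out[[length(out) + 1L]] <<- tibble::tibble(
          genome = genome$label, chrom = ch,
          start = a$pos[i], end = b$pos[ok] + right_len,
          length = plen[ok],
          fwd_mismatches = if (orientation == "fr") a$mismatches[i]
                           else b$mismatches[ok],
          rev_mismatches = if (orientation == "fr") b$mismatches[ok]
                           else a$mismatches[i],
          orientation = orientation)
      }
    }
  }
  emit(fs[fs$strand == "+", ], rs[rs$strand == "-", ],
       unname(lens["fwd"]), unname(lens["rev"]), "fr")
  emit(rs[rs$strand == "+", ], fs[fs$strand == "-", ],
       unname(lens["rev"]), unname(lens["fwd"]), "rf")
  if (length(out) == 0)
    return(tibble::tibble(genome = character(), chrom = character(),
                          start = integer(), end = integer(),
                          length = integer(), fwd_mismatches = integer(),
                          rev_mismatches = integer(),
                          orientation = character()))
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start,
                 .data$end)
}

#' Collapse amplicon lengths to gel bands
#'
#' Greedy ascending single-linkage clustering: adjacent sorted lengths
#' merge into one band when their difference is within the gel resolution
#' `max(band_min_bp, band_frac x larger)`. Each band is represented by the
#' median of its member lengths.
#'
#' @param lengths Numeric vector of amplicon lengths.
#' @param params An [epcr_params()].
#' @return Sorted numeric vector of band lengths.
#' @export
collapse_bands <- function(lengths, params = epcr_params()) {
  if (length(lengths) == 0) return(numeric(0))
  x <- sort(lengths)
  cluster <- cumsum(c(1, diff(x) > band_resolution(x[-1], params)))
  as.numeric(sort(vapply(split(x, cluster), stats::median, numeric(1))))
}

#' Single-band screen for a primer pair
#'
#' A pair passes when each of the two assemblies yields exactly one band,
#' both bands lie inside the product-size window, and the two bands differ
#' by more than the gel resolution -- i.e. the variant is visible as a size
#' shift on a gel.
#'
#' @param pair One-row primer-pair tibble.
#' @param genomes List of the two [genome] assemblies.
#' @param params An [epcr_params()].
#' @return A list of class `band_screen`: `pass`, `bands` (named list per
#'   genome label), `reason`.
#' @export
screen_single_band <- function(pair, genomes, params = epcr_params()) {
  if (length(genomes) != 2) stop("exactly two genomes required",
                                 call. = FALSE)
  bands <- lapply(genomes, function(g) {
    collapse_bands(predict_amplicons(g, pair, params)$length, params)
  })
  names(bands) <- vapply(genomes, `[[`, "", "label")
  n_bands <- lengths(bands)
  reason <- "ok"
  pass <- TRUE
  if (any(n_bands != 1)) { pass <- FALSE; reason <- "not_single_band" }
  else {
    b <- sort(unlist(bands))
    if (any(b < params$product_range[1] | b > params$product_range[2])) {
      pass <- FALSE; reason <- "size_out_of_range"
    } else if (diff(b) <= band_resolution(b[2], params)) {
      pass <- FALSE; reason <- "bands_not_resolvable"
    }
  }
  structure(list(pass = pass, bands = bands, reason = reason),
            class = "band_screen")
}

#' Predict per-sex gel band patterns
#'
#' The homogametic sex shows the bands of its own assembly; the
#' heterogametic sex carries both haplotypes (e.g. the X1X2Y male in an
#' X1X1X2X2/X1X2Y system), so its pattern is the collapse of the union of
#' amplicons from both assemblies. A marker is diagnostic when the two
#' patterns differ in band count -- the "2 bands in the heterogametic sex,
#' 1 in the homogametic" signature.
#'
#' @param pair One-row primer-pair tibble.
#' @param genome_f,genome_m Female and male [genome] assemblies.
#' @param sex_system `"male_heterogametic"` (XY-like, including X1X2Y) or
#'   `"female_heterogametic"` (ZW-like).
#' @param params An [epcr_params()].
#' @return A list of class `band_pattern`: `female`, `male` (band length
#'   vectors), `diagnostic`.
#' @export
predict_band_pattern <- function(pair, genome_f, genome_m,
                                 sex_system = c("male_heterogametic",
                                                "female_heterogametic"),
                                 params = epcr_params()) {
  sex_system <- match.arg(sex_system)
  amp_f <- predict_amplicons(genome_f, pair, params)$length
  amp_m <- predict_amplicons(genome_m, pair, params)$length
  if (sex_system == "male_heterogametic") {
    female <- collapse_bands(amp_f, params)
    male <- collapse_bands(c(amp_f, amp_m), params)
  } else {
    female <- collapse_bands(c(amp_f, amp_m), params)
    male <- collapse_bands(amp_m, params)
  }
  structure(list(female = female, male = male,
                 diagnostic = length(female) != length(male)),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  cat("<band_pattern> female:", paste(round(x$female), collapse = ", "),
      "| male:", paste(round(x$male), collapse = ", "),
      if (x$diagnostic) "(diagnostic)" else "(non-diagnostic)", "\n")
  invisible(x)
}
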