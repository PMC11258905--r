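#' Primer design parameters
#'
#' Primer3-style constraint set. The only constraint anchored to the
#' published screen is the product window of 100--2,000 bp (gel-resolvable
#' amplicons); the rest are standard PCR design defaults, all exposed here.
#'
#' @param len_range,len_opt Primer length bounds and optimum, nt.
#' @param tm_range,tm_opt Melting-temperature bounds and optimum, deg C.
#' @param gc_range GC-fraction bounds.
#' @param max_homopolymer Longest tolerated single-base run.
#' @param max_pair_tm_diff Maximum |Tm(fwd) - Tm(rev)|, deg C.
#' @param product_range Allowed amplicon size on the design genome, bp.
#' @param flank_search Window searched on each side of the variant, bp.
#' @param margin_bp Required distance between each primer's inner end and
#'   the variant, bp.
#' @param salt_mM Monovalent cation concentration, mM.
#' @param conc_nM Primer concentration, nM.
#' @return A list of class `primer_params`.
#' @export
primer_params <- function(len_range = c(18, 27), len_opt = 20,
                          tm_range = c(57, 63), tm_opt = 60,
                          gc_range = c(0.30, 0.70),
                          max_homopolymer = 4,
                          max_pair_tm_diff = 5,
                          product_range = c(100, 2000),
                          flank_search = 600,
                          margin_bp = 20,
                          salt_mM = 50, conc_nM = 250) {
  stopifnot(len_range[1] <= len_range[2], tm_range[1] <= tm_range[2],
            gc_range[1] <= gc_range[2], product_range[1] >= 1,
            product_range[1] <= product_range[2])
  structure(list(len_range = len_range, len_opt = len_opt,
                 tm_range = tm_range, tm_opt = tm_opt, gc_range = gc_range,
                 max_homopolymer = max_homopolymer,
                 max_pair_tm_diff = max_pair_tm_diff,
                 product_range = product_range, flank_search = flank_search,
                 margin_bp = margin_bp, salt_mM = salt_mM,
                 conc_nM = conc_nM),
            class = "primer_params")
}

# unified nearest-neighbor parameters (Allawi & SantaLucia 1997):
# dH kcal/mol, dS cal/(mol K), 5'->3' top-strand dinucleotides
nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from the unified nearest-neighbor thermodynamic parameter set
#' with terminal-initiation terms, monovalent-salt entropy correction
#' (0.368 (N-1) ln[Na+]) and the CT/4 concentration term for
#' non-self-complementary duplexes:
#' Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15.
#'
#' @param sequence Character vector of oligo sequences (8--50 nt, ACGT).
#' @param salt_mM Monovalent cation concentration, mM.
#' @param conc_nM Total oligo concentration CT, nM.
#' @return Melting temperatures in deg C (vectorised).
#' @export
melting_temperature <- function(sequence, salt_mM = 50, conc_nM = 250) {
  # dinucleotide tables indexed by 4*(first-1) + second over A,C,G,T
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  DH <- nn_dh[dinucs]; DS <- nn_ds[dinucs]
  base_raw <- as.integer(charToRaw("ACGT"))
  rln <- 1.987 * log(conc_nM * 1e-9 / 4)
  salt <- 0.368 * log(salt_mM / 1000)
  vapply(toupper(sequence), function(s) {
    n <- nchar(s)
    if (n < 8 || n > 50)
      stop("oligo length must be 8-50 nt, got ", n, call. = FALSE)
    idx <- match(as.integer(charToRaw(s)), base_raw)
    if (anyNA(idx))
      stop("oligo contains non-ACGT characters", call. = FALSE)
    di <- 4L * (idx[-n] - 1L) + idx[-1L]
    dh <- sum(DH[di])
    ds <- sum(DS[di])
    # terminal initiation: G/C end +0.1 / -2.8, A/T end +2.3 / +4.1
    for (e in idx[c(1L, n)]) {
      if (e == 2L || e == 3L) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + salt * (n - 1)
    1000 * dh / (ds + rln) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# longest complementarity run anchored at the 3' terminus against any
# position of the same oligo (self-dimer screen)
self_dimer_3prime_run <- function(s) {
  n <- nchar(s)
  best <- 0L
  for (run in seq_len(min(n, 12L))) {
    suffix <- substr(s, n - run + 1, n)
    if (grepl(revcomp(suffix), s, fixed = TRUE)) best <- run else break
  }
  best
}

# hairpin: a stem of >= stem_min pairing with a downstream site separated by
# a loop of >= loop_min. Stems of length stem_min at positions i and j pair
# when the i-words of s match the reverse-complemented j-words; positions
# must satisfy j >= i + stem_min + loop_min.
has_hairpin <- function(s, stem_min = 6, loop_min = 3) {
  n <- nchar(s)
  if (n < 2 * stem_min + loop_min) return(FALSE)
  nw <- n - stem_min + 1L
  words <- substring(s, 1:nw, stem_min:n)
  rc <- revcomp(s)
  # rc word starting at k (1-based) covers original positions
  # (n-k-stem_min+2) .. (n-k+1); its original start j = n-k-stem_min+2
  rc_words <- substring(rc, 1:nw, stem_min:n)
  j_of_rc <- n - (1:nw) - stem_min + 2L
  hit <- match(words, rc_words)
  ok <- !is.na(hit) & j_of_rc[ifelse(is.na(hit), 1L, hit)] >=
    (1:nw) + stem_min + loop_min
  if (any(ok)) return(TRUE)
  # match() returns only the first rc occurrence; check duplicates fully
  dup <- unique(words[words %in% rc_words[duplicated(rc_words)]])
  for (w in dup) {
    i_min <- min(which(words == w))
    if (max(j_of_rc[rc_words == w]) >= i_min + stem_min + loop_min)
      return(TRUE)
  }
  FALSE
}

#' Score a primer candidate
#'
#' Hard rejects: length, GC or homopolymer bounds, a self-complementary
#' 3'-anchored run of 5+ bp, or a hairpin stem of 6+ bp with a 3+ nt loop.
#' Accepted candidates get penalty
#' `|Tm - tm_opt| + 0.5 |len - len_opt| + 10 |GC - 0.5|`.
#'
#' @param sequence Primer sequence (ACGT).
#' @param params A [primer_params()].
#' @return A one-row tibble: `sequence`, `accept`, `reason`, `tm`, `gc`,
#'   `penalty` (`NA` when rejected).
#' @export
score_primer <- function(sequence, params = primer_params()) {
  s <- toupper(sequence)
  n <- nchar(s)
  reject <- function(why) tibble::tibble(
    sequence = s, accept = FALSE, reason = why, tm = NA_real_,
    gc = gc_fraction(s), penalty = NA_real_)
  if (grepl("[^ACGT]", s)) return(reject("non_acgt"))
  if (n < params$len_range[1] || n > params$len_range[2])
    return(reject("length"))
  gc <- gc_fraction(s)
  if (gc < params$gc_range[1] || gc > params$gc_range[2])
    return(reject("gc"))
  if (longest_homopolymer(s) > params$max_homopolymer)
    return(reject("homopolymer"))
  if (self_dimer_3prime_run(s) >= 5) return(reject("self_dimer_3prime"))
  if (has_hairpin(s)) return(reject("hairpin"))
  tm <- melting_temperature(s, params$salt_mM, params$conc_nM)
  if (tm < params$tm_range[1] || tm > params$tm_range[2])
    return(reject("tm"))
  penalty <- abs(tm - params$tm_opt) + 0.5 * abs(n - params$len_opt) +
    10 * abs(gc - 0.5)
  tibble::tibble(sequence = s, accept = TRUE, reason = "ok", tm = tm,
                 gc = gc, penalty = penalty)
}

# enumerate and score candidates in a window [w0, w1) of chrom seq;
# returns accepted candidates with 0-based footprint coordinates
enumerate_candidates <- function(chrom_seq, w0, w1, params, reverse) {
  lens <- params$len_range[1]:params$len_range[2]
  cand <- list()
  for (L in lens) {
    if (w1 - w0 < L) next
    starts <- w0:(w1 - L)
    seqs <- substring(chrom_seq, starts + 1, starts + L)
    cand[[length(cand) + 1L]] <- tibble::tibble(
      start = starts, end = starts + L,
      sequence = if (reverse) revcomp(seqs) else seqs
    )
  }
  if (length(cand) == 0) return(NULL)
  cc <- dplyr::bind_rows(cand)
  # cheap vectorised filters first; structural checks on the survivors
  hp_re <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                   params$max_homopolymer + 1, params$max_homopolymer + 1,
                   params$max_homopolymer + 1, params$max_homopolymer + 1)
  gc <- gc_fraction(cc$sequence)
  keep <- !grepl("[^ACGT]", cc$sequence) &
    gc >= params$gc_range[1] & gc <= params$gc_range[2] &
    !grepl(hp_re, cc$sequence)
  cc <- cc[keep, , drop = FALSE]; gc <- gc[keep]
  if (nrow(cc) == 0) return(NULL)
  tm <- melting_temperature(cc$sequence, params$salt_mM, params$conc_nM)
  keep <- tm >= params$tm_range[1] & tm <= params$tm_range[2]
  cc <- cc[keep, , drop = FALSE]; gc <- gc[keep]; tm <- tm[keep]
  if (nrow(cc) == 0) return(NULL)
  keep <- vapply(cc$sequence, function(s) {
    self_dimer_3prime_run(s) < 5 && !has_hairpin(s)
  }, logical(1), USE.NAMES = FALSE)
  cc <- cc[keep, , drop = FALSE]; gc <- gc[keep]; tm <- tm[keep]
  if (nrow(cc) == 0) return(NULL)
  nlen <- nchar(cc$sequence)
  tibble::tibble(start = cc$start, end = cc$end, sequence = cc$sequence,
                 tm = tm, gc = gc,
                 penalty = abs(tm - params$tm_opt) +
                   0.5 * abs(nlen - params$len_opt) +
                   10 * abs(gc - 0.5))
}

#' Design the best primer pair for one variant target
#'
#' Forward candidates are enumerated from the `flank_search` window left of
#' the variant, reverse candidates (reverse-complemented) from the window to
#' its right; neither primer may overlap the variant allele and the product
#' must span the variant with `margin_bp` slack on each side. Among
#' admissible pairs (|dTm| within `max_pair_tm_diff`, product within
#' `product_range`) the pair minimising the summed penalty wins; ties go to
#' the smaller product, then the leftmost forward primer.
#'
#' @param genome Design [genome] (the variant's reference).
#' @param variant One-row variant catalog tibble.
#' @param params A [primer_params()].
#' @return A one-row tibble (`variant_id`, `fwd_seq`, `rev_seq`, `fwd_tm`,
#'   `rev_tm`, `fwd_gc`, `rev_gc`, `fwd_start`, `rev_end`, `penalty`,
#'   `design_product_len`) or `NULL` when no admissible pair exists.
#' @export
design_pair_for_target <- function(genome, variant,
                                   params = primer_params()) {
  chrom <- variant$ref_chrom
  if (!chrom %in% names(genome$seq))
    stop("variant chromosome '", chrom, "' not in genome", call. = FALSE)
  L <- unname(genome$lengths[chrom])
  vstart <- variant$ref_start
  vend <- max(variant$ref_end, variant$ref_start)
  left0 <- max(0, vstart - params$margin_bp - params$flank_search)
  left1 <- vstart - params$margin_bp
  right0 <- vend + params$margin_bp
  right1 <- min(L, vend + params$margin_bp + params$flank_search)
  if (left1 - left0 < params$len_range[1] ||
      right1 - right0 < params$len_range[1]) return(NULL)
  seq_ <- genome$seq[[chrom]]
  fwd <- enumerate_candidates(seq_, left0, left1, params, reverse = FALSE)
  rev_ <- enumerate_candidates(seq_, right0, right1, params, reverse = TRUE)
  if (is.null(fwd) || is.null(rev_)) return(NULL)

  # product length: forward 5' to reverse 5', inclusive of both footprints
  plen <- outer(fwd$start, rev_$end, function(a, b) b - a)
  dtm <- abs(outer(fwd$tm, rev_$tm, `-`))
  pen <- outer(fwd$penalty, rev_$penalty, `+`)
  adm <- plen >= params$product_range[1] & plen <= params$product_range[2] &
    dtm <= params$max_pair_tm_diff
  if (!any(adm)) return(NULL)
  pen[!adm] <- Inf
  best_pen <- min(pen)
  hits <- which(pen == best_pen, arr.ind = TRUE)
  if (nrow(hits) > 1) {
    hp <- plen[hits]
    hits <- hits[hp == min(hp), , drop = FALSE]
    if (nrow(hits) > 1) {
      hf <- fwd$start[hits[, 1]]
      hits <- hits[which.min(hf), , drop = FALSE]
    }
  }
  i <- hits[1, 1]; j <- hits[1, 2]
  tibble::tibble(
    variant_id = variant$id,
    fwd_seq = fwd$sequence[i], rev_seq = rev_$sequence[j],
    fwd_tm = fwd$tm[i], rev_tm = rev_$tm[j],
    fwd_gc = fwd$gc[i], rev_gc = rev_$gc[j],
    fwd_start = fwd$start[i], rev_end = rev_$end[j],
    penalty = fwd$penalty[i] + rev_$penalty[j],
    design_product_len = plen[i, j]
  )
}

#' Batch primer design over a catalog
#'
#' Applies [design_pair_for_target()] to every variant, in catalog order
#' (deterministic). The funnel statistics record how many targets got an
#' admissible pair.
#'
#' @param genome Design [genome].
#' @param catalog Variant catalog tibble.
#' @param params A [primer_params()].
#' @return A tibble of primer pairs with attribute `stats` (a tibble
#'   `targets`, `designed`, `failed`).
#' @export
batch_design <- function(genome, catalog, params = primer_params()) {
  pairs <- purrr::map(seq_len(nrow(catalog)), function(i) {
    design_pair_for_target(genome, catalog[i, ], params)
  })
  out <- dplyr::bind_rows(pairs)
  if (nrow(out) == 0)
    out <- tibble::tibble(variant_id = character(), fwd_seq = character(),
                          rev_seq = character(), fwd_tm = numeric(),
                          rev_tm = numeric(), fwd_gc = numeric(),
                          rev_gc = numeric(), fwd_start = integer(),
                          rev_end = integer(), penalty = numeric(),
                          design_product_len = integer())
  attr(out, "stats") <- tibble::tibble(
    targets = nrow(catalog), designed = nrow(out),
    failed = nrow(catalog) - nrow(out))
  out
}
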