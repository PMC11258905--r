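# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: byte-wise loops and naive scans only.

# all primer binding sites by an exhaustive all-positions byte comparison
# (vectorised over positions, looped over primer offsets; no string search
# library involved)
bf_binding_sites <- function(seq, primer, max_mm = 0, three_prime_exact = 3) {
  n <- nchar(seq); m <- nchar(primer)
  sr <- charToRaw(seq)
  Nr <- charToRaw("N")
  hits <- list()
  npos <- n - m + 1
  if (npos < 1) {
    return(data.frame(pos = integer(), strand = character(),
                      mismatches = integer()))
  }
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else sexmarkr::revcomp(primer)
    pr <- charToRaw(pat)
    mm <- integer(npos)
    mm3 <- integer(npos)
    hasN <- logical(npos)
    ex <- if (strand == "+") (m - three_prime_exact + 1):m
          else seq_len(three_prime_exact)
    for (j in seq_len(m)) {
      seg <- sr[j:(j + npos - 1)]
      bad <- seg != pr[j]
      mm <- mm + bad
      if (three_prime_exact > 0 && j %in% ex) mm3 <- mm3 + bad
      hasN <- hasN | seg == Nr
    }
    ok <- mm <= max_mm & mm3 == 0 & !hasN
    if (any(ok))
      hits[[length(hits) + 1]] <- data.frame(
        pos = which(ok) - 1L, strand = strand,
        mismatches = mm[ok])
  }
  if (length(hits) == 0)
    return(data.frame(pos = integer(), strand = character(),
                      mismatches = integer()))
  do.call(rbind, hits)
}

# amplicons by brute force over all site pairs (both role orientations)
bf_amplicons <- function(seq, fwd, rev, max_mm = 0, three_prime_exact = 3,
                         max_product = 5000) {
  sf <- bf_binding_sites(seq, fwd, max_mm, three_prime_exact)
  sr <- bf_binding_sites(seq, rev, max_mm, three_prime_exact)
  out <- integer(0)
  combos <- list(list(sf[sf$strand == "+", ], sr[sr$strand == "-", ],
                      nchar(rev)),
                 list(sr[sr$strand == "+", ], sf[sf$strand == "-", ],
                      nchar(fwd)))
  for (cb in combos) {
    a <- cb[[1]]; b <- cb[[2]]; right_len <- cb[[3]]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      plen <- b$pos[j] + right_len - a$pos[i]
      if (plen > 0 && plen <= max_product) out <- c(out, plen)
    }
  }
  sort(out)
}

# single-linkage band clustering by naive repeated merging
bf_collapse <- function(lengths, band_min = 10, band_frac = 0.02) {
  if (length(lengths) == 0) return(numeric(0))
  x <- sort(lengths)
  groups <- as.list(x)
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)[-1]) {
      a <- groups[[i - 1]]; b <- groups[[i]]
      if (min(b) - max(a) <= max(band_min, band_frac * min(b))) {
        groups[[i - 1]] <- c(a, b); groups[[i]] <- NULL; merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  sort(vapply(groups, stats::median, numeric(1)))
}

# per-base region attribution by direct point classification
bf_deletion_bases <- function(index, chrom, start, end) {
  cls <- sexmarkr::classify_point(index, chrom, start:(end - 1))
  counts <- table(factor(cls, levels = c("five_prime_UTR",
                                         "three_prime_UTR", "CDS", "intron",
                                         "intergenic")))
  stats::setNames(as.numeric(counts), names(counts))
}

# naive shift-identity tandem scan
bf_tandem <- function(s, min_identity = 0.8, min_span = 50,
                      min_frac = 0.8) {
  n <- nchar(s)
  if (n < 20) return(FALSE)
  ch <- strsplit(s, "")[[1]]
  floor_w <- min(min_span, ceiling(min_frac * n))
  for (p in 2:(n %/% 2)) {
    w <- n - p
    if (w < floor_w) next
    if (mean(ch[1:w] == ch[(p + 1):n]) >= min_identity) return(TRUE)
  }
  FALSE
}

# primer acceptability predicate evaluated naively
bf_primer_accept <- function(s, params = sexmarkr::primer_params()) {
  n <- nchar(s)
  if (grepl("[^ACGT]", s)) return(FALSE)
  if (n < params$len_range[1] || n > params$len_range[2]) return(FALSE)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / n
  if (gc < params$gc_range[1] || gc > params$gc_range[2]) return(FALSE)
  r <- rle(strsplit(s, "")[[1]])
  if (max(r$lengths) > params$max_homopolymer) return(FALSE)
  # 3'-anchored self-complementarity run
  run <- 0
  for (L in 1:min(n, 12)) {
    suf <- substr(s, n - L + 1, n)
    if (grepl(sexmarkr::revcomp(suf), s, fixed = TRUE)) run <- L else break
  }
  if (run >= 5) return(FALSE)
  # hairpin by double loop
  for (i in 1:(n - 5)) {
    if (i + 9 > n - 5) break
    target <- sexmarkr::revcomp(substr(s, i, i + 5))
    for (j in (i + 9):(n - 5)) {
      if (substr(s, j, j + 5) == target) return(FALSE)
    }
  }
  tm <- sexmarkr::melting_temperature(s, params$salt_mM, params$conc_nM)
  tm >= params$tm_range[1] && tm <= params$tm_range[2]
}

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# a tiny deterministic two-variant genome pair used by several files
make_tiny_pair <- function(seed = 11) {
  sexmarkr::simulate_genome_pair(sexmarkr::sim_config(
    seed = seed, n_chroms = 1, chrom_len = 60000, n_ins = 2, n_del = 2,
    indel_len_range = c(101, 600), min_spacing = 3000))
}

variant_key <- function(d) {
  paste(d$type, d$ref_chrom, d$ref_start, d$ref_end, d$length, d$sequence)
}
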