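#' Synthetic study configuration
#'
#' Describes the simulated diploid-sex data regime: a female-like reference
#' genome and a male-like genome derived from it by planted large indels,
#' with long-read coverage for both sexes. Defaults give two 500-kb
#' chromosomes at GC 0.41 (typical of teleost genomes) carrying 10
#' insertions and 10 deletions of 101--2,000 bp with no repeat content, and
#' 30x long-read coverage with a 5% mismapped background -- the regime the
#' package's property tests run under.
#'
#' @param seed RNG seed; all generators are pure functions of
#'   (config, seed).
#' @param n_chroms,chrom_len Number and length of chromosomes.
#' @param gc GC fraction of the background sequence.
#' @param n_ins,n_del Planted insertion/deletion counts (genome-wide).
#' @param indel_len_range Planted indel length range, bp.
#' @param min_spacing Minimum spacing between planted events, bp.
#' @param edge_buffer Keep events this far from chromosome ends, bp.
#' @param te_fraction,tandem_fraction Fraction of planted alleles copied
#'   from a TE-like library tract / built as tandem arrays.
#' @param coverage_homogametic,coverage_heterogametic Mean long-read depth
#'   by sequenced sex.
#' @param read_len_mean Mean read length, bp (lognormal lengths, CLR-like).
#' @param read_len_sdlog Lognormal sdlog of read lengths.
#' @param background_rate Mismapped background as a fraction of coverage;
#'   this is why real hemizygous loci sit at low-but-nonzero depth.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42, n_chroms = 2, chrom_len = 500000,
                       gc = 0.41, n_ins = 10, n_del = 10,
                       indel_len_range = c(101, 2000),
                       min_spacing = 5000, edge_buffer = 3000,
                       te_fraction = 0, tandem_fraction = 0,
                       coverage_homogametic = 30,
                       coverage_heterogametic = 30,
                       read_len_mean = 8000, read_len_sdlog = 0.2,
                       background_rate = 0.05) {
  n_var <- n_ins + n_del
  if (n_var > 0 &&
      (min_spacing + mean(indel_len_range)) * ceiling(n_var / n_chroms) >
        chrom_len - 2 * edge_buffer)
    stop("planted variants do not fit: reduce counts or spacing",
         call. = FALSE)
  stopifnot(gc >= 0, gc <= 1, te_fraction >= 0, te_fraction <= 1,
            tandem_fraction >= 0, tandem_fraction <= 1,
            te_fraction + tandem_fraction <= 1)
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

# force the first/last allele bases to differ from the flanking reference
# bases so planted breakpoints are alignment-stable (exactly recoverable)
stabilise_edges <- function(allele, left_flank_base, right_next_base) {
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  if (substr(allele, 1, 1) == right_next_base)
    substr(allele, 1, 1) <- other(right_next_base)
  n <- nchar(allele)
  if (substr(allele, n, n) == left_flank_base)
    substr(allele, n, n) <- other(left_flank_base)
  allele
}

#' Generate a synthetic female/male genome pair with known truth
#'
#' The female genome is i.i.d. random sequence at the target GC; the male
#' genome is derived from it by applying the planted insertions (novel
#' sequence, TE-library copies, or tandem arrays per the configured
#' fractions) and deletions at spaced positions. Planted breakpoints are
#' alignment-stable, so an exact scan can recover them to the base. The
#' truth set records both coordinate systems; truth alleles are literal
#' substrings of the emitted sequences.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_pair`: `genome_f`, `genome_m` ([genome]s
#'   labelled `"female"`/`"male"`), `truth` (tibble like a variant catalog,
#'   plus `te`/`tandem` flags), `repeats` (planted repeat intervals with a
#'   `genome` column).
#' @export
simulate_genome_pair <- function(config = sim_config()) {
  set.seed(config$seed)
  cl <- config$chrom_len
  chroms <- paste0("chr", seq_len(config$n_chroms))
  fseq <- stats::setNames(
    vapply(chroms, function(ch) random_dna(cl, config$gc), character(1)),
    chroms)

  n_var <- config$n_ins + config$n_del
  types <- c(rep("INS", config$n_ins), rep("DEL", config$n_del))
  if (n_var > 0) types <- sample(types)
  chrom_of <- rep(chroms, length.out = n_var)
  te_lib <- random_dna(2000, config$gc)

  truth_rows <- list()
  repeat_rows <- list()
  idx_on <- stats::setNames(rep(0L, length(chroms)), chroms)

  for (ch in chroms) {
    k <- sum(chrom_of == ch)
    if (k == 0) next
    usable <- cl - 2 * config$edge_buffer
    slot <- usable / k
    pos <- sort(config$edge_buffer +
                  round((seq_len(k) - 1) * slot +
                          stats::runif(k, 0.1 * slot,
                                       0.55 * slot)))
    tt <- types[chrom_of == ch]
    for (i in seq_len(k)) {
      rng <- config$indel_len_range
      len <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
      cls <- sample(c("te", "tandem", "novel"), 1,
                    prob = c(config$te_fraction, config$tandem_fraction,
                             1 - config$te_fraction -
                               config$tandem_fraction))
      allele <- switch(cls,
        novel = random_dna(len, config$gc),
        te = {
          reps <- ceiling(len / nchar(te_lib))
          substr(paste(rep(te_lib, reps), collapse = ""), 1, len)
        },
        tandem = {
          unit <- random_dna(sample(3:12, 1), config$gc)
          reps <- ceiling(len / nchar(unit))
          substr(paste(rep(unit, reps), collapse = ""), 1, len)
        })
      p <- pos[i]
      if (tt[i] == "DEL") {
        # plant the allele INTO the female sequence, then delete it in male
        allele <- stabilise_edges(allele,
                                  substr(fseq[[ch]], p, p),
                                  substr(fseq[[ch]], p + len + 1,
                                         p + len + 1))
        substr(fseq[[ch]], p + 1, p + len) <- allele
        truth_rows[[length(truth_rows) + 1L]] <- list(
          chrom = ch, type = "DEL", ref_start = p, ref_end = p + len,
          length = len, sequence = allele, te = cls == "te",
          tandem = cls == "tandem")
        if (cls != "novel")
          repeat_rows[[length(repeat_rows) + 1L]] <- list(
            genome = "female", chrom = ch, start = p, end = p + len)
      } else {
        allele <- stabilise_edges(allele,
                                  substr(fseq[[ch]], p, p),
                                  substr(fseq[[ch]], p + 1, p + 1))
        truth_rows[[length(truth_rows) + 1L]] <- list(
          chrom = ch, type = "INS", ref_start = p, ref_end = p,
          length = len, sequence = allele, te = cls == "te",
          tandem = cls == "tandem")
      }
    }
  }

  truth <- if (length(truth_rows))
    dplyr::arrange(dplyr::bind_rows(lapply(truth_rows, tibble::as_tibble)),
                   .data$chrom, .data$ref_start)
  else tibble::tibble(chrom = character(), type = character(),
                      ref_start = integer(), ref_end = integer(),
                      length = integer(), sequence = character(),
                      te = logical(), tandem = logical())

  # derive the male genome and the query-side coordinates
  mseq <- character(0)
  truth$qry_start <- NA_integer_
  truth$qry_end <- NA_integer_
  for (ch in chroms) {
    rows <- which(truth$chrom == ch)
    pieces <- character(0)
    cursor <- 0L   # female coordinate
    offset <- 0L   # male minus female coordinate
    for (r in rows) {
      p <- truth$ref_start[r]
      pieces <- c(pieces, substr(fseq[[ch]], cursor + 1, p))
      if (truth$type[r] == "INS") {
        truth$qry_start[r] <- p + offset
        truth$qry_end[r] <- p + offset + truth$length[r]
        pieces <- c(pieces, truth$sequence[r])
        if (truth$te[r] || truth$tandem[r])
          repeat_rows[[length(repeat_rows) + 1L]] <- list(
            genome = "male", chrom = ch, start = p + offset,
            end = p + offset + truth$length[r])
        offset <- offset + truth$length[r]
        cursor <- p
      } else {
        truth$qry_start[r] <- p + offset
        truth$qry_end[r] <- p + offset
        offset <- offset - truth$length[r]
        cursor <- truth$ref_end[r]
      }
    }
    pieces <- c(pieces, substr(fseq[[ch]], cursor + 1, cl))
    mseq[[ch]] <- paste(pieces, collapse = "")
  }

  repeats <- if (length(repeat_rows))
    dplyr::bind_rows(lapply(repeat_rows, tibble::as_tibble))
  else tibble::tibble(genome = character(), chrom = character(),
                      start = integer(), end = integer())

  truth <- dplyr::mutate(
    truth,
    id = sprintf("truth_%s_%05d", .data$type, dplyr::row_number()),
    ref_label = "female", ref_chrom = .data$chrom,
    qry_chrom = .data$chrom, source = "truth", flags = "")
  truth <- truth[, c("id", "type", "ref_label", "ref_chrom", "ref_start",
                     "ref_end", "qry_chrom", "qry_start", "qry_end",
                     "length", "sequence", "source", "flags", "te",
                     "tandem")]

  structure(list(genome_f = genome(fseq, label = "female"),
                 genome_m = genome(stats::setNames(unlist(mseq), chroms),
                                   label = "male"),
                 truth = truth, repeats = repeats, config = config),
            class = "sim_pair")
}

#' @export
print.sim_pair <- function(x, ...) {
  cat("<sim_pair>", length(x$genome_f), "chromosome(s) x",
      format(x$config$chrom_len, big.mark = ","), "bp;",
      sum(x$truth$type == "INS"), "INS +", sum(x$truth$type == "DEL"),
      "DEL planted\n")
  invisible(x)
}

#' Generate a toy gene annotation with known per-class totals
#'
#' Lays `n_genes` non-overlapping genes across the genome, each with a 5'
#' UTR, three exons (CDS), two introns and a 3' UTR, jittered by the seed.
#'
#' @param g A [genome].
#' @param n_genes Number of genes (spread across chromosomes).
#' @param seed RNG seed.
#' @return A feature tibble as from [read_gff3()], with attribute
#'   `class_bp` (named per-class genome-wide bp totals).
#' @export
simulate_annotation <- function(g, n_genes = 50, seed = 1) {
  set.seed(seed)
  if (n_genes == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          kind = character(), gene_id = character())
    attr(out, "class_bp") <- stats::setNames(
      c(0, 0, 0, 0, sum(g$lengths)), region_classes)
    return(out)
  }
  gene_len <- 4000L
  chroms <- names(g$seq)
  per <- rep(chroms, length.out = n_genes)
  rows <- list()
  gi <- 0L
  for (ch in chroms) {
    k <- sum(per == ch)
    if (k == 0) next
    L <- unname(g$lengths[ch])
    if (k * (gene_len + 1000) > L)
      stop("genes don't fit on ", ch, call. = FALSE)
    slot <- L / k
    starts <- floor((seq_len(k) - 1) * slot +
                      stats::runif(k, 0, slot - gene_len - 1))
    for (s in starts) {
      gi <- gi + 1L
      id <- sprintf("gene%04d", gi)
      s <- as.integer(s)
      seg <- function(kind, a, b) list(chrom = ch, start = s + a,
                                       end = s + b, strand = "+",
                                       kind = kind, gene_id = id)
      rows <- c(rows, list(
        seg("gene", 0L, gene_len),
        seg("exon", 0L, 600L),
        seg("five_prime_UTR", 0L, 200L),
        seg("CDS", 200L, 600L),
        seg("exon", 1600L, 2400L),
        seg("CDS", 1600L, 2400L),
        seg("exon", 3400L, gene_len),
        seg("CDS", 3400L, 3800L),
        seg("three_prime_UTR", 3800L, gene_len)
      ))
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(lapply(rows, tibble::as_tibble)),
                        .data$chrom, .data$start, .data$end)
  per_gene <- c(five_prime_UTR = 200, three_prime_UTR = 200, CDS = 1600,
                intron = 2000)
  class_bp <- c(per_gene * n_genes,
                intergenic = sum(g$lengths) - gene_len * n_genes)
  attr(out, "class_bp") <- class_bp[c(region_classes)]
  out
}

# collinear segment map female <-> male from the truth set (one chrom)
segment_map <- function(truth_ch, chrom_len_f) {
  segs <- list()
  r <- 0L; q <- 0L
  add <- function(r0, r1, q0) {
    if (r1 > r0) segs[[length(segs) + 1L]] <<- c(r0 = r0, r1 = r1, q0 = q0)
  }
  if (nrow(truth_ch) > 0) {
    for (i in seq_len(nrow(truth_ch))) {
      v <- truth_ch[i, ]
      add(r, v$ref_start, q)
      q <- q + (v$ref_start - r)
      r <- v$ref_start
      if (v$type == "INS") q <- q + v$length
      else r <- r + v$length
    }
  }
  add(r, chrom_len_f, q)
  do.call(rbind, segs)
}

#' Simulate a long-read depth track
#'
#' Read start positions follow a Poisson process along the source genome
#' with lognormal CLR-like lengths; each read is projected onto the
#' reference through the truth coordinate map, so reference bases absent
#' from the source sex (hemizygous deletions when male reads are mapped to
#' the female assembly) receive only a uniform mismapped background at
#' `background_rate` of the coverage.
#'
#' @param pair A `sim_pair` from [simulate_genome_pair()].
#' @param source `"male"` or `"female"`: which sex the reads come from.
#' @param reference `"female"` or `"male"`: the mapping target. Only the
#'   female reference is supported for projected reads (the truth set is
#'   female-referenced); female-sourced reads on the female reference use
#'   the identity map.
#' @param coverage Mean depth; defaults to the config value for the source
#'   sex (male = heterogametic).
#' @return A depth-track tibble (`chrom`, `pos` 0-based, `depth`) covering
#'   every reference base.
#' @export
simulate_depth <- function(pair, source = c("male", "female"),
                           reference = "female", coverage = NULL) {
  source <- match.arg(source)
  if (reference != "female")
    stop("only the female reference is supported", call. = FALSE)
  cfg <- pair$config
  coverage <- coverage %||% if (source == "male")
    cfg$coverage_heterogametic else cfg$coverage_homogametic
  src_g <- if (source == "male") pair$genome_m else pair$genome_f
  ref_g <- pair$genome_f
  meanlog <- log(cfg$read_len_mean) - cfg$read_len_sdlog^2 / 2

  tracks <- lapply(names(ref_g$seq), function(ch) {
    Lr <- unname(ref_g$lengths[ch])
    Ls <- unname(src_g$lengths[ch])
    diffarr <- numeric(Lr + 1)
    add_iv <- function(s, e) {
      s <- max(0L, s); e <- min(Lr, e)
      if (e > s) {
        diffarr[s + 1] <<- diffarr[s + 1] + 1
        diffarr[e + 1] <<- diffarr[e + 1] - 1
      }
    }
    if (coverage > 0) {
      n_reads <- stats::rpois(1, Ls * coverage / cfg$read_len_mean)
      if (n_reads > 0) {
        starts <- sample.int(Ls, n_reads, replace = TRUE) - 1L
        lens <- pmax(200, round(stats::rlnorm(n_reads, meanlog,
                                              cfg$read_len_sdlog)))
        ends <- pmin(starts + lens, Ls)
        if (source == "female") {
          for (i in seq_len(n_reads)) add_iv(starts[i], ends[i])
        } else {
          tch <- pair$truth[pair$truth$ref_chrom == ch, , drop = FALSE]
          sm <- segment_map(tch, Lr)
          # segments as source intervals: [q0, q0 + (r1 - r0)) -> r0
          for (k in seq_len(nrow(sm))) {
            q0 <- sm[k, "q0"]; r0 <- sm[k, "r0"]
            q1 <- q0 + (sm[k, "r1"] - r0)
            s <- pmax(starts, q0); e <- pmin(ends, q1)
            ok <- e > s
            if (any(ok))
              for (i in which(ok)) add_iv(r0 + (s[i] - q0),
                                          r0 + (e[i] - q0))
          }
        }
        # mismapped background, uniform over the reference
        n_bg <- stats::rpois(1, cfg$background_rate * coverage * Lr /
                               cfg$read_len_mean)
        if (n_bg > 0) {
          bs <- sample.int(Lr, n_bg, replace = TRUE) - 1L
          bl <- pmax(200, round(stats::rlnorm(n_bg, meanlog,
                                              cfg$read_len_sdlog)))
          for (i in seq_len(n_bg)) add_iv(bs[i], pmin(bs[i] + bl[i], Lr))
        }
      }
    }
    tibble::tibble(chrom = ch, pos = 0:(Lr - 1),
                   depth = cumsum(diffarr)[seq_len(Lr)])
  })
  dplyr::bind_rows(tracks)
}
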