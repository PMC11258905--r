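#' Whole-genome scan configuration
#'
#' Bundles the thresholds of the variant-scanning stage. The published
#' parameter set this mirrors is: per-kb divergence guard ("diff: one in a
#' thousand"), variant range 0--1,000,000 bp, batch size 500 bp, minimum
#' alignment length 10,000 bp for coverage calculation and 50,000 bp for
#' variant calling. The `desk` profile lowers the two alignment-length floors
#' to 1,000 bp so that sub-megabase synthetic genomes have callable chains;
#' the `paper` profile keeps the production values.
#'
#' @param min_indel_bp Large-indel size cut; kept variants are strictly
#'   longer than this unless `inclusive = TRUE`.
#' @param inclusive Treat the size cut as `>=` instead of `>`.
#' @param var_range_bp Maximum event length considered by the caller.
#' @param batch_size_bp Maximum size of the minor gap for an inter-anchor
#'   event to be typed as a clean insertion or deletion.
#' @param min_align_len_cov_bp Minimum chain span for coverage accounting.
#' @param min_align_len_var_bp Minimum chain span for variant calling;
#'   shorter chains are kept but flagged not callable.
#' @param anchor_k Anchor k-mer size (odd, 11--31).
#' @param max_anchor_gap_bp Maximum gap on either axis between consecutive
#'   anchors of one chain.
#' @param diff_per_kb Divergence guard, tolerated mismatch rate per kb when
#'   interpreting anchor gaps (interpretation of the published "one in a
#'   thousand" setting; exposed for transparency, not used by the exact
#'   anchor matcher).
#' @param max_kmers Memory budget for the k-mer tables.
#' @param profile `"paper"` or `"desk"`; presets applied before explicit
#'   arguments.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(min_indel_bp = 100,
                        inclusive = FALSE,
                        var_range_bp = 1000000,
                        batch_size_bp = 500,
                        min_align_len_cov_bp = NULL,
                        min_align_len_var_bp = NULL,
                        anchor_k = 21,
                        max_anchor_gap_bp = 1000000,
                        diff_per_kb = 1,
                        max_kmers = 5e7,
                        profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") c(cov = 10000, var = 50000)
              else c(cov = 1000, var = 1000)
  min_align_len_cov_bp <- min_align_len_cov_bp %||% defaults[["cov"]]
  min_align_len_var_bp <- min_align_len_var_bp %||% defaults[["var"]]
  vals <- c(min_indel_bp, var_range_bp, batch_size_bp, min_align_len_cov_bp,
            min_align_len_var_bp, anchor_k, max_anchor_gap_bp)
  if (any(vals <= 0)) stop("scan_config values must be positive", call. = FALSE)
  if (anchor_k %% 2 == 0 || anchor_k < 11 || anchor_k > 31)
    stop("anchor_k must be odd and in [11, 31]", call. = FALSE)
  if (min_align_len_var_bp < min_align_len_cov_bp)
    warning("min_align_len_var_bp < min_align_len_cov_bp; ",
            "calling threshold is below the coverage threshold")
  structure(list(
    min_indel_bp = min_indel_bp, inclusive = inclusive,
    var_range_bp = var_range_bp, batch_size_bp = batch_size_bp,
    min_align_len_cov_bp = min_align_len_cov_bp,
    min_align_len_var_bp = min_align_len_var_bp,
    anchor_k = anchor_k, max_anchor_gap_bp = max_anchor_gap_bp,
    diff_per_kb = diff_per_kb, max_kmers = max_kmers, profile = profile
  ), class = "scan_config")
}

# enumerate all k-mers of one sequence; returns positions of kmers with no N
kmer_positions <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(list(kmer = character(), pos = integer()))
  n <- L - k + 1L
  km <- substring(seq, 1:n, k:L)
  ok <- !grepl("N", km, fixed = TRUE)
  list(kmer = km[ok], pos = (0:(n - 1L))[ok])
}

genome_kmer_table <- function(g, k, both_strands = FALSE) {
  out <- list()
  for (ch in names(g$seq)) {
    kp <- kmer_positions(g$seq[[ch]], k)
    out[[length(out) + 1L]] <- list(kmer = kp$kmer, chrom = ch,
                                    pos = kp$pos, strand = "+")
    if (both_strands) {
      rc <- revcomp(g$seq[[ch]])
      km <- kmer_positions(rc, k)
      out[[length(out) + 1L]] <- list(kmer = km$kmer, chrom = ch,
                                      pos = km$pos, strand = "-")
    }
  }
  list(kmer = unlist(lapply(out, `[[`, "kmer"), use.names = FALSE),
       chrom = rep(vapply(out, `[[`, "", "chrom"),
                   vapply(out, function(x) length(x$kmer), 0L)),
       pos = unlist(lapply(out, `[[`, "pos"), use.names = FALSE),
       strand = rep(vapply(out, `[[`, "", "strand"),
                    vapply(out, function(x) length(x$kmer), 0L)))
}

#' Build exact-match anchors between two genomes
#'
#' Seeds anchors from k-mers that occur exactly once in the reference and
#' exactly once in the query (both query strands considered), then merges
#' runs of diagonal-consecutive seed matches into maximal exact anchors. This
#' is a transparent MUM-style internal aligner so that the scan needs no
#' external tool; PAF alignments from an external aligner may substitute for
#' its output in [chain_anchors()].
#'
#' @param ref,qry [genome] objects (reference/target and query).
#' @param k Anchor k-mer size.
#' @param max_kmers Error if the combined k-mer tables would exceed this.
#' @return A tibble of alignment blocks: `qname`, `qstart`, `qend` (query
#'   forward strand, 0-based half-open), `strand`, `tname`, `tstart`,
#'   `tend`, `matches`, `block_len`, plus `qstart_rc`/`qend_rc` giving minus-
#'   strand anchors in query reverse-complement coordinates.
#' @export
build_anchors <- function(ref, qry, k = 21, max_kmers = 5e7) {
  if (k %% 2 == 0 || k < 11 || k > 31)
    stop("k must be odd and in [11, 31]", call. = FALSE)
  n_est <- sum(pmax(ref$lengths - k + 1, 0)) +
    2 * sum(pmax(qry$lengths - k + 1, 0))
  if (n_est > max_kmers)
    stop("k-mer table would hold ", n_est, " entries (> budget ", max_kmers,
         "); use a larger k or raise max_kmers", call. = FALSE)

  tr <- genome_kmer_table(ref, k, both_strands = FALSE)
  tq <- genome_kmer_table(qry, k, both_strands = TRUE)

  uniq <- function(x) !(duplicated(x) | duplicated(x, fromLast = TRUE))
  ur <- uniq(tr$kmer)
  uq <- uniq(tq$kmer)

  rk <- tr$kmer[ur]
  hit <- match(rk, tq$kmer[uq])
  keep <- !is.na(hit)
  if (!any(keep)) return(empty_anchors())

  qi <- which(uq)[hit[keep]]
  ri <- which(ur)[keep]

  t_chrom <- tr$chrom[ri]; t_pos <- tr$pos[ri]
  q_chrom <- tq$chrom[qi]; q_pos <- tq$pos[qi]; q_strand <- tq$strand[qi]

  # merge diagonal-consecutive seeds into maximal runs
  diag <- t_pos - q_pos
  key <- paste(t_chrom, q_chrom, q_strand, diag, sep = "\r")
  o <- order(key, t_pos)
  key <- key[o]; t_pos <- t_pos[o]; q_pos <- q_pos[o]
  t_chrom <- t_chrom[o]; q_chrom <- q_chrom[o]; q_strand <- q_strand[o]
  n <- length(t_pos)
  new_run <- c(TRUE, key[-1] != key[-n] | diff(t_pos) != 1L)
  run <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, n)

  tstart <- t_pos[starts]
  tend <- t_pos[ends] + k
  q0 <- q_pos[starts]
  q1 <- q_pos[ends] + k
  strand <- q_strand[starts]
  run_key <- key[starts]

  # seed uniqueness can drop out mid-match (a k-mer duplicated by chance
  # elsewhere breaks the diagonal run even though the region still matches
  # exactly); rejoin same-diagonal runs whose intervening sequence verifies
  # as an exact match, so anchors are truly maximal
  rc_cache <- new.env(parent = emptyenv())
  q_frame_seq <- function(ch, strand) {
    if (strand == "+") return(qry$seq[[ch]])
    if (is.null(rc_cache[[ch]])) rc_cache[[ch]] <- revcomp(qry$seq[[ch]])
    rc_cache[[ch]]
  }
  keep <- rep(TRUE, length(starts))
  i <- 1L
  for (j in seq_along(starts)[-1]) {
    mergeable <- FALSE
    if (run_key[j] == run_key[i]) {
      if (tstart[j] <= tend[i]) {
        mergeable <- TRUE  # overlapping exact matches on one diagonal
      } else {
        ch_t <- t_chrom[starts[i]]; ch_q <- q_chrom[starts[i]]
        d <- tstart[i] - q0[i]
        mid_t <- substr(ref$seq[[ch_t]], tend[i] + 1, tstart[j])
        qs_ <- q_frame_seq(ch_q, strand[i])
        mid_q <- substr(qs_, tend[i] - d + 1, tstart[j] - d)
        mergeable <- identical(mid_t, mid_q)
      }
    }
    if (mergeable) {
      tend[i] <- max(tend[i], tend[j])
      q1[i] <- max(q1[i], q1[j])
      keep[j] <- FALSE
    } else {
      i <- j
    }
  }
  starts <- starts[keep]
  tstart <- tstart[keep]; tend <- tend[keep]
  q0 <- q0[keep]; q1 <- q1[keep]
  strand <- strand[keep]
  qlen <- unname(qry$lengths[q_chrom[starts]])

  minus <- strand == "-"
  anchors <- tibble::tibble(
    qname = q_chrom[starts],
    qstart = ifelse(minus, qlen - q1, q0),
    qend = ifelse(minus, qlen - q0, q1),
    strand = strand,
    tname = t_chrom[starts],
    tstart = tstart, tend = tend,
    matches = tend - tstart,
    block_len = tend - tstart,
    qstart_rc = ifelse(minus, q0, NA_integer_),
    qend_rc = ifelse(minus, q1, NA_integer_)
  )
  dplyr::arrange(anchors, .data$tname, .data$tstart, .data$qname,
                 .data$qstart)
}

empty_anchors <- function() {
  tibble::tibble(qname = character(), qstart = integer(), qend = integer(),
                 strand = character(), tname = character(),
                 tstart = integer(), tend = integer(), matches = integer(),
                 block_len = integer(), qstart_rc = integer(),
                 qend_rc = integer())
}

# query coordinate on the chaining axis: forward coords on '+', reverse-
# complement frame coords on '-' (so both axes increase along the chain)
chain_axis_q <- function(anchors) {
  minus <- anchors$strand == "-"
  list(start = ifelse(minus, anchors$qstart_rc, anchors$qstart),
       end = ifelse(minus, anchors$qend_rc, anchors$qend))
}

#' Chain anchors into collinear runs
#'
#' Partitions anchors from one genome pair into maximal-score collinear
#' chains (weighted longest increasing subsequence on reference order with
#' query monotonicity; anchor length is the weight). Gaps larger than
#' `max_anchor_gap_bp` on either axis break a chain. Chains spanning less
#' than `min_align_len_var_bp` on the reference are kept but flagged not
#' callable. Ties between equal-score chains resolve to the leftmost
#' reference start, then leftmost query start.
#'
#' @param anchors Anchor tibble from [build_anchors()] (or PAF blocks from
#'   [read_paf()] with an added `qstart_rc`/`qend_rc` of `NA`).
#' @param config A [scan_config()].
#' @return A list of class `anchor_chains`: `anchors` (input plus
#'   `chain_id`) and `chains` (per-chain summary with `callable` flag).
#' @export
chain_anchors <- function(anchors, config = scan_config()) {
  if (nrow(anchors) == 0) {
    return(structure(list(
      anchors = dplyr::mutate(anchors, chain_id = integer()),
      chains = tibble::tibble(chain_id = integer(), qname = character(),
                              tname = character(), strand = character(),
                              n_blocks = integer(), chain_len = integer(),
                              ref_span = integer(), callable = logical())
    ), class = "anchor_chains"))
  }
  if (is.null(anchors$qstart_rc)) anchors$qstart_rc <- NA_integer_
  if (is.null(anchors$qend_rc)) anchors$qend_rc <- NA_integer_

  qa <- chain_axis_q(anchors)
  anchors$.qs <- qa$start
  anchors$.qe <- qa$end
  grp <- paste(anchors$qname, anchors$tname, anchors$strand, sep = "\r")
  anchors$chain_id <- NA_integer_
  next_id <- 1L
  max_gap <- config$max_anchor_gap_bp

  for (g in unique(grp)) {
    idx <- which(grp == g)
    a <- anchors[idx, ]
    o <- order(a$tstart, a$.qs)
    a <- a[o, ]; idx <- idx[o]
    remaining <- rep(TRUE, nrow(a))
    while (any(remaining)) {
      ii <- which(remaining)
      ts <- a$tstart[ii]; te <- a$tend[ii]
      qs <- a$.qs[ii]; qe <- a$.qe[ii]
      w <- a$block_len[ii]
      m <- length(ii)
      score <- w
      prev <- rep(0L, m)
      for (j in seq_len(m)) {
        if (j > 1) for (i in 1:(j - 1)) {
          if (te[i] <= ts[j] && qe[i] <= qs[j] &&
              ts[j] - te[i] <= max_gap && qs[j] - qe[i] <= max_gap) {
            cand <- score[i] + w[j]
            if (cand > score[j]) { score[j] <- cand; prev[j] <- i }
          }
        }
      }
      best <- which.max(score)  # ties -> leftmost (which.max picks first)
      path <- integer(0)
      at <- best
      while (at != 0L) { path <- c(at, path); at <- prev[at] }
      anchors$chain_id[idx[ii[path]]] <- next_id
      next_id <- next_id + 1L
      remaining[ii[path]] <- FALSE
    }
  }

  chains <- anchors |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(
      qname = .data$qname[1], tname = .data$tname[1],
      strand = .data$strand[1], n_blocks = dplyr::n(),
      chain_len = sum(.data$block_len),
      ref_span = max(.data$tend) - min(.data$tstart),
      .groups = "drop"
    ) |>
    dplyr::mutate(callable = .data$ref_span >= config$min_align_len_var_bp) |>
    dplyr::arrange(.data$tname, .data$chain_id)
  anchors$.qs <- NULL; anchors$.qe <- NULL
  structure(list(anchors = anchors, chains = chains),
            class = "anchor_chains")
}

#' @export
print.anchor_chains <- function(x, ...) {
  cat("<anchor_chains>", nrow(x$anchors), "anchors in", nrow(x$chains),
      "chains (", sum(x$chains$callable), "callable )\n")
  invisible(x)
}

#' Call variants from inter-anchor gaps
#'
#' For each adjacent anchor pair in a callable chain with reference gap
#' `g_r` and query gap `g_q`: an insertion of length `g_q - g_r` is called
#' when `g_q - g_r >= 1` and `g_r <= batch_size_bp`; a deletion of length
#' `g_r - g_q` when `g_r - g_q >= 1` and `g_q <= batch_size_bp`; a
#' substitution of span `g_r` when the gaps are equal and positive. Events
#' whose two gaps both exceed `batch_size_bp` are emitted as substitutions
#' flagged `complex`. Variants overlapping an N run are flagged `n_run`;
#' events longer than `var_range_bp` are dropped with a warning.
#'
#' @param chains An `anchor_chains` object.
#' @param ref,qry The [genome]s the chains were built on.
#' @param config A [scan_config()].
#' @return A variant catalog tibble with 0-based half-open coordinates
#'   (`ref_start == ref_end` marks an insertion breakpoint), allele
#'   `sequence`, and `source = "internal_scan"`.
#' @export
call_variants <- function(chains, ref, qry, config = scan_config()) {
  an <- chains$anchors
  callable <- chains$chains$chain_id[chains$chains$callable]
  out <- list()
  rc_cache <- new.env(parent = emptyenv())
  qry_rc <- function(ch) {
    if (is.null(rc_cache[[ch]])) rc_cache[[ch]] <- revcomp(qry$seq[[ch]])
    rc_cache[[ch]]
  }
  for (cid in callable) {
    a <- an[!is.na(an$chain_id) & an$chain_id == cid, ]
    if (nrow(a) < 2) next
    if (!all(a$tname %in% names(ref$seq)))
      stop("chain references unknown reference chromosome", call. = FALSE)
    if (!all(a$qname %in% names(qry$seq)))
      stop("chain references unknown query chromosome", call. = FALSE)
    qa <- chain_axis_q(a)
    o <- order(a$tstart)
    a <- a[o, ]; qs <- qa$start[o]; qe <- qa$end[o]
    minus <- a$strand[1] == "-"
    qname <- a$qname[1]; tname <- a$tname[1]
    qlen <- unname(qry$lengths[qname])
    q_gap_seq <- function(g0, g1) {
      # gap on the chain axis; for '-' chains this is the rc frame
      if (minus) substr(qry_rc(qname), g0 + 1, g1)
      else substr(qry$seq[[qname]], g0 + 1, g1)
    }
    q_fwd <- function(p) if (minus) qlen - p else p

    for (i in seq_len(nrow(a) - 1)) {
      g_r <- a$tstart[i + 1] - a$tend[i]
      g_q <- qs[i + 1] - qe[i]
      if (g_r == 0 && g_q == 0) next
      rs <- a$tend[i]; re <- a$tstart[i + 1]
      q0 <- qe[i]; q1 <- qs[i + 1]
      flags <- character(0)
      if (g_q - g_r >= 1 && g_r <= config$batch_size_bp) {
        type <- "INS"; len <- g_q - g_r
        seq_ <- substr(q_gap_seq(q0, q1), 1, len)
        if (g_r > 0) flags <- c(flags, "mixed")
        rec <- list(type = type, ref_start = rs, ref_end = rs,
                    qry_start = min(q_fwd(q0), q_fwd(q0 + len)),
                    qry_end = max(q_fwd(q0), q_fwd(q0 + len)),
                    length = len, sequence = seq_)
      } else if (g_r - g_q >= 1 && g_q <= config$batch_size_bp) {
        type <- "DEL"; len <- g_r - g_q
        seq_ <- substr(ref$seq[[tname]], rs + 1, rs + len)
        if (g_q > 0) flags <- c(flags, "mixed")
        rec <- list(type = type, ref_start = rs, ref_end = rs + len,
                    qry_start = q_fwd(q0), qry_end = q_fwd(q0),
                    length = len, sequence = seq_)
      } else {
        type <- "SUB"; len <- g_r
        seq_ <- substr(ref$seq[[tname]], rs + 1, re)
        if (g_r > config$batch_size_bp && g_q > config$batch_size_bp)
          flags <- c(flags, "complex")
        rec <- list(type = type, ref_start = rs, ref_end = re,
                    qry_start = min(q_fwd(q0), q_fwd(q1)),
                    qry_end = max(q_fwd(q0), q_fwd(q1)),
                    length = max(len, 1L), sequence = seq_)
      }
      if (rec$length > config$var_range_bp) {
        warning("dropping ", type, " of length ", rec$length,
                " (> var_range_bp)")
        next
      }
      if (grepl("N", rec$sequence, fixed = TRUE))
        flags <- c(flags, "n_run")
      rec$ref_chrom <- tname; rec$qry_chrom <- qname
      rec$flags <- paste(flags, collapse = ",")
      out[[length(out) + 1L]] <- rec
    }
  }
  if (length(out) == 0) return(empty_catalog())
  v <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  v <- dplyr::arrange(v, .data$ref_chrom, .data$ref_start, .data$ref_end)
  tibble::tibble(
    id = sprintf("%s_%s_%05d", ref$label, v$type, seq_len(nrow(v))),
    type = v$type, ref_label = ref$label,
    ref_chrom = v$ref_chrom,
    ref_start = as.integer(v$ref_start), ref_end = as.integer(v$ref_end),
    qry_chrom = v$qry_chrom,
    qry_start = as.integer(v$qry_start), qry_end = as.integer(v$qry_end),
    length = as.integer(v$length), sequence = v$sequence,
    source = "internal_scan", flags = v$flags
  )
}

#' Keep only large insertions and deletions
#'
#' Retains INS/DEL calls strictly longer than `min_indel_bp` (or `>=` when
#' the config sets `inclusive = TRUE`); substitutions are discarded. Input
#' order is preserved.
#'
#' @param variants Variant catalog tibble.
#' @param config A [scan_config()].
#' @return The filtered catalog.
#' @export
screen_large_indels <- function(variants, config = scan_config()) {
  keep <- variants$type %in% c("INS", "DEL") &
    (if (isTRUE(config$inclusive)) variants$length >= config$min_indel_bp
     else variants$length > config$min_indel_bp)
  variants[keep, , drop = FALSE]
}

scan_direction <- function(ref, qry, config) {
  anchors <- build_anchors(ref, qry, k = config$anchor_k,
                           max_kmers = config$max_kmers)
  chains <- chain_anchors(anchors, config)
  calls <- call_variants(chains, ref, qry, config)
  list(anchors = anchors, chains = chains, calls = calls,
       catalog = screen_large_indels(calls, config))
}

#' Bidirectional whole-genome variant scan
#'
#' Runs the anchor, chain, call, and large-indel screen path twice -- once
#' with each assembly as the reference -- and reconciles the two catalogs:
#' an insertion called against one reference should reappear as a deletion
#' with the identical allele against the other.
#'
#' @param genome_f,genome_m The two [genome] assemblies (conventionally the
#'   female and male).
#' @param config A [scan_config()].
#' @param reconcile_tol_bp Coordinate slack when pairing mirrored calls.
#' @return An object of class `sexscan` with elements `catalog_f`,
#'   `catalog_m` (large-indel catalogs with reference `genome_f` and
#'   `genome_m` respectively), `calls_f`, `calls_m` (unfiltered calls),
#'   `reconciliation` (pairing table) and `config`.
#' @export
bidirectional_scan <- function(genome_f, genome_m, config = scan_config(),
                               reconcile_tol_bp = 10) {
  if (length(genome_f) == 0 || length(genome_m) == 0)
    stop("both genomes must be non-empty", call. = FALSE)
  fwd <- scan_direction(genome_f, genome_m, config)
  rev <- scan_direction(genome_m, genome_f, config)
  rec <- reconcile_catalogs(fwd$catalog, rev$catalog, tol = reconcile_tol_bp)
  structure(list(catalog_f = fwd$catalog, catalog_m = rev$catalog,
                 calls_f = fwd$calls, calls_m = rev$calls,
                 reconciliation = rec, config = config),
            class = "sexscan")
}

# pair A-ref events with their mirrored B-ref counterparts
reconcile_catalogs <- function(cat_a, cat_b, tol = 10) {
  if (nrow(cat_a) == 0 || nrow(cat_b) == 0) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          type_a = character(), matched = logical()))
  }
  swap <- c(INS = "DEL", DEL = "INS")
  used <- rep(FALSE, nrow(cat_b))
  rows <- lapply(seq_len(nrow(cat_a)), function(i) {
    a <- cat_a[i, ]
    want_type <- swap[[a$type]]
    # the A-ref event's query-side location is a B-ref-side location
    pos_b <- if (a$type == "INS") a$qry_start else a$qry_start
    j <- which(!used & cat_b$type == want_type &
                 cat_b$ref_chrom == a$qry_chrom &
                 cat_b$length == a$length &
                 cat_b$sequence == a$sequence &
                 abs(cat_b$ref_start - pos_b) <= tol)
    if (length(j) > 0) {
      used[j[1]] <<- TRUE
      tibble::tibble(id_a = a$id, id_b = cat_b$id[j[1]], type_a = a$type,
                     matched = TRUE)
    } else {
      tibble::tibble(id_a = a$id, id_b = NA_character_, type_a = a$type,
                     matched = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

#' @export
print.sexscan <- function(x, ...) {
  cat("<sexscan> bidirectional whole-genome scan\n")
  cat("  ", x$catalog_f$ref_label[1] %||% "A", "as reference:",
      sum(x$catalog_f$type == "INS"), "INS /",
      sum(x$catalog_f$type == "DEL"), "DEL (>", x$config$min_indel_bp,
      "bp)\n")
  cat("  ", x$catalog_m$ref_label[1] %||% "B", "as reference:",
      sum(x$catalog_m$type == "INS"), "INS /",
      sum(x$catalog_m$type == "DEL"), "DEL\n")
  cat("   reconciled:", sum(x$reconciliation$matched), "/",
      nrow(x$reconciliation), "\n")
  invisible(x)
}

#' Intersect an internal catalog with external calls
#'
#' Two variants match when they have the same type and either a reciprocal
#' overlap of at least `min_reciprocal` of each span, or (for insertions)
#' breakpoints within `max_breakpoint_dist` bp. The reported percentage is
#' shared / external total x 100, rounded half-up to two decimals -- the
#' convention behind printed cross-validation figures such as 1,791 of
#' 2,116 shared deletion sites = 84.64%.
#'
#' @param internal,external Variant catalogs on the same reference label.
#' @param min_reciprocal Reciprocal-overlap fraction for span variants.
#' @param max_breakpoint_dist Breakpoint slack for insertions, bp.
#' @return A list of class `intersection_report`: `shared`,
#'   `internal_total`, `external_total`, `pct_of_external`, `pairs`.
#' @export
intersect_external_calls <- function(internal, external,
                                     min_reciprocal = 0.5,
                                     max_breakpoint_dist = 100) {
  la <- unique(stats::na.omit(internal$ref_label))
  lb <- unique(stats::na.omit(external$ref_label))
  if (length(la) == 1 && length(lb) == 1 && la != lb)
    stop("catalogs are on different references: ", la, " vs ", lb,
         call. = FALSE)
  if (nrow(external) == 0) stop("external catalog is empty", call. = FALSE)
  used <- rep(FALSE, nrow(internal))
  match_of <- rep(NA_character_, nrow(external))
  for (j in seq_len(nrow(external))) {
    e <- external[j, ]
    cand <- which(!used & internal$type == e$type &
                    internal$ref_chrom == e$ref_chrom)
    if (length(cand) == 0) next
    if (e$type == "INS") {
      ok <- abs(internal$ref_start[cand] - e$ref_start) <=
        max_breakpoint_dist
    } else {
      ov <- pmin(internal$ref_end[cand], e$ref_end) -
        pmax(internal$ref_start[cand], e$ref_start)
      ok <- ov >= min_reciprocal * (internal$ref_end[cand] -
                                      internal$ref_start[cand]) &
        ov >= min_reciprocal * (e$ref_end - e$ref_start)
    }
    hit <- cand[ok]
    if (length(hit) > 0) {
      used[hit[1]] <- TRUE
      match_of[j] <- internal$id[hit[1]]
    }
  }
  shared <- sum(!is.na(match_of))
  structure(list(
    shared = shared,
    internal_total = nrow(internal),
    external_total = nrow(external),
    pct_of_external = round_half_up(shared / nrow(external) * 100, 2),
    pairs = tibble::tibble(external_id = external$id,
                           internal_id = match_of)
  ), class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat("<intersection_report> shared", x$shared, "of", x$external_total,
      "external calls (", sprintf("%.2f%%", x$pct_of_external), ")\n")
  invisible(x)
}
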