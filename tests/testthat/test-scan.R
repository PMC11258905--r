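test_that("self-comparison yields one full-length anchor and no variants", {
  set.seed(5)
  g <- genome(c(chr1 = random_seq(10000)), label = "self")
  an <- build_anchors(g, g, k = 21)
  expect_gte(max(an$tend - an$tstart), 10000 - 2 * 20)
  sc <- bidirectional_scan(g, genome(g$seq, label = "self2"),
                           scan_config())
  expect_equal(nrow(sc$catalog_f), 0L)
  expect_equal(nrow(sc$catalog_m), 0L)
})

test_that("genomes sharing no k-mer give no anchors", {
  a <- genome(c(c1 = strrep("A", 500)), label = "a")
  b <- genome(c(c1 = strrep("C", 500)), label = "b")
  expect_equal(nrow(build_anchors(a, b, k = 21)), 0L)
})

test_that("a planted insertion leaves flanking anchors with the right gaps", {
  pair <- sexmarkr::simulate_genome_pair(sexmarkr::sim_config(
    seed = 31, n_chroms = 1, chrom_len = 50000, n_ins = 1, n_del = 0,
    indel_len_range = c(599, 599), min_spacing = 3000))
  tr <- pair$truth
  an <- build_anchors(pair$genome_f, pair$genome_m, 21)
  an <- an[an$strand == "+", ]
  an <- dplyr::arrange(an, tstart)
  expect_equal(nrow(an), 2L)
  expect_equal(an$tend[1], tr$ref_start[1])      # reference gap 0
  expect_equal(an$tstart[2], tr$ref_start[1])
  expect_equal(an$qstart[2] - an$qend[1], 599L)  # query gap = insert length
  # every anchor is an exact match between the two sequences
  for (i in seq_len(nrow(an))) {
    expect_identical(
      substr(pair$genome_f$seq[[1]], an$tstart[i] + 1, an$tend[i]),
      substr(pair$genome_m$seq[[1]], an$qstart[i] + 1, an$qend[i]))
  }
})

test_that("chaining keeps collinear anchors together, splits crossings", {
  cfg <- scan_config()
  two <- tibble::tibble(
    qname = "q", qstart = c(0L, 150L), qend = c(100L, 250L),
    strand = "+", tname = "t", tstart = c(0L, 150L),
    tend = c(100L, 250L), matches = 100L, block_len = 100L,
    qstart_rc = NA_integer_, qend_rc = NA_integer_)
  ch <- chain_anchors(two, cfg)
  expect_equal(nrow(ch$chains), 1L)
  expect_equal(ch$chains$n_blocks, 2L)

  crossing <- two
  crossing$qstart <- c(150L, 0L); crossing$qend <- c(250L, 100L)
  ch2 <- chain_anchors(crossing, cfg)
  expect_equal(nrow(ch2$chains), 2L)
  expect_true(all(ch2$chains$n_blocks == 1L))

  far <- two
  far$tstart[2] <- far$tstart[2] + 2000000L
  far$tend[2] <- far$tend[2] + 2000000L
  ch3 <- chain_anchors(far, cfg)
  expect_equal(nrow(ch3$chains), 2L)
})

test_that("maximal-score chaining matches exhaustive enumeration", {
  # enumerate all increasing subsets of <= 5 anchors and compare the best
  # chain's score with the DP result
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    t0 <- sort(sample(0:5000, k)) * 10L
    q0 <- sample(0:50000, k)
    an <- tibble::tibble(
      qname = "q", qstart = as.integer(q0),
      qend = as.integer(q0 + sample(50:400, k, TRUE)), strand = "+",
      tname = "t", tstart = as.integer(t0),
      tend = as.integer(t0 + sample(50:400, k, TRUE)),
      qstart_rc = NA_integer_, qend_rc = NA_integer_)
    an$block_len <- an$tend - an$tstart
    an$matches <- an$block_len
    cfg <- scan_config(max_anchor_gap_bp = 100000)
    ch <- chain_anchors(an, cfg)
    best_dp <- max(vapply(split(ch$anchors, ch$anchors$chain_id),
                          function(a) sum(a$block_len), numeric(1)))
    # brute force over all subsets
    best_bf <- 0
    for (mask in 1:(2^k - 1)) {
      sel <- which(bitwAnd(mask, 2^(0:(k - 1))) > 0)
      a <- an[sel, ][order(an$tstart[sel]), ]
      ok <- TRUE
      if (nrow(a) > 1) for (i in 2:nrow(a)) {
        if (!(a$tstart[i] >= a$tend[i - 1] && a$qstart[i] >= a$qend[i - 1] &&
              a$tstart[i] - a$tend[i - 1] <= cfg$max_anchor_gap_bp &&
              a$qstart[i] - a$qend[i - 1] <= cfg$max_anchor_gap_bp))
          ok <- FALSE
      }
      if (ok) best_bf <- max(best_bf, sum(a$block_len))
    }
    expect_equal(best_dp, best_bf)
  }
})

test_that("planted indels are called with exact breakpoints and alleles", {
  pair <- make_tiny_pair(seed = 11)
  sc <- bidirectional_scan(pair$genome_f, pair$genome_m, scan_config())
  cols <- c("type", "ref_chrom", "ref_start", "ref_end", "qry_start",
            "qry_end", "length", "sequence")
  got <- dplyr::arrange(sc$catalog_f[cols], ref_chrom, ref_start)
  want <- dplyr::arrange(pair$truth[cols], ref_chrom, ref_start)
  want$ref_start <- as.integer(want$ref_start)
  want$ref_end <- as.integer(want$ref_end)
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("the 343-bp deletion convention matches flank arithmetic", {
  # flanks ending at 1-based x and starting at y delete [x+1, y-1],
  # length y - x - 1
  x <- 1161186L; y <- 1161530L
  len <- y - x - 1L
  expect_equal(len, 343L)
  set.seed(88)
  left <- random_seq(3000); mid <- random_seq(len); right <- random_seq(3000)
  f <- genome(c(chr8 = paste0(left, mid, right)), label = "female")
  m <- genome(c(chr8 = paste0(left, right)), label = "male")
  sc <- bidirectional_scan(f, m, scan_config())
  d <- sc$catalog_f[sc$catalog_f$type == "DEL", ]
  expect_equal(nrow(d), 1L)
  expect_equal(d$length, 343L)
  r1 <- sexmarkr:::variant_to_1based("DEL", d$ref_start, d$ref_end)
  expect_equal(r1$start1, 3000 + 1)        # first deleted base, 1-based
  expect_equal(r1$end1 - r1$start1 + 1L, 343L)
})

test_that("the large-indel screen is a strict > filter and a subset", {
  cfg <- scan_config()
  v <- tibble::tibble(
    id = sprintf("v%d", 1:4), type = "INS", ref_label = "f",
    ref_chrom = "c", ref_start = 1:4 * 1000L, ref_end = 1:4 * 1000L,
    qry_chrom = "c", qry_start = 0L, qry_end = 0L,
    length = c(99L, 100L, 101L, 599L), sequence = "A",
    source = "internal_scan", flags = "")
  kept <- screen_large_indels(v, cfg)
  expect_equal(kept$length, c(101L, 599L))
  expect_equal(screen_large_indels(v, scan_config(inclusive = TRUE))$length,
               c(100L, 101L, 599L))

  subs <- dplyr::mutate(v, type = "SUB")
  expect_equal(nrow(screen_large_indels(subs, cfg)), 0L)

  set.seed(10)
  big <- dplyr::bind_rows(lapply(1:1000, function(i) dplyr::mutate(
    v[1, ], id = paste0("r", i),
    type = sample(c("INS", "DEL", "SUB"), 1),
    length = sample(50:200, 1))))
  kept <- screen_large_indels(big, cfg)
  want <- big[big$type %in% c("INS", "DEL") & big$length > 100, ]
  expect_equal(kept, want)
  expect_true(all(kept$id %in% big$id))
  expect_equal(nrow(kept) + sum(!big$id %in% kept$id), nrow(big))
})

test_that("bidirectional duality holds on a repeat-free pair", {
  pair <- make_tiny_pair(seed = 19)
  sc <- bidirectional_scan(pair$genome_f, pair$genome_m, scan_config())
  expect_equal(nrow(sc$reconciliation), nrow(sc$catalog_f))
  expect_true(all(sc$reconciliation$matched))
  # types swap per event and alleles are identical
  for (i in seq_len(nrow(sc$catalog_f))) {
    a <- sc$catalog_f[i, ]
    j <- match(sc$reconciliation$id_b[i], sc$catalog_m$id)
    b <- sc$catalog_m[j, ]
    expect_equal(b$type, c(INS = "DEL", DEL = "INS")[[a$type]])
    expect_equal(b$sequence, a$sequence)
  }
})

test_that("external-call intersection matches brute-force pairing", {
  mk <- function(n, start, label = "female", type = "DEL", len = 200L) {
    tibble::tibble(
      id = sprintf("%s%04d", type, seq_len(n)), type = type,
      ref_label = label, ref_chrom = "chr1",
      ref_start = as.integer(start),
      ref_end = as.integer(start + ifelse(type == "INS", 0L, len)),
      qry_chrom = "chr1", qry_start = 0L, qry_end = 0L,
      length = len, sequence = "A", source = "external_caller", flags = "")
  }
  # planted overlap 37 of 50: first 37 shifted by <50% of span
  ext <- mk(50, seq(1000, by = 5000, length.out = 50))
  int <- mk(37, seq(1000, by = 5000, length.out = 37) + 40)
  rep <- intersect_external_calls(int, ext)
  expect_equal(rep$shared, 37L)
  expect_equal(rep$pct_of_external, 74.00)

  # identical catalogs -> 100.00
  rep2 <- intersect_external_calls(ext, ext)
  expect_equal(rep2$pct_of_external, 100.00)

  # the printed arithmetic: 1,791 shared of 2,116 external = 84.64%
  expect_equal(overlap_percentage(1791, 2116), 84.64)

  # INS use breakpoint distance, not overlap
  ei <- mk(5, c(1000, 3000, 5000, 7000, 9000), type = "INS")
  ii <- mk(5, c(1080, 3101, 5020, 7500, 9000) + 0L, type = "INS")
  rep3 <- intersect_external_calls(ii, ei)
  expect_equal(rep3$shared, 3L)  # 80, 20, 0 within 100 bp; 101, 500 not

  expect_error(intersect_external_calls(mk(2, c(1, 2), label = "male"),
                                        ext), "different reference")
})
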