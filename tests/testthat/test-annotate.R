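make_features <- function() {
  # one gene on chr1: [1000, 5000); exon1 [1000,1600) = UTR5 [1000,1200) +
  # CDS [1200,1600); intron [1600,2600); exon2 [2600,3400) CDS;
  # intron [3400,4400); exon3 [4400,5000) = CDS [4400,4800) + UTR3
  tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 1000L, 1000L, 1200L, 2600L, 2600L, 4400L, 4400L,
              4800L),
    end = c(5000L, 1600L, 1200L, 1600L, 3400L, 3400L, 5000L, 4800L,
            5000L),
    strand = "+",
    kind = c("gene", "exon", "five_prime_UTR", "CDS", "exon", "CDS",
             "exon", "CDS", "three_prime_UTR"),
    gene_id = "g1")
}

test_that("point classification follows the documented precedence", {
  ix <- annotation_index(make_features())
  expect_equal(classify_point(ix, "chr1", 100), "intergenic")
  expect_equal(classify_point(ix, "chr1", 1100), "five_prime_UTR")
  expect_equal(classify_point(ix, "chr1", 1300), "CDS")
  expect_equal(classify_point(ix, "chr1", 2000), "intron")
  expect_equal(classify_point(ix, "chr1", 4900), "three_prime_UTR")
  expect_equal(classify_point(ix, "chr1", 6000), "intergenic")
  expect_error(classify_point(ix, "chrX", 1, strict = TRUE), "chrX")
  # empty index: everything intergenic
  expect_equal(classify_point(annotation_index(), "chr9", 5), "intergenic")
})

test_that("deletion bases split exactly across classes", {
  ix <- annotation_index(make_features())
  # fully intergenic 343-bp deletion
  m <- attribute_deletion_bases(ix, "chr1", 10000, 10343)
  expect_equal(unname(m["intergenic"]), 343)
  expect_equal(sum(m), 343)

  # spanning CDS / intron / intergenic with known composition:
  # [3200, 3700) = 200 CDS (3200-3400) + 300 intron (3400-3700)
  m2 <- attribute_deletion_bases(ix, "chr1", 3200, 3700)
  expect_equal(unname(m2["CDS"]), 200)
  expect_equal(unname(m2["intron"]), 300)
  expect_equal(sum(m2), 500)

  # against the per-base oracle
  m3 <- attribute_deletion_bases(ix, "chr1", 900, 1700)
  expect_equal(m3, bf_deletion_bases(ix, "chr1", 900, 1700))

  expect_error(attribute_deletion_bases(ix, "chr1", 100, 100), "invalid")
  expect_error(attribute_deletion_bases(ix, "chr1", 100, 200,
                                        chrom_len = 150), "past end")
})

test_that("deletion attribution conserves length over fuzzed intervals", {
  g <- genome(c(chr1 = random_seq(60000)), "anno")
  feats <- simulate_annotation(g, n_genes = 10, seed = 5)
  ix <- annotation_index(feats)
  set.seed(6)
  for (i in 1:300) {
    s <- sample(0:55000, 1); len <- sample(1:4000, 1)
    m <- attribute_deletion_bases(ix, "chr1", s, s + len)
    expect_equal(sum(m), len)
  }
})

test_that("region summaries count insertions and sum deletion bases", {
  ix <- annotation_index(make_features())
  cat <- tibble::tibble(
    id = c("i1", "i2", "d1"), type = c("INS", "INS", "DEL"),
    ref_label = "female", ref_chrom = "chr1",
    ref_start = c(1300L, 9000L, 3200L),
    ref_end = c(1300L, 9000L, 3700L),
    qry_chrom = "chr1", qry_start = 0L, qry_end = 0L,
    length = c(200L, 150L, 500L), sequence = "A",
    source = "internal_scan", flags = "")
  s <- summarize_regions(cat, ix)
  expect_equal(s$ins_events[s$region_class == "CDS"], 1L)
  expect_equal(s$ins_events[s$region_class == "intergenic"], 1L)
  expect_equal(s$del_bases[s$region_class == "CDS"], 200)
  expect_equal(s$del_bases[s$region_class == "intron"], 300)
  expect_equal(unname(attr(s, "totals")), c(2, 500))

  empty <- summarize_regions(cat[0, ], ix)
  expect_true(all(empty$ins_events == 0))
  expect_true(all(empty$del_bases == 0))
})

test_that("published per-class deletion lengths sum to the printed total", {
  # female-reference deletion bp by class; the totals row equals the sum
  per_class <- c(7859, 20521, 366302, 3550553, 6520393)
  expect_equal(sum(per_class), 10465628)
})

test_that("percentage tables use half-up rounding to two decimals", {
  counts <- c(five_prime_UTR = 5, three_prime_UTR = 17, CDS = 48,
              intron = 1775, intergenic = 2577)
  pt <- percentage_table(counts)
  # 48/4,422 = 1.0855 rounds half-up to 1.09
  expect_equal(pt$percent,
               c(0.11, 0.38, 1.09, 40.14, 58.28))
  expect_lte(abs(sum(pt$percent) - 100), 0.03)

  expect_equal(percentage_table(c(only = 7))$percent, 100.00)
  expect_error(percentage_table(c(a = 0, b = 0)), "zero total")

  set.seed(12)
  for (i in 1:50) {
    x <- stats::setNames(sample(0:1000, 5), letters[1:5])
    if (sum(x) == 0) next
    pt <- percentage_table(x)
    manual <- floor(x / sum(x) * 100 * 100 + 0.5) / 100
    expect_equal(pt$percent, unname(manual))
  }
})

test_that("TE attribution counts majority-overlap variants", {
  # 100 deletions; repeat tracts fully cover the first 30
  n <- 100
  start <- seq(1000, by = 2000, length.out = n)
  cat <- tibble::tibble(
    id = sprintf("d%03d", 1:n), type = "DEL", ref_label = "female",
    ref_chrom = "chr1", ref_start = as.integer(start),
    ref_end = as.integer(start + 200), qry_chrom = "chr1",
    qry_start = 0L, qry_end = 0L, length = 200L,
    sequence = strrep("ACGTT", 40), source = "internal_scan", flags = "")
  reps <- tibble::tibble(genome = "female", chrom = "chr1",
                         start = as.integer(start[1:30]),
                         end = as.integer(start[1:30] + 200))
  att <- attribute_repeats(cat, reps)
  expect_equal(att$summary$te_count, 30L)
  expect_equal(att$summary$te_pct, 30.00)

  # no repeat intervals -> all overlaps zero
  att0 <- attribute_repeats(cat, NULL)
  expect_true(all(att0$per_variant$te_overlap == 0))

  # monotone: growing the repeat set never lowers the TE fraction
  more <- as.integer(start[31:50])
  reps2 <- dplyr::bind_rows(reps, tibble::tibble(
    genome = "female", chrom = "chr1", start = more, end = more + 200L))
  att2 <- attribute_repeats(cat, reps2)
  expect_gte(att2$summary$te_count, att$summary$te_count)

  # printed arithmetic: 3,667 of 4,675 = 78.44%
  expect_equal(overlap_percentage(3667, 4675), 78.44)
})

test_that("tandem periodicity detection agrees with the naive scan", {
  perfect <- strrep("ACGT", 50)
  td <- detect_tandem_periodicity(perfect)
  expect_true(td$tandem)
  expect_equal(td$period, 4L)

  expect_false(detect_tandem_periodicity("ACGTACGTACG")$tandem)
  expect_equal(detect_tandem_periodicity("ACGTACGTACG")$flag, "too_short")

  set.seed(33)
  rand <- random_seq(200)
  expect_equal(detect_tandem_periodicity(rand)$tandem, bf_tandem(rand))

  # 10-mer array with 10% point mutations keeps identity >= 0.8
  unit <- random_seq(10)
  arr <- strsplit(strrep(unit, 20), "")[[1]]
  idx <- sample(length(arr), 20)
  arr[idx] <- sample(c("A", "C", "G", "T"), 20, TRUE)
  mutated <- paste(arr, collapse = "")
  expect_true(detect_tandem_periodicity(mutated)$tandem)

  # fuzzed agreement with the brute-force oracle
  for (i in 1:25) {
    s <- if (i %% 2 == 0) random_seq(sample(30:120, 1))
         else strrep(random_seq(sample(2:8, 1)), 30)
    expect_equal(detect_tandem_periodicity(s)$tandem, bf_tandem(s),
                 info = s)
  }
})
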