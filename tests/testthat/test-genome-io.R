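test_that("genome construction normalises and validates", {
  g <- genome(c(a = "acgtn", b = "ACG"), label = "toy")
  expect_equal(unname(g$lengths), c(5L, 3L))
  expect_equal(g$seq[["a"]], "ACGTN")
  expect_error(genome(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(genome(c(a = "ACXT")), "outside")
  expect_error(genome(stats::setNames("ACGT", "")), "named")
})

test_that("FASTA read/write round-trips many records", {
  set.seed(4)
  seqs <- stats::setNames(
    vapply(1:50, function(i) random_seq(sample(50:300, 1)), character(1)),
    paste0("ctg", 1:50))
  g <- genome(seqs, label = "rt")
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, path)
  g2 <- read_genome_fasta(path, label = "rt")
  expect_identical(g2$seq, g$seq)
  expect_identical(names(g2$seq), names(g$seq))
})

test_that("GFF3 reading converts coordinates and filters kinds", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t150\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t101\t150\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tlnc_RNA\t300\t400\t.\t+\t.\tID=x1"
  ), path)
  expect_message(f <- read_gff3(path), "skipped 1")
  expect_equal(f$start[f$kind == "gene"], 100L)
  expect_equal(f$end[f$kind == "gene"], 200L)
  expect_setequal(f$kind, c("gene", "exon", "CDS"))
  expect_true(all(f$gene_id == "g1"))

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\tsrc\tgene\t200\t100\t.\t+\t.\tID=g1", bad)
  expect_error(read_gff3(bad), "line 1")
})

test_that("GFF3 write/read is a lossless round trip", {
  feats <- simulate_annotation(genome(c(chr1 = random_seq(60000)),
                                      "anno"), n_genes = 8, seed = 2)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, path)
  back <- read_gff3(path)
  cols <- c("chrom", "start", "end", "strand", "kind", "gene_id")
  expect_equal(
    dplyr::arrange(back[cols], chrom, start, end, kind),
    dplyr::arrange(tibble::as_tibble(feats)[cols], chrom, start, end, kind),
    ignore_attr = TRUE)
})

test_that("PAF reading maps fields and rejects malformed lines", {
  path <- withr::local_tempfile(fileext = ".paf")
  writeLines("q\t1000\t100\t900\t+\tt\t2000\t200\t1000\t700\t800\t60", path)
  b <- read_paf(path)
  expect_equal(b$qstart, 100L)
  expect_equal(b$tstart, 200L)
  expect_equal(b$matches, 700L)
  expect_equal(b$strand, "+")

  writeLines(character(0), path)
  expect_equal(nrow(read_paf(path)), 0L)

  writeLines("q\t1000\t100", path)
  expect_error(read_paf(path), "fewer than 12")
  writeLines("q\t1000\tXX\t900\t+\tt\t2000\t200\t1000\t700\t800\t60", path)
  expect_error(read_paf(path), "non-integer")
})

test_that("PAF write/read round-trips", {
  set.seed(9)
  b <- tibble::tibble(
    qname = paste0("q", 1:20), qlen = 10000L,
    qstart = as.integer(sample(0:5000, 20)), strand = sample(c("+", "-"),
                                                             20, TRUE),
    tname = paste0("t", 1:20), tlen = 20000L,
    tstart = as.integer(sample(0:5000, 20)))
  b$qend <- b$qstart + 500L
  b$tend <- b$tstart + 500L
  b$matches <- 450L
  b$block_len <- 500L
  b <- b[, c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
             "tstart", "tend", "matches", "block_len")]
  path <- withr::local_tempfile(fileext = ".paf")
  write_paf(b, path)
  expect_equal(read_paf(path), b)
})

test_that("variant catalog renders 1-based coordinates and round-trips", {
  # a 343-bp deletion whose 1-based rendering spans [1161187, 1161529]
  del <- tibble::tibble(
    id = "d1", type = "DEL", ref_label = "female", ref_chrom = "chr8",
    ref_start = 1161186L, ref_end = 1161529L, qry_chrom = "chr9",
    qry_start = 1000000L, qry_end = 1000000L, length = 343L,
    sequence = paste(rep("A", 343), collapse = ""),
    source = "internal_scan", flags = "")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_catalog(del, path)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(raw$ref_start_1based, 1161187)
  expect_equal(raw$ref_end_1based, 1161529)
  expect_equal(raw$length, 343)
  expect_equal(read_variant_catalog(path), del)

  # empty catalogs are valid files
  write_variant_catalog(del[0, ], path)
  expect_equal(nrow(read_variant_catalog(path)), 0L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_catalog(del[0, ], vcf, format = "vcf")
  expect_equal(nrow(read_variant_catalog(vcf, format = "vcf")), 0L)

  # mixed reference labels refuse to serialise
  two <- dplyr::bind_rows(del, dplyr::mutate(del, id = "d2",
                                             ref_label = "male"))
  expect_error(write_variant_catalog(two, path), "mixes")
})

test_that("random catalogs survive TSV and VCF round trips", {
  set.seed(21)
  n <- 100
  type <- sample(c("INS", "DEL"), n, TRUE)
  len <- sample(101:900, n, TRUE)
  start <- sort(sample(1000:900000, n))
  cat <- tibble::tibble(
    id = sprintf("v%03d", 1:n), type = type, ref_label = "female",
    ref_chrom = sample(c("chr1", "chr2"), n, TRUE),
    ref_start = start,
    ref_end = ifelse(type == "INS", start, start + len),
    qry_chrom = "chrQ",
    qry_start = start + 7L,
    qry_end = ifelse(type == "DEL", start + 7L, start + 7L + len),
    length = len,
    sequence = vapply(len, random_seq, character(1)),
    source = "internal_scan", flags = "")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_catalog(cat, tsv)
  expect_equal(read_variant_catalog(tsv), cat)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_catalog(cat, vcf, format = "vcf")
  back <- read_variant_catalog(vcf, format = "vcf")
  cols <- c("id", "type", "ref_chrom", "ref_start", "ref_end", "qry_chrom",
            "qry_start", "qry_end", "length", "sequence", "source")
  expect_equal(back[cols], cat[cols])
})

test_that("depth track read/write round-trips and converts coordinates", {
  tr <- tibble::tibble(chrom = "chr1", pos = 0:99,
                       depth = as.numeric(rpois(100, 10)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_track(tr, path)
  expect_equal(read_depth_track(path), tr)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(raw$pos_1based[1], 1)
})

test_that("coordinate rendering round trip is the identity", {
  set.seed(2)
  for (type in c("INS", "DEL", "SUB")) {
    s0 <- sample(1:10000, 50)
    e0 <- if (type == "INS") s0 else s0 + sample(1:500, 50, TRUE)
    r1 <- sexmarkr:::variant_to_1based(type, s0, e0)
    back <- sexmarkr:::variant_from_1based(type, r1$start1, r1$end1)
    expect_equal(back$start0, s0)
    expect_equal(back$end0, e0)
  }
})
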