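test_that("binding sites match the brute-force scanner", {
  set.seed(70)
  seq_ <- random_seq(10000)
  primer <- random_seq(20)
  # plant the primer once at position 1,000
  substr(seq_, 1001, 1020) <- primer
  g <- genome(c(chr1 = seq_), "toy")
  hits <- find_binding_sites(g, primer)
  bf <- bf_binding_sites(seq_, primer)
  expect_equal(hits$pos[hits$strand == "+"], bf$pos[bf$strand == "+"])
  expect_true(1000 %in% hits$pos[hits$strand == "+"])

  # absent primer
  expect_equal(nrow(find_binding_sites(g, "GGGGGGCCCCCCGGGGGGCC")),
               nrow(bf_binding_sites(seq_, "GGGGGGCCCCCCGGGGGGCC")))
})

test_that("mismatch tolerance spares internal but not 3' mismatches", {
  set.seed(71)
  base <- random_seq(5000)
  primer <- random_seq(22)
  internal_mut <- primer
  substr(internal_mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                          substr(primer, 10, 10))[1]
  tail_mut <- primer
  substr(tail_mut, 22, 22) <- setdiff(c("A", "C", "G", "T"),
                                      substr(primer, 22, 22))[1]
  s1 <- base; substr(s1, 501, 522) <- internal_mut
  s2 <- base; substr(s2, 501, 522) <- tail_mut
  p1 <- epcr_params(max_mismatches = 1)
  g1 <- genome(c(c1 = s1), "g1"); g2 <- genome(c(c1 = s2), "g2")

  h1 <- find_binding_sites(g1, primer, p1)
  expect_true(500 %in% h1$pos[h1$strand == "+" & h1$mismatches == 1])
  h2 <- find_binding_sites(g2, primer, p1)
  expect_false(500 %in% h2$pos[h2$strand == "+"])

  # zero tolerance finds neither
  h0 <- find_binding_sites(g1, primer, epcr_params())
  expect_false(500 %in% h0$pos)

  # monotonicity: more tolerance never removes sites
  for (mm in 0:2) {
    a <- find_binding_sites(g1, primer, epcr_params(max_mismatches = mm))
    b <- find_binding_sites(g1, primer,
                            epcr_params(max_mismatches = mm + 1))
    expect_true(all(paste(a$pos, a$strand) %in% paste(b$pos, b$strand)))
  }

  # N in the genome never matches
  sN <- base; substr(sN, 501, 522) <- primer; substr(sN, 505, 505) <- "N"
  hN <- find_binding_sites(genome(c(c1 = sN), "gN"), primer, p1)
  expect_false(500 %in% hN$pos)
})

test_that("amplicon enumeration equals brute force over site pairs", {
  set.seed(72)
  for (i in 1:10) {
    seq_ <- random_seq(20000)
    fwd <- random_seq(20); rev_ <- random_seq(20)
    pos_f <- sample(1000:8000, 1); pos_r <- pos_f + sample(300:3000, 1)
    substr(seq_, pos_f, pos_f + 19) <- fwd
    substr(seq_, pos_r, pos_r + 19) <- revcomp(rev_)
    g <- genome(c(c1 = seq_), "toy")
    pair <- tibble::tibble(fwd_seq = fwd, rev_seq = rev_)
    amp <- predict_amplicons(g, pair)
    expect_equal(sort(amp$length),
                 bf_amplicons(seq_, fwd, rev_))
    expect_equal(amp$length, amp$end - amp$start)
  }

  # no reverse site -> no product
  seq2 <- random_seq(5000)
  f2 <- random_seq(20)
  substr(seq2, 1001, 1020) <- f2
  amp2 <- predict_amplicons(genome(c(c1 = seq2), "t2"),
                            tibble::tibble(fwd_seq = f2,
                                           rev_seq = "GCGCGCATATGCGCGCATAT"))
  expect_equal(nrow(amp2), 0L)
})

test_that("e-PCR on the reverse-complemented genome mirrors amplicons", {
  set.seed(73)
  seq_ <- random_seq(20000)
  fwd <- random_seq(20); rev_ <- random_seq(20)
  substr(seq_, 3001, 3020) <- fwd
  substr(seq_, 4501, 4520) <- revcomp(rev_)
  g <- genome(c(c1 = seq_), "fwd")
  grc <- genome(c(c1 = revcomp(seq_)), "rc")
  pair <- tibble::tibble(fwd_seq = fwd, rev_seq = rev_)
  a1 <- predict_amplicons(g, pair)
  a2 <- predict_amplicons(grc, pair)
  expect_equal(sort(a1$length), sort(a2$length))
  expect_equal(sort(20000 - a1$end), sort(a2$start))
})

test_that("band collapsing matches single-linkage clustering", {
  p <- epcr_params()
  expect_equal(collapse_bands(c(500, 505), p), 502.5)
  expect_length(collapse_bands(c(500, 505), p), 1L)
  expect_equal(collapse_bands(c(390, 989), p), c(390, 989))
  expect_equal(collapse_bands(numeric(0), p), numeric(0))

  set.seed(74)
  for (i in 1:100) {
    lens <- sample(100:2000, sample(1:8, 1), replace = TRUE)
    expect_equal(collapse_bands(lens, p), bf_collapse(lens),
                 info = paste(lens, collapse = ","))
  }
})

test_that("single-band screen demands one resolvable in-range band per sex", {
  set.seed(75)
  backbone <- random_seq(30000)
  fwd <- random_seq(20); rev_ <- random_seq(20)
  insert <- random_seq(599)
  sf <- backbone
  substr(sf, 5001, 5020) <- fwd
  substr(sf, 5371, 5390) <- revcomp(rev_)   # female product 390 bp
  sm <- paste0(substr(sf, 1, 5200), insert, substr(sf, 5201, 30000))
  gf <- genome(c(c1 = sf), "female")
  gm <- genome(c(c1 = sm), "male")           # male product 989 bp
  pair <- tibble::tibble(fwd_seq = fwd, rev_seq = rev_)

  af <- predict_amplicons(gf, pair)
  am <- predict_amplicons(gm, pair)
  expect_equal(af$length, 390)
  expect_equal(am$length, 989)   # 390 + 599

  scr <- screen_single_band(pair, list(gf, gm))
  expect_true(scr$pass)
  expect_equal(unname(unlist(scr$bands)), c(390, 989))

  # multi-band in one assembly fails: append a second copy of the target
  # region with 400 bp removed between the primer sites, giving a second,
  # distinct product of 589 bp
  sm2 <- paste0(sm, substr(sm, 4001, 5500), substr(sm, 5901, 7000))
  scr2 <- screen_single_band(pair, list(gf, genome(c(c1 = sm2), "male")))
  expect_false(scr2$pass)
  expect_equal(scr2$reason, "not_single_band")

  expect_error(screen_single_band(pair, list(gf)), "two genomes")
})

test_that("band patterns give 2 bands to the heterogametic sex", {
  set.seed(76)
  backbone <- random_seq(20000)
  fwd <- random_seq(20); rev_ <- random_seq(20)
  sf <- backbone
  substr(sf, 5001, 5020) <- fwd
  substr(sf, 5371, 5390) <- revcomp(rev_)
  sm <- paste0(substr(sf, 1, 5200), random_seq(599),
               substr(sf, 5201, 20000))
  gf <- genome(c(c1 = sf), "female")
  gm <- genome(c(c1 = sm), "male")
  pair <- tibble::tibble(fwd_seq = fwd, rev_seq = rev_)

  bp <- predict_band_pattern(pair, gf, gm, "male_heterogametic")
  expect_equal(bp$female, 390)
  expect_equal(bp$male, c(390, 989))
  expect_true(bp$diagnostic)

  # identical assemblies: equal patterns, non-diagnostic
  bp2 <- predict_band_pattern(pair, gf, genome(gf$seq, "male"),
                              "male_heterogametic")
  expect_equal(bp2$female, bp2$male)
  expect_false(bp2$diagnostic)

  # mirrored ZW configuration: female heterogametic, 2 bands in females
  bp3 <- predict_band_pattern(pair, gf, gm, "female_heterogametic")
  expect_equal(bp3$female, c(390, 989))
  expect_equal(bp3$male, 989)
  expect_true(bp3$diagnostic)

  expect_error(predict_band_pattern(pair, gf, gm, "zz_system"))
})

test_that("fuzzed primer pairs: screen verdict equals the three predicates", {
  set.seed(77)
  backbone <- random_seq(15000)
  gf <- genome(c(c1 = backbone), "female")
  gm <- genome(c(c1 = paste0(substr(backbone, 1, 7000), random_seq(300),
                             substr(backbone, 7001, 15000))), "male")
  p <- epcr_params()
  for (i in 1:20) {
    s <- sample(1000:12000, 1)
    fwd <- substr(backbone, s, s + 19)
    e <- s + sample(200:2500, 1)
    rev_ <- revcomp(substr(backbone, e, e + 19))
    pair <- tibble::tibble(fwd_seq = fwd, rev_seq = rev_)
    scr <- screen_single_band(pair, list(gf, gm), p)
    bands <- lapply(list(gf, gm), function(g)
      bf_collapse(bf_amplicons(g$seq[[1]], fwd, rev_)))
    want <- length(bands[[1]]) == 1 && length(bands[[2]]) == 1 &&
      all(unlist(bands) >= 100) && all(unlist(bands) <= 2000) &&
      abs(bands[[2]] - bands[[1]]) >
        max(10, 0.02 * max(unlist(bands)))
    expect_equal(scr$pass, want, info = i)
  }
})
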