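test_that("the deletion worked example gives hom_len 4 and seq CTAG", {
  ref <- ref_genome(c(chr1 = "AGCTAGTCTAGG"))
  h <- homology_at_junction(ref, breakend("chr1", 3, "+"),
                            breakend("chr1", 8, "-"), max_len = 10)
  expect_equal(h$hom_len, 4L)
  expect_equal(h$hom_seq, "CTAG")
  # oracle agrees on the worked example
  expect_equal(oracle_homology(list(chr1 = "AGCTAGTCTAGG"),
                               "chr1", 3, "+", "chr1", 8, "-", 10), 4)
})

test_that("tandem-repeat homology is capped at svlen", {
  ref <- ref_genome(c(chr1 = "ACGTACGTACGT"))
  h <- homology_at_junction(ref, breakend("chr1", 4, "+"),
                            breakend("chr1", 8, "-"), max_len = 10,
                            svlen = 4)
  expect_equal(h$hom_len, 4L)
  expect_equal(nchar(h$hom_seq), 4L)
})

test_that("junctions without shared bases and zero budget give zero", {
  ref <- ref_genome(c(chr1 = "AAAAAACCCCCCGGGGGGTTTTTT"))
  h <- homology_at_junction(ref, breakend("chr1", 3, "+"),
                            breakend("chr1", 15, "-"), max_len = 10)
  expect_equal(h$hom_len, 0L)
  expect_equal(h$hom_seq, "")
  h0 <- homology_at_junction(ref_genome(c(chr1 = "ACGTACGTACGT")),
                             breakend("chr1", 4, "+"),
                             breakend("chr1", 8, "-"), max_len = 0)
  expect_equal(h0$hom_len, 0L)
})

test_that("N bases and junction insertions interrupt homology", {
  ref <- ref_genome(c(chr1 = "AGNTAGTCNTAGG"))
  h <- homology_at_junction(ref, breakend("chr1", 2, "+"),
                            breakend("chr1", 8, "-"), max_len = 10)
  expect_equal(h$hom_len, 0L)  # continuation starts with N, flanks differ
  ref2 <- ref_genome(c(chr1 = "AGCTAGTCTAGG"))
  h2 <- homology_at_junction(ref2, breakend("chr1", 3, "+"),
                             breakend("chr1", 8, "-"), max_len = 10,
                             inserted_seq = "TT")
  expect_equal(h2$hom_len, 0L)
})

test_that("strand-flipped inversion junctions give equal homology", {
  seqs <- make_toy_reference(1, 500, seed = 9)
  ref <- ref_genome(seqs)
  withr::with_seed(10, {
    for (i in 1:50) {
      p1 <- sample(50:200, 1)
      p2 <- sample(250:450, 1)
      a <- homology_at_junction(ref, breakend("chr1", p1, "+"),
                                breakend("chr1", p2, "+"), max_len = 40)
      b <- homology_at_junction(ref, breakend("chr1", p1, "-"),
                                breakend("chr1", p2, "-"), max_len = 40)
      expect_equal(a$hom_len, b$hom_len)
    }
  })
})

test_that("incremental extension matches the brute-force oracle", {
  seqs <- make_toy_reference(2, 2000, seed = 5)
  ref <- ref_genome(seqs)
  withr::with_seed(6, {
    for (i in 1:200) {
      interchrom <- i %% 5 == 0
      chrom1 <- "chr1"
      chrom2 <- if (interchrom) "chr2" else "chr1"
      p1 <- sample.int(2000, 1)
      p2 <- if (interchrom) sample.int(2000, 1)
            else min(2000, p1 + sample.int(400, 1))
      strands <- sample(list(c("+", "-"), c("-", "+"), c("+", "+"),
                             c("-", "-")), 1)[[1]]
      max_len <- sample(c(5, 25, 100), 1)
      svlen <- if (!interchrom) p2 - p1 else NA
      h <- homology_at_junction(ref, breakend(chrom1, p1, strands[1]),
                                breakend(chrom2, p2, strands[2]),
                                max_len = max_len, svlen = svlen)
      want <- oracle_homology(as.list(seqs), chrom1, p1, strands[1],
                              chrom2, p2, strands[2], max_len, svlen)
      expect_equal(h$hom_len, want)
      expect_equal(nchar(h$hom_seq), h$hom_len)
    }
  })
})

test_that("container-level inference adds homlen/homseq info", {
  seqs <- make_toy_reference(2, 5000, seed = 12)
  cont <- build_container(list(
    sv_record("d1", breakend("chr1", 100, "+"), breakend("chr1", 900, "-"),
              svtype = "DEL"),
    sv_record("d2", breakend("chr1", 1500, "+"),
              breakend("chr1", 2800, "-"), svtype = "DEL"),
    sv_record("t1", breakend("chr1", 3000, "+"),
              breakend("chr2", 400, "-"), svtype = "BND")))
  out <- infer_microhomology(cont, seqs)
  hl <- get_info(out, "homlen")
  expect_equal(nrow(hl), 3)
  expect_true(all(hl$value >= 0))
  hs <- setNames(get_info(out, "homseq")$value, get_info(out, "homseq")$id)
  expect_equal(unname(nchar(hs[hl$id])), hl$value)

  bad <- build_container(list(
    sv_record("x", breakend("chrZ", 10, "+"), breakend("chrZ", 99, "-"),
              svtype = "DEL")))
  expect_error(infer_microhomology(bad, seqs), "chrZ")

  zero <- infer_microhomology(cont, seqs, max_len = 0)
  expect_true(all(get_info(zero, "homlen")$value == 0))
})
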