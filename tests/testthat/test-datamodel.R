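test_that("build_container populates tidy linked tables", {
  expect_identical(n_records(build_container(list())), 0L)

  r <- sv_record("sv1", breakend("chr1", 1000, "+"),
                 breakend("chr1", 6000, "-"), svtype = "DEL")
  cont <- build_container(list(r))
  expect_equal(nrow(cont$positions), 1)
  expect_equal(cont$positions$pos2, 6000)
  st <- get_info(cont, "svtype")
  expect_equal(st$id, "sv1")
  expect_equal(st$value_index, 0L)
  expect_equal(st$value, "DEL")
  expect_equal(get_info(cont, "svlen")$value, 5000)

  # multi-valued INFO expands long-form with 0-based value_index
  r2 <- list(
    sv_record("a", breakend("chr1", 10, "+"), breakend("chr1", 99, "-"),
              svtype = "DEL", info = list(cs = c(1, 2))),
    sv_record("b", breakend("chr1", 20, "+"), breakend("chr1", 88, "-"),
              svtype = "DEL", info = list(cs = c(3, 4))))
  cont2 <- build_container(r2)
  cs <- get_info(cont2, "cs")
  expect_equal(nrow(cs), 4)
  expect_setequal(cs$value_index, c(0L, 1L))
})

test_that("container construction rejects inconsistent input", {
  r <- sv_record("dup", breakend("chr1", 10, "+"),
                 breakend("chr1", 50, "-"), svtype = "DEL")
  expect_error(build_container(list(r, r)), "dup")
  expect_error(breakend("chr1", 10, "x"), "strand")
  expect_error(breakend("chr1", 10, "+", 5, -5), "ci_lo")
})

test_that("records are canonically ordered and svlen tracks positions", {
  # breakends supplied in reverse order get swapped
  r <- sv_record("x", breakend("chr1", 6000, "-"),
                 breakend("chr1", 1000, "+"), svtype = "DEL")
  expect_equal(r$bp1$pos, 1000)
  expect_equal(r$bp1$strand, "+")
  expect_equal(r$svlen, 5000)
  # interchromosomal: ordered by chromosome name, svlen absent
  r2 <- sv_record("y", breakend("chr5", 100, "+"),
                  breakend("chr1", 900, "-"), svtype = "BND")
  expect_equal(r2$bp1$chrom, "chr1")
  expect_true(is.na(r2$svlen))
})

test_that("add_info and get_info are consistent and copy-safe", {
  cont <- build_container(list(
    sv_record("sv1", breakend("chr1", 10, "+"), breakend("chr1", 500, "-"),
              svtype = "DEL")))
  cont2 <- add_info(cont, "is_cfs1", list(sv1 = TRUE))
  expect_true("is_cfs1" %in% names(cont2$info))
  expect_true("is_cfs1" %in% cont2$header$info_meta$key)
  expect_false("is_cfs1" %in% names(cont$info))
  expect_error(add_info(cont, "bad", list(zzz = 1)), "zzz")
  expect_error(add_info(cont2, "is_cfs1", list(sv1 = FALSE)), "overwrite")
  expect_error(get_info(cont, "nonexistent"), "available")
  got <- get_info(cont2, "is_cfs1")
  expect_true(got$value)
  got$value <- FALSE  # mutating the copy must not touch the container
  expect_true(get_info(cont2, "is_cfs1")$value)
})

test_that("record extraction round-trips field-for-field", {
  recs <- list(
    sv_record("d1", breakend("chr1", 100, "+", -20, 20),
              breakend("chr1", 900, "-", -15, 10), svtype = "DEL",
              qual = 88, filter = c("PASS"),
              info = list(note = "x", pair = c(1, 2)),
              formats = tibble::tibble(sample = "s1", key = "GT",
                                       value_index = 0L, value = "0/1")),
    sv_record("b1", breakend("chr2", 50, "-"), breakend("chr3", 70, "+"),
              svtype = "BND"))
  cont <- build_container(recs,
                          sv_header(samples = "s1"))
  back <- sv_records(cont)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$bp1$ci_lo, -20)
  expect_equal(back[[1]]$bp2$ci_hi, 10)
  expect_equal(back[[1]]$info$pair, c(1, 2))
  expect_equal(back[[1]]$formats$value, "0/1")
  expect_equal(back[[2]]$bp2$chrom, "chr3")
  # rebuilt container equals the original
  cont2 <- build_container(back, cont$header)
  expect_equal(as.data.frame(cont2$positions),
               as.data.frame(cont$positions))
  expect_equal(as.data.frame(cont2$info$cipos),
               as.data.frame(cont$info$cipos))
})

test_that("every id in secondary tables exists in positions", {
  cont <- build_container(list(
    sv_record("a", breakend("chr1", 10, "+"), breakend("chr1", 99, "-"),
              svtype = "DEL", info = list(k = 1)),
    sv_record("b", breakend("chr1", 20, "+"), breakend("chr1", 88, "-"),
              svtype = "DEL")))
  sub <- subset_container(cont, "a")
  for (tab in sub$info) expect_true(all(tab$id %in% sub$positions$id))
  expect_error(subset_container(cont, "zzz"), "zzz")
})

test_that("MultiSVContainer keeps labels unique and ordered", {
  c1 <- build_container(list())
  expect_error(multi_sv_container(list(c1, c1)), "labels")
  m <- multi_sv_container(list(s2 = c1, s1 = c1))
  expect_identical(names(m$members), c("s2", "s1"))
})
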