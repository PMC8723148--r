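cfs_index_fixture <- function() {
  build_interval_index(data.frame(chrom = "chr1", start = c(0, 50000),
                                  end = c(10000, 60000)))
}

timing_index_fixture <- function() {
  build_interval_index(data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 500000, 0), end = c(500000, 2000000, 2000000),
    name = c("early", "late", "early")))
}

classification_fixture <- function() {
  build_container(list(
    sv_record("cfs_dup", breakend("chr1", 5000, "-"),
              breakend("chr1", 30000, "+"), svtype = "DUP"),
    sv_record("small_del", breakend("chr1", 100000, "+"),
              breakend("chr1", 140000, "-"), svtype = "DEL"),
    sv_record("big_dup", breakend("chr1", 600000, "-"),
              breakend("chr1", 1400000, "+"), svtype = "DUP"),
    sv_record("tra", breakend("chr1", 200000, "+"),
              breakend("chr2", 999, "-"), svtype = "BND"),
    sv_record("ins", breakend("chr2", 5000, "+"),
              breakend("chr2", 5000, "-"), svtype = "INS", svlen = 120)))
}

test_that("first-match-wins classification assigns exactly one class", {
  cont <- classification_fixture()
  cont <- annotate_bed(cont, cfs_index_fixture(), "cfs")
  f1 <- get_info(cont, "cfs1"); f2 <- get_info(cont, "cfs2")
  flags <- setNames(as.list(f1$value | f2$value), f1$id)
  cont <- add_info(cont, "cfs_site", flags)
  def <- class_definition(list(
    CFS_dup = c("svtype == DUP", "cfs_site == TRUE"),
    any_dup = "svtype == DUP",
    small_del = c("svtype == DEL", "svlen < 50000")))
  out <- classify(cont, def)
  lab <- setNames(get_info(out, "manual_sv_type")$value,
                  get_info(out, "manual_sv_type")$id)
  expect_equal(unname(lab["cfs_dup"]), "CFS_dup")   # rule 1 beats rule 2
  expect_equal(unname(lab["big_dup"]), "any_dup")
  expect_equal(unname(lab["small_del"]), "small_del")
  expect_equal(unname(lab["tra"]), "others")        # fallback
  expect_equal(length(lab), n_records(cont))        # exactly one each
})

test_that("predicates on missing INFO point at annotation", {
  def <- class_definition(list(x = "nonexistent_key == 1"))
  expect_error(classify(classification_fixture(), def), "annotate")
})

test_that("classes survive a VCF round-trip", {
  cont <- classify(classification_fixture(),
                   get_default_definitions("simple"))
  vp <- tempfile(fileext = ".vcf")
  write_sv_vcf(cont, vp)
  back <- read_sv_vcf(vp, "manta")
  a <- get_info(cont, "manual_sv_type")
  b <- get_info(back, "manual_sv_type")
  expect_equal(setNames(b$value, b$id)[a$id], setNames(a$value, a$id))
})

test_that("the simple scheme bins by type and length", {
  def <- get_default_definitions("simple")
  expect_equal(length(def$rules), 16)
  out <- classify(classification_fixture(), def)
  lab <- setNames(get_info(out, "manual_sv_type")$value,
                  get_info(out, "manual_sv_type")$id)
  expect_equal(unname(lab["small_del"]), "DEL_10kb-100kb")
  expect_equal(unname(lab["big_dup"]), "DUP_100kb-1Mb")
  expect_equal(unname(lab["tra"]), "translocation")
  expect_equal(unname(lab["ins"]), "others")
})

test_that("the PCAWG-style scheme has exactly 25 classes", {
  def <- get_default_definitions("pcawg_like", cfs_index_fixture(),
                                 timing_index_fixture())
  expect_equal(length(class_names(def)), 25)
  expect_error(get_default_definitions("pcawg_like", cfs_index_fixture()),
               "timing_index")
  out <- classify(classification_fixture(), def)
  lab <- setNames(get_info(out, "manual_sv_type")$value,
                  get_info(out, "manual_sv_type")$id)
  expect_equal(unname(lab["cfs_dup"]), "CFS")
  expect_equal(unname(lab["small_del"]), "DEL_early_<50kb")
  expect_equal(unname(lab["big_dup"]), "DUP_late_>500kb")
  expect_equal(unname(lab["tra"]), "translocation")
  expect_equal(unname(lab["ins"]), "insertion")
})

test_that("feature matrices count every record exactly once", {
  def <- get_default_definitions("pcawg_like", cfs_index_fixture(),
                                 timing_index_fixture())
  cont <- classification_fixture()
  multi <- multi_sv_container(list(
    sampleA = cont,
    sampleB = subset_container(cont, c("small_del", "tra"))))
  fm <- feature_matrix(multi, def)
  expect_equal(dim(fm$values), c(2, 25))
  expect_equal(unname(rowSums(fm$values)), c(5, 2))
  expect_equal(fm$values["sampleB", "CFS"], 0L)
  expect_equal(colnames(fm$values), class_names(def))
  expect_error(feature_matrix(list(), def), "no samples")

  # determinism: identical labels on repeated classification
  l1 <- get_info(classify(cont, def), "manual_sv_type")
  l2 <- get_info(classify(cont, def), "manual_sv_type")
  expect_identical(l1, l2)

  tsv <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, tsv)
  got <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(ncol(got), 26)  # sample column + 25 classes
  expect_equal(got$sample, c("sampleA", "sampleB"))
})
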