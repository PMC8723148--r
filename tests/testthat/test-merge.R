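two_caller_fixture <- function(a_recs, b_recs) {
  list(callerA = build_container(a_recs), callerB = build_container(b_recs))
}

test_that("the three merge conditions gate linking as specified", {
  # (i)+(ii)+(iii) all hold: same event recorded 50/40 bp apart
  m <- merge_containers(two_caller_fixture(
    list(sv_record("a1", breakend("chr1", 1000, "+"),
                   breakend("chr1", 5000, "-"), svtype = "DEL")),
    list(sv_record("b1", breakend("chr1", 1050, "+"),
                   breakend("chr1", 5040, "-"), svtype = "DEL"))),
    mode = "proximity", threshold = 100)
  expect_equal(n_records(m$container), 1)
  expect_equal(m$container$info$supportingcallercount$value, 2)
  expect_setequal(m$container$info$supportingcaller$value,
                  c("callerA", "callerB"))

  # (ii) discordant strands block the merge
  m2 <- merge_containers(two_caller_fixture(
    list(sv_record("a1", breakend("chr1", 1000, "+"),
                   breakend("chr1", 5000, "-"), svtype = "DEL")),
    list(sv_record("b1", breakend("chr1", 1000, "-"),
                   breakend("chr1", 5000, "+"), svtype = "DUP"))),
    mode = "proximity", threshold = 100)
  expect_equal(n_records(m2$container), 2)

  # (iii) close breakends but disjoint spans stay separate
  m3 <- merge_containers(two_caller_fixture(
    list(sv_record("a1", breakend("chr1", 1000, "+"),
                   breakend("chr1", 1040, "-"), svtype = "DEL")),
    list(sv_record("b1", breakend("chr1", 1090, "+"),
                   breakend("chr1", 1130, "-"), svtype = "DEL"))),
    mode = "proximity", threshold = 100)
  expect_equal(n_records(m3$container), 2)

  # interchromosomal pairs waive (iii)
  m4 <- merge_containers(two_caller_fixture(
    list(sv_record("a1", breakend("chr1", 1000, "+"),
                   breakend("chr7", 5000, "-"), svtype = "BND")),
    list(sv_record("b1", breakend("chr1", 1030, "+"),
                   breakend("chr7", 5020, "-"), svtype = "BND"))),
    mode = "proximity", threshold = 100)
  expect_equal(n_records(m4$container), 1)
})

test_that("confidence-interval mode links iff both breakend CIs overlap", {
  mk <- function(ci_b1_pos1) two_caller_fixture(
    list(sv_record("a1", breakend("chr1", 1000, "+", -50, 50),
                   breakend("chr1", 5000, "-", -50, 50), svtype = "DEL")),
    list(sv_record("b1", breakend("chr1", 1120, "+", ci_b1_pos1[1],
                                  ci_b1_pos1[2]),
                   breakend("chr1", 5010, "-", -50, 50), svtype = "DEL")))
  # [950,1050] vs [1050,1190]: share exactly 1 bp
  m <- merge_containers(mk(c(-70, 70)), mode = "confidence_interval")
  expect_equal(n_records(m$container), 1)
  # [950,1050] vs [1061,1190]: disjoint at pos1
  m2 <- merge_containers(mk(c(-59, 70)), mode = "confidence_interval")
  expect_equal(n_records(m2$container), 2)
})

test_that("degenerate thresholds merge only exact duplicates", {
  inputs <- two_caller_fixture(
    list(sv_record("a1", breakend("chr1", 1000, "+"),
                   breakend("chr1", 5000, "-"), svtype = "DEL"),
         sv_record("a2", breakend("chr1", 1001, "+"),
                   breakend("chr1", 5000, "-"), svtype = "DEL")),
    list(sv_record("b1", breakend("chr1", 1000, "+"),
                   breakend("chr1", 5000, "-"), svtype = "DEL")))
  m <- merge_containers(inputs, mode = "proximity", threshold = 0)
  expect_equal(n_records(m$container), 2)
  counts <- setNames(m$container$info$supportingcallercount$value,
                     m$container$info$supportingcallercount$id)
  expect_setequal(unname(counts), c(2, 1))
  # all-degenerate CIs behave like proximity 0
  mci <- merge_containers(inputs, mode = "confidence_interval")
  expect_equal(sort(mci$container$info$supportingcallercount$value),
               sort(m$container$info$supportingcallercount$value))
})

test_that("input validation catches bad merge arguments", {
  one <- list(x = build_container(list(
    sv_record("a", breakend("chr1", 1, "+"), breakend("chr1", 99, "-"),
              svtype = "DEL"))))
  expect_error(merge_containers(one), "at least 2")
  expect_error(merge_containers(c(one, list(y = one$x)), threshold = -5),
               ">= 0")
})

test_that("support filtering keeps well-supported events", {
  sim <- simulate_caller_vcfs(truth_n = 12, jitter = 80, seed = 21,
                              out_dir = tempfile())
  ms <- read_all_callers(sim)
  res <- merge_containers(ms, mode = "proximity", threshold = 100)
  counts <- res$container$info$supportingcallercount$value
  expect_true(any(counts == 1))   # private events exercise the filter
  expect_true(any(counts == 4))
  f2 <- filter_by_support(res, 2)
  expect_true(all(f2$container$info$supportingcallercount$value >= 2))
  f1 <- filter_by_support(res, 1)
  expect_equal(n_records(f1$container), n_records(res$container))
  expect_warning(f9 <- filter_by_support(res, 9), "exceeds")
  expect_equal(n_records(f9$container), 0)
  expect_error(filter_by_support(res, 0), ">= 1")
})

test_that("cluster membership is invariant to caller input order", {
  withr::with_seed(77, {
    inputs <- random_merge_containers(n_callers = 3)
    res <- merge_containers(inputs, mode = "proximity", threshold = 120)
    res_rev <- merge_containers(rev(inputs), mode = "proximity",
                                threshold = 120)
    key <- function(r) {
      cl <- r$clusters[order(r$clusters$caller, r$clusters$id), ]
      split(paste(cl$caller, cl$id), cl$mergedid[order(cl$caller, cl$id)])
    }
    a <- res$clusters[order(res$clusters$caller, res$clusters$id), ]
    b <- res_rev$clusters[order(res_rev$clusters$caller,
                                res_rev$clusters$id), ]
    expect_same_partition(a$mergedid, b$mergedid)
  })
})

test_that("union-find clustering equals the pairwise oracle", {
  withr::with_seed(303, {
    for (rep in 1:15) {
      inputs <- random_merge_containers()
      mode <- sample(c("proximity", "confidence_interval"), 1)
      thr <- sample(c(0, 50, 150), 1)
      res <- merge_containers(inputs, mode = mode, threshold = thr)
      oracle <- oracle_merge_clusters(inputs, mode, thr)
      got <- res$clusters[order(res$clusters$caller, res$clusters$id), ]
      want <- oracle[order(oracle$caller, oracle$id), ]
      expect_identical(got$id, want$id)
      expect_same_partition(got$mergedid, want$component)
    }
  })
})

test_that("merged output exports to VCF with its merge INFO", {
  sim <- simulate_caller_vcfs(truth_n = 6, jitter = 50, seed = 31,
                              out_dir = tempfile())
  res <- filter_by_support(
    merge_containers(read_all_callers(sim), mode = "proximity",
                     threshold = 100), 2)
  vp <- tempfile(fileext = ".vcf")
  write_sv_vcf(res$container, vp)
  back <- read_sv_vcf(vp, "manta")
  expect_equal(n_records(back), n_records(res$container))
  expect_true("mergedid" %in% names(back$info))
  expect_true("supportingcaller" %in% names(back$info))
  expect_match(paste(readLines(vp)[1:40], collapse = "\n"),
               "##INFO=<ID=mergedid")
})
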