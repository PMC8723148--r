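test_that("a rank-1 matrix is recovered nearly perfectly at k = 1", {
  u <- c(2, 5, 1, 8, 4) * 20
  v <- c(1, 3, 2, 6, 1, 4, 2, 5, 3, 1)
  M <- outer(v, u)  # samples x classes
  res <- nmf_stability_scan(M, k_range = 1, n_iter = 10, seed = 3)
  expect_lt(res$metrics$reconstruction_error[1], 0.05)
  expect_gte(res$metrics$stability[1], 0.99)
  expect_equal(colSums(res$signatures), c(S1 = 1), tolerance = 1e-8)
})

test_that("input validation guards the scan", {
  M <- matrix(1:12, 3, 4)
  expect_error(nmf_stability_scan(M - 10, 2, n_iter = 3, seed = 1),
               "non-negative")
  expect_error(nmf_stability_scan(M, 5, n_iter = 3, seed = 1), "k_range")
  expect_error(nmf_stability_scan(M, 2, n_iter = 1, seed = 1), "n_iter")
})

test_that("three planted signatures are recovered at the right rank", {
  S <- toy_signatures(25, 3)
  sim <- simulate_signature_matrix(120, S, exposure_scale = 50, seed = 7)
  res <- nmf_stability_scan(sim$matrix, k_range = 2:4, n_iter = 8,
                            seed = 7)
  expect_equal(res$selected_rank, 3L)
  match_cos <- apply(S, 2, function(s)
    max(apply(res$signatures, 2, cosine_sim, a = s)))
  expect_true(all(match_cos >= 0.9))
})

test_that("the scan is deterministic given a seed", {
  S <- toy_signatures(10, 2)
  sim <- simulate_signature_matrix(40, S, exposure_scale = 30, seed = 13)
  r1 <- nmf_stability_scan(sim$matrix, 2:3, n_iter = 4, seed = 99)
  r2 <- nmf_stability_scan(sim$matrix, 2:3, n_iter = 4, seed = 99)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$signatures, r2$signatures)
  expect_identical(r1$exposures, r2$exposures)
})

test_that("exposures reconstruct the un-resampled matrix", {
  S <- toy_signatures(12, 2)
  sim <- simulate_signature_matrix(60, S, exposure_scale = 40, seed = 17)
  res <- nmf_stability_scan(sim$matrix, 2, n_iter = 6, seed = 17)
  V <- t(sim$matrix$values)
  pk <- res$per_k[["2"]]
  err <- sqrt(sum((V - pk$signatures %*% pk$exposures)^2)) / sqrt(sum(V^2))
  expect_lte(err, pk$reconstruction_error + 0.02)
  expect_true(all(pk$exposures >= 0))
  expect_equal(unname(colSums(pk$signatures)), rep(1, 2), tolerance = 1e-8)
})

test_that("rank selection is invariant to positive rescaling", {
  # enough restarts that the stability estimate, not restart noise,
  # drives the argmax
  S <- toy_signatures(25, 3)
  for (seed in 1:5) {
    sim <- simulate_signature_matrix(120, S, exposure_scale = 40,
                                     seed = seed)
    r1 <- nmf_stability_scan(sim$matrix, 2:4, n_iter = 16, seed = seed)
    r2 <- nmf_stability_scan(sim$matrix$values * 3, 2:4, n_iter = 16,
                             seed = seed)
    expect_equal(r1$selected_rank, r2$selected_rank)
  }
})

test_that("association testing flags a strongly shifted exposure", {
  fx <- shifted_exposure_fixture()
  res <- nmf_stability_scan(fx$M, 3, n_iter = 6, seed = 11)
  assoc <- exposure_association(res, fx$groups)
  expect_equal(nrow(assoc), 3)
  top <- assoc$signature[which.min(assoc$q)]
  expect_lt(min(assoc$q), 0.05)
  # the flagged signature is the planted one
  best_match <- names(which.max(apply(res$signatures, 2, cosine_sim,
                                      a = fx$truth_sig)))
  expect_equal(top, best_match)
})

test_that("null and degenerate group comparisons behave", {
  fx <- shifted_exposure_fixture(seed = 23, shift_sd = 0)
  res <- nmf_stability_scan(fx$M, 3, n_iter = 6, seed = 23)
  assoc <- exposure_association(res, fx$groups)
  expect_true(all(assoc$q > 0.05))
  expect_error(exposure_association(res, setNames("carrier", "s001")),
               "two labels")
  g <- fx$groups; g[] <- "carrier"
  expect_error(exposure_association(res, g), "two labels")
  expect_error(
    exposure_association(res, setNames(c("a", "b"), c("zzz", "s001"))),
    "unknown sample")
  # one sample per group falls back to the exact rank-sum test
  tiny <- exposure_association(res, setNames(c("carrier", "non-carrier"),
                                             c("s001", "s002")))
  expect_true(all(is.finite(tiny$p)))
})

test_that("signature outputs are written as TSV", {
  S <- toy_signatures(8, 2)
  sim <- simulate_signature_matrix(30, S, exposure_scale = 30, seed = 29)
  res <- nmf_stability_scan(sim$matrix, 2, n_iter = 4, seed = 29)
  dir <- tempfile()
  write_signature_result(res, dir)
  expect_true(file.exists(file.path(dir, "signatures_k2.tsv")))
  expect_true(file.exists(file.path(dir, "exposures_k2.tsv")))
  sig <- readr::read_tsv(file.path(dir, "signatures_k2.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(sig), 8)
})
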