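#' SV signature extraction by stability-evaluated NMF
#'
#' Factorizes a samples x classes count matrix `M` as `t(M) ~ S %*% E`
#' with non-negative signatures `S` (classes x k, column-stochastic) and
#' exposures `E` (k x samples), while evaluating how stably the
#' signatures are recovered across restarts to choose the number of
#' signatures.
#'
#' For each candidate rank `k`, `n_iter` factorizations are run, each on
#' an independent Poisson-resampled copy of the count matrix with random
#' non-negative initialization (Frobenius objective, multiplicative
#' updates). The `k * n_iter` pooled signature vectors are partitioned
#' into `k` clusters by cosine-distance k-medoids; stability is the mean
#' silhouette width under cosine distance (singleton or identical
#' clusters score 1). Consensus signatures are the L1-normalized cluster
#' means and exposures are obtained by non-negative least squares of the
#' original (un-resampled) matrix onto the consensus signatures.
#'
#' @param matrix a `FeatureMatrix` from [feature_matrix()], or a plain
#'   non-negative samples x classes matrix.
#' @param k_range integer vector of candidate ranks.
#' @param n_iter restarts per rank (>= 2).
#' @param seed integer seed; the whole scan is deterministic given it.
#' @param max_update_iter,tol multiplicative-update iteration cap and
#'   relative-change convergence tolerance.
#' @return a `SignatureResult`: per-k list (`signatures`, `exposures`,
#'   `stability`, `reconstruction_error`), a `metrics` tibble,
#'   `selected_rank` (max stability, ties to the smaller k), and the
#'   selected `signatures`/`exposures`.
#' @export
nmf_stability_scan <- function(matrix, k_range, n_iter = 10, seed = 1,
                               max_update_iter = 400, tol = 1e-6) {
  values <- if (inherits(matrix, "FeatureMatrix")) matrix$values else matrix
  if (any(values < 0)) stop_tidysv("matrix must be non-negative")
  if (n_iter < 2) stop_tidysv("n_iter must be >= 2")
  V <- t(values)  # classes x samples
  if (any(k_range < 1) || max(k_range) > min(dim(V)))
    stop_tidysv("k_range must lie within 1..min(dim) = 1..", min(dim(V)))
  k_range <- sort(unique(as.integer(k_range)))
  class_names <- rownames(V) %||% paste0("class", seq_len(nrow(V)))
  sample_names <- colnames(V) %||% paste0("sample", seq_len(ncol(V)))
  normV <- sqrt(sum(V^2))

  per_k <- with_seed(seed, lapply(k_range, function(k) {
    sigs <- vector("list", n_iter)
    for (r in seq_len(n_iter)) {
      Vr <- stats::rpois(length(V), lambda = as.numeric(V))
      Vr <- base::matrix(Vr, nrow = nrow(V))
      fit <- nmf_multiplicative(Vr, k, max_iter = max_update_iter,
                                tol = tol)
      W <- fit$W
      csum <- colSums(W)
      csum[csum == 0] <- 1
      sigs[[r]] <- sweep(W, 2, csum, "/")
    }
    pooled <- do.call(cbind, sigs)
    clus <- cluster_signatures(pooled, k)
    S <- consensus_signatures(pooled, clus$clustering, k)
    rownames(S) <- class_names
    colnames(S) <- paste0("S", seq_len(k))
    E <- nnls_exposures(S, V)
    rownames(E) <- colnames(S)
    colnames(E) <- sample_names
    err <- if (normV > 0) sqrt(sum((V - S %*% E)^2)) / normV else 0
    list(k = k, signatures = S, exposures = E,
         stability = clus$stability, reconstruction_error = err)
  }))
  names(per_k) <- as.character(k_range)
  metrics <- tibble::tibble(
    k = k_range,
    stability = vapply(per_k, `[[`, numeric(1), "stability"),
    reconstruction_error = vapply(per_k, `[[`, numeric(1),
                                  "reconstruction_error"))
  best <- metrics$k[which.max(metrics$stability)]
  structure(list(per_k = per_k, metrics = metrics,
                 selected_rank = best,
                 signatures = per_k[[as.character(best)]]$signatures,
                 exposures = per_k[[as.character(best)]]$exposures,
                 k_range = k_range, n_iter = n_iter, seed = seed),
            class = "SignatureResult")
}

#' @export
print.SignatureResult <- function(x, ...) {
  cat("SignatureResult: ranks", paste(x$k_range, collapse = ", "),
      "| selected rank", x$selected_rank, "\n")
  print(x$metrics)
  invisible(x)
}

# Frobenius NMF by multiplicative updates (Lee & Seung), V ~ W H.
nmf_multiplicative <- function(V, k, max_iter = 400, tol = 1e-6) {
  eps <- 1e-10
  n <- nrow(V); m <- ncol(V)
  mx <- max(mean(V), eps)
  W <- base::matrix(stats::runif(n * k, 0, sqrt(mx)), n, k)
  H <- base::matrix(stats::runif(k * m, 0, sqrt(mx)), k, m)
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10 == 0) {
      err <- sum((V - W %*% H)^2)
      if (is.finite(err_old) && err_old > 0 &&
          abs(err_old - err) / err_old < tol) break
      err_old <- err
    }
  }
  list(W = W, H = H)
}

cosine_distance_matrix <- function(X) {
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  Xn <- sweep(X, 2, nrm, "/")
  sim <- crossprod(Xn)
  d <- 1 - sim
  d[d < 0] <- 0
  d
}

# k-medoids over pooled signature vectors; stability = mean silhouette
# width (cosine distance). Degenerate geometries (all points identical)
# and singleton clusters score 1.
cluster_signatures <- function(pooled, k) {
  d <- cosine_distance_matrix(pooled)
  if (k == 1 || max(d) < 1e-12) {
    return(list(clustering = rep(1L, ncol(pooled)),
                stability = 1))
  }
  pam_fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  clustering <- pam_fit$clustering
  sil <- cluster::silhouette(clustering, stats::as.dist(d))
  widths <- sil[, "sil_width"]
  sizes <- table(clustering)
  widths[sizes[as.character(clustering)] == 1] <- 1
  list(clustering = as.integer(clustering),
       stability = mean(widths))
}

consensus_signatures <- function(pooled, clustering, k) {
  S <- vapply(seq_len(k), function(j) {
    members <- pooled[, clustering == j, drop = FALSE]
    rowMeans(members)
  }, numeric(nrow(pooled)))
  S <- base::matrix(S, nrow = nrow(pooled))
  csum <- colSums(S)
  csum[csum == 0] <- 1
  sweep(S, 2, csum, "/")
}

# Non-negative least squares of each sample column of V onto S.
nnls_exposures <- function(S, V) {
  E <- vapply(seq_len(ncol(V)), function(j)
    pracma::lsqnonneg(S, V[, j])$x, numeric(ncol(S)))
  base::matrix(E, nrow = ncol(S))
}

#' Test association between signature exposures and a sample grouping
#'
#' Per-signature two-sided rank-sum (Mann-Whitney) test of the selected
#' rank's exposures between two groups (e.g. driver-mutation carriers vs
#' non-carriers), with Benjamini-Hochberg correction across signatures.
#'
#' @param result a `SignatureResult`.
#' @param groups named vector mapping sample id to one of two group
#'   labels (e.g. `"carrier"`/`"non-carrier"`); every named sample must
#'   exist in the exposure matrix and both groups must be non-empty.
#' @param rank which factorization rank to test (default the selected
#'   one).
#' @return tibble `(signature, statistic, p, q)` sorted by rule order.
#' @export
exposure_association <- function(result, groups, rank = NULL) {
  stopifnot(inherits(result, "SignatureResult"))
  rank <- rank %||% result$selected_rank
  E <- result$per_k[[as.character(rank)]]$exposures
  if (is.null(E)) stop_tidysv("rank ", rank, " was not scanned")
  groups <- groups[!is.na(groups)]
  unknown <- setdiff(names(groups), colnames(E))
  if (length(unknown))
    stop_tidysv("unknown sample(s) in groups: ",
                paste(utils::head(unknown, 5), collapse = ", "))
  lv <- unique(groups)
  if (length(lv) != 2)
    stop_tidysv("groups must contain exactly two labels, found: ",
                paste(lv, collapse = ", "))
  g1 <- names(groups)[groups == lv[1]]
  g2 <- names(groups)[groups == lv[2]]
  if (length(g1) == 0 || length(g2) == 0)
    stop_tidysv("both groups must be non-empty")
  res <- lapply(rownames(E), function(sg) {
    wt <- suppressWarnings(stats::wilcox.test(E[sg, g1], E[sg, g2],
                                              alternative = "two.sided"))
    tibble::tibble(signature = sg, statistic = unname(wt$statistic),
                   p = wt$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Write signatures and exposures as TSV files
#' @param result a `SignatureResult`.
#' @param dir output directory (created if needed).
#' @param rank rank to export (default selected).
#' @return the directory, invisibly.
#' @export
write_signature_result <- function(result, dir, rank = NULL) {
  stopifnot(inherits(result, "SignatureResult"))
  rank <- rank %||% result$selected_rank
  pk <- result$per_k[[as.character(rank)]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::as_tibble(pk$signatures, rownames = "class"),
                   file.path(dir, sprintf("signatures_k%d.tsv", rank)))
  readr::write_tsv(tibble::as_tibble(t(pk$exposures),
                                     rownames = "sample"),
                   file.path(dir, sprintf("exposures_k%d.tsv", rank)))
  readr::write_tsv(result$metrics, file.path(dir, "rank_metrics.tsv"))
  invisible(dir)
}
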