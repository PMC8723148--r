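# Independent brute-force oracles and random-instance generators used by
# the property-style tests. These deliberately avoid the package's own
# code paths (interval trees, windowed candidate generation, incremental
# extension) and recompute everything by direct enumeration.

revcomp_str <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# --- microhomology oracle --------------------------------------------------
# Direct enumeration: for each h, build both junction-frame strings in
# full (truncated windows or any 'N' invalidate the candidate) and take
# the largest h with string equality; then apply the svlen cap, trimming
# the backward extension first.
oracle_homology <- function(seqs, chrom1, p1, s1, chrom2, p2, s2,
                            max_len, svlen = NA) {
  reverse_str <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  complement_str <- function(x) chartr("ACGTN", "TGCAN", x)
  # Junction-frame flank of length h read outward from the junction.
  # A breakend whose strand differs from its canonical role orientation
  # ('+' for the junction's left partner, '-' for the right) is read on
  # the reverse-complement. NA marks a window leaving the contig.
  outward <- function(chrom, p, flipped, side, h) {
    L <- nchar(seqs[[chrom]])
    if (!flipped && side == "toward") {
      if (p - h + 1 < 1) return(NA_character_)
      reverse_str(toupper(substr(seqs[[chrom]], p - h + 1, p)))
    } else if (!flipped && side == "beyond") {
      if (p + h > L) return(NA_character_)
      toupper(substr(seqs[[chrom]], p + 1, p + h))
    } else if (flipped && side == "toward") {
      if (p + h > L) return(NA_character_)
      complement_str(toupper(substr(seqs[[chrom]], p + 1, p + h)))
    } else {
      if (p - h + 1 < 1) return(NA_character_)
      revcomp_str(toupper(substr(seqs[[chrom]], p - h + 1, p)))
    }
  }
  f1 <- !identical(s1, "+")
  f2 <- !identical(s2, "-")
  best <- function(side) {
    out <- 0
    for (h in seq_len(max_len)) {
      a <- outward(chrom1, p1, f1, side, h)
      b <- outward(chrom2, p2, f2, side, h)
      if (is.na(a) || is.na(b)) break
      if (grepl("N", a, fixed = TRUE) || grepl("N", b, fixed = TRUE)) break
      if (a == b) out <- h
    }
    out
  }
  f <- best("beyond")
  b <- min(best("toward"), max_len - f)
  hom <- f + b
  cap <- if (!is.na(svlen) && chrom1 == chrom2) svlen else Inf
  if (hom > cap) {
    f <- min(f, cap)
    b <- max(0, cap - f)
    hom <- f + b
  }
  hom
}

# --- annotation oracle -----------------------------------------------------
# All-pairs scan with the membership rule: 1-based point p is inside the
# 0-based half-open BED interval [s, e) iff s < p <= e.
oracle_annotate_presence <- function(positions, bed, side) {
  chrom <- positions[[paste0("chrom", side)]]
  p <- positions[[paste0("pos", side)]]
  vapply(seq_len(nrow(positions)), function(i) {
    if (is.na(chrom[i])) return(FALSE)
    any(bed$chrom == chrom[i] & bed$start < p[i] & p[i] <= bed$end)
  }, logical(1))
}

# --- merge oracle ----------------------------------------------------------
# O(n^2) pairwise predicate + connected components (igraph), entirely
# independent of the package's windowed candidate generation and
# union-find.
oracle_merge_clusters <- function(containers, mode, threshold) {
  pool <- dplyr::bind_rows(lapply(names(containers), function(cl) {
    x <- containers[[cl]]
    pos <- x$positions[!is.na(x$positions$chrom2), , drop = FALSE]
    if (nrow(pos) == 0) return(NULL)
    ci <- function(key, id, default = c(0, 0)) {
      v <- x$info[[key]]$value[x$info[[key]]$id == id]
      if (length(v) >= 2) v[1:2] else default
    }
    svlen <- vapply(pos$id, function(id) {
      v <- x$info$svlen$value[x$info$svlen$id == id]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    cim <- t(vapply(pos$id, function(id) c(ci("cipos", id),
                                           ci("ciend", id)), numeric(4)))
    tibble::tibble(caller = cl, id = pos$id, chrom1 = pos$chrom1,
                   pos1 = pos$pos1, strand1 = pos$strand1,
                   chrom2 = pos$chrom2, pos2 = pos$pos2,
                   strand2 = pos$strand2, svtype = pos$svtype,
                   svlen = svlen,
                   c1l = pos$pos1 + cim[, 1], c1h = pos$pos1 + cim[, 2],
                   c2l = pos$pos2 + cim[, 3], c2h = pos$pos2 + cim[, 4])
  }))
  n <- nrow(pool)
  linked <- function(i, j) {
    if (pool$chrom1[i] != pool$chrom1[j] ||
        pool$chrom2[i] != pool$chrom2[j]) return(FALSE)
    if (is.na(pool$strand1[i]) || is.na(pool$strand1[j])) return(FALSE)
    if (pool$strand1[i] != pool$strand1[j] ||
        pool$strand2[i] != pool$strand2[j]) return(FALSE)
    if (mode == "proximity") {
      if (abs(pool$pos1[i] - pool$pos1[j]) > threshold) return(FALSE)
      if (abs(pool$pos2[i] - pool$pos2[j]) > threshold) return(FALSE)
    } else {
      if (pool$c1l[i] > pool$c1h[j] || pool$c1l[j] > pool$c1h[i])
        return(FALSE)
      if (pool$c2l[i] > pool$c2h[j] || pool$c2l[j] > pool$c2h[i])
        return(FALSE)
    }
    intra_i <- pool$chrom1[i] == pool$chrom2[i]
    intra_j <- pool$chrom1[j] == pool$chrom2[j]
    if (intra_i && intra_j) {
      span <- function(k) {
        if (pool$svtype[k] == "INS")
          c(pool$pos1[k],
            pool$pos1[k] + max(ifelse(is.na(pool$svlen[k]), 1,
                                      pool$svlen[k]), 1))
        else c(pool$pos1[k], pool$pos2[k])
      }
      si <- span(i); sj <- span(j)
      if (max(si[1], sj[1]) > min(si[2], sj[2])) return(FALSE)
    }
    TRUE
  }
  edges <- integer()
  if (n > 1) {
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        if (linked(i, j)) edges <- c(edges, i, j)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  pool$component <- comp
  pool
}

# --- random instance generators -------------------------------------------
random_merge_containers <- function(n_callers = 3, n_min = 10, n_max = 40,
                                    coord_max = 2500) {
  callers <- paste0("caller", seq_len(n_callers))
  out <- lapply(callers, function(cl) {
    n <- sample(n_min:n_max, 1)
    recs <- lapply(seq_len(n), function(i) {
      type <- sample(c("DEL", "DUP", "INV", "INS", "BND"), 1,
                     prob = c(0.3, 0.2, 0.2, 0.1, 0.2))
      chrom1 <- sample(c("chrA", "chrB"), 1)
      p1 <- sample.int(coord_max, 1)
      ci <- function() sort(c(-sample.int(80, 1), sample.int(80, 1)))
      c1 <- ci(); c2 <- ci()
      if (type == "BND") {
        chrom2 <- sample(c("chrA", "chrB", "chrC"), 1)
        p2 <- sample.int(coord_max, 1)
        s <- c(sample(c("+", "-"), 1), sample(c("+", "-"), 1))
        if (chrom1 == chrom2) type <- "DEL"  # keep strands consistent
      }
      if (type != "BND") {
        chrom2 <- chrom1
        p2 <- p1 + sample.int(600, 1)
        s <- switch(type, DEL = c("+", "-"), INS = c("+", "-"),
                    DUP = c("-", "+"),
                    INV = sample(list(c("+", "+"), c("-", "-")), 1)[[1]])
      }
      sv_record(paste0(cl, "_r", i),
                breakend(chrom1, p1, s[1], c1[1], c1[2]),
                breakend(chrom2, p2, s[2], c2[1], c2[2]),
                svtype = type,
                svlen = if (type == "INS") sample.int(200, 1) else NA_real_)
    })
    build_container(recs)
  })
  names(out) <- callers
  out
}

random_annotation_instance <- function(n_records = 30, n_intervals = 25,
                                       coord_max = 1000) {
  recs <- lapply(seq_len(n_records), function(i) {
    p1 <- sample.int(coord_max, 1)
    sv_record(paste0("r", i),
              breakend(sample(c("chr1", "chr2"), 1), p1, "+"),
              breakend(sample(c("chr1", "chr2"), 1),
                       sample.int(coord_max, 1), "-"),
              svtype = "BND")
  })
  start <- sample.int(coord_max, n_intervals, replace = TRUE) - 1
  bed <- data.frame(chrom = sample(c("chr1", "chr2"), n_intervals,
                                   replace = TRUE),
                    start = start,
                    end = start + sample.int(80, n_intervals,
                                             replace = TRUE))
  list(container = build_container(recs), bed = bed)
}

# Same-cluster partitions compared as co-membership relations.
expect_same_partition <- function(labels_a, labels_b) {
  expect_equal(length(labels_a), length(labels_b))
  ca <- as.integer(factor(labels_a, levels = unique(labels_a)))
  cb <- as.integer(factor(labels_b, levels = unique(labels_b)))
  expect_identical(outer(ca, ca, "=="), outer(cb, cb, "=="))
}

read_all_callers <- function(sim) {
  out <- lapply(names(sim$paths), function(cl)
    read_sv_vcf(sim$paths[[cl]], cl))
  names(out) <- names(sim$paths)
  out
}

position_tuples <- function(container) {
  key <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
           "svtype")
  p <- container$positions[order(container$positions$chrom1,
                                 container$positions$pos1,
                                 container$positions$chrom2,
                                 container$positions$pos2), key]
  rownames(p) <- NULL
  as.data.frame(p)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Count matrix with one signature's exposure shifted upward in a carrier
# group by `shift_sd` standard deviations; truth for association tests.
shifted_exposure_fixture <- function(seed = 11, n = 60, shift_sd = 10) {
  S <- toy_signatures(20, 3)
  withr::with_seed(seed, {
    k <- ncol(S)
    E <- matrix(stats::rgamma(k * n, shape = 2, scale = 25), nrow = k)
    carriers <- sample(c(TRUE, FALSE), n, replace = TRUE)
    E[1, carriers] <- E[1, carriers] + shift_sd * stats::sd(E[1, ])
    counts <- matrix(stats::rpois(length(S %*% E), as.numeric(S %*% E)),
                     nrow = nrow(S))
    samples <- sprintf("s%03d", seq_len(n))
    M <- t(counts)
    rownames(M) <- samples
    colnames(M) <- rownames(S)
    groups <- stats::setNames(ifelse(carriers, "carrier", "non-carrier"),
                              samples)
    list(M = M, groups = groups, truth_sig = S[, 1])
  })
}
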