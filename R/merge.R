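#' Merge SV calls from multiple callers into consensus events
#'
#' Two records are linked iff all three conditions hold:
#'
#' 1. their breakend coordinates agree under the chosen criterion — in
#'    `proximity` mode the records share the same ordered `(chrom1,
#'    chrom2)` pair and both breakend positions differ by at most
#'    `threshold` bp; in `confidence_interval` mode the CIPOS-derived
#'    intervals around `pos1` share at least 1 bp and likewise the
#'    CIEND-derived intervals around `pos2`;
#' 2. both breakend strands are concordant;
#' 3. for intrachromosomal records, the `[pos1, pos2]` spans overlap by at
#'    least 1 bp (insertions use the span `[pos1, pos1 + max(svlen, 1)]`;
#'    interchromosomal pairs waive this condition, whose purpose is to
#'    keep small non-overlapping events apart).
#'
#' Merged events are the transitive closures (union-find) of this link
#' relation, so a chain of pairwise-close records can span more than
#' `threshold` bp end to end. Each event receives one representative
#' record, taken verbatim (no coordinate averaging) from the first caller
#' in input order that supports the event, plus INFO entries `mergedid`,
#' `supportingcaller`, `supportingcallercount` and `originalid_<caller>`.
#' Records with an unresolved second breakend are excluded.
#'
#' @param inputs named list of `SVContainer` objects (>= 2), or a
#'   `MultiSVContainer`; names are the caller labels.
#' @param mode `"proximity"` or `"confidence_interval"`.
#' @param threshold maximum breakend distance in bp (proximity mode only).
#' @return a `MergeResult`: list with `container` (representative
#'   records), `clusters` (tibble `caller, id, mergedid`) and `callers`.
#' @export
merge_containers <- function(inputs, mode = c("proximity",
                                              "confidence_interval"),
                             threshold = 100) {
  mode <- match.arg(mode)
  if (inherits(inputs, "MultiSVContainer")) inputs <- inputs$members
  if (length(inputs) < 2)
    stop_tidysv("merge_containers needs at least 2 input containers")
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    stop_tidysv("inputs must be a named list (caller labels)")
  if (mode == "proximity" && threshold < 0)
    stop_tidysv("threshold must be >= 0")
  pool <- merge_pool(inputs)
  if (nrow(pool) == 0)
    stop_tidysv("no records with two resolved breakends to merge")
  links <- candidate_links(pool, mode, threshold)
  comp <- union_find(nrow(pool), links)
  build_merge_result(inputs, pool, comp)
}

# Pooled per-record table used by the link predicate.
merge_pool <- function(inputs) {
  tabs <- lapply(names(inputs), function(cl) {
    x <- inputs[[cl]]
    stopifnot(inherits(x, "SVContainer"))
    pos <- x$positions
    keep <- !is.na(pos$chrom2)
    pos <- pos[keep, , drop = FALSE]
    if (nrow(pos) == 0) return(NULL)
    ci1 <- matrix(0, nrow(pos), 2)
    ci2 <- matrix(0, nrow(pos), 2)
    t1 <- x$info$cipos; t2 <- x$info$ciend
    for (j in seq_len(nrow(pos))) {
      v1 <- t1$value[t1$id == pos$id[j]]
      v2 <- t2$value[t2$id == pos$id[j]]
      if (length(v1) >= 2) ci1[j, ] <- v1[1:2]
      if (length(v2) >= 2) ci2[j, ] <- v2[1:2]
    }
    svlen <- info_first_value(subset_container(x, pos$id), "svlen",
                              NA_real_)
    intra <- pos$chrom1 == pos$chrom2
    span_lo <- ifelse(intra, pos$pos1, NA_real_)
    span_hi <- ifelse(intra,
                      ifelse(pos$svtype == "INS",
                             pos$pos1 + pmax(ifelse(is.na(svlen), 1, svlen), 1),
                             pos$pos2),
                      NA_real_)
    tibble::tibble(caller = cl, id = pos$id,
                   chrom1 = pos$chrom1, pos1 = pos$pos1,
                   strand1 = pos$strand1,
                   chrom2 = pos$chrom2, pos2 = pos$pos2,
                   strand2 = pos$strand2,
                   ci1_lo = pos$pos1 + ci1[, 1], ci1_hi = pos$pos1 + ci1[, 2],
                   ci2_lo = pos$pos2 + ci2[, 1], ci2_hi = pos$pos2 + ci2[, 2],
                   intra = intra, span_lo = span_lo, span_hi = span_hi)
  })
  dplyr::bind_rows(tabs)
}

# Candidate pair generation by interval self-overlap on the first
# breakend within strand/chromosome-compatible groups, then exact
# predicate evaluation. Returns a 2-column matrix of row indices.
candidate_links <- function(pool, mode, threshold) {
  grp <- paste(pool$chrom1, pool$chrom2, pool$strand1, pool$strand2,
               sep = "\r")
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    if (anyNA(pool$strand1[idx[1]]) || anyNA(pool$strand2[idx[1]])) next
    if (mode == "proximity") {
      ir <- IRanges::IRanges(start = pool$pos1[idx] - threshold,
                             end = pool$pos1[idx] + threshold)
    } else {
      ir <- IRanges::IRanges(start = pool$ci1_lo[idx],
                             end = pool$ci1_hi[idx])
    }
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    cand <- cbind(idx[qh[qh < sh]], idx[sh[qh < sh]])
    if (nrow(cand) == 0) next
    a <- cand[, 1]; b <- cand[, 2]
    if (mode == "proximity") {
      ok <- abs(pool$pos1[a] - pool$pos1[b]) <= threshold &
            abs(pool$pos2[a] - pool$pos2[b]) <= threshold
    } else {
      ok <- pool$ci1_lo[a] <= pool$ci1_hi[b] &
            pool$ci1_lo[b] <= pool$ci1_hi[a] &
            pool$ci2_lo[a] <= pool$ci2_hi[b] &
            pool$ci2_lo[b] <= pool$ci2_hi[a]
    }
    both_intra <- pool$intra[a] & pool$intra[b]
    span_ok <- !both_intra |
      (pmax(pool$span_lo[a], pool$span_lo[b]) <=
         pmin(pool$span_hi[a], pool$span_hi[b]))
    ok <- ok & span_ok
    out[[length(out) + 1]] <- cand[ok, , drop = FALSE]
  }
  if (length(out) == 0) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

# Plain union-find with path halving.
union_find <- function(n, links) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(links) > 0) {
    for (r in seq_len(nrow(links))) {
      ra <- find(links[r, 1]); rb <- find(links[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

build_merge_result <- function(inputs, pool, comp) {
  callers <- names(inputs)
  pool$component <- comp
  # representative per component: first caller in input order, then
  # smallest (chrom1, pos1, id) within that caller
  pool$caller_rank <- match(pool$caller, callers)
  comp_ids <- unique(comp)
  rep_rows <- integer(length(comp_ids))
  for (j in seq_along(comp_ids)) {
    rows <- which(comp == comp_ids[j])
    rows <- rows[pool$caller_rank[rows] == min(pool$caller_rank[rows])]
    o <- order(pool$chrom1[rows], pool$pos1[rows], pool$id[rows])
    rep_rows[j] <- rows[o[1]]
  }
  # stable event numbering by representative coordinates
  o <- order(pool$chrom1[rep_rows], pool$pos1[rep_rows],
             pool$chrom2[rep_rows], pool$pos2[rep_rows], pool$id[rep_rows])
  comp_ids <- comp_ids[o]
  rep_rows <- rep_rows[o]
  mergedid <- setNames(paste0("merged_", seq_along(comp_ids)),
                       as.character(comp_ids))
  pool$mergedid <- mergedid[as.character(pool$component)]

  # representative records, re-identified uniquely across callers
  recs <- list()
  merged_contigs <- dplyr::distinct(dplyr::bind_rows(
    lapply(inputs, function(x) x$header$contigs)))
  info_meta <- dplyr::distinct(dplyr::bind_rows(
    lapply(inputs, function(x) x$header$info_meta)), key, .keep_all = TRUE)
  for (j in seq_along(rep_rows)) {
    row <- rep_rows[j]
    cl <- pool$caller[row]
    rec <- sv_records(subset_container(inputs[[cl]], pool$id[row]))[[1]]
    new_id <- pool$id[row]
    if (new_id %in% names(recs)) new_id <- paste(cl, new_id, sep = "_")
    rec$id <- new_id
    ev <- pool$mergedid[row]
    members <- pool[pool$mergedid == ev, , drop = FALSE]
    sup <- callers[sort(unique(members$caller_rank))]
    rec$info$mergedid <- ev
    rec$info$supportingcaller <- sup
    rec$info$supportingcallercount <- length(sup)
    for (cl2 in sup)
      rec$info[[paste0("originalid_", cl2)]] <-
        members$id[members$caller == cl2]
    recs[[new_id]] <- rec
  }
  header <- sv_header(contigs = merged_contigs,
                      samples = character(), info_meta = info_meta)
  container <- build_container(unname(recs), header)
  structure(list(container = container,
                 clusters = tibble::as_tibble(
                   pool[, c("caller", "id", "mergedid")]),
                 callers = callers),
            class = "MergeResult")
}

#' @export
print.MergeResult <- function(x, ...) {
  cat("MergeResult:", n_records(x$container), "merged event(s) from",
      length(x$callers), "caller(s) [",
      paste(x$callers, collapse = ", "), "]\n")
  invisible(x)
}

#' Keep only events supported by enough callers
#'
#' @param result a `MergeResult` from [merge_containers()].
#' @param min_callers minimum number of supporting callers (>= 1).
#' @return a filtered `MergeResult`. Requesting more callers than were
#'   merged yields a valid empty result with a warning.
#' @export
filter_by_support <- function(result, min_callers) {
  stopifnot(inherits(result, "MergeResult"))
  if (min_callers < 1) stop_tidysv("min_callers must be >= 1")
  if (min_callers > length(result$callers))
    warning("min_callers exceeds the number of merged callers; ",
            "result is empty")
  counts <- result$container$info$supportingcallercount
  keep <- counts$id[counts$value >= min_callers]
  result$container <- subset_container(result$container, keep)
  kept_events <- result$container$info$mergedid$value
  result$clusters <- result$clusters[result$clusters$mergedid %in%
                                       kept_events, , drop = FALSE]
  result
}
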