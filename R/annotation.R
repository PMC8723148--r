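#' Build an interval index from a BED file
#'
#' Indexes BED records (0-based half-open) for fast point queries against
#' breakend positions. Internally the index is a `GRanges` object backed
#' by interval trees (nested containment lists), giving
#' `O(log n + k)`-style query cost; intervals may overlap and duplicate
#' freely. A 1-based breakend position `p` is considered inside BED
#' interval `[s, e)` iff `s < p <= e`.
#'
#' @param bed path to a BED3+ file, or a data frame with columns
#'   `chrom, start, end` and optionally `name, score`.
#' @return an `IntervalIndex`.
#' @export
build_interval_index <- function(bed) {
  if (is.character(bed)) {
    lines <- readLines(bed)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    if (!any(keep)) {
      df <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
    } else {
      raw <- strsplit(lines[keep], "\t", fixed = TRUE)
      ncol <- min(lengths(raw))
      if (ncol < 3) stop_tidysv("BED needs >= 3 columns")
      line_no <- which(keep)
      df <- data.frame(
        chrom = vapply(raw, `[`, character(1), 1),
        start = suppressWarnings(as.numeric(vapply(raw, `[`, character(1), 2))),
        end = suppressWarnings(as.numeric(vapply(raw, `[`, character(1), 3))),
        stringsAsFactors = FALSE)
      if (ncol >= 4) df$name <- vapply(raw, `[`, character(1), 4)
      if (ncol >= 5) df$score <-
          suppressWarnings(as.numeric(vapply(raw, `[`, character(1), 5)))
      bad <- which(is.na(df$start) | is.na(df$end))
      if (length(bad))
        stop_tidysv("non-numeric BED coordinates at line(s) ",
                    paste(line_no[bad], collapse = ", "))
      bad <- which(df$end <= df$start)
      if (length(bad))
        stop_tidysv("BED end <= start at line(s) ",
                    paste(line_no[bad], collapse = ", "))
    }
  } else {
    df <- as.data.frame(bed)
    if (!all(c("chrom", "start", "end") %in% names(df)))
      stop_tidysv("BED data frame needs chrom/start/end columns")
    if (any(df$end <= df$start))
      stop_tidysv("BED end <= start at row(s) ",
                  paste(which(df$end <= df$start), collapse = ", "))
  }
  gr <- if (nrow(df) == 0) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  if (nrow(df) > 0) {
    S4Vectors::mcols(gr)$name <-
      if ("name" %in% names(df)) df$name else as.character(seq_len(nrow(df)))
    S4Vectors::mcols(gr)$score <-
      if ("score" %in% names(df)) df$score else NA_real_
  }
  structure(list(gr = gr, n = length(gr)), class = "IntervalIndex")
}

#' @export
print.IntervalIndex <- function(x, ...) {
  cat("IntervalIndex with", x$n, "interval(s)\n")
  invisible(x)
}

# Query: for 1-based points, return a list (parallel to points) of
# subject indices of overlapping intervals.
index_query <- function(index, chroms, pts) {
  n <- length(pts)
  hits_list <- rep(list(integer()), n)
  ok <- !is.na(chroms) & !is.na(pts)
  if (index$n == 0 || !any(ok)) return(hits_list)
  q <- GenomicRanges::GRanges(
    seqnames = chroms[ok],
    ranges = IRanges::IRanges(start = pts[ok], width = 1))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$gr, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  idx_ok <- which(ok)
  grouped <- split(sh, qh)
  for (g in names(grouped)) hits_list[[idx_ok[as.integer(g)]]] <- grouped[[g]]
  hits_list
}

#' Annotate breakends against an interval index
#'
#' Adds two new INFO tables, `<name>1` and `<name>2`, one per breakend.
#' In `presence` mode each holds a logical flag: does the breakend point
#' fall inside any indexed interval. In `value` mode each holds the
#' payload (`name` column) of every overlapping interval, long-form when
#' several overlap. The breakend point (not its confidence interval) is
#' the query locus.
#'
#' @param container an `SVContainer`.
#' @param index an `IntervalIndex` from [build_interval_index()].
#' @param name base name for the new INFO keys.
#' @param mode `"presence"` or `"value"`.
#' @param overwrite replace existing keys of the same names.
#' @return a new `SVContainer` with the two INFO tables added.
#' @export
annotate_bed <- function(container, index, name,
                         mode = c("presence", "value"), overwrite = FALSE) {
  stopifnot(inherits(container, "SVContainer"),
            inherits(index, "IntervalIndex"))
  mode <- match.arg(mode)
  pos <- container$positions
  for (side in 1:2) {
    key <- paste0(name, side)
    if (key %in% names(container$info) && !overwrite)
      stop_tidysv("INFO key '", key, "' already exists (use overwrite)")
    chroms <- pos[[paste0("chrom", side)]]
    pts <- pos[[paste0("pos", side)]]
    hits <- index_query(index, chroms, pts)
    if (mode == "presence") {
      vals <- as.list(lengths(hits) > 0)
      names(vals) <- pos$id
    } else {
      payload <- S4Vectors::mcols(index$gr)$name
      vals <- lapply(hits, function(h) payload[h])
      names(vals) <- pos$id
      vals <- vals[lengths(vals) > 0]
    }
    container <- add_info(container, key, vals, overwrite = overwrite,
                          description = paste0("annotation '", name,
                                               "' at breakend ", side))
  }
  container
}
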