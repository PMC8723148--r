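#' Read a BEDPE file into an SVContainer
#'
#' BEDPE intervals are 0-based half-open; each breakend position is taken
#' as the (1-based) coordinate of its interval end, i.e. `start + 1` for a
#' one-bp interval, and the interval width beyond one bp becomes the
#' breakend confidence interval. The SV type is derived from strands and
#' chromosomes (`+-` deletion, `-+` duplication, `++`/`--` inversion,
#' different chromosomes `BND`) and `svlen` is derived for
#' intrachromosomal records, mirroring how BEDPE files lacking an INFO
#' notion are auto-annotated. Columns beyond the tenth are kept as INFO
#' tables, named from a leading `#`-comment header line when present.
#'
#' @param path BEDPE file with at least 10 columns
#'   (`chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2`).
#' @return an `SVContainer`.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop_tidysv("no such file: ", path)
  first <- readLines(path, n = 1)
  col_names <- NULL
  if (length(first) && startsWith(first, "#"))
    col_names <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  if (length(body) == 0 || all(body == ""))
    return(build_container(list(), sv_header()))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 10)
    stop_tidysv("BEDPE needs >= 10 columns, found ", ncol(df))
  std <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
           "name", "score", "strand1", "strand2")
  if (is.null(col_names) || length(col_names) != ncol(df)) {
    n_extra <- ncol(df) - 10
    col_names <- c(std, if (n_extra > 0) paste0("extra", seq_len(n_extra)))
  }
  names(df) <- c(std, col_names[-(1:10)])
  for (col in c("start1", "end1", "start2", "end2")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(num)) stop_tidysv("non-numeric coordinate in column ", col)
    df[[col]] <- num
  }
  bad <- !(df$strand1 %in% c("+", "-", ".")) |
         !(df$strand2 %in% c("+", "-", "."))
  if (any(bad))
    stop_tidysv("invalid strand value(s) in row(s): ",
                paste(which(bad), collapse = ", "))
  ids <- df$name
  ids[is.na(ids) | ids == "." | ids == ""] <-
    paste0("bedpe_", which(is.na(ids) | ids == "." | ids == ""))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  extra_cols <- setdiff(names(df), std)
  records <- lapply(seq_len(nrow(df)), function(i) {
    s1 <- if (df$strand1[i] == ".") NA_character_ else df$strand1[i]
    s2 <- if (df$strand2[i] == ".") NA_character_ else df$strand2[i]
    pos1 <- df$start1[i] + 1
    pos2 <- df$start2[i] + 1
    interchrom <- df$chrom1[i] != df$chrom2[i]
    svtype <- if (interchrom || is.na(s1) || is.na(s2)) "BND"
              else if (s1 == "+" && s2 == "-") "DEL"
              else if (s1 == "-" && s2 == "+") "DUP"
              else "INV"
    qual <- suppressWarnings(as.numeric(df$score[i]))
    info <- lapply(extra_cols, function(cl) {
      v <- df[[cl]][i]
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    names(info) <- extra_cols
    sv_record(
      ids[i],
      breakend(df$chrom1[i], pos1, s1, 0, df$end1[i] - df$start1[i] - 1),
      breakend(df$chrom2[i], pos2, s2, 0, df$end2[i] - df$start2[i] - 1),
      svtype = svtype, qual = qual, filter = "PASS", info = info)
  })
  contigs <- tibble::tibble(name = sort(unique(c(df$chrom1, df$chrom2))),
                            length = NA_real_)
  build_container(records, sv_header(contigs = contigs))
}

#' Write an SVContainer as a BEDPE file
#'
#' Inverse coordinate conversion of [read_bedpe()]: each 1-based breakend
#' position `p` becomes the 0-based half-open interval `[p-1, p)` widened
#' by the breakend confidence interval. INFO keys other than the derived
#' core (`svtype`, `svlen`, `cipos`, `ciend`) are exported as trailing
#' named columns; a `#`-prefixed header line carries the column names so
#' the file round-trips through [read_bedpe()].
#'
#' @param container an `SVContainer`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(container, path) {
  stopifnot(inherits(container, "SVContainer"))
  pos <- container$positions
  core <- c("svtype", "svlen", "cipos", "ciend")
  extra_keys <- setdiff(names(container$info), core)
  header <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
              "name", "score", "strand1", "strand2", "svclass", "svlen",
              extra_keys)
  lines <- paste0("#", paste(header, collapse = "\t"))
  for (i in seq_len(nrow(pos))) {
    id <- pos$id[i]
    svlen <- container$info$svlen$value[container$info$svlen$id == id]
    extras <- vapply(extra_keys, function(k) {
      tab <- container$info[[k]]
      v <- tab$value[tab$id == id]
      if (length(v) == 0) "." else paste(v, collapse = ",")
    }, character(1))
    fields <- c(
      pos$chrom1[i],
      format(pos$pos1[i] - 1, scientific = FALSE),
      format(pos$pos1[i], scientific = FALSE),
      if (is.na(pos$chrom2[i])) "." else pos$chrom2[i],
      if (is.na(pos$pos2[i])) "-1"
        else format(pos$pos2[i] - 1, scientific = FALSE),
      if (is.na(pos$pos2[i])) "-1"
        else format(pos$pos2[i], scientific = FALSE),
      id,
      if (is.na(pos$qual[i])) "." else format(pos$qual[i]),
      if (is.na(pos$strand1[i])) "." else pos$strand1[i],
      if (is.na(pos$strand2[i])) "." else pos$strand2[i],
      pos$svtype[i],
      if (length(svlen)) format(svlen[1], scientific = FALSE) else ".",
      extras)
    lines <- c(lines, paste(fields, collapse = "\t"))
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_tidysv("cannot write ", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
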