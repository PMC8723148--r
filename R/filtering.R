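#' Declarative filtering of SV containers
#'
#' Conditions are strings of the form `"item op value"`, where `item` is
#' `svtype`, `svlen`, `qual`, `filter` or any INFO key, and `op` is one of
#' `==`, `!=`, `<`, `<=`, `>`, `>=`, `in`, `not in`. For `in`/`not in` the
#' value is a comma-separated list (optionally parenthesised). Several
#' conditions combine as a conjunction; express a disjunction by filtering
#' twice and taking [container_union()]. A comparison on a multi-valued
#' INFO key holds if ANY of the record's values satisfies it, matching
#' VCF multi-value semantics; records with no value for the item never
#' match.
#'
#' @name sv_filtering
NULL

parse_condition <- function(cond) {
  m <- regmatches(cond, regexec(
    "^\\s*(\\S+)\\s+(==|!=|<=|>=|<|>|not in|in)\\s+(.+?)\\s*$", cond))[[1]]
  if (length(m) == 0)
    stop_tidysv("cannot parse condition '", cond, "'")
  value <- m[4]
  if (m[3] %in% c("in", "not in")) {
    value <- gsub("^[\\(\\[]|[\\)\\]]$", "", value)
    value <- trimws(strsplit(value, ",", fixed = TRUE)[[1]])
  }
  list(item = m[2], op = m[3], value = value)
}

# All values of `item` per record id (list id -> vector), plus whether the
# underlying data is numeric.
item_values <- function(container, item) {
  pos <- container$positions
  if (item == "qual") {
    vals <- as.list(pos$qual)
    names(vals) <- pos$id
    return(vals[!is.na(pos$qual)])
  }
  if (item == "filter") {
    return(split(container$filters$filter, container$filters$id))
  }
  tab <- container$info[[item]]
  if (is.null(tab)) {
    known <- c("svtype", "svlen", "qual", "filter", names(container$info))
    stop_tidysv("unknown filter item '", item, "'; known items: ",
                paste(unique(known), collapse = ", "))
  }
  split(tab$value, tab$id)
}

apply_op <- function(vals, op, target) {
  if (op %in% c("<", "<=", ">", ">=")) {
    tnum <- suppressWarnings(as.numeric(target))
    if (anyNA(tnum))
      stop_tidysv("ordered comparison against non-numeric value '",
                  paste(target, collapse = ","), "'")
    if (!is.numeric(vals)) {
      vnum <- suppressWarnings(as.numeric(vals))
      if (anyNA(vnum))
        stop_tidysv("ordered comparison on non-numeric values")
      vals <- vnum
    }
    return(switch(op, "<" = vals < tnum, "<=" = vals <= tnum,
                  ">" = vals > tnum, ">=" = vals >= tnum))
  }
  if (is.numeric(vals)) {
    tnum <- suppressWarnings(as.numeric(target))
    if (!anyNA(tnum)) target <- tnum
    else vals <- as.character(vals)
  } else if (is.logical(vals)) {
    tl <- as.logical(target)
    if (!anyNA(tl)) target <- tl else vals <- as.character(vals)
  }
  switch(op,
         "==" = vals == target[1],
         "!=" = vals != target[1],
         "in" = vals %in% target,
         "not in" = !(vals %in% target))
}

# ids satisfying one parsed condition
condition_ids <- function(container, cond) {
  p <- if (is.character(cond)) parse_condition(cond) else cond
  vals <- item_values(container, p$item)
  if (length(vals) == 0) return(character())
  hit <- vapply(vals, function(v) any(apply_op(v, p$op, p$value),
                                      na.rm = TRUE), logical(1))
  names(vals)[hit]
}

#' Filter a container on INFO-level conditions
#'
#' @param container an `SVContainer`.
#' @param conditions character vector of `"item op value"` conditions,
#'   combined as a conjunction.
#' @return a new `SVContainer` with only the records satisfying all
#'   conditions; all linked tables are subset consistently.
#' @export
#' @examples
#' \dontrun{
#' filter_by_info(cont, c("svtype == DEL", "svlen < 50000"))
#' }
filter_by_info <- function(container, conditions) {
  stopifnot(inherits(container, "SVContainer"))
  keep <- sv_ids(container)
  for (cond in conditions)
    keep <- intersect(keep, condition_ids(container, cond))
  subset_container(container, keep)
}

#' Filter a container on breakend coordinates
#'
#' @param container an `SVContainer`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval bounds (`start <= end`).
#' @param which which breakend(s) must fall in the region: `"bp1"`,
#'   `"bp2"`, `"either"` or `"both"`.
#' @return a new `SVContainer`. An unknown chromosome yields an empty
#'   result (with a message), not an error.
#' @export
filter_by_region <- function(container, chrom, start, end,
                             which = c("either", "bp1", "bp2", "both")) {
  stopifnot(inherits(container, "SVContainer"))
  which <- match.arg(which)
  if (start > end) stop_tidysv("filter_by_region: start > end")
  pos <- container$positions
  if (!chrom %in% c(pos$chrom1, pos$chrom2))
    message("filter_by_region: chromosome '", chrom,
            "' not present; empty result")
  in1 <- !is.na(pos$chrom1) & pos$chrom1 == chrom &
    pos$pos1 >= start & pos$pos1 <= end
  in2 <- !is.na(pos$chrom2) & pos$chrom2 == chrom &
    pos$pos2 >= start & pos$pos2 <= end
  keep <- switch(which, bp1 = in1, bp2 = in2,
                 either = in1 | in2, both = in1 & in2)
  subset_container(container, pos$id[keep])
}

#' Filter a container on a FORMAT value
#'
#' @param container an `SVContainer`.
#' @param sample sample name (must exist in the formats table).
#' @param key FORMAT key (must exist in the formats table).
#' @param op comparison operator as in [filter_by_info()].
#' @param value comparison value.
#' @return a new `SVContainer` keeping records whose FORMAT value for
#'   `(sample, key)` satisfies the comparison.
#' @export
filter_by_format <- function(container, sample, key, op, value) {
  stopifnot(inherits(container, "SVContainer"))
  fmt <- container$formats
  if (!sample %in% fmt$sample)
    stop_tidysv("unknown sample '", sample, "'; known: ",
                paste(unique(fmt$sample), collapse = ", "))
  if (!key %in% fmt$key[fmt$sample == sample])
    stop_tidysv("unknown FORMAT key '", key, "' for sample '", sample, "'")
  sub <- fmt[fmt$sample == sample & fmt$key == key, , drop = FALSE]
  vals <- split(sub$value, sub$id)
  num <- suppressWarnings(lapply(vals, as.numeric))
  if (!any(vapply(num, anyNA, logical(1)))) vals <- num
  hit <- vapply(vals, function(v)
    any(apply_op(v, op, value), na.rm = TRUE), logical(1))
  subset_container(container, names(vals)[hit])
}

#' Union of two filtered views of the same container
#'
#' Set-operation helper expressing disjunction: filter twice, then union
#' the kept record ids.
#'
#' @param x,y `SVContainer` objects subset from a common parent.
#' @param parent the parent `SVContainer` the views were filtered from.
#' @return `parent` subset to the union of ids of `x` and `y`.
#' @export
container_union <- function(x, y, parent) {
  ids <- union(sv_ids(x), sv_ids(y))
  subset_container(parent, intersect(sv_ids(parent), ids))
}
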