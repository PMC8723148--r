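#' Tidy linked-table model for structural variant calls
#'
#' An `SVContainer` stores one sample's SV calls as a set of tidy
#' rectangular tables linked by the SV identifier, instead of the packed
#' INFO/FORMAT columns of a VCF file:
#'
#' * `positions`: one row per SV record
#'   (`id, chrom1, pos1, strand1, chrom2, pos2, strand2, qual, svtype`).
#' * `filters`: long table `(id, filter)`, one row per FILTER entry.
#' * `info`: a named list of long tables `(id, value_index, value)`, one
#'   table per INFO key; multi-valued keys occupy several rows with
#'   0-based `value_index`.
#' * `formats`: long table `(id, sample, key, value_index, value)`.
#' * `header`: contigs, INFO/FORMAT declarations and sample names.
#'
#' Every variable is a column, every observational-unit type its own table,
#' and no element ever packs multiple values, so any single value is
#' addressed by a plain row/column lookup.
#'
#' Coordinates are 1-based VCF-style throughout; conversion to 0-based
#' half-open happens only at the BED/BEDPE boundary. A breakend strand of
#' `'+'` means the derivative chromosome retains the segment extending left
#' of `pos`; `'-'` retains the segment extending right. Deletions are
#' `(+,-)`, tandem duplications `(-,+)`, inversion junctions `(+,+)` or
#' `(-,-)`.
#'
#' @name sv_datamodel
NULL

#' Construct a breakend
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param strand `'+'` or `'-'` (side of the breakpoint retained in the
#'   derivative chromosome).
#' @param ci_lo,ci_hi confidence-interval offsets in bp relative to `pos`
#'   (`ci_lo <= 0 <= ci_hi`), as reported on CIPOS/CIEND.
#' @return a `breakend` object (named list).
#' @export
#' @examples
#' breakend("chr1", 1000, "+")
breakend <- function(chrom, pos, strand, ci_lo = 0L, ci_hi = 0L) {
  if (!is.na(pos) && pos < 1) stop_tidysv("breakend pos must be >= 1")
  if (!is.na(strand) && !strand %in% c("+", "-"))
    stop_tidysv("breakend strand must be '+' or '-'")
  if (!is.na(ci_lo) && !is.na(ci_hi) && ci_lo > ci_hi)
    stop_tidysv("breakend requires ci_lo <= ci_hi")
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos),
                 strand = as.character(strand),
                 ci_lo = as.numeric(ci_lo), ci_hi = as.numeric(ci_hi)),
            class = "breakend")
}

#' Construct an SV record
#'
#' Intrachromosomal records are canonically ordered so that
#' `bp1$pos <= bp2$pos`; interchromosomal records are ordered by chromosome
#' name (plain string comparison). `svlen` is present iff both breakends
#' lie on the same chromosome and equals `bp2$pos - bp1$pos` for
#' DEL/DUP/INV.
#'
#' @param id unique record identifier within a container.
#' @param bp1,bp2 [breakend()] objects; `bp2` may be `NULL` for a single
#'   breakend (e.g. an unresolved Gridss adjacency).
#' @param svtype one of `DEL`, `DUP`, `INV`, `INS`, `BND`.
#' @param svlen SV length in bp (non-negative) or `NA` for
#'   interchromosomal records.
#' @param qual numeric quality or `NA`.
#' @param filter character vector of FILTER strings.
#' @param info named list of additional INFO values (each a vector).
#' @param formats tibble `(sample, key, value_index, value)` or `NULL`.
#' @return an `sv_record` object.
#' @export
sv_record <- function(id, bp1, bp2 = NULL, svtype, svlen = NA_real_,
                      qual = NA_real_, filter = "PASS", info = list(),
                      formats = NULL) {
  stopifnot(inherits(bp1, "breakend"))
  if (!is.null(bp2)) {
    stopifnot(inherits(bp2, "breakend"))
    swap <- if (bp1$chrom == bp2$chrom) bp1$pos > bp2$pos else bp1$chrom > bp2$chrom
    if (isTRUE(swap)) { tmp <- bp1; bp1 <- bp2; bp2 <- tmp }
    if (bp1$chrom == bp2$chrom && is.na(svlen) &&
        svtype %in% c("DEL", "DUP", "INV", "BND"))
      svlen <- bp2$pos - bp1$pos
    if (bp1$chrom != bp2$chrom) svlen <- NA_real_
  }
  structure(list(id = as.character(id), bp1 = bp1, bp2 = bp2,
                 svtype = as.character(svtype), svlen = as.numeric(svlen),
                 qual = as.numeric(qual), filter = as.character(filter),
                 info = info, formats = formats),
            class = "sv_record")
}

#' Construct header metadata for an SVContainer
#'
#' @param contigs tibble `(name, length)` of reference contigs.
#' @param samples character vector of sample names.
#' @param info_meta tibble `(key, number, type, description)` of INFO
#'   declarations.
#' @param format_meta tibble of FORMAT declarations, same columns.
#' @return an `sv_header` object.
#' @export
sv_header <- function(contigs = tibble::tibble(name = character(),
                                               length = numeric()),
                      samples = character(),
                      info_meta = NULL, format_meta = NULL) {
  empty_meta <- tibble::tibble(key = character(), number = character(),
                               type = character(), description = character())
  structure(list(contigs = contigs, samples = samples,
                 info_meta = info_meta %||% empty_meta,
                 format_meta = format_meta %||% empty_meta),
            class = "sv_header")
}

empty_positions <- function() {
  tibble::tibble(id = character(), chrom1 = character(), pos1 = numeric(),
                 strand1 = character(), chrom2 = character(),
                 pos2 = numeric(), strand2 = character(), qual = numeric(),
                 svtype = character())
}

empty_info_table <- function(value = character()) {
  tibble::tibble(id = character(), value_index = integer(), value = value)
}

empty_formats <- function() {
  tibble::tibble(id = character(), sample = character(), key = character(),
                 value_index = integer(), value = character())
}

new_sv_container <- function(positions, filters, info, formats, header) {
  structure(list(positions = positions, filters = filters, info = info,
                 formats = formats, header = header),
            class = "SVContainer")
}

info_table_from_values <- function(ids, values) {
  # values: list parallel to ids, each a vector (possibly length > 1)
  lens <- lengths(values)
  keep <- lens > 0
  ids <- rep(ids[keep], lens[keep])
  idx <- unlist(lapply(lens[keep], function(n) seq_len(n) - 1L),
                use.names = FALSE) %||% integer()
  vals <- unlist(values[keep], use.names = FALSE)
  if (length(ids) == 0)
    return(empty_info_table())
  tibble::tibble(id = ids, value_index = as.integer(idx), value = vals)
}

#' Build an SVContainer from SV records
#'
#' Populates the tidy linked tables: the positions table gets one row per
#' record; `svtype`, `svlen`, `cipos`/`ciend` and any per-record INFO
#' values are expanded into long-form info tables keyed by record id.
#'
#' @param records list of [sv_record()] objects (ids must be unique).
#' @param header an [sv_header()]; a minimal header is built if omitted.
#' @return an `SVContainer`.
#' @export
#' @examples
#' r <- sv_record("sv1", breakend("chr1", 1000, "+"),
#'                breakend("chr1", 6000, "-"), svtype = "DEL")
#' cont <- build_container(list(r))
#' cont$positions
build_container <- function(records, header = sv_header()) {
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_tidysv("duplicate record id(s): ", paste(dup, collapse = ", "))
  }
  if (length(records) == 0) {
    return(new_sv_container(empty_positions(),
                            tibble::tibble(id = character(),
                                           filter = character()),
                            list(svtype = empty_info_table(),
                                 svlen = empty_info_table(numeric()),
                                 cipos = empty_info_table(numeric()),
                                 ciend = empty_info_table(numeric())),
                            empty_formats(), header))
  }
  pos <- tibble::tibble(
    id = ids,
    chrom1 = vapply(records, function(r) r$bp1$chrom, character(1)),
    pos1 = vapply(records, function(r) r$bp1$pos, numeric(1)),
    strand1 = vapply(records, function(r) r$bp1$strand, character(1)),
    chrom2 = vapply(records, function(r)
      if (is.null(r$bp2)) NA_character_ else r$bp2$chrom, character(1)),
    pos2 = vapply(records, function(r)
      if (is.null(r$bp2)) NA_real_ else r$bp2$pos, numeric(1)),
    strand2 = vapply(records, function(r)
      if (is.null(r$bp2)) NA_character_ else r$bp2$strand, character(1)),
    qual = vapply(records, function(r) r$qual, numeric(1)),
    svtype = vapply(records, function(r) r$svtype, character(1))
  )
  filters <- tibble::tibble(
    id = rep(ids, vapply(records, function(r) length(r$filter), integer(1))),
    filter = unlist(lapply(records, function(r) r$filter), use.names = FALSE)
  )
  info <- list(
    svtype = info_table_from_values(ids, lapply(records, function(r) r$svtype)),
    svlen = info_table_from_values(
      ids, lapply(records, function(r)
        if (is.na(r$svlen)) numeric() else r$svlen)),
    cipos = info_table_from_values(
      ids, lapply(records, function(r) c(r$bp1$ci_lo, r$bp1$ci_hi))),
    ciend = info_table_from_values(
      ids, lapply(records, function(r)
        if (is.null(r$bp2)) numeric() else c(r$bp2$ci_lo, r$bp2$ci_hi)))
  )
  extra_keys <- unique(unlist(lapply(records, function(r) names(r$info))))
  for (key in setdiff(extra_keys, names(info))) {
    info[[key]] <- info_table_from_values(
      ids, lapply(records, function(r) r$info[[key]] %||% vector(mode = "list", 0)))
  }
  fmts <- lapply(records, function(r) {
    if (is.null(r$formats) || nrow(r$formats) == 0) return(NULL)
    tibble::tibble(id = r$id, r$formats)
  })
  fmts <- dplyr::bind_rows(fmts)
  if (is.null(fmts) || nrow(fmts) == 0) fmts <- empty_formats()
  cont <- new_sv_container(pos, filters, info, fmts, header)
  validate_container(cont)
  cont
}

validate_container <- function(x) {
  ids <- x$positions$id
  for (key in names(x$info)) {
    bad <- setdiff(unique(x$info[[key]]$id), ids)
    if (length(bad))
      stop_tidysv("info table '", key, "' references unknown id(s): ",
                  paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(x$filters$id), ids)
  if (length(bad))
    stop_tidysv("filters table references unknown id(s): ",
                paste(bad, collapse = ", "))
  bad <- setdiff(unique(x$formats$id), ids)
  if (length(bad))
    stop_tidysv("formats table references unknown id(s): ",
                paste(bad, collapse = ", "))
  invisible(x)
}

#' Number of SV records in a container
#' @param x an `SVContainer`.
#' @return integer count.
#' @export
n_records <- function(x) nrow(x$positions)

#' Record identifiers of a container
#' @param x an `SVContainer`.
#' @return character vector of ids in positions-table order.
#' @export
sv_ids <- function(x) x$positions$id

#' @export
print.SVContainer <- function(x, ...) {
  cat("SVContainer with", n_records(x), "record(s),",
      length(x$info), "INFO table(s),",
      length(x$header$samples), "sample(s)\n")
  if (n_records(x) > 0) print(utils::head(x$positions, 6))
  invisible(x)
}

#' Add an INFO table to a container
#'
#' New annotations (SV classes, BED flags, microhomology calls) enter the
#' model as new INFO entries, so they survive export to VCF/BEDPE.
#'
#' @param container an `SVContainer`.
#' @param name INFO key to create.
#' @param values named list or vector mapping record id to a value or a
#'   vector of values. Ids absent from `values` get no rows.
#' @param overwrite replace an existing key of the same name.
#' @param description optional header description.
#' @return a new `SVContainer` with the key added and a matching header
#'   INFO declaration.
#' @export
add_info <- function(container, name, values, overwrite = FALSE,
                     description = "") {
  stopifnot(inherits(container, "SVContainer"))
  if (name %in% names(container$info) && !overwrite)
    stop_tidysv("INFO key '", name,
                "' already exists (use overwrite = TRUE)")
  if (!is.list(values)) values <- as.list(values)
  bad <- setdiff(names(values), sv_ids(container))
  if (length(bad))
    stop_tidysv("add_info: unknown id(s): ", paste(bad, collapse = ", "))
  tab <- info_table_from_values(names(values), unname(values))
  container$info[[name]] <- tab
  v <- tab$value
  type <- if (is.logical(v)) "Flag"
          else if (is.numeric(v) && all(v == as.integer(v) | is.na(v))) "Integer"
          else if (is.numeric(v)) "Float" else "String"
  number <- if (is.logical(v)) "0" else "."
  hm <- container$header$info_meta
  hm <- hm[hm$key != name, , drop = FALSE]
  container$header$info_meta <- dplyr::bind_rows(
    hm, tibble::tibble(key = name, number = number, type = type,
                       description = description))
  container
}

#' Retrieve one INFO table from a container
#'
#' @param container an `SVContainer`.
#' @param name INFO key.
#' @return a copy of the long table `(id, value_index, value)`.
#' @export
get_info <- function(container, name) {
  stopifnot(inherits(container, "SVContainer"))
  if (!name %in% names(container$info))
    stop_tidysv("unknown INFO key '", name, "'; available: ",
                paste(names(container$info), collapse = ", "))
  tibble::as_tibble(container$info[[name]])
}

#' Subset a container to a set of record ids
#'
#' All linked tables are subset consistently; row order follows the
#' original positions table.
#'
#' @param container an `SVContainer`.
#' @param ids character vector of record ids to keep.
#' @return a new `SVContainer`.
#' @export
subset_container <- function(container, ids) {
  stopifnot(inherits(container, "SVContainer"))
  bad <- setdiff(ids, sv_ids(container))
  if (length(bad))
    stop_tidysv("subset_container: unknown id(s): ",
                paste(bad, collapse = ", "))
  keep <- container$positions$id %in% ids
  container$positions <- container$positions[keep, , drop = FALSE]
  container$filters <- container$filters[container$filters$id %in% ids, ,
                                         drop = FALSE]
  container$info <- lapply(container$info, function(tab)
    tab[tab$id %in% ids, , drop = FALSE])
  container$formats <- container$formats[container$formats$id %in% ids, ,
                                         drop = FALSE]
  container
}

# Single values of an info key aligned to positions-table order (NA where
# a record has no value; first value where multi-valued).
info_first_value <- function(container, name, default = NA) {
  tab <- container$info[[name]]
  if (is.null(tab)) return(rep(default, n_records(container)))
  first <- tab[!duplicated(tab$id), , drop = FALSE]
  out <- first$value[match(sv_ids(container), first$id)]
  out
}

#' Extract SV records from a container
#'
#' Inverse of [build_container()]: rebuilds a list of [sv_record()]
#' objects, including breakend confidence intervals, generic INFO values
#' and FORMAT values, so that
#' `build_container(sv_records(x), x$header)` reproduces `x`.
#'
#' @param container an `SVContainer`.
#' @return list of `sv_record` objects.
#' @export
sv_records <- function(container) {
  stopifnot(inherits(container, "SVContainer"))
  pos <- container$positions
  core_keys <- c("svtype", "svlen", "cipos", "ciend")
  extra <- setdiff(names(container$info), core_keys)
  lapply(seq_len(nrow(pos)), function(i) {
    id <- pos$id[i]
    ci1 <- container$info$cipos$value[container$info$cipos$id == id]
    ci2 <- container$info$ciend$value[container$info$ciend$id == id]
    if (length(ci1) < 2) ci1 <- c(0, 0)
    bp1 <- breakend(pos$chrom1[i], pos$pos1[i], pos$strand1[i],
                    ci1[1], ci1[2])
    bp2 <- NULL
    if (!is.na(pos$chrom2[i])) {
      if (length(ci2) < 2) ci2 <- c(0, 0)
      bp2 <- breakend(pos$chrom2[i], pos$pos2[i], pos$strand2[i],
                      ci2[1], ci2[2])
    }
    svlen <- container$info$svlen$value[container$info$svlen$id == id]
    info <- lapply(extra, function(key) {
      tab <- container$info[[key]]
      tab$value[tab$id == id]
    })
    names(info) <- extra
    info <- info[lengths(info) > 0]
    fmt <- container$formats[container$formats$id == id,
                             c("sample", "key", "value_index", "value")]
    sv_record(id, bp1, bp2, svtype = pos$svtype[i],
              svlen = if (length(svlen)) svlen[1] else NA_real_,
              qual = pos$qual[i],
              filter = container$filters$filter[container$filters$id == id],
              info = info,
              formats = if (nrow(fmt)) fmt else NULL)
  })
}

#' Ordered collection of SVContainers
#'
#' Labels are sample ids, or caller names in a merging context; iteration
#' order is insertion order.
#'
#' @param members named list of `SVContainer` objects.
#' @return a `MultiSVContainer`.
#' @export
multi_sv_container <- function(members) {
  if (is.null(names(members)) || any(names(members) == "") ||
      anyDuplicated(names(members)))
    stop_tidysv("members must have unique non-empty labels")
  ok <- vapply(members, inherits, logical(1), what = "SVContainer")
  if (!all(ok)) stop_tidysv("all members must be SVContainer objects")
  structure(list(members = members), class = "MultiSVContainer")
}

#' @export
print.MultiSVContainer <- function(x, ...) {
  cat("MultiSVContainer with", length(x$members), "member(s):\n")
  for (nm in names(x$members))
    cat("  ", nm, ": ", n_records(x$members[[nm]]), " record(s)\n", sep = "")
  invisible(x)
}
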