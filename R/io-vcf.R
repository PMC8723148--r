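#' Parse VCF breakend ALT bracket notation
#'
#' Decodes the four bracket forms `t[p[`, `t]p]`, `]p]t`, `[p[t`. The
#' local strand is `'+'` when the replacement string `t` precedes the
#' bracket (the local segment left of POS is retained) and `'-'` when it
#' follows; the mate strand is `'-'` for `[` and `'+'` for `]`. Any novel
#' sequence inserted at the junction is `t` with the local REF allele
#' stripped from its junction-proximal end.
#'
#' @param alt ALT string in bracket notation.
#' @param local_chrom,local_pos coordinates of the record carrying `alt`
#'   (used only for error messages).
#' @param ref REF allele of the record (default `"N"`), needed to isolate
#'   the inserted sequence.
#' @return list with `mate_chrom`, `mate_pos`, `strand_local`,
#'   `strand_mate`, `inserted_seq`.
#' @export
#' @examples
#' parse_breakend_alt("T[chr3:500[", "chr1", 100, ref = "T")
parse_breakend_alt <- function(alt, local_chrom = NA, local_pos = NA,
                               ref = "N") {
  m <- regmatches(alt, regexec(
    "^([A-Za-z.]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([A-Za-z.]*)$",
    alt, perl = TRUE))[[1]]
  if (length(m) == 0 || m[3] != m[6] ||
      (nchar(m[2]) > 0) == (nchar(m[7]) > 0))
    stop_tidysv("malformed breakend ALT '", alt, "' at ",
                local_chrom, ":", local_pos)
  t_seq <- if (nchar(m[2]) > 0) m[2] else m[7]
  local_first <- nchar(m[2]) > 0
  strand_local <- if (local_first) "+" else "-"
  strand_mate <- if (m[3] == "[") "-" else "+"
  nref <- nchar(ref)
  inserted <- if (local_first) {
    if (nchar(t_seq) > nref) substr(t_seq, nref + 1L, nchar(t_seq)) else ""
  } else {
    if (nchar(t_seq) > nref) substr(t_seq, 1L, nchar(t_seq) - nref) else ""
  }
  list(mate_chrom = m[4], mate_pos = as.numeric(m[5]),
       strand_local = strand_local, strand_mate = strand_mate,
       inserted_seq = inserted)
}

# ---- header parsing -------------------------------------------------------

parse_meta_fields <- function(line) {
  inner <- sub("^##[A-Za-z]+=<", "", sub(">$", "", line))
  # split on commas outside quotes
  chars <- strsplit(inner, "")[[1]]
  out <- character(); buf <- ""; inq <- FALSE
  for (ch in chars) {
    if (ch == '"') inq <- !inq
    if (ch == "," && !inq) { out <- c(out, buf); buf <- "" }
    else buf <- paste0(buf, ch)
  }
  out <- c(out, buf)
  kv <- regmatches(out, regexec("^([^=]+)=(.*)$", out))
  vals <- vapply(kv, function(x) gsub('^"|"$', "", x[3]), character(1))
  names(vals) <- vapply(kv, function(x) x[2], character(1))
  vals
}

parse_vcf_header <- function(meta, samples) {
  contig_lines <- grep("^##contig=", meta, value = TRUE)
  contigs <- if (length(contig_lines)) {
    f <- lapply(contig_lines, parse_meta_fields)
    tibble::tibble(
      name = vapply(f, function(x) unname(x["ID"]), character(1)),
      length = vapply(f, function(x)
        suppressWarnings(as.numeric(x["length"])), numeric(1)))
  } else tibble::tibble(name = character(), length = numeric())
  meta_tab <- function(prefix) {
    lines <- grep(paste0("^##", prefix, "="), meta, value = TRUE)
    if (!length(lines))
      return(tibble::tibble(key = character(), number = character(),
                            type = character(), description = character()))
    f <- lapply(lines, parse_meta_fields)
    tibble::tibble(
      key = vapply(f, function(x) unname(x["ID"]), character(1)),
      number = vapply(f, function(x)
        unname(x["Number"]) %||% NA_character_, character(1)),
      type = vapply(f, function(x)
        unname(x["Type"]) %||% NA_character_, character(1)),
      description = vapply(f, function(x)
        unname(x["Description"]) %||% "", character(1)))
  }
  sv_header(contigs = contigs, samples = samples,
            info_meta = meta_tab("INFO"), format_meta = meta_tab("FORMAT"))
}

# Parse one raw INFO string into a named list; flags become TRUE,
# multi-valued entries become vectors, numbers are left as strings here
# (typed later per header declaration).
parse_info_string <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) out[[p]] <- TRUE
    else out[[substr(p, 1, eq - 1)]] <-
        strsplit(substr(p, eq + 1, nchar(p)), ",", fixed = TRUE)[[1]]
  }
  out
}

type_info_value <- function(key, value, info_meta) {
  if (isTRUE(value)) return(TRUE)
  type <- info_meta$type[match(key, info_meta$key)]
  if (!is.na(type) && type %in% c("Integer", "Float")) {
    num <- suppressWarnings(as.numeric(value))
    if (!anyNA(num)) return(num)
  }
  value
}

ci_pair <- function(x) {
  if (is.null(x)) return(c(0, 0))
  v <- suppressWarnings(as.numeric(x))
  if (length(v) < 2 || anyNA(v)) return(c(0, 0))
  v[1:2]
}

# Strand orientation by SV type under the BEDPE community convention.
strands_for_type <- function(svtype) {
  switch(svtype,
         DEL = c("+", "-"), INS = c("+", "-"),
         DUP = c("-", "+"),
         INV = c("+", "+"),
         c(NA_character_, NA_character_))
}

ct_to_strands <- function(ct) {
  switch(ct,
         "3to5" = c("+", "-"), "5to3" = c("-", "+"),
         "3to3" = c("+", "+"), "5to5" = c("-", "-"),
         stop_tidysv("unknown Delly CT value '", ct, "'"))
}

# Infer an SV type from normalized breakend strands for intrachromosomal
# breakend-only records (Gridss emits everything as BND pairs).
svtype_from_strands <- function(s1, s2) {
  if (is.na(s1) || is.na(s2)) return("BND")
  if (s1 == "+" && s2 == "-") "DEL"
  else if (s1 == "-" && s2 == "+") "DUP"
  else "INV"
}

#' Read an SV VCF from one of four supported callers
#'
#' Normalizes the caller dialects into the tidy container model: one
#' record per SV event (BND mate pairs are collapsed onto the
#' lower-coordinate mate), caller-specific orientation encodings (Delly
#' `CT`, Lumpy `STRANDS`, Manta `INV3`/`INV5`) mapped to breakend strands,
#' `SVLEN` normalized to a magnitude, missing `CIPOS`/`CIEND` taken as the
#' degenerate interval `(0,0)`, and every other INFO key preserved
#' verbatim as its own long table. Intrachromosomal breakend-only events
#' (typical of Gridss) have their SV type inferred from the strand pair;
#' interchromosomal adjacencies stay `BND`. Gridss single breakends (ALT
#' containing `.`) are retained with `bp2` absent.
#'
#' @param path VCF file.
#' @param caller one of `"manta"`, `"delly"`, `"lumpy"`, `"gridss"`.
#' @return an `SVContainer`.
#' @export
read_sv_vcf <- function(path, caller) {
  caller <- match.arg(caller, c("manta", "delly", "lumpy", "gridss"))
  if (!file.exists(path)) stop_tidysv("no such file: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  gt <- v@gt
  header <- parse_vcf_header(v@meta,
                             if (!is.null(gt) && ncol(gt) > 1)
                               colnames(gt)[-1] else character())
  if (is.null(fix) || nrow(fix) == 0)
    return(build_container(list(), header))
  info_meta <- header$info_meta
  n <- nrow(fix)
  rows <- lapply(seq_len(n), function(i) {
    info <- parse_info_string(fix[i, "INFO"])
    list(chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
         id = fix[i, "ID"], ref = fix[i, "REF"], alt = fix[i, "ALT"],
         qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
         filter = fix[i, "FILTER"], info = info,
         svtype = if (!is.null(info$SVTYPE)) info$SVTYPE[1] else NA_character_)
  })
  names(rows) <- vapply(rows, `[[`, character(1), "id")
  if (anyDuplicated(names(rows)))
    stop_tidysv("duplicate VCF record IDs in ", path)

  formats_for <- function(id) {
    if (is.null(gt) || ncol(gt) < 2) return(NULL)
    i <- which(fix[, "ID"] == id)
    keys <- strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    out <- lapply(colnames(gt)[-1], function(smp) {
      vals <- strsplit(gt[i, smp] %||% ".", ":", fixed = TRUE)[[1]]
      vals <- c(vals, rep(".", max(0, length(keys) - length(vals))))
      dplyr::bind_rows(lapply(seq_along(keys), function(j) {
        vv <- strsplit(vals[j], ",", fixed = TRUE)[[1]]
        tibble::tibble(sample = smp, key = keys[j],
                       value_index = seq_along(vv) - 1L, value = vv)
      }))
    })
    dplyr::bind_rows(out)
  }

  # normalized into the container structure, or line-level mate-pair
  # plumbing that is meaningless after BND collapse
  drop_keys <- c("SVTYPE", "END", "SVLEN", "CIPOS", "CIEND",
                 "MATEID", "SECONDARY", "POS2")
  generic_info <- function(info) {
    keep <- setdiff(names(info), drop_keys)
    out <- lapply(keep, function(k) type_info_value(k, info[[k]], info_meta))
    names(out) <- keep
    out
  }

  records <- list()
  bnd_like <- vapply(rows, function(r) {
    isTRUE(r$svtype %in% c("BND", "TRA")) || grepl("[][]", r$alt)
  }, logical(1))

  # --- symmetric (non-breakend) records ---------------------------------
  for (r in rows[!bnd_like]) {
    svtype <- r$svtype
    if (is.na(svtype))
      stop_tidysv("record ", r$id, " has no SVTYPE and no breakend ALT")
    end <- suppressWarnings(as.numeric(r$info$END[1] %||% NA))
    svlen <- suppressWarnings(as.numeric(r$info$SVLEN[1] %||% NA))
    if (!is.na(svlen)) svlen <- abs(svlen)
    if (is.na(end)) end <- if (svtype == "INS") r$pos else r$pos + svlen
    strands <- strands_for_type(svtype)
    if (svtype == "INV") {
      if (!is.null(r$info$CT)) strands <- ct_to_strands(r$info$CT[1])
      else if (isTRUE(r$info$INV3)) strands <- c("+", "+")
      else if (isTRUE(r$info$INV5)) strands <- c("-", "-")
      else if (!is.null(r$info$STRANDS))
        strands <- strsplit(sub(":.*$", "", r$info$STRANDS[1]), "")[[1]]
    } else if (!is.null(r$info$CT)) {
      strands <- ct_to_strands(r$info$CT[1])
    } else if (!is.null(r$info$STRANDS)) {
      strands <- strsplit(sub(":.*$", "", r$info$STRANDS[1]), "")[[1]]
    }
    ci1 <- ci_pair(r$info$CIPOS)
    ci2 <- ci_pair(r$info$CIEND)
    records[[r$id]] <- sv_record(
      r$id,
      breakend(r$chrom, r$pos, strands[1], ci1[1], ci1[2]),
      breakend(r$chrom, end, strands[2], ci2[1], ci2[2]),
      svtype = svtype,
      svlen = if (svtype == "INS") svlen else NA_real_,
      qual = r$qual, filter = strsplit(r$filter, ";", fixed = TRUE)[[1]],
      info = generic_info(r$info), formats = formats_for(r$id))
  }

  # --- breakend records --------------------------------------------------
  bnd_rows <- rows[bnd_like]
  done <- character()
  for (r in bnd_rows) {
    if (r$id %in% done) next
    # single breakend (ALT with a '.' terminus, no mate coordinate)
    if (!grepl(":", r$alt, fixed = TRUE) && grepl(".", r$alt, fixed = TRUE)) {
      ci1 <- ci_pair(r$info$CIPOS)
      strand <- if (grepl("\\.$", r$alt)) "+" else "-"
      records[[r$id]] <- sv_record(
        r$id, breakend(r$chrom, r$pos, strand, ci1[1], ci1[2]), NULL,
        svtype = "BND", qual = r$qual,
        filter = strsplit(r$filter, ";", fixed = TRUE)[[1]],
        info = generic_info(r$info), formats = formats_for(r$id))
      done <- c(done, r$id)
      next
    }
    # Delly-style BND: no bracket ALT, mate given by CHR2/END
    if (!grepl("[][]", r$alt)) {
      chr2 <- r$info$CHR2[1] %||%
        stop_tidysv("BND record ", r$id, " has neither bracket ALT nor CHR2")
      pos2 <- as.numeric(r$info$POS2[1] %||% r$info$END[1] %||%
        stop_tidysv("BND record ", r$id, " lacks a mate position"))
      strands <- if (!is.null(r$info$CT)) ct_to_strands(r$info$CT[1])
                 else c("+", "-")
      svtype <- if (r$chrom == chr2)
        svtype_from_strands(strands[1], strands[2]) else "BND"
      ci1 <- ci_pair(r$info$CIPOS); ci2 <- ci_pair(r$info$CIEND)
      records[[r$id]] <- sv_record(
        r$id, breakend(r$chrom, r$pos, strands[1], ci1[1], ci1[2]),
        breakend(chr2, pos2, strands[2], ci2[1], ci2[2]),
        svtype = svtype, qual = r$qual,
        filter = strsplit(r$filter, ";", fixed = TRUE)[[1]],
        info = generic_info(r$info), formats = formats_for(r$id))
      done <- c(done, r$id)
      next
    }
    b <- parse_breakend_alt(r$alt, r$chrom, r$pos, ref = r$ref)
    mate_id <- r$info$MATEID[1] %||% NA_character_
    mate <- if (!is.na(mate_id)) rows[[mate_id]] else NULL
    if (!is.na(mate_id) && is.null(mate))
      stop_tidysv("BND record ", r$id, " names missing mate '", mate_id, "'")
    if (is.null(mate))
      stop_tidysv("BND record ", r$id, " has no MATEID partner")
    # choose the lower-coordinate mate as representative
    this_first <- chrompos_leq(r$chrom, r$pos, b$mate_chrom, b$mate_pos)
    rep_row <- if (this_first) r else mate
    oth_row <- if (this_first) mate else r
    rb <- parse_breakend_alt(rep_row$alt, rep_row$chrom, rep_row$pos,
                             ref = rep_row$ref)
    ci1 <- ci_pair(rep_row$info$CIPOS)
    ci2 <- ci_pair(oth_row$info$CIPOS)
    svtype <- if (rep_row$chrom == rb$mate_chrom)
      svtype_from_strands(rb$strand_local, rb$strand_mate) else "BND"
    info <- generic_info(rep_row$info)
    if (nzchar(rb$inserted_seq)) info$insseq <- rb$inserted_seq
    records[[rep_row$id]] <- sv_record(
      rep_row$id,
      breakend(rep_row$chrom, rep_row$pos, rb$strand_local, ci1[1], ci1[2]),
      breakend(rb$mate_chrom, rb$mate_pos, rb$strand_mate, ci2[1], ci2[2]),
      svtype = svtype, qual = rep_row$qual,
      filter = strsplit(rep_row$filter, ";", fixed = TRUE)[[1]],
      info = info, formats = formats_for(rep_row$id))
    done <- c(done, r$id, mate_id)
  }
  # keep file order: records keyed by the representative line's ID
  records <- records[names(rows)[names(rows) %in% names(records)]]
  build_container(unname(records), header)
}

# ---- writing --------------------------------------------------------------

format_info_value <- function(v) {
  if (is.logical(v)) return(NULL)  # flags handled by caller
  paste(v, collapse = ",")
}

meta_decl <- function(kind, tab) {
  if (nrow(tab) == 0) return(character())
  sprintf('##%s=<ID=%s,Number=%s,Type=%s,Description="%s">',
          kind, tab$key,
          ifelse(is.na(tab$number), ".", tab$number),
          ifelse(is.na(tab$type), "String", tab$type),
          tab$description)
}

info_string_for <- function(container, id, extra_keys, extra = character()) {
  parts <- extra
  for (key in extra_keys) {
    tab <- container$info[[key]]
    vals <- tab$value[tab$id == id]
    if (length(vals) == 0) next
    if (is.logical(vals)) {
      if (isTRUE(vals[1])) parts <- c(parts, key)
    } else {
      parts <- c(parts, paste0(key, "=", paste(vals, collapse = ",")))
    }
  }
  if (length(parts) == 0) "." else paste(parts, collapse = ";")
}

format_columns_for <- function(container, id) {
  fmt <- container$formats[container$formats$id == id, , drop = FALSE]
  samples <- container$header$samples
  if (length(samples) == 0 || nrow(fmt) == 0) return(NULL)
  keys <- unique(fmt$key)
  cols <- vapply(samples, function(smp) {
    paste(vapply(keys, function(k) {
      vv <- fmt$value[fmt$sample == smp & fmt$key == k]
      if (length(vv) == 0) "." else paste(vv, collapse = ",")
    }, character(1)), collapse = ":")
  }, character(1))
  c(paste(keys, collapse = ":"), cols)
}

bracket_alt <- function(t_seq, mate_chrom, mate_pos, strand_local,
                        strand_mate) {
  br <- if (strand_mate == "-") "[" else "]"
  p <- paste0(br, mate_chrom, ":", mate_pos, br)
  if (strand_local == "+") paste0(t_seq, p) else paste0(p, t_seq)
}

#' Write an SVContainer as a VCF 4.2 file
#'
#' Emits header declarations for every info/format table. BND
#' (interchromosomal) events are re-expanded into bracket-notation mate
#' pairs cross-referenced by `MATEID`; inversion strand pairs are encoded
#' as `INV3`/`INV5` flags, so the output re-reads losslessly with
#' `read_sv_vcf(..., caller = "manta")`.
#'
#' @param container an `SVContainer`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(container, path) {
  stopifnot(inherits(container, "SVContainer"))
  core <- c("svtype", "svlen", "cipos", "ciend")
  extra_keys <- setdiff(names(container$info), core)
  std <- tibble::tibble(
    key = c("SVTYPE", "END", "SVLEN", "CIPOS", "CIEND", "MATEID",
            "INV3", "INV5"),
    number = c("1", "1", "1", "2", "2", "1", "0", "0"),
    type = c("String", "Integer", "Integer", "Integer", "Integer",
             "String", "Flag", "Flag"),
    description = c("SV type", "End position", "SV length",
                    "CI around POS", "CI around END", "Mate breakend ID",
                    "3' inversion", "5' inversion"))
  im <- container$header$info_meta
  im <- im[im$key %in% extra_keys, , drop = FALSE]
  missing_meta <- setdiff(extra_keys, im$key)
  if (length(missing_meta)) {
    im <- dplyr::bind_rows(im, dplyr::bind_rows(lapply(
      missing_meta, function(k) {
        v <- container$info[[k]]$value
        tibble::tibble(
          key = k, number = if (is.logical(v)) "0" else ".",
          type = if (is.logical(v)) "Flag"
                 else if (is.numeric(v)) "Float" else "String",
          description = "")
      })))
  }
  fm <- container$header$format_meta
  used_fmt <- unique(container$formats$key)
  fm_missing <- setdiff(used_fmt, fm$key)
  if (length(fm_missing))
    fm <- dplyr::bind_rows(fm, tibble::tibble(
      key = fm_missing, number = ".", type = "String", description = ""))
  fm <- fm[fm$key %in% used_fmt, , drop = FALSE]

  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>",
                     container$header$contigs$name,
                     as.integer(container$header$contigs$length)),
             meta_decl("INFO", std), meta_decl("INFO", im),
             meta_decl("FORMAT", fm))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(container$header$samples))
    cols <- c(cols, "FORMAT", container$header$samples)
  lines <- c(lines, paste(cols, collapse = "\t"))

  pos <- container$positions
  for (i in seq_len(nrow(pos))) {
    id <- pos$id[i]
    qual <- if (is.na(pos$qual[i])) "." else format(pos$qual[i])
    filt <- container$filters$filter[container$filters$id == id]
    filt <- if (length(filt)) paste(filt, collapse = ";") else "."
    ci1 <- container$info$cipos$value[container$info$cipos$id == id]
    ci2 <- container$info$ciend$value[container$info$ciend$id == id]
    if (length(ci1) < 2) ci1 <- c(0, 0)
    if (length(ci2) < 2) ci2 <- c(0, 0)
    svlen <- container$info$svlen$value[container$info$svlen$id == id]
    fmt_cols <- format_columns_for(container, id)
    interchrom <- !is.na(pos$chrom2[i]) && pos$chrom2[i] != pos$chrom1[i]
    single <- is.na(pos$chrom2[i])
    if (pos$svtype[i] == "BND" || interchrom || single) {
      if (single) {
        alt <- if (identical(pos$strand1[i], "-")) ".N" else "N."
        extra <- c("SVTYPE=BND",
                   sprintf("CIPOS=%d,%d", as.integer(ci1[1]),
                           as.integer(ci1[2])))
        line <- c(pos$chrom1[i], format(pos$pos1[i], scientific = FALSE),
                  id, "N", alt, qual, filt,
                  info_string_for(container, id, extra_keys, extra))
        lines <- c(lines, paste(c(line, fmt_cols), collapse = "\t"))
      } else {
        id2 <- paste0(id, "_mate")
        alt1 <- bracket_alt("N", pos$chrom2[i],
                            format(pos$pos2[i], scientific = FALSE),
                            pos$strand1[i], pos$strand2[i])
        alt2 <- bracket_alt("N", pos$chrom1[i],
                            format(pos$pos1[i], scientific = FALSE),
                            pos$strand2[i], pos$strand1[i])
        e1 <- c("SVTYPE=BND", paste0("MATEID=", id2),
                sprintf("CIPOS=%d,%d", as.integer(ci1[1]), as.integer(ci1[2])))
        e2 <- c("SVTYPE=BND", paste0("MATEID=", id),
                sprintf("CIPOS=%d,%d", as.integer(ci2[1]), as.integer(ci2[2])))
        l1 <- c(pos$chrom1[i], format(pos$pos1[i], scientific = FALSE), id,
                "N", alt1, qual, filt,
                info_string_for(container, id, extra_keys, e1))
        l2 <- c(pos$chrom2[i], format(pos$pos2[i], scientific = FALSE), id2,
                "N", alt2, qual, filt,
                info_string_for(container, id, character(), e2))
        lines <- c(lines, paste(c(l1, fmt_cols), collapse = "\t"),
                   paste(c(l2, fmt_cols), collapse = "\t"))
      }
    } else {
      svtype <- pos$svtype[i]
      extra <- c(paste0("SVTYPE=", svtype),
                 sprintf("END=%s", format(pos$pos2[i], scientific = FALSE)))
      if (length(svlen)) {
        sl <- if (svtype == "DEL") -svlen[1] else svlen[1]
        extra <- c(extra, sprintf("SVLEN=%d", as.integer(sl)))
      }
      extra <- c(extra,
                 sprintf("CIPOS=%d,%d", as.integer(ci1[1]), as.integer(ci1[2])),
                 sprintf("CIEND=%d,%d", as.integer(ci2[1]), as.integer(ci2[2])))
      if (svtype == "INV") {
        if (identical(pos$strand1[i], "+")) extra <- c(extra, "INV3")
        else extra <- c(extra, "INV5")
      }
      line <- c(pos$chrom1[i], format(pos$pos1[i], scientific = FALSE), id,
                "N", paste0("<", svtype, ">"), qual, filt,
                info_string_for(container, id, extra_keys, extra))
      lines <- c(lines, paste(c(line, fmt_cols), collapse = "\t"))
    }
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_tidysv("cannot write ", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
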