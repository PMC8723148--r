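#' Reference sequence accessor
#'
#' Wraps a reference genome for 1-based inclusive subsequence access by
#' contig. Accepts a FASTA path, a named character vector of sequences,
#' or a `Biostrings::DNAStringSet`.
#'
#' @param x FASTA path, named character vector, or `DNAStringSet`.
#' @return a `RefSeq` object.
#' @export
ref_genome <- function(x) {
  if (inherits(x, "RefSeq")) return(x)
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- x
  } else {
    stop_tidysv("ref_genome needs a FASTA path, a named character vector ",
                "or a DNAStringSet")
  }
  structure(list(seq = toupper(seqs),
                 lengths = nchar(seqs)), class = "RefSeq")
}

#' @export
print.RefSeq <- function(x, ...) {
  cat("RefSeq with", length(x$seq), "contig(s):",
      paste(utils::head(names(x$seq), 5), collapse = ", "), "\n")
  invisible(x)
}

# 1-based inclusive subsequence, truncated to the contig; "" if empty.
ref_sub <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref$seq))
    stop_tidysv("chromosome '", chrom, "' absent from reference")
  L <- ref$lengths[[chrom]]
  start <- max(1, start); end <- min(L, end)
  if (start > end) return("")
  substr(ref$seq[[chrom]], start, end)
}

# Single reference base at offset i from a breakend, in the junction-local
# frame. `role` is 1 for the junction's left partner, 2 for the right one;
# canonical strands are '+' (role 1) and '-' (role 2). A breakend whose
# strand is flipped relative to its canonical role is read on the
# reverse-complemented window. `side` is "toward" (i-th base walking away
# from the junction into the flank that ends at it) or "beyond" (i-th base
# walking past the junction). Out-of-range positions return NA.
bnd_base <- function(ref, chrom, pos, strand, role, side, i) {
  canonical <- if (role == 1) "+" else "-"
  flipped <- !identical(strand, canonical)
  p <- if (!flipped) {
    if (side == "toward") pos - i + 1 else pos + i
  } else {
    if (side == "toward") pos + i else pos - i + 1
  }
  if (is.na(p) || p < 1 || p > ref$lengths[[chrom]]) return(NA_character_)
  b <- substr(ref$seq[[chrom]], p, p)
  if (flipped) b <- chartr("ACGTN", "TGCAN", b)
  b
}

#' Microhomology at a single SV junction
#'
#' Two-way maximal extension of junction-spanning homology. For a
#' canonical deletion-type junction (strands `+,-`, positions `p1 < p2`)
#' the forward extension is the largest `f <= max_len` with
#' `ref[p1+1 .. p1+f] == ref[p2+1 .. p2+f]` and the backward extension the
#' largest `b <= max_len - f` with `ref[p1-b+1 .. p1] == ref[p2-b+1 .. p2]`;
#' then `hom_len = f + b` and `hom_seq = ref[p1-b+1 .. p1+f]`. For other
#' strand combinations each breakend whose strand differs from its
#' canonical role orientation has its flank read on the reverse complement
#' so the same extension applies. Comparison is case-insensitive; `N`
#' never matches; windows are truncated (not errors) at contig ends. For
#' intrachromosomal events `hom_len` is additionally capped at `svlen`
#' (the backward extension is trimmed first). A non-empty inserted
#' sequence at the junction interrupts homology and forces
#' `hom_len = 0`.
#'
#' @param ref a [ref_genome()] accessor (or something coercible).
#' @param bp1,bp2 [breakend()] objects.
#' @param max_len maximum homology length searched (bp).
#' @param svlen SV length cap for intrachromosomal events (`NA` = no cap).
#' @param inserted_seq junction insertion from the caller's ALT, if any.
#' @return list with `hom_len` (bp) and `hom_seq` (string,
#'   `nchar(hom_seq) == hom_len`).
#' @export
#' @examples
#' ref <- ref_genome(c(chr1 = "AGCTAGTCTAGG"))
#' homology_at_junction(ref, breakend("chr1", 3, "+"),
#'                      breakend("chr1", 8, "-"), max_len = 10)
homology_at_junction <- function(ref, bp1, bp2, max_len = 200,
                                 svlen = NA_real_, inserted_seq = "") {
  ref <- ref_genome(ref)
  if (max_len < 0) stop_tidysv("max_len must be >= 0")
  for (ch in unique(c(bp1$chrom, bp2$chrom)))
    if (!ch %in% names(ref$seq))
      stop_tidysv("chromosome '", ch, "' absent from reference")
  if (nzchar(inserted_seq %||% ""))
    return(list(hom_len = 0L, hom_seq = ""))
  match_at <- function(side, i) {
    a <- bnd_base(ref, bp1$chrom, bp1$pos, bp1$strand, 1, side, i)
    b <- bnd_base(ref, bp2$chrom, bp2$pos, bp2$strand, 2, side, i)
    !is.na(a) && !is.na(b) && a != "N" && b != "N" && a == b
  }
  f <- 0L
  while (f < max_len && match_at("beyond", f + 1L)) f <- f + 1L
  b <- 0L
  while (b < max_len - f && match_at("toward", b + 1L)) b <- b + 1L
  hom <- f + b
  cap <- if (!is.na(svlen) && bp1$chrom == bp2$chrom) svlen else Inf
  if (hom > cap) {
    f <- as.integer(min(f, cap))
    b <- as.integer(max(0, cap - f))
    hom <- f + b
  }
  seq_toward <- if (b > 0) paste(vapply(rev(seq_len(b)), function(i)
    bnd_base(ref, bp1$chrom, bp1$pos, bp1$strand, 1, "toward", i),
    character(1)), collapse = "") else ""
  seq_beyond <- if (f > 0) paste(vapply(seq_len(f), function(i)
    bnd_base(ref, bp1$chrom, bp1$pos, bp1$strand, 1, "beyond", i),
    character(1)), collapse = "") else ""
  list(hom_len = as.integer(hom), hom_seq = paste0(seq_toward, seq_beyond))
}

#' Infer microhomology for every record in a container
#'
#' Adds INFO tables `homlen` and `homseq` for every record with two
#' resolved breakends. Caller-provided `HOMLEN`/`HOMSEQ` values, if any,
#' are preserved untouched under their original keys. Records carrying a
#' junction insertion (INFO key `insseq`, filled by the VCF reader from
#' bracket ALTs) get `homlen = 0`.
#'
#' @param container an `SVContainer`.
#' @param ref reference accessor (see [ref_genome()]).
#' @param max_len maximum homology length searched (default 200 bp).
#' @return a new `SVContainer` with `homlen`/`homseq` INFO tables.
#' @export
infer_microhomology <- function(container, ref, max_len = 200) {
  stopifnot(inherits(container, "SVContainer"))
  ref <- ref_genome(ref)
  pos <- container$positions
  resolved <- !is.na(pos$chrom2) & !is.na(pos$strand1) & !is.na(pos$strand2)
  used <- unique(c(pos$chrom1[resolved], pos$chrom2[resolved]))
  missing <- setdiff(used, names(ref$seq))
  if (length(missing))
    stop_tidysv("contig(s) absent from reference: ",
                paste(missing, collapse = ", "))
  svlen <- info_first_value(container, "svlen", NA_real_)
  ins <- container$info$insseq
  homlen <- list(); homseq <- list()
  for (i in which(resolved)) {
    id <- pos$id[i]
    inserted <- if (!is.null(ins)) {
      v <- ins$value[ins$id == id]
      if (length(v)) v[1] else ""
    } else ""
    h <- homology_at_junction(
      ref,
      breakend(pos$chrom1[i], pos$pos1[i], pos$strand1[i]),
      breakend(pos$chrom2[i], pos$pos2[i], pos$strand2[i]),
      max_len = max_len, svlen = svlen[i], inserted_seq = inserted)
    homlen[[id]] <- h$hom_len
    homseq[[id]] <- h$hom_seq
  }
  container <- add_info(container, "homlen", homlen, overwrite = TRUE,
                        description = "Inferred microhomology length (bp)")
  add_info(container, "homseq", homseq, overwrite = TRUE,
           description = "Inferred microhomology sequence")
}
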