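#' Synthetic data generators
#'
#' Deterministic, seeded generators that make every part of the toolkit
#' testable without external downloads: a toy reference genome, four-caller
#' VCF sets with a known truth clustering, and count matrices drawn from
#' known signatures.
#'
#' @name sv_fixtures
NULL

#' Generate a toy reference genome
#'
#' Uniform random ACGT sequence per chromosome, deterministic per seed.
#'
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param length length of each chromosome in bp (>= 1).
#' @param seed integer seed.
#' @param path optional FASTA output path; when given the FASTA is
#'   written there.
#' @return named character vector of sequences (invisibly also written to
#'   `path` if requested).
#' @export
make_toy_reference <- function(n_chroms = 1, length = 10000, seed = 42,
                               path = NULL) {
  if (length < 1) stop_tidysv("length must be >= 1")
  seqs <- with_seed(seed, vapply(seq_len(n_chroms), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1)))
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  if (!is.null(path)) {
    ss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(ss, path)
  }
  seqs
}

# One truth event set: well-separated breakpoints so that events jittered
# by up to `jitter` bp can never collide across events.
simulate_truth_events <- function(truth_n, n_private_per_caller, jitter,
                                  callers, chrom_len = 5e6) {
  n_total <- truth_n + n_private_per_caller * length(callers)
  types <- sample(c("DEL", "DUP", "INV", "BND"), n_total, replace = TRUE,
                  prob = c(0.35, 0.25, 0.25, 0.15))
  gap <- max(20 * jitter + 2000, 4000)
  chroms <- sample(c("chr1", "chr2"), n_total, replace = TRUE)
  ev <- vector("list", n_total)
  offset <- c(chr1 = 10000, chr2 = 10000, chr3 = 10000)
  for (i in seq_len(n_total)) {
    ch <- chroms[i]
    p1 <- offset[[ch]] + sample.int(1000, 1)
    if (types[i] == "BND") {
      ch2 <- "chr3"
      p2 <- offset[["chr3"]] + sample.int(1000, 1)
      offset[["chr3"]] <- p2 + gap
      strands <- c(sample(c("+", "-"), 1), sample(c("+", "-"), 1))
      len <- NA_real_
    } else {
      ch2 <- ch
      len <- round(stats::runif(1, 5000, 30000))
      p2 <- p1 + len
      strands <- switch(types[i], DEL = c("+", "-"), DUP = c("-", "+"),
                        INV = sample(list(c("+", "+"), c("-", "-")), 1)[[1]])
    }
    offset[[ch]] <- max(offset[[ch]], p2) + gap
    ev[[i]] <- list(truth_id = sprintf("truth_%03d", i), svtype = types[i],
                    chrom1 = ch, pos1 = p1, strand1 = strands[1],
                    chrom2 = ch2, pos2 = p2, strand2 = strands[2],
                    svlen = len)
  }
  shared <- rep(c(TRUE, FALSE), c(truth_n, n_total - truth_n))
  private_caller <- c(rep(NA_character_, truth_n),
                      rep(callers, each = n_private_per_caller))
  list(events = ev, shared = shared, private_caller = private_caller)
}

vcf_header_lines <- function(caller, contigs, extra_info = character()) {
  base_info <- c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=CIPOS,Number=2,Type=Integer,Description="CI around POS">',
    '##INFO=<ID=CIEND,Number=2,Type=Integer,Description="CI around END">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate id">')
  c("##fileformat=VCFv4.2",
    paste0("##source=", caller),
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    base_info, extra_info,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PR,Number=1,Type=Integer,Description="Paired-read support">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sample1"), collapse = "\t"))
}

# Emit one event in a caller's dialect; returns lines + the record id(s).
# Per-caller offsets are drawn within +/- jitter/2 so that any two
# callers' renderings of the same breakend differ by at most `jitter` bp
# (the merge threshold the files are designed for) while every position
# stays within `jitter` bp of truth.
emit_event_lines <- function(caller, ev, idx, jitter, ci) {
  half <- floor(jitter / 2)
  j1 <- if (half > 0) sample(seq(-half, half), 1) else 0
  j2 <- if (half > 0) sample(seq(-half, half), 1) else 0
  p1 <- ev$pos1 + j1
  p2 <- ev$pos2 + j2
  cistr <- sprintf("CIPOS=-%d,%d;CIEND=-%d,%d", ci, ci, ci, ci)
  cip <- sprintf("CIPOS=-%d,%d", ci, ci)
  qual <- round(stats::runif(1, 50, 999))
  fmt <- sprintf("GT:PR\t0/1:%d", sample.int(40, 1) + 4)
  id <- sprintf("%s_%d", caller, idx)
  intra <- ev$chrom1 == ev$chrom2
  svlen <- if (intra) p2 - p1 else NA
  if (caller == "delly" && ev$svtype == "BND") {
    ct <- if (ev$strand1 == "+" && ev$strand2 == "-") "3to5"
          else if (ev$strand1 == "-" && ev$strand2 == "+") "5to3"
          else if (ev$strand1 == "+") "3to3" else "5to5"
    line <- sprintf(
      "%s\t%d\t%s\tN\t<BND>\t%d\tPASS\tSVTYPE=BND;CHR2=%s;END=%d;CT=%s;%s\t%s",
      ev$chrom1, p1, id, qual, ev$chrom2, p2, ct, cistr, fmt)
    return(list(lines = line, ids = id, rep_id = id))
  }
  if (caller == "gridss" || ev$svtype == "BND") {
    id1 <- paste0(id, "o"); id2 <- paste0(id, "h")
    alt1 <- bracket_alt("N", ev$chrom2, p2, ev$strand1, ev$strand2)
    alt2 <- bracket_alt("N", ev$chrom1, p1, ev$strand2, ev$strand1)
    extra <- if (caller == "lumpy")
      sprintf(";STRANDS=%s%s:%d", ev$strand1, ev$strand2,
              sample.int(30, 1)) else ""
    sec <- if (caller == "lumpy") ";SECONDARY" else ""
    ev_tag <- if (caller == "gridss") sprintf(";EVENT=%s", id) else ""
    l1 <- sprintf("%s\t%d\t%s\tN\t%s\t%d\tPASS\tSVTYPE=BND;MATEID=%s;%s%s%s\t%s",
                  ev$chrom1, p1, id1, alt1, qual, id2, cip, extra, ev_tag, fmt)
    l2 <- sprintf("%s\t%d\t%s\tN\t%s\t%d\tPASS\tSVTYPE=BND;MATEID=%s;%s%s%s%s\t%s",
                  ev$chrom2, p2, id2, alt2, qual, id1, cip, extra, sec,
                  ev_tag, fmt)
    return(list(lines = c(l1, l2), ids = c(id1, id2), rep_id = id1))
  }
  if (caller == "manta") {
    svlen_field <- if (ev$svtype == "DEL") -svlen else svlen
    inv_flag <- if (ev$svtype == "INV") {
      if (ev$strand1 == "+") ";INV3" else ";INV5"
    } else ""
    line <- sprintf(
      "%s\t%d\t%s\tN\t<%s>\t%d\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d;%s%s\t%s",
      ev$chrom1, p1, id, ev$svtype, qual, ev$svtype, p2, svlen_field,
      cistr, inv_flag, fmt)
    return(list(lines = line, ids = id, rep_id = id))
  }
  if (caller == "delly") {
    ct <- if (ev$strand1 == "+" && ev$strand2 == "-") "3to5"
          else if (ev$strand1 == "-" && ev$strand2 == "+") "5to3"
          else if (ev$strand1 == "+") "3to3" else "5to5"
    line <- sprintf(
      "%s\t%d\t%s\tN\t<%s>\t%d\tPASS\tSVTYPE=%s;END=%d;CT=%s;%s\t%s",
      ev$chrom1, p1, id, ev$svtype, qual, ev$svtype, p2, ct, cistr, fmt)
    return(list(lines = line, ids = id, rep_id = id))
  }
  # lumpy symmetric records
  line <- sprintf(
    "%s\t%d\t%s\tN\t<%s>\t%d\tPASS\tSVTYPE=%s;END=%d;STRANDS=%s%s:%d;%s\t%s",
    ev$chrom1, p1, id, ev$svtype, qual, ev$svtype, p2, ev$strand1,
    ev$strand2, sample.int(30, 1), cistr, fmt)
  list(lines = line, ids = id, rep_id = id)
}

#' Simulate four-caller VCF files with a known truth clustering
#'
#' Draws `truth_n` shared SV events (mixed DEL/DUP/INV plus
#' interchromosomal breakends) and emits one VCF per caller in that
#' caller's dialect (Manta `SVTYPE/END` with `INV3`/`INV5`; Delly `CT`;
#' Lumpy `STRANDS` with `SECONDARY`-flagged BND mates; Gridss
#' breakend-only mate pairs). Each caller perturbs every shared
#' breakend position by an independent uniform offset in
#' `[-jitter, +jitter]` and reports confidence intervals of half-width
#' `jitter`, so the confidence intervals of shared breakends are
#' guaranteed to pairwise overlap. Each caller additionally receives
#' private events (default 20% of `truth_n`) to exercise support
#' filtering. Distinct truth events are placed far enough apart that no
#' cross-event link can form at the simulated jitter.
#'
#' @param truth_n number of shared truth events (>= 1).
#' @param jitter maximum per-caller breakend error in bp (>= 0).
#' @param seed integer seed.
#' @param out_dir output directory for `<caller>.vcf` files and
#'   `truth.tsv`.
#' @param private_frac fraction of `truth_n` emitted as caller-private
#'   events per caller.
#' @return list with `paths` (named VCF paths), `truth_path`, and `truth`
#'   (tibble `caller, record_id, truth_id, shared` mapping every emitted
#'   record to its truth event).
#' @export
simulate_caller_vcfs <- function(truth_n = 50, jitter = 100, seed = 1,
                                 out_dir = tempfile("svsim"),
                                 private_frac = 0.2) {
  if (truth_n < 1) stop_tidysv("truth_n must be >= 1")
  if (jitter < 0) stop_tidysv("jitter must be >= 0")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_tidysv("cannot create ", out_dir)
  callers <- c("manta", "delly", "lumpy", "gridss")
  n_private <- round(truth_n * private_frac)
  ci <- max(jitter, 1)
  with_seed(seed, {
    sim <- simulate_truth_events(truth_n, n_private, jitter, callers)
    contigs <- c(chr1 = 6e6, chr2 = 6e6, chr3 = 6e6)
    truth <- list()
    paths <- character()
    extra_info <- c(
      '##INFO=<ID=CT,Number=1,Type=String,Description="Junction orientation">',
      '##INFO=<ID=CHR2,Number=1,Type=String,Description="Mate chromosome">',
      '##INFO=<ID=STRANDS,Number=.,Type=String,Description="Strand counts">',
      '##INFO=<ID=INV3,Number=0,Type=Flag,Description="3p inversion">',
      '##INFO=<ID=INV5,Number=0,Type=Flag,Description="5p inversion">',
      '##INFO=<ID=SECONDARY,Number=0,Type=Flag,Description="Secondary breakend">',
      '##INFO=<ID=EVENT,Number=1,Type=String,Description="Event id">')
    for (cl in callers) {
      lines <- vcf_header_lines(cl, contigs, extra_info)
      idx <- 0
      for (i in seq_along(sim$events)) {
        take <- sim$shared[i] ||
          identical(sim$private_caller[i], cl)
        if (!take) next
        idx <- idx + 1
        out <- emit_event_lines(cl, sim$events[[i]], idx, jitter, ci)
        lines <- c(lines, out$lines)
        truth[[length(truth) + 1]] <- tibble::tibble(
          caller = cl, record_id = out$ids,
          truth_id = sim$events[[i]]$truth_id, shared = sim$shared[i])
      }
      p <- file.path(out_dir, paste0(cl, ".vcf"))
      writeLines(lines, p)
      paths[cl] <- p
    }
    truth <- dplyr::bind_rows(truth)
    truth_path <- file.path(out_dir, "truth.tsv")
    readr::write_tsv(truth, truth_path)
    list(paths = paths, truth_path = truth_path, truth = truth)
  })
}

#' Deterministic block-structured true signatures
#'
#' Column-stochastic classes x k matrix splitting the classes into k
#' contiguous blocks with uniform weight inside each block; used as the
#' known truth for signature-recovery simulations.
#'
#' @param n_classes number of SV classes (rows).
#' @param k number of signatures.
#' @return classes x k column-stochastic matrix.
#' @export
toy_signatures <- function(n_classes = 25, k = 3) {
  stopifnot(k >= 1, n_classes >= k)
  S <- base::matrix(0, n_classes, k)
  bounds <- round(seq(0, n_classes, length.out = k + 1))
  for (j in seq_len(k)) {
    rows <- (bounds[j] + 1):bounds[j + 1]
    S[rows, j] <- 1 / length(rows)
  }
  colnames(S) <- paste0("true", seq_len(k))
  rownames(S) <- paste0("class", seq_len(n_classes))
  S
}

#' Simulate a per-sample SV count matrix from known signatures
#'
#' Per-sample exposures are drawn from a gamma distribution
#' (shape 2, mean `exposure_scale` per signature) and counts from
#' Poisson around `signatures %*% exposures`.
#'
#' @param n_samples number of samples.
#' @param true_signatures column-stochastic classes x k matrix (e.g.
#'   [toy_signatures()]).
#' @param exposure_scale mean exposure per signature and sample (>= 0).
#' @param seed integer seed.
#' @return list with `matrix` (a `FeatureMatrix`), `exposures` (k x
#'   samples truth) and `signatures` (the input truth).
#' @export
simulate_signature_matrix <- function(n_samples, true_signatures,
                                      exposure_scale = 50, seed = 7) {
  S <- as.matrix(true_signatures)
  if (any(S < 0) || any(abs(colSums(S) - 1) > 1e-8))
    stop_tidysv("true_signatures must be column-stochastic")
  if (exposure_scale < 0) stop_tidysv("exposure_scale must be >= 0")
  k <- ncol(S)
  with_seed(seed, {
    E <- base::matrix(stats::rgamma(k * n_samples, shape = 2,
                                    scale = exposure_scale / 2),
                      nrow = k)
    lambda <- S %*% E
    counts <- base::matrix(stats::rpois(length(lambda),
                                        lambda = as.numeric(lambda)),
                           nrow = nrow(S))
    samples <- sprintf("sample%03d", seq_len(n_samples))
    values <- t(counts)
    dimnames(values) <- list(samples,
                             rownames(S) %||%
                               paste0("class", seq_len(nrow(S))))
    colnames(E) <- samples
    rownames(E) <- colnames(S) %||% paste0("true", seq_len(k))
    fm <- structure(list(values = values, sample_order = samples,
                         class_order = colnames(values)),
                    class = "FeatureMatrix")
    list(matrix = fm, exposures = E, signatures = S)
  })
}
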