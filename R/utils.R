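#' @importFrom stats p.adjust rgamma rpois runif setNames wilcox.test
#' @importFrom utils head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse-complement of a DNA string
#'
#' Plain-character helper used by the breakend-frame transformations in
#' microhomology inference. IUPAC ambiguity codes other than N are not
#' handled; case is preserved.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps generators deterministic without
# clobbering user code.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Order keys by (chrom, pos) with plain string comparison on chrom. Returns
# TRUE where (chrom_a, pos_a) <= (chrom_b, pos_b).
chrompos_leq <- function(chrom_a, pos_a, chrom_b, pos_b) {
  ifelse(chrom_a == chrom_b, pos_a <= pos_b, chrom_a < chrom_b)
}

stop_tidysv <- function(...) stop(..., call. = FALSE)
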