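#' Define an ordered SV classification
#'
#' A classification is an ordered list of `(class_name, predicate)` rules;
#' predicates are conjunctions of filter conditions over `svtype`,
#' `svlen`, `qual` or any INFO key (see [filter_by_info()] for the
#' grammar). Evaluation is first-match-wins and every SV receives exactly
#' one class: records matching no rule get `fallback_name`.
#'
#' `preparers` is an optional list of functions `container -> container`
#' run before rule evaluation (typically BED annotation and derived-flag
#' construction), so a definition can carry the annotations it depends
#' on.
#'
#' @param rules named list: class name -> character vector of conditions.
#' @param fallback_name class for unmatched records (default `"others"`).
#' @param preparers list of functions applied to the container before
#'   evaluation.
#' @return a `ClassDefinition`.
#' @export
class_definition <- function(rules, fallback_name = "others",
                             preparers = list()) {
  if (is.null(names(rules)) || any(names(rules) == ""))
    stop_tidysv("rules must be a named list of condition vectors")
  if (anyDuplicated(c(names(rules), fallback_name)))
    stop_tidysv("class names must be unique")
  structure(list(rules = rules, fallback_name = fallback_name,
                 preparers = preparers), class = "ClassDefinition")
}

#' @export
print.ClassDefinition <- function(x, ...) {
  cat("ClassDefinition with", length(x$rules), "rule(s) + fallback '",
      x$fallback_name, "'\n", sep = "")
  invisible(x)
}

#' Class names of a definition, in evaluation order (fallback last)
#' @param definition a `ClassDefinition`.
#' @return character vector of class names.
#' @export
class_names <- function(definition) {
  c(names(definition$rules), definition$fallback_name)
}

run_preparers <- function(container, definition) {
  for (prep in definition$preparers) container <- prep(container)
  container
}

#' Classify every SV in a container
#'
#' Runs the definition's preparers, evaluates the rules first-match-wins
#' and stores the resulting class of each record as a new INFO table
#' `manual_sv_type`, so classes survive export to VCF/BEDPE.
#'
#' @param container an `SVContainer`.
#' @param definition a [class_definition()].
#' @return a new `SVContainer` with the `manual_sv_type` INFO table.
#' @export
classify <- function(container, definition) {
  stopifnot(inherits(container, "SVContainer"),
            inherits(definition, "ClassDefinition"))
  container <- run_preparers(container, definition)
  labels <- setNames(rep(definition$fallback_name, n_records(container)),
                     sv_ids(container))
  unassigned <- sv_ids(container)
  for (nm in names(definition$rules)) {
    hit <- sv_ids(container)
    for (cond in definition$rules[[nm]]) {
      hit <- tryCatch(
        intersect(hit, condition_ids(container, cond)),
        error = function(e)
          stop_tidysv("rule '", nm, "': ", conditionMessage(e),
                      " (annotate the container first?)"))
    }
    take <- intersect(unassigned, hit)
    labels[take] <- nm
    unassigned <- setdiff(unassigned, take)
  }
  add_info(container, "manual_sv_type", as.list(labels), overwrite = TRUE,
           description = "User-defined SV class")
}

#' Per-sample SV class count matrix
#'
#' Classifies every member container and counts `manual_sv_type` per
#' sample. Column order is rule order plus the fallback class; classes
#' absent in a sample count 0, so the schema depends only on the
#' definition.
#'
#' @param multi a `MultiSVContainer` (labels = sample ids) or a named
#'   list of `SVContainer` objects.
#' @param definition a [class_definition()].
#' @return a `FeatureMatrix`: list with `values` (samples x classes
#'   integer matrix), `sample_order`, `class_order`.
#' @export
feature_matrix <- function(multi, definition) {
  if (inherits(multi, "MultiSVContainer")) multi <- multi$members
  if (length(multi) == 0) stop_tidysv("feature_matrix: no samples")
  if (is.null(names(multi)) || any(names(multi) == ""))
    stop_tidysv("feature_matrix: members must be named by sample id")
  classes <- class_names(definition)
  values <- matrix(0L, nrow = length(multi), ncol = length(classes),
                   dimnames = list(names(multi), classes))
  for (smp in names(multi)) {
    cls <- classify(multi[[smp]], definition)
    lab <- cls$info$manual_sv_type$value
    tab <- table(factor(lab, levels = classes))
    values[smp, ] <- as.integer(tab)
  }
  structure(list(values = values, sample_order = names(multi),
                 class_order = classes), class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat("FeatureMatrix:", nrow(x$values), "sample(s) x", ncol(x$values),
      "class(es); total", sum(x$values), "SV(s)\n")
  invisible(x)
}

#' Write a feature matrix as TSV (samples as rows)
#' @param fm a `FeatureMatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- tibble::as_tibble(fm$values, rownames = "sample")
  readr::write_tsv(df, path)
  invisible(path)
}

# Derived INFO keys used by the default definitions: an effective SV type
# (resolving intrachromosomal breakend-only records by strand pattern and
# interchromosomal ones to TRA) and, for the PCAWG-style scheme, a CFS
# flag and a replication-timing class at the first breakend.
prepare_evtype <- function(container) {
  pos <- container$positions
  ev <- pos$svtype
  interchrom <- !is.na(pos$chrom2) & pos$chrom2 != pos$chrom1
  ev[ev == "BND" & interchrom] <- "TRA"
  intra_bnd <- ev == "BND" & !is.na(pos$chrom2) & !interchrom
  for (i in which(intra_bnd))
    ev[i] <- svtype_from_strands(pos$strand1[i], pos$strand2[i])
  ev[ev == "BND" & interchrom] <- "TRA"
  add_info(container, "evtype", setNames(as.list(ev), pos$id),
           overwrite = TRUE, description = "Effective SV type")
}

prepare_cfs <- function(cfs_index) {
  function(container) {
    if (!all(c("cfs1", "cfs2") %in% names(container$info)))
      container <- annotate_bed(container, cfs_index, "cfs",
                                mode = "presence", overwrite = TRUE)
    f1 <- info_first_value(container, "cfs1", FALSE)
    f2 <- info_first_value(container, "cfs2", FALSE)
    vals <- setNames(as.list(isTRUE_vec(f1) | isTRUE_vec(f2)),
                     sv_ids(container))
    add_info(container, "cfs_site", vals, overwrite = TRUE,
             description = "Either breakend on a common fragile site")
  }
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

prepare_timing <- function(timing_index) {
  function(container) {
    if (!all(c("timing1", "timing2") %in% names(container$info)))
      container <- annotate_bed(container, timing_index, "timing",
                                mode = "value", overwrite = TRUE)
    tab <- container$info$timing1
    per_id <- split(tolower(tab$value), tab$id)
    cls <- vapply(sv_ids(container), function(id) {
      v <- unique(per_id[[id]] %||% character())
      if (length(v) == 1 && v %in% c("early", "late")) v else "unknown"
    }, character(1))
    add_info(container, "timing_class", as.list(cls), overwrite = TRUE,
             description = "Replication timing at breakend 1")
  }
}

#' Built-in SV classification schemes
#'
#' Two ready-made classifications:
#'
#' * `simple`: translocation plus \{DEL, DUP, INV\} x five length bins
#'   (<1 kb, 1-10 kb, 10-100 kb, 100 kb-1 Mb, >=1 Mb) - 16 named rules;
#'   with the fallback class the feature-matrix schema has 17 columns.
#' * `pcawg_like`: a 25-class scheme over the three axes common fragile
#'   sites, replication timing and SV length: one CFS class (either
#'   breakend on a CFS), \{DEL, DUP, INV\} x \{early, late\} x
#'   \{<50 kb, 50-500 kb, >=500 kb\} (18), \{DEL, DUP, INV\} with unknown
#'   timing (3), translocation, insertion, and the fallback `others` -
#'   25 classes in total. Timing is classed by the first breakend's
#'   annotation value; absent or conflicting values give `unknown`.
#'
#' @param scheme `"simple"` or `"pcawg_like"`.
#' @param cfs_index `IntervalIndex` of common-fragile-site regions
#'   (required for `pcawg_like`).
#' @param timing_index `IntervalIndex` of replication-timing zones whose
#'   `name` payload is `early`/`late` (required for `pcawg_like`).
#' @return a [class_definition()].
#' @export
get_default_definitions <- function(scheme = c("simple", "pcawg_like"),
                                    cfs_index = NULL, timing_index = NULL) {
  scheme <- match.arg(scheme)
  bins5 <- list("<1kb" = c(0, 1e3), "1kb-10kb" = c(1e3, 1e4),
                "10kb-100kb" = c(1e4, 1e5), "100kb-1Mb" = c(1e5, 1e6),
                ">1Mb" = c(1e6, Inf))
  len_conds <- function(lo, hi) {
    c(sprintf("svlen >= %s", format(lo, scientific = FALSE)),
      if (is.finite(hi)) sprintf("svlen < %s", format(hi, scientific = FALSE)))
  }
  if (scheme == "simple") {
    rules <- list(translocation = "evtype == TRA")
    for (t in c("DEL", "DUP", "INV"))
      for (bn in names(bins5))
        rules[[paste0(t, "_", bn)]] <-
          c(sprintf("evtype == %s", t),
            len_conds(bins5[[bn]][1], bins5[[bn]][2]))
    return(class_definition(rules, preparers = list(prepare_evtype)))
  }
  if (is.null(cfs_index) || is.null(timing_index))
    stop_tidysv("pcawg_like requires both cfs_index and timing_index")
  bins3 <- list("<50kb" = c(0, 5e4), "50kb-500kb" = c(5e4, 5e5),
                ">500kb" = c(5e5, Inf))
  rules <- list(CFS = "cfs_site == TRUE")
  for (t in c("DEL", "DUP", "INV"))
    for (tm in c("early", "late"))
      for (bn in names(bins3))
        rules[[paste0(t, "_", tm, "_", bn)]] <-
          c(sprintf("evtype == %s", t), sprintf("timing_class == %s", tm),
            len_conds(bins3[[bn]][1], bins3[[bn]][2]))
  for (t in c("DEL", "DUP", "INV"))
    rules[[paste0(t, "_timing_unknown")]] <-
      c(sprintf("evtype == %s", t), "timing_class == unknown")
  rules$translocation <- "evtype == TRA"
  rules$insertion <- "evtype == INS"
  class_definition(rules, preparers = list(
    prepare_evtype, prepare_cfs(cfs_index), prepare_timing(timing_index)))
}
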