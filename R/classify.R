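# Functional classification: the non-synonymous exonic mutation universe and
# per-sample count decomposition.

NONSYN_FUNCTIONS <- c("nonsynonymous_SNV", "stopgain", "stoploss")

#' Is a call a non-synonymous exonic mutation?
#'
#' The mutation universe used by every downstream pre/post comparison:
#' exonic calls whose functional class is nonsynonymous SNV, stopgain or
#' stoploss. Synonymous SNVs, indels and non-exonic calls are excluded
#' (indels can be pulled into *position-based* comparisons via the
#' `include_indels` switch of the overlap functions, but never into the
#' non-synonymous SNV counts).
#'
#' @param variants a variant table (or any data.frame with `region_class`
#'   and `exonic_function` columns).
#' @return logical vector; absent exonic function yields FALSE.
#' @export
is_nonsynonymous <- function(variants) {
  out <- variants$region_class == "exonic" &
    !is.na(variants$exonic_function) &
    variants$exonic_function %in% NONSYN_FUNCTIONS
  out[is.na(out)] <- FALSE
  out
}

#' Per-sample somatic mutation count summary
#'
#' Decomposes one sample's calls into the count categories used in
#' whole-exome reporting: total somatic mutations, exonic mutations,
#' synonymous SNVs, non-synonymous SNVs, stopgain/stoploss, plus the derived
#' non-synonymous total and the number of distinct genes with at least one
#' non-synonymous mutation. Totals count distinct normalized variant keys
#' (multi-allelic splitting can make this exceed the VCF line count;
#' multi-gene expansion rows are deduplicated by key). Duplicate keys within
#' a sample are collapsed with a warning.
#'
#' @param variants variant table rows belonging to one sample.
#' @param sample_id optional check: error if the table's sample differs.
#' @return one-row data.frame: `sample_id`, `total_somatic`, `exonic`,
#'   `synonymous_snv`, `nonsynonymous_snv`, `stop_gain_loss`, `indel`,
#'   `other_exonic`, `nonsyn_total`, `nonsyn_gene_count`.
#' @export
summarize_counts <- function(variants, sample_id = NULL) {
  sid <- unique(variants$sample_id)
  if (length(sid) > 1L)
    stopf("summarize_counts: variants from multiple samples (%s)",
          paste(sid, collapse = ", "))
  if (is.null(sample_id)) sample_id <- if (length(sid)) sid else NA_character_
  else if (length(sid) && !identical(sid, sample_id))
    stopf("summarize_counts: sample_id mismatch ('%s' vs '%s')",
          sid, sample_id)

  key <- variant_key(variants)
  # multi-gene expansion legitimately duplicates keys; collapse to one row
  # per key for counting, warn only on true duplicates
  first <- !duplicated(key)
  dup_real <- duplicated(key) &
    !(variants$multi_gene %||% rep(FALSE, nrow(variants)))
  if (any(dup_real))
    warnf("summarize_counts: %d duplicate variant key(s) in sample %s collapsed",
          sum(dup_real), sample_id)
  v <- variants[first, , drop = FALSE]

  exonic <- v$region_class == "exonic"
  fn <- v$exonic_function
  syn <- sum(exonic & fn %in% "synonymous_SNV", na.rm = TRUE)
  nonsyn <- sum(exonic & fn %in% "nonsynonymous_SNV", na.rm = TRUE)
  stp <- sum(exonic & fn %in% c("stopgain", "stoploss"), na.rm = TRUE)
  ind <- sum(exonic & fn %in% c("frameshift_indel", "nonframeshift_indel"),
             na.rm = TRUE)
  oth <- sum(exonic, na.rm = TRUE) - syn - nonsyn - stp - ind

  ns_genes <- unique(trimws(
    variants$gene[is_nonsynonymous(variants)]))

  data.frame(
    sample_id = sample_id,
    total_somatic = nrow(v),
    exonic = sum(exonic, na.rm = TRUE),
    synonymous_snv = syn,
    nonsynonymous_snv = nonsyn,
    stop_gain_loss = stp,
    indel = ind,
    other_exonic = oth,
    nonsyn_total = nonsyn + stp,
    nonsyn_gene_count = length(ns_genes),
    stringsAsFactors = FALSE)
}

#' Count summaries for every sample of a cohort
#'
#' @param variants variant table with one or more samples.
#' @param samples optional `sample_table`; when given, rows come out in
#'   manifest order and samples with zero calls get an all-zero row.
#' @return data.frame, one [summarize_counts()] row per sample.
#' @export
summarize_cohort_counts <- function(variants, samples = NULL) {
  ids <- if (is.null(samples)) sort(unique(variants$sample_id))
         else samples$sample_id
  rows <- lapply(ids, function(s)
    summarize_counts(variants[variants$sample_id == s, , drop = FALSE],
                     sample_id = s))
  do.call(rbind, rows)
}

#' Check the count-decomposition invariants of a summary table
#'
#' Conservation of counts: exonic categories sum to the exonic total, the
#' non-synonymous total is nonsynonymous SNV + stopgain/stoploss, the
#' distinct-gene count never exceeds it, and exonic <= total.
#'
#' @param summary a data.frame of [summarize_counts()] rows (the column
#'   `indel`/`other_exonic` may be absent, in which case they default to 0).
#' @return TRUE invisibly; errors on the first violated invariant.
#' @export
check_count_invariants <- function(summary) {
  ind <- summary$indel %||% rep(0L, nrow(summary))
  oth <- summary$other_exonic %||% rep(0L, nrow(summary))
  ok1 <- summary$exonic ==
    summary$synonymous_snv + summary$nonsynonymous_snv +
    summary$stop_gain_loss + ind + oth
  if (!all(ok1))
    stopf("count invariant violated (exonic decomposition) for sample(s): %s",
          paste(summary$sample_id[!ok1], collapse = ", "))
  ok2 <- summary$nonsyn_total ==
    summary$nonsynonymous_snv + summary$stop_gain_loss
  if (!all(ok2))
    stopf("count invariant violated (nonsyn_total) for sample(s): %s",
          paste(summary$sample_id[!ok2], collapse = ", "))
  if (!is.null(summary$nonsyn_gene_count)) {
    ok3 <- summary$nonsyn_gene_count <= summary$nonsyn_total
    if (!all(ok3))
      stopf("count invariant violated (gene count > nonsyn total): %s",
            paste(summary$sample_id[!ok3], collapse = ", "))
  }
  ok4 <- summary$exonic <= summary$total_somatic
  if (!all(ok4))
    stopf("count invariant violated (exonic > total) for sample(s): %s",
          paste(summary$sample_id[!ok4], collapse = ", "))
  invisible(TRUE)
}
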