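# Pre/post overlap within a case: shared fractions (position- and
# gene-based) and per-gene stable/emergent/lost status.

#' Integer percent, rounded half-up
#'
#' @param shared numerator (count).
#' @param total denominator (count, must be > 0).
#' @return integer percent `round_half_up(100 * shared / total)`.
#' @examples
#' round_pct(27, 40)   # 68 (the 67.5 tie rounds up)
#' round_pct(6, 831)   # 1
#' @export
round_pct <- function(shared, total) {
  if (any(total == 0))
    stopf("round_pct: undefined percentage (total = 0)")
  if (any(shared < 0 | shared > total))
    stopf("round_pct: shared must be within [0, total]")
  as.integer(round_half_up(100 * shared / total))
}

# distinct comparison units of one sample's non-synonymous calls
overlap_units <- function(variants, basis, position_only = FALSE,
                          include_indels = FALSE) {
  keep <- is_nonsynonymous(variants)
  if (include_indels && basis == "position")
    keep <- keep | (variants$region_class %in% "exonic" &
                      variants$exonic_function %in%
                        c("frameshift_indel", "nonframeshift_indel"))
  v <- variants[keep, , drop = FALSE]
  if (basis == "position") unique(variant_key(v, position_only))
  else unique(trimws(v$gene))
}

#' Shared fraction between a focal sample and other samples of its case
#'
#' The denominator is the focal sample's non-synonymous mutation count
#' (`basis = "position"`, distinct normalized keys) or its distinct mutated
#' gene count (`basis = "gene"`); the numerator is how many of those units
#' are present in at least one of the other samples under the same basis.
#' This is deliberately asymmetric: in a paired pre/post design the pre
#' sample is compared against the union of all post samples, while each post
#' sample is compared against the pre sample alone (see
#' [case_shared_fractions()]).
#'
#' @param focal variant table of the focal sample (single sample).
#' @param others variant table of one or more comparison samples from the
#'   same case; must be non-empty and not contain the focal sample.
#' @param basis `"position"` or `"gene"`.
#' @param position_only match positions as chrom:pos only instead of the
#'   full chrom:pos:ref:alt key.
#' @param include_indels also count exonic indels in position-based
#'   comparisons (they are never part of the non-synonymous SNV universe).
#' @return one-row data.frame: `sample_id`, `basis`, `shared`, `total`,
#'   `pct` (NA with a warning when the denominator is 0).
#' @export
shared_fraction <- function(focal, others,
                            basis = c("position", "gene"),
                            position_only = FALSE, include_indels = FALSE) {
  basis <- match.arg(basis)
  fid <- unique(focal$sample_id)
  if (length(fid) != 1L)
    stopf("shared_fraction: focal must contain exactly one sample")
  oid <- unique(others$sample_id)
  if (length(oid) == 0L || nrow(others) == 0L)
    stopf("shared_fraction: comparison sample set is empty")
  if (fid %in% oid)
    stopf("shared_fraction: focal sample '%s' present in comparison set", fid)
  fu <- overlap_units(focal, basis, position_only, include_indels)
  ou <- overlap_units(others, basis, position_only, include_indels)
  total <- length(fu)
  shared <- sum(fu %in% ou)
  if (total == 0L) {
    warnf("shared_fraction: sample %s has no units on basis '%s'; pct undefined",
          fid, basis)
    pct <- NA_integer_
  } else pct <- round_pct(shared, total)
  data.frame(sample_id = fid, basis = basis, shared = shared, total = total,
             pct = pct, stringsAsFactors = FALSE)
}

#' Shared pre/post fractions for every sample of a cohort
#'
#' For each case with at least one pre and one post sample: the pre sample's
#' mutations are compared against the union of the case's post samples
#' ("shared with at least one post sample"), and each post sample is
#' compared against the pre sample. Both bases are reported.
#'
#' @param variants cohort variant table.
#' @param samples `sample_table` for the cohort.
#' @inheritParams shared_fraction
#' @return data.frame with one row per (sample, basis), columns of
#'   [shared_fraction()] plus `case_id` and `timepoint`.
#' @export
case_shared_fractions <- function(variants, samples,
                                  position_only = FALSE,
                                  include_indels = FALSE) {
  out <- list()
  for (cid in unique(samples$case_id)) {
    ss <- samples[samples$case_id == cid, , drop = FALSE]
    pre_ids <- ss$sample_id[ss$timepoint == "pre"]
    post_ids <- ss$sample_id[ss$timepoint == "post"]
    if (length(pre_ids) == 0L || length(post_ids) == 0L)
      stopf("case %s lacks a %s sample", cid,
            if (length(pre_ids) == 0L) "pre" else "post")
    for (basis in c("position", "gene")) {
      for (p in pre_ids) {
        r <- shared_fraction(
          variants[variants$sample_id == p, , drop = FALSE],
          variants[variants$sample_id %in% post_ids, , drop = FALSE],
          basis, position_only, include_indels)
        r$case_id <- cid; r$timepoint <- "pre"
        out[[length(out) + 1L]] <- r
      }
      for (q in post_ids) {
        r <- shared_fraction(
          variants[variants$sample_id == q, , drop = FALSE],
          variants[variants$sample_id %in% pre_ids, , drop = FALSE],
          basis, position_only, include_indels)
        r$case_id <- cid; r$timepoint <- "post"
        out[[length(out) + 1L]] <- r
      }
    }
  }
  do.call(rbind, out)
}

#' Stable / emergent / lost gene status within a case
#'
#' Partition of a case's non-synonymous gene universe by timepoint presence
#' under union-over-samples semantics: *stable* genes are mutated in the pre
#' sample and in at least one post sample, *emergent* genes only post,
#' *lost* genes only pre.
#'
#' @param pre_genes character vector (or list of vectors, unioned) of genes
#'   mutated at the pre timepoint.
#' @param post_gene_sets list of character vectors, one per post sample (a
#'   single vector is accepted); must be non-empty.
#' @param case_id label carried into the output.
#' @return data.frame with class `gene_status`: `case_id`, `gene`, `status`,
#'   and `supporting_samples` (comma-separated post sample names when
#'   `post_gene_sets` is named).
#' @export
gene_status <- function(pre_genes, post_gene_sets, case_id = NA_character_) {
  if (is.list(pre_genes)) pre_genes <- unique(unlist(pre_genes))
  if (!is.list(post_gene_sets)) post_gene_sets <- list(post_gene_sets)
  if (length(post_gene_sets) == 0L)
    stopf("gene_status: case %s has no post-treatment gene sets", case_id)
  pre <- unique(trimws(pre_genes))
  post_union <- unique(trimws(unlist(post_gene_sets)))
  genes <- sort(union(pre, post_union))
  status <- ifelse(genes %in% pre & genes %in% post_union, "stable",
                   ifelse(genes %in% post_union, "emergent", "lost"))
  supp <- vapply(genes, function(g) {
    hit <- vapply(post_gene_sets, function(s) g %in% s, logical(1))
    nm <- names(post_gene_sets) %||% as.character(seq_along(post_gene_sets))
    paste(nm[hit], collapse = ",")
  }, character(1))
  out <- data.frame(case_id = rep(case_id, length(genes)), gene = genes,
                    status = as.character(status),
                    supporting_samples = unname(supp),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_status", "data.frame")
  out
}

#' Gene status for every case of a cohort variant table
#'
#' @param variants cohort variant table (non-synonymous filtering is applied
#'   internally).
#' @param samples `sample_table`; every case needs >= 1 pre and >= 1 post
#'   sample.
#' @return row-bound [gene_status()] tables for all cases.
#' @export
gene_status_cohort <- function(variants, samples) {
  out <- list()
  for (cid in unique(samples$case_id)) {
    ss <- samples[samples$case_id == cid, , drop = FALSE]
    pre_ids <- ss$sample_id[ss$timepoint == "pre"]
    post_ids <- ss$sample_id[ss$timepoint == "post"]
    if (length(pre_ids) == 0L || length(post_ids) == 0L)
      stopf("case %s lacks a %s sample", cid,
            if (length(pre_ids) == 0L) "pre" else "post")
    pre_genes <- unlist(lapply(pre_ids, function(s)
      overlap_units(variants[variants$sample_id == s, , drop = FALSE],
                    "gene")))
    post_sets <- lapply(post_ids, function(s)
      overlap_units(variants[variants$sample_id == s, , drop = FALSE],
                    "gene"))
    names(post_sets) <- post_ids
    out[[length(out) + 1L]] <- gene_status(pre_genes, post_sets, cid)
  }
  do.call(rbind, out)
}

#' Emergent-gene fraction of a case
#'
#' Share of the post-treatment gene universe that is emergent (mutated post
#' but not pre), as an integer percent.
#'
#' @param status a [gene_status()] table for one case.
#' @return one-row data.frame: `case_id`, `emergent`, `post_universe`, `pct`.
#' @export
emergent_fraction <- function(status) {
  cid <- unique(status$case_id)
  if (length(cid) != 1L)
    stopf("emergent_fraction expects a single case")
  emergent <- sum(status$status == "emergent")
  post_universe <- sum(status$status %in% c("stable", "emergent"))
  data.frame(case_id = cid, emergent = emergent,
             post_universe = post_universe,
             pct = round_pct(emergent, post_universe),
             stringsAsFactors = FALSE)
}
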