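# Cross-case recurrence: presence matrices, resistant/sensitive exclusivity,
# recurrently mutated genes, and within-case multi-site Venn partitions.

PRESENCE_STRATA <- c("any", "pre_only", "post_only",
                     "stable_within_case", "emergent_within_case")

#' Long-format case/timepoint gene presence from a variant table
#'
#' One row per (gene, case, timepoint) where the case has at least one
#' non-synonymous mutation in that gene at that timepoint (union over the
#' case's samples at the timepoint).
#'
#' @param variants cohort variant table.
#' @param samples `sample_table`.
#' @return data.frame with columns `gene`, `case_id`, `timepoint`.
#' @export
presence_long <- function(variants, samples) {
  v <- variants[is_nonsynonymous(variants), , drop = FALSE]
  idx <- match(v$sample_id, samples$sample_id)
  if (anyNA(idx))
    stopf("presence_long: variant sample(s) missing from sample table: %s",
          paste(unique(v$sample_id[is.na(idx)]), collapse = ", "))
  out <- unique(data.frame(gene = trimws(v$gene),
                           case_id = samples$case_id[idx],
                           timepoint = samples$timepoint[idx],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Gene-by-case presence matrix under a stratum
#'
#' Builds the boolean gene x case matrix used for recurrence and exclusivity
#' classification. The stratum is applied *within* each case before
#' aggregating to case level:
#' \describe{
#'   \item{any}{mutated at either timepoint}
#'   \item{pre_only}{mutated in the case's pre-treatment sample(s)}
#'   \item{post_only}{mutated in >= 1 post-treatment sample}
#'   \item{stable_within_case}{mutated pre and in >= 1 post sample}
#'   \item{emergent_within_case}{mutated post but not pre}
#' }
#'
#' @param x either a long presence table (columns `gene`, `case_id`,
#'   `timepoint`, see [presence_long()]) or a cohort variant table (in which
#'   case `samples` is required).
#' @param stratum one of `"any"`, `"pre_only"`, `"post_only"`,
#'   `"stable_within_case"`, `"emergent_within_case"`.
#' @param samples `sample_table`, required when `x` is a variant table.
#' @return logical matrix, genes (sorted) x cases (sorted).
#' @export
build_presence <- function(x, stratum = "any", samples = NULL) {
  if (!stratum %in% PRESENCE_STRATA)
    stopf("unknown stratum '%s' (expected one of: %s)", stratum,
          paste(PRESENCE_STRATA, collapse = ", "))
  if (all(c("chrom", "pos") %in% names(x))) {
    if (is.null(samples))
      stopf("build_presence: samples table required for variant input")
    x <- presence_long(x, samples)
  }
  require_columns(x, c("gene", "case_id", "timepoint"), "presence table")
  genes <- sort(unique(x$gene))
  cases <- sort(unique(x$case_id))
  pre <- matrix(FALSE, length(genes), length(cases),
                dimnames = list(genes, cases))
  post <- pre
  xp <- x[x$timepoint == "pre", , drop = FALSE]
  xq <- x[x$timepoint == "post", , drop = FALSE]
  pre[cbind(match(xp$gene, genes), match(xp$case_id, cases))] <- TRUE
  post[cbind(match(xq$gene, genes), match(xq$case_id, cases))] <- TRUE
  mat <- switch(stratum,
    any = pre | post,
    pre_only = pre,
    post_only = post,
    stable_within_case = pre & post,
    emergent_within_case = post & !pre)
  # drop genes absent everywhere under this stratum
  mat[rowSums(mat) > 0L, , drop = FALSE]
}

#' Resistant/sensitive exclusivity sets
#'
#' Classifies genes exclusively mutated in the platinum-resistant or the
#' platinum-sensitive group. A gene is *resistant-exclusive* when present in
#' at least `min_resistant` resistant cases and no sensitive case, and
#' *sensitive-exclusive* when present in **all** sensitive cases and no
#' resistant case (with two sensitive cases this is "both"; the
#' generalization to larger groups is "all").
#'
#' @param mat logical presence matrix (genes x cases), see [build_presence()].
#' @param groups named character vector mapping every case (column) to
#'   `"resistant"` or `"sensitive"`.
#' @param min_resistant minimum resistant case count (default 2, i.e.
#'   "more than one case").
#' @return list with `resistant_exclusive` and `sensitive_exclusive`
#'   (sorted gene vectors, always disjoint) and `recurrent_any` (named
#'   integer, case count per gene mutated in >= 2 cases, count-descending
#'   then lexicographic).
#' @export
exclusivity <- function(mat, groups, min_resistant = 2) {
  if (!all(colnames(mat) %in% names(groups)))
    stopf("exclusivity: case(s) missing a group label: %s",
          paste(setdiff(colnames(mat), names(groups)), collapse = ", "))
  grp <- groups[colnames(mat)]
  if (!all(grp %in% PLATINUM_LEVELS))
    stopf("exclusivity: group labels must be 'resistant' or 'sensitive'")
  if (length(unique(grp)) < 2L)
    stopf("exclusivity: cohort contains a single group; both groups required")
  r <- mat[, grp == "resistant", drop = FALSE]
  s <- mat[, grp == "sensitive", drop = FALSE]
  res_excl <- rowSums(r) >= min_resistant & rowSums(s) == 0L
  sen_excl <- rowSums(s) == ncol(s) & rowSums(r) == 0L
  counts <- rowSums(mat)
  rec <- counts[counts >= 2L]
  rec <- rec[order(-rec, names(rec))]
  list(resistant_exclusive = sort(rownames(mat)[res_excl]),
       sensitive_exclusive = sort(rownames(mat)[sen_excl]),
       recurrent_any = stats::setNames(as.integer(rec), names(rec)))
}

#' Recurrently mutated genes
#'
#' @param mat logical presence matrix (genes x cases).
#' @param min_cases minimum number of cases (>= 2).
#' @return named integer vector of case counts, ordered by count descending
#'   then gene name (deterministic tie-break).
#' @export
recurrent_genes <- function(mat, min_cases = 2) {
  if (min_cases < 2) stopf("recurrent_genes: min_cases must be >= 2")
  counts <- rowSums(mat)
  counts <- counts[counts >= min_cases]
  counts <- counts[order(-counts, names(counts))]
  stats::setNames(as.integer(counts), names(counts))
}

#' Per-case unique-gene fractions
#'
#' For each case (column), the share of its mutated genes found in no other
#' case, as an integer percent — a direct measure of inter-case tumor
#' heterogeneity.
#'
#' @param mat logical presence matrix (genes x cases).
#' @return data.frame: `case_id`, `unique`, `total`, `pct`.
#' @export
case_unique_genes <- function(mat) {
  solo <- rowSums(mat) == 1L
  data.frame(case_id = colnames(mat),
             unique = colSums(mat & solo),
             total = colSums(mat),
             pct = round_pct(colSums(mat & solo), colSums(mat)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Treatment-emergent genes exclusive to the resistant group
#'
#' Reports genes with emergent mutations (post- but not pre-treatment within
#' the case) in at least `min_cases` resistant cases, and then narrows to
#' those with no mutation in any sensitive case at *any* timepoint — a gene
#' can recur as emergent in resistant cases yet show a different mutation
#' pattern in a sensitive case, which disqualifies it from exclusivity.
#'
#' @param presence_emergent presence matrix built with stratum
#'   `emergent_within_case`.
#' @param presence_any presence matrix built with stratum `any` (the
#'   cross-stratum filter).
#' @param groups named case -> group vector as in [exclusivity()].
#' @param min_cases minimum resistant case count (default 2).
#' @return list: `emergent_recurrent` (emergent in >= min_cases resistant,
#'   no sensitive-emergent requirement applied) and `exclusive` (the subset
#'   absent from sensitive cases at any timepoint), both sorted.
#' @export
emergent_exclusive <- function(presence_emergent, presence_any, groups,
                               min_cases = 2) {
  grp_e <- groups[colnames(presence_emergent)]
  r <- presence_emergent[, grp_e == "resistant", drop = FALSE]
  emergent_rec <- rownames(presence_emergent)[rowSums(r) >= min_cases]
  grp_a <- groups[colnames(presence_any)]
  s_any <- presence_any[, grp_a == "sensitive", drop = FALSE]
  in_sensitive <- rownames(s_any)[rowSums(s_any) > 0L]
  list(emergent_recurrent = sort(emergent_rec),
       exclusive = sort(setdiff(emergent_rec, in_sensitive)))
}

#' Multi-sample Venn partition of a case's mutated genes
#'
#' Assigns every gene mutated in >= 1 of a case's samples to exactly one of
#' the 2^k - 1 regions of the k-sample Venn diagram. When sample timepoints
#' (one pre, the rest post) and sites are supplied, the regions relevant to
#' a pre + two-post-sites design get named categories: `all_samples`,
#' `both_site_irrespective_of_treatment` (pre + the same-site post only),
#' `emergent_both_post` (all post samples, not pre) and
#' `emergent_site_specific:<sample>` (a single post sample).
#'
#' @param sets named list (length 2..6) of character gene vectors, one per
#'   sample.
#' @param timepoint optional named character vector (`pre`/`post`) per
#'   sample.
#' @param site optional named character vector of tissue sites per sample.
#' @param case_id label carried into the output.
#' @return list with `membership` (data.frame: `case_id`, `gene`, `region`
#'   — member sample names joined by `&` — and `category`) and `counts`
#'   (named region sizes). Regions partition the gene universe.
#' @export
site_venn <- function(sets, timepoint = NULL, site = NULL,
                      case_id = NA_character_) {
  k <- length(sets)
  if (k < 2L) stopf("site_venn: need at least 2 samples")
  if (k > 6L) stopf("site_venn: at most 6 samples supported")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stopf("site_venn: sets must be named by sample")
  ids <- names(sets)
  genes <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1L) memb <- matrix(memb, nrow = 1L,
                                          dimnames = list(genes, ids))
  region <- apply(memb, 1L, function(m) paste(ids[m], collapse = "&"))

  category <- rep("other", length(genes))
  n_in <- rowSums(memb)
  category[n_in == k] <- "all_samples"
  if (!is.null(timepoint)) {
    pre_ids <- ids[timepoint[ids] == "pre"]
    post_ids <- ids[timepoint[ids] == "post"]
    if (length(pre_ids) == 1L && length(post_ids) >= 1L) {
      in_pre <- memb[, pre_ids, drop = FALSE][, 1L]
      n_post <- rowSums(memb[, post_ids, drop = FALSE])
      sel <- !in_pre & n_post == length(post_ids) & n_in < k
      category[sel] <- "emergent_both_post"
      for (p in post_ids) {
        only_p <- !in_pre & memb[, p] & n_post == 1L
        category[only_p] <- paste0("emergent_site_specific:", p)
      }
      if (!is.null(site)) {
        for (p in post_ids[site[post_ids] == site[pre_ids]]) {
          same <- in_pre & memb[, p] & n_post == 1L & n_in == 2L
          category[same] <- "both_site_irrespective_of_treatment"
        }
      }
      category[in_pre & n_post == 0L] <- "pre_only"
    }
  }
  membership <- data.frame(case_id = case_id, gene = genes, region = region,
                           category = category, stringsAsFactors = FALSE)
  counts <- table(factor(membership$region))
  list(membership = membership,
       counts = stats::setNames(as.integer(counts), names(counts)))
}
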