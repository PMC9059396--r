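# Targeted-panel candidate selection, exome-vs-panel validation, and
# gene-level copy-number flagging.

#' Per-gene panel selection criteria
#'
#' Evaluates the five selection criteria used to design a deep-sequencing
#' validation panel from exome results:
#' \enumerate{
#'   \item mutation present in only one platinum group (resistant- or
#'     sensitive-exclusive, any number of cases);
#'   \item mutation detected in more than one resistant case;
#'   \item mutation detected only in post-treatment samples from resistant
#'     cases (emergent within a resistant case), or at an increased variant
#'     allele fraction post-treatment in a resistant case;
#'   \item prior implication in platinum response (external gene list);
#'   \item association with progression-free survival in an external ovarian
#'     carcinoma dataset (external gene list).
#' }
#'
#' @param presence_any presence matrix, stratum `any` ([build_presence()]).
#' @param groups named case -> `"resistant"`/`"sensitive"` vector.
#' @param presence_emergent presence matrix, stratum `emergent_within_case`;
#'   optional (criterion 3's emergent arm is skipped when NULL).
#' @param vaf_change optional data.frame with columns `gene`, `case_id`,
#'   `delta_vaf` (post minus pre allele fraction) for resistant cases.
#' @param external_platinum,external_pfs character gene vectors for
#'   criteria 4 and 5.
#' @param min_resistant case threshold for criterion 2.
#' @param vaf_increase minimum absolute VAF increase for criterion 3's
#'   second arm (default +0.10).
#' @return data.frame, one row per gene in any input, logical columns
#'   `c1_exclusive_group` .. `c5_tcga_pfs`, `n_criteria` and `selected`
#'   (`n_criteria >= 1`).
#' @export
panel_criteria <- function(presence_any, groups, presence_emergent = NULL,
                           vaf_change = NULL,
                           external_platinum = character(0),
                           external_pfs = character(0),
                           min_resistant = 2, vaf_increase = 0.10) {
  grp <- groups[colnames(presence_any)]
  r <- presence_any[, grp == "resistant", drop = FALSE]
  s <- presence_any[, grp == "sensitive", drop = FALSE]
  genes <- sort(unique(c(rownames(presence_any),
                         rownames(presence_emergent),
                         if (!is.null(vaf_change)) vaf_change$gene,
                         external_platinum, external_pfs)))
  hit <- function(m) rowSums(m)[match(genes, rownames(m))] > 0L
  in_r <- hit(r); in_r[is.na(in_r)] <- FALSE
  in_s <- hit(s); in_s[is.na(in_s)] <- FALSE
  c1 <- xor(in_r, in_s)
  nr <- rowSums(r)[match(genes, rownames(r))]
  nr[is.na(nr)] <- 0L
  c2 <- nr >= min_resistant

  c3 <- rep(FALSE, length(genes))
  if (!is.null(presence_emergent)) {
    grp_e <- groups[colnames(presence_emergent)]
    re <- presence_emergent[, grp_e == "resistant", drop = FALSE]
    em <- rowSums(re)[match(genes, rownames(re))] > 0L
    em[is.na(em)] <- FALSE
    c3 <- c3 | em
  }
  if (!is.null(vaf_change)) {
    rc <- names(groups)[groups == "resistant"]
    up <- unique(vaf_change$gene[vaf_change$case_id %in% rc &
                                   vaf_change$delta_vaf >= vaf_increase])
    c3 <- c3 | genes %in% up
  }
  c4 <- genes %in% external_platinum
  c5 <- genes %in% external_pfs
  n <- c1 + c2 + c3 + c4 + c5
  data.frame(gene = genes,
             c1_exclusive_group = c1, c2_recurrent_resistant = c2,
             c3_post_only_or_vaf_increase = c3,
             c4_literature_platinum = c4, c5_tcga_pfs = c5,
             n_criteria = as.integer(n), selected = n >= 1L,
             stringsAsFactors = FALSE)
}

#' Select panel genes from criteria flags
#'
#' Genes satisfying at least one criterion, ranked by number of criteria met
#' (descending) then gene symbol, truncated at `target_size`.
#'
#' @param criteria output of [panel_criteria()].
#' @param target_size maximum panel size (>= 1).
#' @return data.frame of selected rows in rank order, with a `rank` column.
#' @export
select_panel <- function(criteria, target_size = 75) {
  if (target_size < 1) stopf("select_panel: target_size must be >= 1")
  sel <- criteria[criteria$selected, , drop = FALSE]
  sel <- sel[order(-sel$n_criteria, sel$gene), , drop = FALSE]
  sel <- utils::head(sel, target_size)
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Cross-platform validation of mutation calls
#'
#' Compares exome calls with targeted-panel calls on panel genes, matching
#' by normalized variant key within sample. Every key seen on either
#' platform yields a record: exome calls are `validated` when the same key
#' is present in the targeted calls for the same sample; targeted-only keys
#' are flagged `novel_on_panel`; samples sequenced on only one platform are
#' flagged `platform_missing` rather than dropped.
#'
#' @param exome,targeted variant tables from the two platforms.
#' @param panel_genes restrict both call sets to these genes (default: all
#'   genes present in either set).
#' @param platform_samples optional list with character vectors `exome` and
#'   `targeted` of sample ids actually sequenced on each platform (defaults
#'   to the samples observed in each call set).
#' @return data.frame: `sample_id`, `gene`, `key`, `aa_change`,
#'   `exome_vaf`, `targeted_vaf` (NA when absent), `validated`,
#'   `novel_on_panel`, `platform_missing`.
#' @export
validate_calls <- function(exome, targeted, panel_genes = NULL,
                           platform_samples = NULL) {
  restrict <- function(v) {
    if (!is.null(panel_genes)) v[v$gene %in% panel_genes, , drop = FALSE]
    else v
  }
  ex <- restrict(exome); tg <- restrict(targeted)
  vaf <- function(v) ifelse(v$total_reads > 0, v$alt_reads / v$total_reads,
                            NA_real_)
  ex$vaf <- vaf(ex); tg$vaf <- vaf(tg)
  ex$key <- variant_key(ex); tg$key <- variant_key(tg)
  ex_samples <- platform_samples$exome %||% unique(exome$sample_id)
  tg_samples <- platform_samples$targeted %||% unique(targeted$sample_id)
  all_units <- unique(rbind(
    ex[, c("sample_id", "gene", "key", "aa_change")],
    tg[, c("sample_id", "gene", "key", "aa_change")]))
  mex <- match(paste(all_units$sample_id, all_units$key),
               paste(ex$sample_id, ex$key))
  mtg <- match(paste(all_units$sample_id, all_units$key),
               paste(tg$sample_id, tg$key))
  out <- data.frame(
    all_units,
    exome_vaf = ex$vaf[mex],
    targeted_vaf = tg$vaf[mtg],
    validated = !is.na(mex) & !is.na(mtg),
    novel_on_panel = is.na(mex) & !is.na(mtg),
    platform_missing = !(all_units$sample_id %in% ex_samples &
                           all_units$sample_id %in% tg_samples),
    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$gene, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag gene-level copy number
#'
#' Inclusive thresholds against the diploid normal: amplified at
#' `tumor_cn >= amp_threshold` (default 7, matching deep-sequencing
#' amplification reporting), loss at `tumor_cn <= loss_threshold` (default
#' 1, one copy or fewer), neutral in between. Monotone in `tumor_cn`.
#'
#' @param tumor_cn numeric vector of tumor copy numbers (>= 0).
#' @param amp_threshold,loss_threshold inclusive thresholds.
#' @return character vector: `"loss"`, `"neutral"` or `"amplified"`.
#' @examples
#' cn_flag(c(1, 2, 7))   # loss neutral amplified
#' @export
cn_flag <- function(tumor_cn, amp_threshold = 7, loss_threshold = 1) {
  if (any(is.na(tumor_cn)) || any(tumor_cn < 0))
    stopf("cn_flag: tumor_cn must be non-negative and non-missing")
  if (loss_threshold >= amp_threshold)
    stopf("cn_flag: loss_threshold must be below amp_threshold")
  ifelse(tumor_cn >= amp_threshold, "amplified",
         ifelse(tumor_cn <= loss_threshold, "loss", "neutral"))
}

#' Flag a copy-number table
#'
#' @param cn data.frame with columns `gene`, `sample_id`, `tumor_cn`.
#' @inheritParams cn_flag
#' @return the table with an added `flag` column, ordered by sample then
#'   gene.
#' @export
cn_flags <- function(cn, amp_threshold = 7, loss_threshold = 1) {
  require_columns(cn, c("gene", "sample_id", "tumor_cn"), "copy-number table")
  cn$flag <- cn_flag(cn$tumor_cn, amp_threshold, loss_threshold)
  cn <- cn[order(cn$sample_id, cn$gene), , drop = FALSE]
  rownames(cn) <- NULL
  cn
}
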