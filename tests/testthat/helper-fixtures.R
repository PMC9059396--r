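# Shared fixture builders for the test suite. Everything is generated in
# code; no binary or stored data.

# quick variant-table constructor with sensible defaults
make_variants <- function(sample_id, pos, chrom = "chr1",
                          ref = "A", alt = "T",
                          gene = paste0("G", pos),
                          region_class = "exonic",
                          exonic_function = "nonsynonymous_SNV",
                          aa_change = NA_character_,
                          alt_reads = 30L, total_reads = 100L) {
  if (length(pos) == 0L) {
    sid <- if (length(sample_id)) sample_id[1] else "s"
    return(make_variants(sid, pos = 1L)[0, ])
  }
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene,
             region_class = region_class,
             exonic_function = exonic_function,
             aa_change = aa_change,
             alt_reads = as.integer(alt_reads),
             total_reads = as.integer(total_reads),
             stringsAsFactors = FALSE)
}

# non-synonymous variants at the given integer position keys (unique genes
# unless supplied), for shared-fraction fixtures
make_ns_variants <- function(sample_id, keys, gene = NULL) {
  make_variants(sample_id, pos = keys,
                gene = gene %||% paste0("G", keys))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-timepoint sample table for constructed cohorts
make_samples <- function(case_ids, post_per_case = 1L) {
  rows <- lapply(seq_along(case_ids), function(i) {
    cid <- case_ids[i]
    np <- if (length(post_per_case) > 1L) post_per_case[i] else post_per_case
    data.frame(
      sample_id = c(paste0(cid, "-pre"),
                    paste0(cid, "-post", seq_len(np))),
      case_id = cid,
      timepoint = c("pre", rep("post", np)),
      site = c("omentum", rep("omentum", np)),
      platform = "exome",
      tumor_cellularity = 0.8,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# constructive oracle for allele normalization: build a padded variant from a
# known SNV core and shared pad, the normalized form is known by construction
pad_variant <- function(pos, core_ref, core_alt, prefix, suffix) {
  list(pos = pos,
       ref = paste0(prefix, core_ref, suffix),
       alt = paste0(prefix, core_alt, suffix),
       norm_pos = pos + nchar(prefix),
       norm_ref = core_ref, norm_alt = core_alt)
}

# small synthetic config for fast simulator tests; overrides win
fast_config <- function(...) {
  base <- list(
    n_resistant = 1, n_sensitive = 1,
    truncal_mutations = 12,
    subclones_per_case = 2,
    subclonal_mean = 6, subclonal_dispersion = 5,
    pre_clone_fractions = c(0.7, 0.3),
    bottleneck_resistant = c(0.2, 0.8),
    bottleneck_sensitive = c(0.6, 0.4),
    post_private_mean = 5, post_private_ccf = 0.3,
    shared_resistant_genes = 0, shared_sensitive_genes = 0,
    multisite_case = 0,
    n_genes = 500)
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}
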