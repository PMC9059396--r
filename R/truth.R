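# Independent oracle: recompute the full count/overlap/exclusivity analog
# directly from the simulator's clone algebra. Deliberately shares no
# comparison code with the pipeline modules — everything here is direct set
# enumeration over clone assignments, so that pipeline outputs can be tested
# against it on noiseless simulations.

#' Ground-truth statistics of a synthetic cohort
#'
#' Pure set algebra over the generator's clone assignments and per-sample
#' clone fractions (a mutation is present in a sample iff some clone
#' carrying it has non-zero cancer cell fraction there; no sampling noise).
#' Returns the ground-truth analog of every pipeline output: per-sample
#' count summaries, pre/post shared fractions on both bases, per-case
#' stable/emergent/lost gene partitions, and the cross-case
#' resistant/sensitive exclusivity sets.
#'
#' @param sim a `synthetic_cohort` (only `$truth` and `$manifest` are used).
#' @return list with `counts`, `shared`, `status`, `exclusive` components.
#' @export
truth_statistics <- function(sim) {
  asg <- sim$truth$assignments
  frac <- sim$truth$fractions
  samples <- as.data.frame(sim$manifest$samples)
  cases <- as.data.frame(sim$manifest$cases)

  nonsyn_set <- c("nonsynonymous_SNV", "stopgain", "stoploss")
  akey <- paste(asg$chrom, asg$pos, asg$ref, asg$alt, sep = ":")

  # mutation-index sets per sample, by direct clone lookup
  sample_rows <- lapply(samples$sample_id, function(sid) {
    fr <- frac[frac$sample_id == sid & frac$ccf > 0, , drop = FALSE]
    which(asg$case_id == samples$case_id[match(sid, samples$sample_id)] &
            asg$clone %in% fr$clone)
  })
  names(sample_rows) <- samples$sample_id

  counts <- do.call(rbind, lapply(samples$sample_id, function(sid) {
    i <- sample_rows[[sid]]
    ex <- asg$region_class[i] == "exonic"
    fn <- asg$exonic_function[i]
    ns <- ex & !is.na(fn) & fn %in% nonsyn_set
    data.frame(
      sample_id = sid,
      total_somatic = length(i),
      exonic = sum(ex),
      synonymous_snv = sum(ex & fn %in% "synonymous_SNV"),
      nonsynonymous_snv = sum(ex & fn %in% "nonsynonymous_SNV"),
      stop_gain_loss = sum(ex & fn %in% c("stopgain", "stoploss")),
      nonsyn_total = sum(ex & fn %in% nonsyn_set),
      nonsyn_gene_count = length(unique(asg$gene[i][ns])),
      stringsAsFactors = FALSE)
  }))

  ns_keys <- function(i) {
    ns <- asg$region_class[i] == "exonic" &
      asg$exonic_function[i] %in% nonsyn_set
    unique(akey[i][ns])
  }
  ns_genes <- function(i) {
    ns <- asg$region_class[i] == "exonic" &
      asg$exonic_function[i] %in% nonsyn_set
    unique(asg$gene[i][ns])
  }

  shared <- list()
  status <- list()
  for (cid in cases$case_id) {
    ss <- samples[samples$case_id == cid, , drop = FALSE]
    pre_ids <- ss$sample_id[ss$timepoint == "pre"]
    post_ids <- ss$sample_id[ss$timepoint == "post"]
    post_keys <- unique(unlist(lapply(sample_rows[post_ids], ns_keys)))
    post_genes <- unique(unlist(lapply(sample_rows[post_ids], ns_genes)))
    pre_keys <- unique(unlist(lapply(sample_rows[pre_ids], ns_keys)))
    pre_genes <- unique(unlist(lapply(sample_rows[pre_ids], ns_genes)))
    add <- function(sid, tp, fk, fg, ok, og) {
      rbind(
        data.frame(case_id = cid, sample_id = sid, timepoint = tp,
                   basis = "position", shared = sum(fk %in% ok),
                   total = length(fk), stringsAsFactors = FALSE),
        data.frame(case_id = cid, sample_id = sid, timepoint = tp,
                   basis = "gene", shared = sum(fg %in% og),
                   total = length(fg), stringsAsFactors = FALSE))
    }
    for (p in pre_ids)
      shared[[length(shared) + 1L]] <-
        add(p, "pre", ns_keys(sample_rows[[p]]), ns_genes(sample_rows[[p]]),
            post_keys, post_genes)
    for (q in post_ids)
      shared[[length(shared) + 1L]] <-
        add(q, "post", ns_keys(sample_rows[[q]]), ns_genes(sample_rows[[q]]),
            pre_keys, pre_genes)

    genes_all <- sort(union(pre_genes, post_genes))
    st <- ifelse(genes_all %in% pre_genes & genes_all %in% post_genes,
                 "stable",
                 ifelse(genes_all %in% post_genes, "emergent", "lost"))
    status[[cid]] <- data.frame(case_id = rep(cid, length(genes_all)),
                                gene = genes_all,
                                status = as.character(st),
                                stringsAsFactors = FALSE)
  }
  shared <- do.call(rbind, shared)
  shared$pct <- ifelse(shared$total > 0,
                       as.integer(floor(100 * shared$shared / shared$total +
                                          0.5 + sqrt(.Machine$double.eps))),
                       NA_integer_)
  status <- do.call(rbind, status)
  rownames(status) <- NULL

  # cross-case exclusivity by direct enumeration
  case_genes <- lapply(cases$case_id, function(cid) {
    ss <- samples$sample_id[samples$case_id == cid]
    unique(unlist(lapply(sample_rows[ss], ns_genes)))
  })
  names(case_genes) <- cases$case_id
  rgrp <- cases$case_id[cases$platinum_status == "resistant"]
  sgrp <- cases$case_id[cases$platinum_status == "sensitive"]
  all_genes <- sort(unique(unlist(case_genes)))
  n_res <- vapply(all_genes, function(g)
    sum(vapply(case_genes[rgrp], function(s) g %in% s, logical(1))),
    integer(1))
  n_sen <- vapply(all_genes, function(g)
    sum(vapply(case_genes[sgrp], function(s) g %in% s, logical(1))),
    integer(1))
  exclusive <- list(
    resistant_exclusive = all_genes[n_res >= 2 & n_sen == 0],
    sensitive_exclusive = all_genes[n_sen == length(sgrp) & n_res == 0])

  list(counts = counts, shared = shared, status = status,
       exclusive = exclusive)
}
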