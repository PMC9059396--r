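# Clonal-evolution cohort simulator with exact ground truth.
#
# The generative model mirrors the biology the pre/post comparison assumes:
# each case is a mixture of a truncal clone (every tumor cell) and a few
# disjoint subclones; platinum-based chemotherapy acts as a bottleneck that,
# in resistant cases, expands one pre-existing minor subclone; post-treatment
# samples additionally acquire a private late clone; observed allele
# fractions are purity- and copy-number-aware, and detection is depth-limited
# (binomial read sampling against alt-read and VAF thresholds).

#' Synthetic cohort configuration
#'
#' Defaults state the simulated world: a 5-case cohort (3 platinum-resistant,
#' 2 platinum-sensitive) of matched pre/post tumor samples, tumor purity 0.8
#' (macrodissection-enriched cellularity), whole-exome depth 100x and
#' targeted-panel depth 5000x, and MuTect-style detection thresholds
#' (>= 3 variant reads and >= 5% VAF). One resistant case contributes a
#' second post-treatment site. A small set of gene symbols is re-used in the
#' expanding subclone of every resistant case (and, pre-treatment, in the
#' truncal clone of every sensitive case) so that cross-case exclusivity
#' structure exists by construction.
#'
#' @param n_resistant,n_sensitive number of cases per platinum group.
#' @param truncal_mutations mutations carried by every tumor cell of a case.
#' @param subclones_per_case number of disjoint subclones.
#' @param subclonal_mean,subclonal_dispersion negative-binomial mean / size
#'   for per-subclone mutation counts.
#' @param pre_clone_fractions simplex vector (length `subclones_per_case`,
#'   sums to 1): fraction of pre-treatment tumor cells in each subclone.
#' @param bottleneck_resistant,bottleneck_sensitive post-treatment subclone
#'   fractions (simplex); the resistant default expands the last (minor)
#'   subclone from 10% to 80% of tumor cells.
#' @param post_private_mean,post_private_ccf mean mutation count and cancer
#'   cell fraction of the clone private to each post-treatment sample's
#'   lineage (nested in the dominant post subclone).
#' @param shared_resistant_genes,shared_sensitive_genes sizes of the gene
#'   sets re-used across resistant (expanding subclone) and sensitive
#'   (truncal, hence pre+post) cases.
#' @param multisite_case index of the resistant case sequenced at two
#'   post-treatment sites (0 disables).
#' @param site_private_mean,site_private_ccf mutation count / CCF of each
#'   extra site's private late clone.
#' @param site_jitter_sd lognormal sd perturbing the second site's subclone
#'   fractions.
#' @param purity tumor cell fraction of each sample.
#' @param exome_depth,panel_depth mean sequencing depths (reads).
#' @param min_alt_reads,min_vaf detection thresholds.
#' @param region_exonic probability a mutation is exonic.
#' @param exonic_function_probs named simplex over exonic functional classes.
#' @param cn_states,cn_probs categorical distribution of per-gene tumor copy
#'   number (the default exercises loss/neutral/amplified flag thresholds).
#' @param n_genes size of the synthetic gene universe.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_resistant = 3, n_sensitive = 2,
    truncal_mutations = 40,
    subclones_per_case = 3,
    subclonal_mean = 25, subclonal_dispersion = 5,
    pre_clone_fractions = c(0.6, 0.3, 0.1),
    bottleneck_resistant = c(0.05, 0.15, 0.80),
    bottleneck_sensitive = c(0.50, 0.35, 0.15),
    post_private_mean = 20, post_private_ccf = 0.35,
    shared_resistant_genes = 6, shared_sensitive_genes = 3,
    multisite_case = 1, site_private_mean = 8, site_private_ccf = 0.20,
    site_jitter_sd = 0.15,
    purity = 0.8,
    exome_depth = 100, panel_depth = 5000,
    min_alt_reads = 3, min_vaf = 0.05,
    region_exonic = 0.27,
    exonic_function_probs = c(synonymous_SNV = 0.31,
                              nonsynonymous_SNV = 0.60,
                              stopgain = 0.03, stoploss = 0.01,
                              frameshift_indel = 0.03,
                              nonframeshift_indel = 0.02),
    cn_states = c(1, 2, 3, 7, 9),
    cn_probs = c(0.05, 0.75, 0.12, 0.05, 0.03),
    n_genes = 4000) {
  cfg <- as.list(environment())
  check_simplex <- function(x, what) {
    if (abs(sum(x) - 1) > 1e-8)
      stopf("synthetic_config: %s must sum to 1 (got %.6f)", what, sum(x))
    if (any(x < 0)) stopf("synthetic_config: %s has negative entries", what)
  }
  for (nm in c("pre_clone_fractions", "bottleneck_resistant",
               "bottleneck_sensitive"))
    check_simplex(cfg[[nm]], nm)
  if (length(cfg$pre_clone_fractions) != cfg$subclones_per_case ||
      length(cfg$bottleneck_resistant) != cfg$subclones_per_case ||
      length(cfg$bottleneck_sensitive) != cfg$subclones_per_case)
    stopf("synthetic_config: clone fraction vectors must have length %d",
          cfg$subclones_per_case)
  check_simplex(cfg$exonic_function_probs, "exonic_function_probs")
  if (abs(sum(cfg$cn_probs) - 1) > 1e-8)
    stopf("synthetic_config: cn_probs must sum to 1")
  if (cfg$exome_depth <= 0 || cfg$panel_depth <= 0)
    stopf("synthetic_config: depths must be positive")
  if (cfg$purity <= 0 || cfg$purity > 1)
    stopf("synthetic_config: purity must be in (0, 1]")
  if (cfg$post_private_ccf > max(cfg$bottleneck_resistant) ||
      cfg$post_private_ccf > max(cfg$bottleneck_sensitive))
    stopf("synthetic_config: post_private_ccf exceeds the dominant post subclone")
  class(cfg) <- "synthetic_config"
  cfg
}

# synthetic gene universe: deterministic symbols with per-gene intervals
gene_universe <- function(n_genes) {
  gene_len <- 5000L
  data.frame(
    gene = sprintf("SG%05d", seq_len(n_genes)),
    chrom = paste0("chr", ((seq_len(n_genes) - 1L) %% 22L) + 1L),
    start = ((seq_len(n_genes) - 1L) %/% 22L) * (gene_len + 1000L) + 1L,
    len = gene_len,
    stringsAsFactors = FALSE)
}

BASES <- c("A", "C", "G", "T")

# draw n mutations: genes with replacement, positions without replacement
# within each gene's interval (unique keys guaranteed), alleles, annotation
draw_mutations <- function(n, universe, used_pos_env, cfg,
                           force_genes = NULL) {
  if (n == 0L) return(NULL)
  gi <- sample.int(nrow(universe), n, replace = TRUE)
  forced <- seq_len(length(force_genes %||% character(0)))
  if (length(forced)) gi[forced] <- match(force_genes, universe$gene)
  pos <- integer(n)
  for (j in seq_len(n)) {
    g <- universe$gene[gi[j]]
    used <- used_pos_env[[g]] %||% integer(0)
    repeat {
      off <- sample.int(universe$len[gi[j]], 1L)
      if (!off %in% used) break
    }
    used_pos_env[[g]] <- c(used, off)
    pos[j] <- universe$start[gi[j]] + off - 1L
  }
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  exonic <- stats::runif(n) < cfg$region_exonic
  nonex_levels <- c("intronic", "intergenic", "UTR3", "UTR5", "ncRNA",
                    "splicing", "upstream", "downstream")
  nonex_probs <- c(0.50, 0.20, 0.09, 0.05, 0.07, 0.03, 0.03, 0.03)
  region <- ifelse(exonic, "exonic",
                   sample(nonex_levels, n, replace = TRUE,
                          prob = nonex_probs))
  if (length(forced)) {
    # genes placed deliberately (shared exclusivity structure) must be part
    # of the non-synonymous comparison universe
    exonic[forced] <- TRUE
    region[forced] <- "exonic"
  }
  fn <- rep(NA_character_, n)
  fn[exonic] <- sample(names(cfg$exonic_function_probs), sum(exonic),
                       replace = TRUE, prob = cfg$exonic_function_probs)
  fn[forced] <- "nonsynonymous_SNV"
  # indels: represent as 1-base-anchored insertion/deletion
  is_ind <- !is.na(fn) & fn %in% c("frameshift_indel", "nonframeshift_indel")
  if (any(is_ind)) {
    ins <- stats::runif(sum(is_ind)) < 0.5
    extra <- sample(BASES, sum(is_ind), replace = TRUE)
    alt[is_ind][ins] <- paste0(ref[is_ind][ins], extra[ins])
    ref[is_ind][!ins] <- paste0(ref[is_ind][!ins], extra[!ins])
  }
  aa <- rep(NA_character_, n)
  ns <- !is.na(fn) & fn %in% NONSYN_FUNCTIONS
  aa[ns] <- sprintf("p.%s%d%s",
                    sample(LETTERS, sum(ns), replace = TRUE),
                    sample.int(900L, sum(ns), replace = TRUE),
                    sample(LETTERS, sum(ns), replace = TRUE))
  data.frame(chrom = universe$chrom[gi], pos = pos, ref = ref, alt = alt,
             gene = universe$gene[gi], region_class = region,
             exonic_function = fn, aa_change = aa, stringsAsFactors = FALSE)
}

#' Simulate a matched pre/post cohort with ground truth
#'
#' Draws a cohort under a [synthetic_config()] model. Reproducible: the same
#' `seed` gives byte-identical outputs. Every mutation carried by a clone
#' with non-zero cancer cell fraction in a sample yields a row with binomial
#' read support; `detected` applies the configured thresholds (recompute
#' with [apply_detection()] to study thresholds without re-simulating).
#' Expected VAF of a mutation with cancer cell fraction `ccf` in a sample of
#' purity `p` at a locus with tumor copy number `cn` is
#' `p * ccf / (p * cn + (1 - p) * 2)` (one mutated copy).
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed controlling all randomness.
#' @return list of class `synthetic_cohort`:
#'   `variants` (all rows, with `case_id`, `clone`, `ccf`, `true_vaf`,
#'   `detected`), `manifest` (cases + samples tables), `copy_number`
#'   (gene/sample tumor CN for mutated genes), `truth` (clone assignments
#'   and per-sample clone fractions), and `config`.
#' @export
simulate_cohort <- function(config = synthetic_config(), seed = 1L) {
  cfg <- config
  if (!inherits(cfg, "synthetic_config")) stopf("config must be a synthetic_config")
  set.seed(as.integer(seed))
  universe <- gene_universe(cfg$n_genes)
  n_cases <- cfg$n_resistant + cfg$n_sensitive
  case_ids <- c(sprintf("R%d", seq_len(cfg$n_resistant)),
                sprintf("S%d", seq_len(cfg$n_sensitive)))
  status <- rep(c("resistant", "sensitive"),
                c(cfg$n_resistant, cfg$n_sensitive))

  # shared gene sets giving the cohort its exclusivity structure
  shared_res <- universe$gene[seq_len(cfg$shared_resistant_genes)]
  shared_sen <- universe$gene[cfg$shared_resistant_genes +
                                seq_len(cfg$shared_sensitive_genes)]

  assignments <- list()   # per-case clone -> mutation table
  fractions <- list()     # per-sample clone -> ccf
  sample_rows <- list()
  case_rows <- list()
  K <- cfg$subclones_per_case

  for (ci in seq_len(n_cases)) {
    cid <- case_ids[ci]
    resistant <- status[ci] == "resistant"
    used_pos <- new.env(parent = emptyenv())

    n_sub <- stats::rnbinom(K, size = cfg$subclonal_dispersion,
                            mu = cfg$subclonal_mean)
    n_priv_post <- stats::rnbinom(1, size = cfg$subclonal_dispersion,
                                  mu = cfg$post_private_mean)
    clone_tabs <- list()
    add_clone <- function(n, name, force = NULL) {
      m <- draw_mutations(max(n, length(force %||% character(0))),
                          universe, used_pos, cfg, force)
      if (!is.null(m)) {
        m$clone <- name
        clone_tabs[[name]] <<- m
      }
    }
    add_clone(cfg$truncal_mutations, "truncal",
              if (!resistant) shared_sen else NULL)
    for (k in seq_len(K))
      add_clone(n_sub[k], sprintf("sub%d", k),
                if (resistant && k == K) shared_res else NULL)
    add_clone(n_priv_post, "post_private")

    post_sites <- "omentum"
    if (resistant && ci == cfg$multisite_case && cfg$multisite_case > 0)
      post_sites <- c("omentum", "ovary")
    if (length(post_sites) > 1L)
      add_clone(max(1L, stats::rpois(1, cfg$site_private_mean)),
                "site_private_ovary")
    am <- do.call(rbind, clone_tabs)
    if (is.null(am))
      stopf("simulate_cohort: case %s drew no mutations; increase counts", cid)
    am$case_id <- cid
    assignments[[cid]] <- am

    # clone fractions per sample
    pre_frac <- c(truncal = 1, stats::setNames(cfg$pre_clone_fractions,
                                               sprintf("sub%d", seq_len(K))),
                  post_private = 0)
    post_base <- if (resistant) cfg$bottleneck_resistant
                 else cfg$bottleneck_sensitive
    samp_defs <- rbind(
      data.frame(timepoint = "pre", site = "omentum",
                 stringsAsFactors = FALSE),
      data.frame(timepoint = "post", site = post_sites,
                 stringsAsFactors = FALSE))
    for (si in seq_len(nrow(samp_defs))) {
      tp <- samp_defs$timepoint[si]
      site <- samp_defs$site[si]
      sid <- sprintf("%s-%s%s", cid, tp,
                     if (tp == "post" && length(post_sites) > 1L)
                       paste0("-", substr(site, 1, 2)) else "")
      fr <- pre_frac
      if (tp == "post") {
        pf <- post_base
        if (site != post_sites[1]) {
          pf <- pf * exp(stats::rnorm(K, 0, cfg$site_jitter_sd))
          pf <- pf / sum(pf)
        }
        fr[sprintf("sub%d", seq_len(K))] <- pf
        fr["post_private"] <- cfg$post_private_ccf
      }
      if ("site_private_ovary" %in% names(clone_tabs))
        fr["site_private_ovary"] <-
          if (tp == "post" && site == "ovary") cfg$site_private_ccf else 0
      fractions[[sid]] <- data.frame(
        sample_id = sid, case_id = cid, clone = names(fr),
        ccf = unname(fr), stringsAsFactors = FALSE)
      sample_rows[[sid]] <- data.frame(
        sample_id = sid, case_id = cid, timepoint = tp, site = site,
        platform = "exome", tumor_cellularity = cfg$purity,
        stringsAsFactors = FALSE)
    }

    ttr <- if (resistant) stats::runif(1, 3, 5.5) else stats::runif(1, 15, 24)
    ca_pre <- stats::runif(1, 80, 5000)
    ca_dec <- if (resistant) sample(60:85, 1) else sample(95:99, 1)
    case_rows[[cid]] <- data.frame(
      case_id = cid, stage = sample(c("IIIa", "IIIb", "IIIc"), 1),
      nact_cycles = sample(3:5, 1), total_cycles = sample(5:9, 1),
      ca125_pre = round(ca_pre), ca125_pct_decrease = ca_dec,
      residual_disease = sample(RESIDUAL_LEVELS, 1),
      time_to_recurrence = round(ttr, 1),
      time_to_death_or_fu = round(ttr + stats::runif(1, 8, 30), 1),
      vital_status = if (resistant) "DOD" else "AWD",
      platinum_status = status[ci], stringsAsFactors = FALSE)
  }

  assignments <- do.call(rbind, assignments)
  rownames(assignments) <- NULL
  fractions <- do.call(rbind, fractions)
  rownames(fractions) <- NULL
  cases <- do.call(rbind, case_rows)
  cases$nact_cycles <- pmin(cases$nact_cycles, cases$total_cycles)
  samples <- do.call(rbind, sample_rows)
  rownames(cases) <- rownames(samples) <- NULL

  # per-(gene, sample) tumor copy number for mutated genes
  mut_genes <- sort(unique(assignments$gene))
  cn <- expand.grid(gene = mut_genes, sample_id = samples$sample_id,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cn <- cn[order(cn$sample_id, cn$gene), , drop = FALSE]
  cn$tumor_cn <- sample(cfg$cn_states, nrow(cn), replace = TRUE,
                        prob = cfg$cn_probs)
  cn$normal_cn <- 2
  rownames(cn) <- NULL

  # observe every carried mutation in every sample of its case
  obs <- list()
  for (sid in samples$sample_id) {
    cid <- samples$case_id[samples$sample_id == sid]
    fr <- fractions[fractions$sample_id == sid, , drop = FALSE]
    ccf <- stats::setNames(fr$ccf, fr$clone)
    am <- assignments[assignments$case_id == cid, , drop = FALSE]
    am$ccf <- unname(ccf[am$clone])
    am <- am[am$ccf > 0, , drop = FALSE]
    cn_s <- cn[cn$sample_id == sid, , drop = FALSE]
    cn_g <- stats::setNames(cn_s$tumor_cn, cn_s$gene)[am$gene]
    vaf <- cfg$purity * am$ccf / (cfg$purity * cn_g + (1 - cfg$purity) * 2)
    depth <- stats::rpois(nrow(am), cfg$exome_depth)
    depth[depth < 1L] <- 1L
    altr <- stats::rbinom(nrow(am), depth, pmin(vaf, 1))
    am$sample_id <- sid
    am$true_vaf <- unname(vaf)
    am$alt_reads <- altr
    am$total_reads <- depth
    obs[[sid]] <- am
  }
  variants <- do.call(rbind, obs)
  rownames(variants) <- NULL
  variants <- apply_detection(variants, cfg$min_alt_reads, cfg$min_vaf)

  out <- list(
    variants = variants,
    manifest = list(cases = as_case_table(cases),
                    samples = as_sample_table(samples)),
    copy_number = cn,
    truth = list(assignments = assignments, fractions = fractions,
                 shared_resistant_genes = shared_res,
                 shared_sensitive_genes = shared_sen),
    config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' Apply detection thresholds to simulated calls
#'
#' Sets/overwrites the `detected` flag: a call is detected when
#' `alt_reads >= min_alt_reads` and `alt_reads / total_reads >= min_vaf`.
#' Raising either threshold can only clear flags, never set them, so
#' detected counts are monotone non-increasing in the thresholds.
#'
#' @param variants simulated variant table (needs `alt_reads`,
#'   `total_reads`).
#' @param min_alt_reads,min_vaf thresholds (0 disables, every row detected).
#' @return the table with an updated logical `detected` column.
#' @export
apply_detection <- function(variants, min_alt_reads = 3, min_vaf = 0.05) {
  obs_vaf <- ifelse(variants$total_reads > 0,
                    variants$alt_reads / variants$total_reads, 0)
  variants$detected <- variants$alt_reads >= min_alt_reads &
    obs_vaf >= min_vaf
  variants
}

#' Detected calls of a synthetic cohort as a standard variant table
#'
#' @param sim a `synthetic_cohort`.
#' @return variant table (standard columns) of detected calls only.
#' @export
detected_variants <- function(sim) {
  v <- sim$variants[sim$variants$detected, , drop = FALSE]
  rownames(v) <- NULL
  v[, VARIANT_COLUMNS]
}

#' Write a synthetic cohort to disk
#'
#' Writes the manifest (`cases.tsv`, `samples.tsv`), the detected calls
#' (one MAF-TSV per cohort, or one VCF per sample), and the copy-number
#' table — the same dialects the readers accept. Deterministic: identical
#' cohorts produce byte-identical files.
#'
#' @param sim a `synthetic_cohort`.
#' @param dir output directory.
#' @param format `"maf_tsv"` (single `variants.tsv`) or `"vcf"` (one
#'   `<sample>.vcf` per sample).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir, format = c("maf_tsv", "vcf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_manifest(sim$manifest, dir)
  v <- detected_variants(sim)
  v <- v[order(v$sample_id, v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
  if (format == "maf_tsv") {
    p <- file.path(dir, "variants.tsv")
    write_maf(v, p)
    paths <- c(paths, p)
  } else {
    for (sid in unique(v$sample_id)) {
      p <- file.path(dir, paste0(sid, ".vcf"))
      write_vcf(v[v$sample_id == sid, , drop = FALSE], p)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "copy_number.tsv")
  write_tsv_plain(sim$copy_number, p)
  invisible(c(paths, p))
}
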