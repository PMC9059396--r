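# End-to-end orchestration and the command-line entry point.

#' Run configuration
#'
#' Assembles and validates the options driving [run_pipeline()]. Thresholds
#' default to the values used throughout the package: 6-month platinum
#' cutoff, copy-number amplification at >= 7 and loss at <= 1, detection at
#' >= 3 alt reads and >= 5% VAF, half-up integer rounding everywhere.
#'
#' @param variants path to a MAF-TSV variant table (all samples) or a named
#'   character vector of per-sample VCF paths.
#' @param cases,samples paths to the manifest tables.
#' @param copy_number optional path to a gene/sample/tumor_cn TSV.
#' @param out_dir output directory for report tables.
#' @param format `"maf_tsv"` or `"vcf"`.
#' @param position_only relax position matching to chrom:pos.
#' @param platinum_cutoff months; [classify_platinum_status()].
#' @param amp_threshold,loss_threshold copy-number flag thresholds.
#' @param min_alt_reads,min_vaf detection thresholds (simulate subcommand).
#' @param panel_size target panel size.
#' @param seed seed for the simulate subcommand.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(variants = NULL, cases = NULL, samples = NULL,
                       copy_number = NULL, out_dir = "nactmut_out",
                       format = "maf_tsv", position_only = FALSE,
                       platinum_cutoff = 6, amp_threshold = 7,
                       loss_threshold = 1, min_alt_reads = 3,
                       min_vaf = 0.05, panel_size = 75, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a DCF file
#'
#' Plain-text `key: value` file (Debian control format, one field per
#' line); unknown keys are rejected. Logical and numeric fields are
#' converted.
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  num <- c("platinum_cutoff", "amp_threshold", "loss_threshold",
           "min_alt_reads", "min_vaf", "panel_size", "seed")
  for (k in intersect(num, names(raw))) raw[[k]] <- as.numeric(raw[[k]])
  if ("position_only" %in% names(raw))
    raw$position_only <- as.logical(raw$position_only)
  do.call(run_config, raw)
}

load_inputs <- function(cfg) {
  for (p in c(cfg$cases, cfg$samples))
    if (is.null(p) || !file.exists(p))
      stopf("manifest file missing or not found: %s",
            if (is.null(p)) "(not set)" else p)
  manifest <- read_manifest(cfg$cases, cfg$samples)
  if (is.null(cfg$variants)) stopf("variants input not set")
  if (identical(cfg$format, "vcf")) {
    reads <- lapply(names(cfg$variants), function(sid)
      read_variants(cfg$variants[[sid]], "vcf", sample_id = sid))
  } else {
    reads <- list(read_variants(cfg$variants, "maf_tsv"))
  }
  variants <- do.call(rbind, lapply(reads, `[[`, "variants"))
  rejected <- do.call(rbind, lapply(reads, `[[`, "rejected"))
  counts <- Reduce(`+`, lapply(reads, `[[`, "counts"))
  message(sprintf("inputs: read=%d retained=%d rejected=%d",
                  counts[["read"]], counts[["retained"]],
                  counts[["rejected"]]))
  cn <- NULL
  if (!is.null(cfg$copy_number)) {
    if (!file.exists(cfg$copy_number))
      stopf("copy-number table not found: %s", cfg$copy_number)
    cn <- utils::read.delim(cfg$copy_number, stringsAsFactors = FALSE)
  }
  list(manifest = manifest, variants = variants, rejected = rejected,
       copy_number = cn)
}

#' Run the analysis pipeline
#'
#' Orchestrates the package end to end. Subcommands:
#' \describe{
#'   \item{summarize}{per-sample mutation count summary}
#'   \item{overlap}{pre/post shared fractions and gene status}
#'   \item{recurrence}{presence matrices, recurrent genes, exclusivity}
#'   \item{sites}{multi-site Venn partition for cases with >= 2 post
#'     samples}
#'   \item{panel}{panel criteria and copy-number flags}
#'   \item{simulate}{write a synthetic cohort into `out_dir`}
#'   \item{all}{everything above except simulate}
#' }
#' Outputs are deterministic for fixed inputs/seed and written with
#' [write_tables()]; record counts are logged at each stage.
#'
#' @param command subcommand name.
#' @param config a `run_config` (or path to a DCF config file).
#' @return invisibly, a named list of the result tables written.
#' @export
run_pipeline <- function(command = c("all", "summarize", "overlap",
                                     "recurrence", "sites", "panel",
                                     "simulate"),
                         config = run_config()) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (command == "simulate") {
    sim <- simulate_cohort(synthetic_config(
      min_alt_reads = cfg$min_alt_reads, min_vaf = cfg$min_vaf),
      seed = cfg$seed)
    paths <- write_cohort(sim, cfg$out_dir)
    message(sprintf("simulate: wrote %d files to %s", length(paths),
                    cfg$out_dir))
    return(invisible(list(paths = paths)))
  }
  inp <- load_inputs(cfg)
  variants <- inp$variants
  samples <- inp$manifest$samples
  cases <- inp$manifest$cases
  groups <- stats::setNames(cases$platinum_status, cases$case_id)
  results <- list()

  if (command %in% c("summarize", "all")) {
    results$summary <- summarize_cohort_counts(variants, samples)
    check_count_invariants(results$summary)
    results$cohort <- cohort_summary(cases)
    message(sprintf("summarize: %d samples", nrow(results$summary)))
  }
  if (command %in% c("overlap", "all")) {
    results$overlap <- case_shared_fractions(variants, samples,
                                             cfg$position_only)
    status <- gene_status_cohort(variants, samples)
    results$genestatus <- as.data.frame(status)
    results$emergent <- do.call(rbind, lapply(
      split(status, status$case_id), emergent_fraction))
    message(sprintf("overlap: %d rows, %d gene-status rows",
                    nrow(results$overlap), nrow(results$genestatus)))
  }
  if (command %in% c("recurrence", "all")) {
    long <- presence_long(variants, samples)
    mat_any <- build_presence(long, "any")
    mat_em <- build_presence(long, "emergent_within_case")
    excl <- exclusivity(mat_any, groups)
    results$presence <- data.frame(
      gene = rownames(mat_any),
      as.data.frame(mat_any + 0L, optional = TRUE),
      stringsAsFactors = FALSE, check.names = FALSE)
    results$exclusivity <- rbind(
      data.frame(set = "resistant_exclusive",
                 gene = excl$resistant_exclusive,
                 stringsAsFactors = FALSE),
      data.frame(set = "sensitive_exclusive",
                 gene = excl$sensitive_exclusive,
                 stringsAsFactors = FALSE))
    rec <- recurrent_genes(mat_any, 2)
    results$recurrent <- data.frame(gene = names(rec),
                                    n_cases = as.integer(rec),
                                    stringsAsFactors = FALSE)
    em_ex <- emergent_exclusive(mat_em, mat_any, groups)
    results$emergent_exclusive <- data.frame(
      gene = em_ex$emergent_recurrent,
      exclusive = em_ex$emergent_recurrent %in% em_ex$exclusive,
      stringsAsFactors = FALSE)
    message(sprintf("recurrence: %d genes, %d resistant-/%d sensitive-exclusive",
                    nrow(mat_any), length(excl$resistant_exclusive),
                    length(excl$sensitive_exclusive)))
  }
  if (command %in% c("sites", "all")) {
    venns <- list()
    for (cid in unique(samples$case_id)) {
      ss <- samples[samples$case_id == cid, , drop = FALSE]
      if (sum(ss$timepoint == "post") < 2L) next
      sets <- lapply(ss$sample_id, function(s)
        overlap_units(variants[variants$sample_id == s, , drop = FALSE],
                      "gene"))
      names(sets) <- ss$sample_id
      vv <- site_venn(sets,
                      timepoint = stats::setNames(ss$timepoint, ss$sample_id),
                      site = stats::setNames(ss$site, ss$sample_id),
                      case_id = cid)
      venns[[cid]] <- vv$membership
    }
    results$venn <- if (length(venns)) do.call(rbind, venns)
                    else data.frame(case_id = character(0),
                                    gene = character(0),
                                    region = character(0),
                                    category = character(0))
    message(sprintf("sites: %d multi-post case(s)", length(venns)))
  }
  if (command %in% c("panel", "all")) {
    long <- presence_long(variants, samples)
    crit <- panel_criteria(build_presence(long, "any"), groups,
                           build_presence(long, "emergent_within_case"))
    results$panel <- select_panel(crit, cfg$panel_size)
    if (!is.null(inp$copy_number))
      results$cnflags <- cn_flags(inp$copy_number, cfg$amp_threshold,
                                  cfg$loss_threshold)
    message(sprintf("panel: %d candidate gene(s)", nrow(results$panel)))
  }
  write_tables(results, cfg$out_dir)
  invisible(results)
}

#' Command-line entry point
#'
#' `Rscript -e 'nactmut::cli_main()' <command> [--key value ...]` or via the
#' installed script `system.file("cli", "nactmut.R", package = "nactmut")`.
#' Flags mirror the [run_config()] fields (e.g. `--variants`, `--cases`,
#' `--samples`, `--out_dir`, `--seed`, `--platinum_cutoff`); `--config FILE`
#' loads a DCF config first, with flags overriding. Exits non-zero with a
#' diagnostic naming the failing stage on any validation error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) < 1L)
      stopf("usage: nactmut <command> [--key value ...]")
    command <- args[[1L]]
    rest <- args[-1L]
    if (length(rest) %% 2L != 0L)
      stopf("flags must come in --key value pairs")
    keys <- sub("^--", "", rest[c(TRUE, FALSE)])
    vals <- rest[c(FALSE, TRUE)]
    opts <- stats::setNames(as.list(vals), keys)
    cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
           else run_config()
    opts$config <- NULL
    known <- names(formals(run_config))
    bad <- setdiff(names(opts), known)
    if (length(bad))
      stopf("unknown flag(s): %s", paste(bad, collapse = ", "))
    num <- c("platinum_cutoff", "amp_threshold", "loss_threshold",
             "min_alt_reads", "min_vaf", "panel_size", "seed")
    for (k in names(opts)) {
      cfg[[k]] <- if (k %in% num) as.numeric(opts[[k]])
                  else if (k == "position_only") as.logical(opts[[k]])
                  else opts[[k]]
    }
    run_pipeline(command, cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
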