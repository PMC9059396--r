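# Variant I/O and normalization.
#
# The in-memory representation of annotated somatic calls is a plain
# data.frame (a "variant table") with one row per (sample, variant, gene):
#   sample_id, chrom, pos (1-based), ref, alt, gene, region_class,
#   exonic_function, aa_change, alt_reads, total_reads
# This doubles as the on-disk MAF-like TSV dialect.

VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                     "region_class", "exonic_function", "aa_change",
                     "alt_reads", "total_reads")

REGION_LEVELS <- c("exonic", "splicing", "intronic", "UTR5", "UTR3",
                   "intergenic", "ncRNA", "upstream", "downstream", "other")

EXONIC_FUNCTION_LEVELS <- c("synonymous_SNV", "nonsynonymous_SNV", "stopgain",
                            "stoploss", "frameshift_indel",
                            "nonframeshift_indel", "unknown")

#' Default annotation dialect
#'
#' Maps ANNOVAR-style VCF INFO keys and annotation values onto the package's
#' internal vocabulary. The study cohorts this package targets were annotated
#' with ANNOVAR (Func/Gene/ExonicFunc refGene triplet), but annotation
#' schemas vary, so every key is configurable.
#'
#' @param func_key,gene_key,exonicfunc_key,aa_key INFO keys holding the
#'   region class, gene symbol(s), exonic functional class and amino-acid
#'   change.
#' @param alt_reads_key,total_reads_key INFO keys for variant-supporting and
#'   total read counts at the site.
#' @param region_map,function_map named character vectors translating
#'   annotation values to the internal enums; unmapped region values fall
#'   back to `"other"`, unmapped exonic functions to `"unknown"`.
#' @return a list usable as the `dialect` argument of [read_variants()].
#' @export
default_dialect <- function(func_key = "Func.refGene",
                            gene_key = "Gene.refGene",
                            exonicfunc_key = "ExonicFunc.refGene",
                            aa_key = "AAChange.refGene",
                            alt_reads_key = "AO",
                            total_reads_key = "DP",
                            region_map = NULL,
                            function_map = NULL) {
  if (is.null(region_map))
    region_map <- c(
      "exonic" = "exonic", "splicing" = "splicing", "intronic" = "intronic",
      "UTR5" = "UTR5", "UTR3" = "UTR3", "intergenic" = "intergenic",
      "ncRNA_exonic" = "ncRNA", "ncRNA_intronic" = "ncRNA",
      "ncRNA_splicing" = "ncRNA", "ncRNA" = "ncRNA",
      "upstream" = "upstream", "downstream" = "downstream")
  if (is.null(function_map))
    function_map <- c(
      "synonymous SNV" = "synonymous_SNV",
      "nonsynonymous SNV" = "nonsynonymous_SNV",
      "stopgain" = "stopgain", "stoploss" = "stoploss",
      "frameshift insertion" = "frameshift_indel",
      "frameshift deletion" = "frameshift_indel",
      "frameshift substitution" = "frameshift_indel",
      "nonframeshift insertion" = "nonframeshift_indel",
      "nonframeshift deletion" = "nonframeshift_indel",
      "nonframeshift substitution" = "nonframeshift_indel",
      "unknown" = "unknown",
      # allow already-internal values to pass through
      "synonymous_SNV" = "synonymous_SNV",
      "nonsynonymous_SNV" = "nonsynonymous_SNV",
      "frameshift_indel" = "frameshift_indel",
      "nonframeshift_indel" = "nonframeshift_indel")
  list(func_key = func_key, gene_key = gene_key,
       exonicfunc_key = exonicfunc_key, aa_key = aa_key,
       alt_reads_key = alt_reads_key, total_reads_key = total_reads_key,
       region_map = region_map, function_map = function_map)
}

#' Read annotated somatic variant calls
#'
#' Reads either a VCF 4.x file with ANNOVAR-style INFO annotation (parsed via
#' Bioconductor's VariantAnnotation; multi-allelic records are split into one
#' call per alternate allele) or the package's MAF-like tab-separated dialect.
#' Records violating the variant-table invariants (e.g. region class
#' `exonic` without an exonic functional class, alt reads exceeding total
#' reads) are routed to a reject table with a reason, not dropped silently.
#' Multi-gene annotations (comma/semicolon separated) are expanded to one row
#' per gene and flagged in `multi_gene`.
#'
#' @param path input file.
#' @param format `"vcf"` or `"maf_tsv"`.
#' @param dialect annotation key map, see [default_dialect()]. Ignored for
#'   `maf_tsv`, whose columns are fixed.
#' @param sample_id sample the calls belong to; required for VCF (a somatic
#'   VCF holds one tumor sample), optional for MAF-TSV (taken from the
#'   `sample_id` column).
#' @return list with elements `variants` (validated variant table),
#'   `rejected` (rejected rows plus a `reason` column) and `counts`
#'   (named integer: read, retained, rejected).
#' @export
read_variants <- function(path, format = c("maf_tsv", "vcf"),
                          dialect = default_dialect(), sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("variant file not found: %s", path)
  raw <- switch(format,
    maf_tsv = read_maf_table(path, sample_id),
    vcf = read_vcf_table(path, dialect, sample_id))
  res <- partition_variant_table(raw)
  message(sprintf("read_variants: %s read=%d retained=%d rejected=%d",
                  basename(path), nrow(raw), nrow(res$variants),
                  nrow(res$rejected)))
  res$counts <- c(read = nrow(raw), retained = nrow(res$variants),
                  rejected = nrow(res$rejected))
  res
}

read_maf_table <- function(path, sample_id = NULL) {
  head1 <- readLines(path, n = 1L)
  if (!length(head1) || !grepl("\t", head1))
    stopf("malformed MAF-TSV header in %s: expected tab-separated columns",
          path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  require_columns(df, setdiff(VARIANT_COLUMNS, "sample_id"),
                  sprintf("MAF-TSV %s", path))
  if (!"sample_id" %in% names(df)) {
    if (is.null(sample_id))
      stopf("MAF-TSV %s lacks sample_id column and no sample_id given", path)
    df$sample_id <- sample_id
  }
  df$pos <- as.integer(df$pos)
  df$alt_reads <- as.integer(df$alt_reads)
  df$total_reads <- as.integer(df$total_reads)
  df[df == "" | df == "."] <- NA
  df[, VARIANT_COLUMNS]
}

read_vcf_table <- function(path, dialect, sample_id) {
  if (is.null(sample_id))
    stopf("sample_id is required when reading a VCF")
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) stopf("malformed VCF %s: %s", path,
                              conditionMessage(e)))
  vcf <- VariantAnnotation::expand(vcf)  # multi-allelic -> one row per alt
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  for (k in c(dialect$func_key, dialect$gene_key)) {
    if (!k %in% names(info))
      stopf("annotation key '%s' not present in VCF INFO of %s", k, path)
  }
  info_chr <- function(key) {
    if (!key %in% names(info)) return(rep(NA_character_, nrow(info)))
    v <- info[[key]]
    if (is.list(v) || inherits(v, "List"))
      v <- vapply(as.list(v), function(x)
        if (length(x)) paste(x, collapse = ",") else NA_character_,
        character(1))
    as.character(v)
  }
  info_int <- function(key) {
    if (!key %in% names(info)) return(rep(NA_integer_, nrow(info)))
    v <- info[[key]]
    if (is.list(v) || inherits(v, "List"))
      v <- vapply(as.list(v), function(x)
        if (length(x)) x[[1]] else NA_integer_, numeric(1))
    as.integer(v)
  }
  region_raw <- info_chr(dialect$func_key)
  region <- unname(dialect$region_map[region_raw])
  region[is.na(region) & !is.na(region_raw)] <- "other"
  fun_raw <- info_chr(dialect$exonicfunc_key)
  fun <- unname(dialect$function_map[fun_raw])
  fun[is.na(fun) & !is.na(fun_raw)] <- "unknown"
  data.frame(
    sample_id = sample_id,
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    gene = info_chr(dialect$gene_key),
    region_class = region,
    exonic_function = fun,
    aa_change = info_chr(dialect$aa_key),
    alt_reads = info_int(dialect$alt_reads_key),
    total_reads = info_int(dialect$total_reads_key),
    stringsAsFactors = FALSE)
}

# Split a raw table into retained vs rejected rows, expanding multi-gene
# annotations and normalizing alleles on the way.
partition_variant_table <- function(df) {
  df <- as.data.frame(df)[, VARIANT_COLUMNS]
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  flag(is.na(df$chrom) | is.na(df$pos) | is.na(df$ref) | is.na(df$alt),
       "missing coordinate or allele")
  flag(is.na(df$gene) | trimws(df$gene) == "", "missing gene annotation")
  flag(!is.na(df$pos) & df$pos < 1, "position below 1")
  flag(!is.na(df$ref) & !is.na(df$alt) &
         toupper(df$ref) == toupper(df$alt), "ref equals alt")
  flag(grepl("[^ACGTNacgtn]", df$ref) | grepl("[^ACGTNacgtn]", df$alt),
       "non-ACGTN allele characters")
  flag(is.na(df$region_class) | !df$region_class %in% REGION_LEVELS,
       "unknown region class")
  flag(df$region_class == "exonic" &
         (is.na(df$exonic_function) |
            !df$exonic_function %in% EXONIC_FUNCTION_LEVELS),
       "exonic record without exonic functional class")
  flag(df$region_class != "exonic" & !is.na(df$exonic_function),
       "exonic_function present for non-exonic record")
  flag(!is.na(df$alt_reads) & !is.na(df$total_reads) &
         (df$alt_reads < 0 | df$alt_reads > df$total_reads),
       "alt_reads outside [0, total_reads]")
  rejected <- df[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  keep <- df[is.na(reason), , drop = FALSE]
  if (nrow(keep)) {
    keep <- expand_multi_gene(keep)
    norm <- normalize_variants(keep$chrom, keep$pos, keep$ref, keep$alt)
    keep$pos <- norm$pos
    keep$ref <- norm$ref
    keep$alt <- norm$alt
  } else {
    keep$multi_gene <- logical(0)
  }
  rownames(keep) <- NULL
  rownames(rejected) <- NULL
  list(variants = keep, rejected = rejected)
}

# one row per gene for comma/semicolon-separated annotations; rows sharing a
# position this way are flagged so position-based counts can deduplicate
expand_multi_gene <- function(df) {
  genes <- strsplit(trimws(df$gene), "[,;]\\s*")
  n <- lengths(genes)
  out <- df[rep(seq_len(nrow(df)), n), , drop = FALSE]
  out$gene <- trimws(unlist(genes))
  out$multi_gene <- rep(n > 1L, n)
  rownames(out) <- NULL
  out
}

#' Normalize variant alleles to a canonical key
#'
#' Uppercases alleles and trims bases shared between ref and alt: the common
#' suffix is removed first, then the common prefix (left-trim last), keeping
#' at least one base of each allele; the position is advanced by the number
#' of prefix bases removed. Identical inputs always map to identical keys,
#' and the operation is idempotent.
#'
#' @param chrom,pos,ref,alt parallel vectors describing the calls (1-based
#'   VCF-convention coordinates).
#' @return list with normalized `chrom`, `pos`, `ref`, `alt` and the
#'   canonical string `key` (`chrom:pos:ref:alt`).
#' @examples
#' normalize_variants("chr1", 100, "CA", "CT")  # -> chr1:101 A>T
#' @export
normalize_variants <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(grepl("[^ACGTN]", c(ref, alt))))
    stopf("normalize_variants: alleles contain non-ACGTN characters")
  if (any(ref == alt))
    stopf("normalize_variants: ref equals alt")
  pos <- as.integer(pos)
  if (any(pos < 1L)) stopf("normalize_variants: position below 1")
  n <- length(ref)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    # shared suffix
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix, position advances
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  list(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
       key = paste(chrom, pos, ref, alt, sep = ":"))
}

#' Canonical variant keys of a variant table
#'
#' @param variants a variant table.
#' @param position_only if TRUE the key is `chrom:pos` only (the relaxed
#'   "genomic position" matching mode); default matches the full
#'   chrom/pos/ref/alt tuple.
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(variants, position_only = FALSE) {
  if (position_only)
    paste(variants$chrom, variants$pos, sep = ":")
  else
    paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Write a variant table in the MAF-like TSV dialect
#'
#' @param variants variant table.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_maf <- function(variants, path) {
  write_tsv_plain(variants[, VARIANT_COLUMNS], path)
}

#' Write a variant table as a minimal annotated VCF
#'
#' Emits a VCF 4.2 file for one sample, with annotations in the INFO keys of
#' the supplied dialect — the inverse of [read_variants()]'s VCF route.
#'
#' @param variants variant table (one sample).
#' @param path output file.
#' @param dialect annotation key map, see [default_dialect()].
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, path, dialect = default_dialect()) {
  if (length(unique(variants$sample_id)) > 1L)
    stopf("write_vcf expects variants from a single sample")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Region class\">",
            dialect$func_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">",
            dialect$gene_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Exonic function\">",
            dialect$exonicfunc_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"AA change\">",
            dialect$aa_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Alt reads\">",
            dialect$alt_reads_key),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Total depth\">",
            dialect$total_reads_key),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  inv_region <- names(default_dialect()$region_map)[
    match(variants$region_class, default_dialect()$region_map)]
  inv_region[is.na(inv_region)] <- variants$region_class[is.na(inv_region)]
  info <- paste0(
    dialect$func_key, "=", inv_region, ";",
    dialect$gene_key, "=", variants$gene,
    ifelse(is.na(variants$exonic_function), "",
           paste0(";", dialect$exonicfunc_key, "=", variants$exonic_function)),
    ifelse(is.na(variants$aa_change), "",
           paste0(";", dialect$aa_key, "=", variants$aa_change)),
    ";", dialect$alt_reads_key, "=", variants$alt_reads,
    ";", dialect$total_reads_key, "=", variants$total_reads)
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a set of result tables as TSV reports
#'
#' Each element of `results` is written as `<name>.tsv` under `out_dir` with
#' deterministic row order (case, sample, gene, then remaining columns,
#' lexicographically), so identical inputs produce byte-identical files.
#'
#' @param results named list of data.frames; must be non-empty.
#' @param out_dir output directory (created if needed).
#' @return invisibly, character vector of written paths.
#' @export
write_tables <- function(results, out_dir) {
  if (length(results) == 0L || is.null(names(results)))
    stopf("write_tables: results must be a non-empty named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    df <- order_report_rows(as.data.frame(results[[nm]]))
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_plain(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
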