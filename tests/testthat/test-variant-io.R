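test_that("allele normalization: identity, case folding, trimming", {
  n <- normalize_variants("chr1", 100, "A", "T")
  expect_equal(n$pos, 100L)
  expect_equal(n$ref, "A")
  expect_equal(n$key, "chr1:100:A:T")
  expect_equal(normalize_variants("chr1", 100, "a", "t")$ref, "A")
  # shared prefix: position advances
  n2 <- normalize_variants("chr1", 100, "CA", "CT")
  expect_equal(list(n2$pos, n2$ref, n2$alt), list(101L, "A", "T"))
  # suffix trimmed before prefix (left-trim last)
  n3 <- normalize_variants("chr1", 100, "CAG", "CTG")
  expect_equal(list(n3$pos, n3$ref, n3$alt), list(101L, "A", "T"))
  # indel anchored representation survives with one base kept
  n4 <- normalize_variants("chr1", 100, "AT", "A")
  expect_equal(list(n4$pos, n4$ref, n4$alt), list(100L, "AT", "A"))
  expect_error(normalize_variants("chr1", 100, "AX", "A"), "ACGTN")
  expect_error(normalize_variants("chr1", 100, "A", "A"), "ref equals alt")
})

test_that("normalization matches the constructive padding oracle and is idempotent", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    core_ref <- sample(bases, 1)
    core_alt <- sample(setdiff(bases, core_ref), 1)
    prefix <- paste(sample(bases, sample(0:4, 1), replace = TRUE),
                    collapse = "")
    suffix <- paste(sample(bases, sample(0:4, 1), replace = TRUE),
                    collapse = "")
    pv <- pad_variant(sample(1000L, 1), core_ref, core_alt, prefix, suffix)
    n <- normalize_variants("chr2", pv$pos, pv$ref, pv$alt)
    expect_equal(n$pos, pv$norm_pos)
    expect_equal(n$ref, pv$norm_ref)
    expect_equal(n$alt, pv$norm_alt)
    n2 <- normalize_variants("chr2", n$pos, n$ref, n$alt)
    expect_equal(n2[c("pos", "ref", "alt")], n[c("pos", "ref", "alt")])
  }
})

test_that("MAF-TSV round-trips and rejects invariant-violating records", {
  v <- make_variants("s1", pos = c(100, 200, 300),
                     region_class = c("exonic", "intronic", "exonic"),
                     exonic_function = c("nonsynonymous_SNV", NA,
                                         "synonymous_SNV"),
                     gene = c("TP53", "MUC2", "PAK2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_maf(v, path)
  suppressMessages(back <- read_variants(path, "maf_tsv"))
  expect_equal(back$variants[, names(v)], v)
  expect_equal(nrow(back$rejected), 0L)
  expect_equal(unname(back$counts[c("read", "retained", "rejected")]),
               c(3L, 3L, 0L))

  # exonic without functional class -> rejected with reason, not dropped
  v2 <- v
  v2$exonic_function[1] <- NA
  write_maf(v2, path)
  suppressMessages(back2 <- read_variants(path, "maf_tsv"))
  expect_equal(nrow(back2$variants), 2L)
  expect_equal(nrow(back2$rejected), 1L)
  expect_match(back2$rejected$reason, "exonic")
  # read = retained + rejected
  expect_equal(back2$counts[["read"]],
               back2$counts[["retained"]] + back2$counts[["rejected"]])

  v3 <- v
  v3$alt_reads[2] <- v3$total_reads[2] + 1L
  write_maf(v3, path)
  suppressMessages(back3 <- read_variants(path, "maf_tsv"))
  expect_match(back3$rejected$reason, "alt_reads")
})

test_that("VCF round-trip preserves the normalized calls, multi-allelics split", {
  v <- make_variants("s1", pos = c(100, 200),
                     ref = c("A", "G"), alt = c("T", "C"),
                     gene = c("TP53", "BRCA1"),
                     region_class = "exonic",
                     exonic_function = c("nonsynonymous_SNV", "stopgain"),
                     aa_change = c("p.R175H", "p.Q12X"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, path)
  suppressMessages(back <- read_variants(path, "vcf", sample_id = "s1"))
  expect_equal(back$variants[, names(v)], v)

  # hand-written multi-allelic record splits into one call per alt
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=Func.refGene,Number=1,Type=String,Description=\"f\">",
    "##INFO=<ID=Gene.refGene,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description=\"e\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"a\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr7\t140\t.\tA\tT,C\t.\tPASS\t",
           "Func.refGene=exonic;Gene.refGene=BRAF;",
           "ExonicFunc.refGene=nonsynonymous SNV;AO=10,5;DP=60"))
  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path2)
  suppressMessages(ma <- read_variants(path2, "vcf", sample_id = "s2"))
  expect_equal(nrow(ma$variants), 2L)
  expect_setequal(ma$variants$alt, c("T", "C"))
  expect_equal(ma$variants$alt_reads[ma$variants$alt == "C"], 5L)

  expect_error(suppressMessages(
    read_variants(path2, "vcf",
                  dialect = default_dialect(gene_key = "NoSuchKey"),
                  sample_id = "s2")),
    "NoSuchKey")
  expect_error(suppressMessages(read_variants(path2, "vcf")), "sample_id")
})

test_that("multi-gene annotations expand to one flagged record per gene", {
  v <- make_variants("s1", pos = 500, gene = "MUC17;MUC20")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_maf(v, path)
  suppressMessages(back <- read_variants(path, "maf_tsv"))
  expect_equal(nrow(back$variants), 2L)
  expect_setequal(back$variants$gene, c("MUC17", "MUC20"))
  expect_true(all(back$variants$multi_gene))
  # both rows share one normalized key
  expect_equal(length(unique(variant_key(back$variants))), 1L)
})

test_that("write_tables is deterministic with documented ordering", {
  res <- list(
    summary = data.frame(sample_id = c("b", "a"), n = c(2L, 1L)),
    empty = data.frame(gene = character(0), flag = logical(0)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_tables(res, d1)
  write_tables(res, d2)
  expect_identical(readLines(file.path(d1, "summary.tsv")),
                   readLines(file.path(d2, "summary.tsv")))
  # rows sorted by sample
  expect_equal(utils::read.delim(file.path(d1, "summary.tsv"))$sample_id,
               c("a", "b"))
  # empty table -> header only
  expect_equal(length(readLines(file.path(d1, "empty.tsv"))), 1L)
  expect_error(write_tables(list(), d1), "non-empty")
})
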