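test_that("config validation rejects malformed clone fractions", {
  expect_error(synthetic_config(pre_clone_fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(fast_config(pre_clone_fractions = c(0.5, 0.25, 0.25)),
               "length")
  expect_error(synthetic_config(purity = 0), "purity")
  expect_error(synthetic_config(exome_depth = 0), "depths")
})

test_that("simulation is deterministic in the seed", {
  s1 <- simulate_cohort(fast_config(), seed = 5)
  s2 <- simulate_cohort(fast_config(), seed = 5)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$manifest, s2$manifest)
  s3 <- simulate_cohort(fast_config(), seed = 6)
  expect_false(identical(s1$variants, s3$variants))

  # byte-identical files from the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1, d1); write_cohort(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("expected VAF follows the purity/CN model", {
  sim <- simulate_cohort(fast_config(purity = 0.6), seed = 9)
  v <- sim$variants
  cn <- sim$copy_number
  cn_g <- cn$tumor_cn[match(paste(v$sample_id, v$gene),
                            paste(cn$sample_id, cn$gene))]
  expect_equal(v$true_vaf, 0.6 * v$ccf / (0.6 * cn_g + 0.4 * 2))
  expect_true(all(v$true_vaf > 0 & v$true_vaf <= 1))
  expect_true(all(v$alt_reads <= v$total_reads))
})

test_that("noiseless simulations equal the ground-truth oracle exactly", {
  cfg <- fast_config(min_alt_reads = 0, min_vaf = 0,
                     n_resistant = 2, shared_resistant_genes = 3)
  sim <- simulate_cohort(cfg, seed = 21)
  expect_true(all(sim$variants$detected))
  v <- detected_variants(sim)
  truth <- truth_statistics(sim)

  counts <- summarize_cohort_counts(v, sim$manifest$samples)
  expect_equal(counts$total_somatic, truth$counts$total_somatic)
  expect_equal(counts$nonsyn_total, truth$counts$nonsyn_total)
  expect_equal(counts$nonsyn_gene_count, truth$counts$nonsyn_gene_count)

  sf <- case_shared_fractions(v, sim$manifest$samples)
  m <- merge(sf, truth$shared, by = c("sample_id", "basis"))
  expect_true(all(m$shared.x == m$shared.y))
  expect_true(all(m$total.x == m$total.y))
  expect_true(all(m$pct.x == m$pct.y))

  gs <- as.data.frame(gene_status_cohort(v, sim$manifest$samples))
  a <- gs[order(gs$case_id, gs$gene), c("case_id", "gene", "status")]
  b <- truth$status[order(truth$status$case_id, truth$status$gene), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  groups <- stats::setNames(sim$manifest$cases$platinum_status,
                            sim$manifest$cases$case_id)
  ex <- exclusivity(build_presence(presence_long(v, sim$manifest$samples),
                                   "any"), groups)
  expect_equal(ex$resistant_exclusive,
               sort(truth$exclusive$resistant_exclusive))
  expect_true(all(sim$truth$shared_resistant_genes %in%
                    ex$resistant_exclusive))
})

test_that("a truncal-only cohort shares everything", {
  cfg <- fast_config(subclonal_mean = 0, post_private_mean = 0,
                     subclonal_dispersion = 1e6,
                     min_alt_reads = 0, min_vaf = 0)
  sim <- simulate_cohort(cfg, seed = 2)
  expect_setequal(unique(sim$truth$assignments$clone), "truncal")
  sf <- case_shared_fractions(detected_variants(sim), sim$manifest$samples)
  expect_true(all(sf$pct == 100L))
})

test_that("raising detection thresholds never increases detected counts", {
  sim <- simulate_cohort(fast_config(exome_depth = 40), seed = 13)
  vafs <- seq(0, 0.25, by = 0.05)
  counts <- vapply(vafs, function(mv) {
    sum(apply_detection(sim$variants, min_alt_reads = 3,
                        min_vaf = mv)$detected)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  alts <- 0:8
  counts2 <- vapply(alts, function(ma)
    sum(apply_detection(sim$variants, ma, 0)$detected), numeric(1))
  expect_true(all(diff(counts2) <= 0))
})

test_that("depth-limited dropout only removes sharing (one-sided, 200 reps)", {
  # at shallow depth, detected pre/post shared fractions can fall below the
  # clone-algebra truth (a mutation missed in one sample breaks the pair)
  # but should not systematically exceed it
  cfg <- fast_config(exome_depth = 25, truncal_mutations = 8,
                     subclonal_mean = 4, post_private_mean = 3)
  diffs <- numeric(0)
  for (rep in 1:200) {
    sim <- simulate_cohort(cfg, seed = 1000 + rep)
    truth <- truth_statistics(sim)
    sf <- tryCatch(
      suppressWarnings(
        case_shared_fractions(detected_variants(sim),
                              sim$manifest$samples)),
      error = function(e) NULL)
    if (is.null(sf)) next  # a sample lost every call at this depth
    m <- merge(sf[sf$basis == "position", ],
               truth$shared[truth$shared$basis == "position", ],
               by = "sample_id")
    m <- m[m$total.x > 0 & m$total.y > 0, ]
    diffs <- c(diffs, m$shared.x / m$total.x - m$shared.y / m$total.y)
  }
  expect_gt(length(diffs), 300)
  # one-sided: mean detected share does not exceed truth beyond tolerance
  expect_lte(mean(diffs), 0.01)
})

test_that("simulated manifests validate and carry the stated world", {
  sim <- simulate_cohort(synthetic_config(), seed = 3)
  man <- sim$manifest
  expect_s3_class(man$cases, "case_table")
  expect_equal(sum(man$cases$platinum_status == "resistant"), 3L)
  expect_equal(sum(man$cases$platinum_status == "sensitive"), 2L)
  expect_equal(classify_platinum_status(man$cases$time_to_recurrence),
               man$cases$platinum_status)
  # one resistant case sequenced at two post-treatment sites
  post_counts <- table(man$samples$case_id[man$samples$timepoint == "post"])
  expect_equal(sort(unname(post_counts), decreasing = TRUE)[1], 2L)
  expect_equal(nrow(man$samples), 11L)
  # copy-number states restricted to the configured categorical
  expect_true(all(sim$copy_number$tumor_cn %in% c(1, 2, 3, 7, 9)))
})
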