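test_that("panel criteria flag genes with documented provenance", {
  groups <- c(R1 = "resistant", R2 = "resistant", S1 = "sensitive",
              S2 = "sensitive")
  long <- data.frame(
    gene = c("gx", "gx", "gy", "gy", "gz", "gz", "gn", "gn"),
    case_id = c("R1", "R2", "R1", "S1", "R1", "R1", "S1", "R1"),
    timepoint = c("pre", "pre", "pre", "pre", "pre", "post", "pre", "pre"),
    stringsAsFactors = FALSE)
  crit <- panel_criteria(build_presence(long, "any"), groups,
                         build_presence(long, "emergent_within_case"),
                         external_platinum = "lit1",
                         external_pfs = "tcga1")
  row <- function(g) crit[crit$gene == g, ]
  # gx: resistant-exclusive (c1) and in >1 resistant case (c2)
  expect_true(row("gx")$c1_exclusive_group)
  expect_true(row("gx")$c2_recurrent_resistant)
  expect_equal(row("gx")$n_criteria, 2L)
  # gy: both groups -> no c1; single resistant case -> no c2
  expect_false(row("gy")$selected)
  # external-only genes selected through c4/c5
  expect_true(row("lit1")$c4_literature_platinum && row("lit1")$selected)
  expect_true(row("tcga1")$c5_tcga_pfs)

  # criterion 3's VAF arm: resistant-case increase above the default +0.10
  crit2 <- panel_criteria(build_presence(long, "any"), groups,
                          vaf_change = data.frame(
                            gene = c("gy", "gn"),
                            case_id = c("R1", "S1"),
                            delta_vaf = c(0.25, 0.30)))
  expect_true(crit2[crit2$gene == "gy", ]$c3_post_only_or_vaf_increase)
  # sensitive-case increase does not count
  expect_false(crit2[crit2$gene == "gn", ]$c3_post_only_or_vaf_increase)
})

test_that("select_panel ranks by criteria count and truncates", {
  crit <- data.frame(
    gene = c("b", "a", "c", "d"),
    c1_exclusive_group = c(TRUE, TRUE, TRUE, FALSE),
    c2_recurrent_resistant = c(TRUE, FALSE, FALSE, FALSE),
    c3_post_only_or_vaf_increase = FALSE,
    c4_literature_platinum = FALSE, c5_tcga_pfs = FALSE,
    n_criteria = c(2L, 1L, 1L, 0L),
    selected = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  sel <- select_panel(crit, target_size = 2)
  expect_equal(sel$gene, c("b", "a"))  # count desc, then lexicographic
  expect_equal(sel$rank, 1:2)
  expect_error(select_panel(crit, 0), "target_size")

  # a cohort tuned so exactly 75 genes meet >= 1 criterion yields 75
  crit75 <- data.frame(
    gene = sprintf("g%03d", 1:90),
    c1_exclusive_group = c(rep(TRUE, 75), rep(FALSE, 15)),
    c2_recurrent_resistant = FALSE,
    c3_post_only_or_vaf_increase = FALSE,
    c4_literature_platinum = FALSE, c5_tcga_pfs = FALSE,
    n_criteria = c(rep(1L, 75), rep(0L, 15)),
    selected = c(rep(TRUE, 75), rep(FALSE, 15)), stringsAsFactors = FALSE)
  expect_equal(nrow(select_panel(crit75, 75)), 75L)
})

test_that("validate_calls matches keys within sample across platforms", {
  exome <- rbind(
    make_ns_variants("4-1", c(10, 20), gene = c("DNAH5", "Gq")),
    make_ns_variants("4-2", 10, gene = "DNAH5"))
  targeted <- rbind(
    make_ns_variants("4-1", c(10, 30), gene = c("DNAH5", "Gn")),
    make_ns_variants("4-2", 10, gene = "DNAH5"))
  targeted$alt_reads <- 500L; targeted$total_reads <- 5000L
  vr <- validate_calls(exome, targeted)
  # a stable mutation validated at both timepoints
  dn <- vr[vr$gene == "DNAH5", ]
  expect_equal(nrow(dn), 2L)
  expect_true(all(dn$validated))
  expect_equal(unique(dn$targeted_vaf), 0.1)
  # exome-only key is not validated; targeted-only is flagged novel
  expect_false(vr$validated[vr$gene == "Gq"])
  expect_true(vr$novel_on_panel[vr$gene == "Gn"])
  # record count >= max of either platform's calls (symmetric reporting)
  expect_gte(nrow(vr), max(nrow(exome), nrow(targeted)))

  # sample on one platform only -> flagged, not dropped
  ex2 <- make_ns_variants("5-1", 99, gene = "Gz")
  vr2 <- validate_calls(ex2, targeted[0, ],
                        platform_samples = list(exome = "5-1",
                                                targeted = character(0)))
  expect_true(vr2$platform_missing)
  expect_false(vr2$validated)

  # panel restriction drops off-panel genes
  vr3 <- validate_calls(exome, targeted, panel_genes = "DNAH5")
  expect_setequal(vr3$gene, "DNAH5")
})

test_that("cn_flag applies inclusive thresholds and is monotone", {
  expect_equal(cn_flag(c(0, 1, 2, 6.9, 7, 9)),
               c("loss", "loss", "neutral", "neutral", "amplified",
                 "amplified"))
  expect_error(cn_flag(-1), "non-negative")
  expect_error(cn_flag(2, amp_threshold = 1, loss_threshold = 1), "below")
  # monotone: flag level never decreases as cn increases
  lvl <- c(loss = 1, neutral = 2, amplified = 3)
  grid <- seq(0, 12, by = 0.25)
  expect_true(all(diff(lvl[cn_flag(grid)]) >= 0))

  cnt <- cn_flags(data.frame(gene = c("TMED8", "SPATA31D1", "MMRN1"),
                             sample_id = "1-2",
                             tumor_cn = c(8, 1, 2)))
  expect_equal(cnt$flag[cnt$gene == "TMED8"], "amplified")
  expect_equal(cnt$flag[cnt$gene == "SPATA31D1"], "loss")
  expect_equal(cnt$flag[cnt$gene == "MMRN1"], "neutral")
})
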