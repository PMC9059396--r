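test_that("build_presence applies strata before case aggregation", {
  long <- data.frame(
    gene = c("g", "g", "h", "h", "k"),
    case_id = c("A", "A", "A", "B", "B"),
    timepoint = c("pre", "post", "post", "pre", "post"),
    stringsAsFactors = FALSE)
  any_m <- build_presence(long, "any")
  expect_true(any_m["g", "A"] && any_m["h", "B"])
  expect_false(any_m["k", "A"])
  expect_false(build_presence(long, "post_only")["h", "B"])
  expect_true(build_presence(long, "stable_within_case")["g", "A"])
  em <- build_presence(long, "emergent_within_case")
  expect_true(em["h", "A"])      # post without pre in A
  expect_false("g" %in% rownames(em))  # stable genes drop out entirely
  expect_error(build_presence(long, "nope"), "stratum")

  # variant-table input goes through the same path
  samples <- make_samples(c("A", "B"))
  v <- rbind(make_ns_variants("A-pre", 1, gene = "g"),
             make_ns_variants("A-post1", 2, gene = "g"))
  expect_true(build_presence(v, "stable_within_case", samples)["g", "A"])
  expect_error(build_presence(v, "any"), "samples")
})

test_that("exclusivity classifies group-exclusive recurrent genes", {
  groups <- c(R1 = "resistant", R2 = "resistant", S1 = "sensitive")
  long <- data.frame(
    gene = c("g1", "g1", "g2", "g2", "g3"),
    case_id = c("R1", "R2", "R1", "S1", "S1"),
    timepoint = "pre", stringsAsFactors = FALSE)
  ex <- exclusivity(build_presence(long, "any"), groups)
  expect_equal(ex$resistant_exclusive, "g1")
  expect_equal(ex$sensitive_exclusive, "g3")  # all (one) sensitive, no resistant
  expect_length(intersect(ex$resistant_exclusive, ex$sensitive_exclusive), 0)

  # all genes everywhere -> both sets empty
  full <- matrix(TRUE, 2, 3, dimnames = list(c("a", "b"), names(groups)))
  ex2 <- exclusivity(full, groups)
  expect_length(ex2$resistant_exclusive, 0)
  expect_length(ex2$sensitive_exclusive, 0)

  expect_error(exclusivity(full, c(R1 = "resistant", R2 = "resistant",
                                   S1 = "resistant")), "single group")
  expect_error(exclusivity(full, groups[1:2]), "group label")
})

test_that("exclusivity is stable under row/column permutations (property)", {
  set.seed(3)
  groups <- c(R1 = "resistant", R2 = "resistant", R3 = "resistant",
              S1 = "sensitive", S2 = "sensitive")
  for (i in 1:20) {
    m <- matrix(runif(40) < 0.4, 8, 5,
                dimnames = list(paste0("g", 1:8), names(groups)))
    ex <- exclusivity(m, groups)
    pm <- m[sample.int(8), sample.int(5), drop = FALSE]
    ex2 <- exclusivity(pm, groups)
    expect_identical(ex, ex2)
    expect_length(intersect(ex$resistant_exclusive,
                            ex$sensitive_exclusive), 0)
  }
})

test_that("recurrent_genes orders by count then name", {
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE,
                TRUE, TRUE, FALSE, FALSE,
                TRUE, TRUE, FALSE, FALSE),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("zzz", "bbb", "aaa"), paste0("c", 1:4)))
  rec <- recurrent_genes(m, 2)
  expect_equal(names(rec), c("zzz", "aaa", "bbb"))
  expect_equal(unname(rec), c(3L, 2L, 2L))
  expect_error(recurrent_genes(m, 1), ">= 2")
})

test_that("site_venn partitions the gene universe with named categories", {
  sets <- list(pre = c("g"), postA = c("g"), postB = c("g"))
  vv <- site_venn(sets, case_id = "c")
  expect_equal(vv$membership$category, "all_samples")

  # k = 2 disjoint: both exclusive regions populated, intersection empty
  v2 <- site_venn(list(a = c("x"), b = c("y")))
  expect_setequal(v2$membership$region, c("a", "b"))

  # constructed three-sample case: 8 all-sample, 2 emergent both-post,
  # 10 ovary-only, 14 omentum-only
  all8 <- paste0("A", 1:8); both2 <- paste0("B", 1:2)
  ov10 <- paste0("V", 1:10); om14 <- paste0("M", 1:14)
  sets3 <- list(pre = c(all8, paste0("P", 1:5)),
                post_ov = c(all8, both2, ov10),
                post_om = c(all8, both2, om14))
  tp <- c(pre = "pre", post_ov = "post", post_om = "post")
  site <- c(pre = "omentum", post_ov = "ovary", post_om = "omentum")
  v3 <- site_venn(sets3, tp, site, "case3")
  cat3 <- table(v3$membership$category)
  expect_equal(unname(cat3[["all_samples"]]), 8L)
  expect_equal(unname(cat3[["emergent_both_post"]]), 2L)
  expect_equal(unname(cat3[["emergent_site_specific:post_ov"]]), 10L)
  expect_equal(unname(cat3[["emergent_site_specific:post_om"]]), 14L)
  expect_equal(unname(cat3[["pre_only"]]), 5L)
  # regions partition the universe
  expect_equal(nrow(v3$membership), length(unique(unlist(sets3))))
  expect_equal(sum(v3$counts), nrow(v3$membership))

  expect_error(site_venn(list(a = "x")), "at least 2")
  expect_error(site_venn(unname(list(c("x"), c("y")))), "named")
})

test_that("case_unique_genes measures inter-case heterogeneity", {
  long <- data.frame(gene = c("u1", "u2", "s", "s"),
                     case_id = c("A", "B", "A", "B"),
                     timepoint = "pre", stringsAsFactors = FALSE)
  u <- case_unique_genes(build_presence(long, "any"))
  expect_equal(u$unique, c(1L, 1L))
  expect_equal(u$total, c(2L, 2L))
  expect_equal(u$pct, c(50L, 50L))
})
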