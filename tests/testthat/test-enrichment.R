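test_that("index filtering applies the smallest and largest rules", {
  genes <- sprintf("g%03d", 1:200)
  ann <- make_annotation(list(
    small = genes[1:9],        # 9 members: below smallest = 10
    ok = genes[1:12],
    big = genes[1:30]          # 15% of universe: above largest = 0.1
  ))
  idx <- build_go_index(ann, genes, smallest = 10, largest = 0.1)
  expect_setequal(names(idx$categories), "ok")

  # membership is restricted to the universe
  idx2 <- build_go_index(ann, genes[1:50], smallest = 5, largest = 0.5)
  expect_true(all(unlist(idx2$categories) %in% genes[1:50]))
})

test_that("parent propagation closes memberships over ancestors", {
  genes <- sprintf("g%03d", 1:100)
  ann <- make_annotation(list(child = genes[1:10], parent = genes[11:15]))
  ann$parents <- data.frame(child = "child", parent = "parent",
                            stringsAsFactors = FALSE)
  idx <- build_go_index(ann, genes, smallest = 5, largest = 0.5,
                        propagate = TRUE)
  expect_setequal(idx$categories$parent, genes[1:15])
  idx_np <- build_go_index(ann, genes, smallest = 5, largest = 0.5,
                           propagate = FALSE)
  expect_setequal(idx_np$categories$parent, genes[11:15])
})

test_that("adaptive clustering merges by overlap over the smaller set", {
  genes <- sprintf("g%03d", 1:200)
  ann <- make_annotation(list(
    a = genes[1:10],
    a_copy = genes[1:10],                 # identical: d = 0, merged
    b = genes[c(1:6, 30:43)],             # |b| = 20, |a∩b| = 6 -> d = 0.4
    c = genes[100:115]                    # disjoint: d = 1, never merged
  ))
  idx <- build_go_index(ann, genes, smallest = 5, largest = 0.2)
  merged <- cluster_go_terms(idx, cut_height = 0.5, largest = 0.2)
  keys <- names(merged$categories)
  joint <- keys[grepl("a", keys) & grepl("b", keys)]
  expect_length(joint, 1)       # a, a_copy and b merged (complete linkage: d(a,b)=0.4)
  expect_setequal(merged$categories[[joint]], union(genes[1:10], genes[c(1:6, 30:43)]))
  expect_true(any(vapply(merged$categories, setequal, TRUE, genes[100:115])))
})

test_that("merged categories are re-checked against the largest filter", {
  genes <- sprintf("g%03d", 1:100)
  ann <- make_annotation(list(a = genes[1:10], b = genes[6:15]))
  idx <- build_go_index(ann, genes, smallest = 5, largest = 0.12)
  # a and b overlap 5/10 -> d = 0.5, merged at cut 0.5; union has 15 genes
  # which violates largest = 0.12 * 100 = 12 and is dropped
  expect_error(cluster_go_terms(idx, cut_height = 0.5, largest = 0.12),
               "no testable categories")
})

test_that("rank enrichment finds a planted top category on a toy universe", {
  genes <- sprintf("g%02d", 1:20)
  measure <- stats::setNames(seq(0.1, 2, length.out = 20), genes)
  ann <- make_annotation(list(top = genes[16:20], rand = genes[c(2, 5, 9, 13, 17)]))
  idx <- build_go_index(ann, genes, smallest = 3, largest = 0.4)
  res <- mwu_enrichment(measure, idx)
  top <- res[res$category == "top", ]
  expect_gt(top$delta_rank, 0)
  # the category holds exactly the top-5 measures: its p is the smallest
  # achievable for that size (matches the exact MWU of complete separation)
  minimal <- mann_whitney_u(measure[16:20], measure[1:15], mode = "normal")$p_value
  expect_equal(top$p_value, minimal, tolerance = 1e-12)
  expect_lte(top$p_value, min(res$p_value))
})

test_that("delta-rank relates to U and survives monotone transforms", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:80)
  measure <- stats::setNames(rnorm(80), genes)
  ann <- make_annotation(list(a = genes[1:12], b = genes[30:49]))
  idx <- build_go_index(ann, genes, smallest = 5, largest = 0.5)
  res <- mwu_enrichment(measure, idx)
  for (key in res$category) {
    memb <- genes %in% idx$categories[[key]]
    u <- mann_whitney_u(measure[memb], measure[!memb])$u_statistic
    n_m <- sum(memb)
    r <- rank(measure)
    # U = member rank sum - n_m (n_m + 1) / 2
    expect_equal(u, sum(r[memb]) - n_m * (n_m + 1) / 2, tolerance = 1e-9)
  }
  res_exp <- mwu_enrichment(exp(measure), idx)
  expect_equal(res$delta_rank, res_exp$delta_rank)
  expect_equal(res$p_value, res_exp$p_value)
})

test_that("constant measures and whole-universe categories are degenerate", {
  genes <- sprintf("g%02d", 1:30)
  ann <- make_annotation(list(a = genes[1:10]))
  idx <- build_go_index(ann, genes, smallest = 5, largest = 0.5)
  res <- mwu_enrichment(stats::setNames(rep(1, 30), genes), idx)
  expect_equal(res$delta_rank, 0)
  expect_equal(res$p_value, 1)

  idx_all <- structure(
    list(categories = list(a = genes), names = c(a = "a"),
         term_ids = list(a = "a"), universe = genes),
    class = "go_index"
  )
  expect_error(mwu_enrichment(stats::setNames(rnorm(30), genes), idx_all),
               "whole universe")
})

test_that("Fisher enrichment matches the reference on canonical tables", {
  genes <- sprintf("g%03d", 1:100)
  flagged <- genes[1:10]
  ann <- make_annotation(list(exact = flagged, off = genes[50:59]))
  idx <- build_go_index(ann, genes, smallest = 5, largest = 0.2)
  flag <- stats::setNames(genes %in% flagged, genes)
  res <- fisher_enrichment(flag, idx)
  # category identical to the flagged set: minimal configuration p
  p_ref <- stats::fisher.test(matrix(c(10, 0, 0, 90), 2))$p.value
  expect_equal(res$p_value[res$category == "exact"], p_ref, tolerance = 1e-12)
  # disjoint small category: no enrichment
  expect_gt(res$p_value[res$category == "off"], 0.2)

  # the printed example table
  p <- coralfront:::fisher_p_two_sided(8, 2, 2, 88)
  ref <- stats::fisher.test(matrix(c(8, 2, 2, 88), 2))$p.value
  expect_equal(p, ref, tolerance = 1e-10)

  expect_error(fisher_enrichment(stats::setNames(rep(TRUE, 100), genes), idx),
               "constant")
})

test_that("delta-rank correlation matches categories across analyses", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:120)
  ann <- make_annotation(list(a = genes[1:15], b = genes[20:39],
                              c = genes[50:61]))
  idx <- build_go_index(ann, genes, smallest = 5, largest = 0.5)
  m1 <- stats::setNames(rnorm(120), genes)
  res_a <- mwu_enrichment(m1, idx)
  expect_equal(delta_rank_correlation(res_a, res_a)$r, 1)
  res_neg <- res_a
  res_neg$delta_rank <- -res_neg$delta_rank
  expect_equal(delta_rank_correlation(res_a, res_neg)$r, -1)

  small <- res_a[1:2, ]
  attr(small, "members") <- attr(res_a, "members")
  expect_error(delta_rank_correlation(small, small), "fewer than 3")
})
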