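test_that("median-of-ratios size factors follow their defining identities", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  # sample b = 2x sample a over genes (10, 20, 30): factors (1/sqrt(2), sqrt(2))
  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)

  # a gene containing a zero is excluded from the reference set
  m3 <- rbind(m2, g4 = c(0, 100))
  expect_equal(estimate_size_factors(m3), estimate_size_factors(m2))

  # multiplying one sample by c multiplies its factor relative to the other
  # samples by c (the geometric-mean reference itself absorbs c^(1/m), so
  # only factor ratios carry the scaling exactly)
  set.seed(5)
  m4 <- matrix(rpois(60, 50) + 1, ncol = 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  f0 <- estimate_size_factors(m4)
  m5 <- m4; m5[, 2] <- m5[, 2] * 3
  f1 <- estimate_size_factors(m5)
  expect_equal((f1[["s2"]] / f1[["s1"]]) / (f0[["s2"]] / f0[["s1"]]), 3,
               tolerance = 1e-9)

  expect_error(estimate_size_factors(rbind(c(0, 1), c(1, 0))), "all-positive")
})

test_that("BH step-up matches hand computations and the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-14)
  }
})

test_that("dispersion estimation brackets the truth and flags degenerate genes", {
  set.seed(9)
  n <- 12
  design <- cbind(1, rep(0:1, each = n / 2))
  sf <- rep(1, n)
  # Poisson counts: estimates collapse toward zero
  pois <- matrix(rpois(400 * n, 80), ncol = n)
  d_pois <- estimate_dispersions(pois, sf, design)
  expect_lt(median(d_pois$dispersion), 0.01)
  # NB at dispersion 0.5
  nb <- matrix(rnbinom(400 * n, mu = 80, size = 2), ncol = n)
  d_nb <- estimate_dispersions(nb, sf, design)
  expect_gt(median(d_nb$dispersion), 0.3)
  expect_lt(median(d_nb$dispersion), 0.7)
  # all-zero gene: floored and flagged
  z <- rbind(nb[1:50, ], 0)
  d_z <- estimate_dispersions(z, sf, design)
  expect_true(d_z$flagged[51])
  expect_equal(d_z$dispersion[51], 1e-8)
})

test_that("Wald test is null on equal groups and matches log-ratio in the easy limit", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   grp = rep(c("a", "b"), each = 3),
                   mother_colony = "A", stringsAsFactors = FALSE)
  cnt <- matrix(rep(c(50L, 60L, 70L), times = 2), nrow = 1,
                dimnames = list("g1", md$sample_id))
  cnt <- rbind(cnt, g2 = rep(100L, 6))
  res <- suppressMessages(
    wald_nb_test(cnt, md, "grp", c("b", "a"), size_factors = rep(1, 6),
                 dispersions = rep(0.05, 2))
  )
  expect_equal(res$log2fc, c(0, 0), tolerance = 1e-8)
  expect_true(all(res$p_value > 0.99))

  # no covariate, equal size factors, large counts: log2fc converges to the
  # log-ratio of group means
  set.seed(31)
  mu <- c(rep(2000, 4), rep(8000, 4))
  y <- matrix(rnbinom(200 * 8, mu = rep(mu, each = 200), size = 1 / 0.01),
              ncol = 8, dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  md2 <- data.frame(sample_id = paste0("s", 1:8),
                    grp = rep(c("a", "b"), each = 4), mother_colony = "A")
  res2 <- suppressMessages(
    wald_nb_test(y, md2, "grp", c("b", "a"), size_factors = rep(1, 8))
  )
  naive <- log2(rowMeans(y[, 5:8]) / rowMeans(y[, 1:4]))
  expect_equal(res2$log2fc, unname(naive), tolerance = 1e-2)
})

test_that("rank-deficient designs are rejected with the aliased columns named", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   grp = rep(c("a", "b"), each = 3),
                   mother_colony = rep(c("A", "B"), each = 3))
  cnt <- matrix(50L, nrow = 2, ncol = 6,
                dimnames = list(c("g1", "g2"), md$sample_id))
  expect_error(
    suppressMessages(wald_nb_test(cnt, md, "grp", c("b", "a"))),
    "rank deficient"
  )
})

test_that("all-zero genes are dropped with a message", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   grp = rep(c("a", "b"), each = 3), mother_colony = "A")
  set.seed(4)
  cnt <- matrix(rpois(5 * 6, 40), nrow = 5,
                dimnames = list(paste0("g", 1:5), md$sample_id))
  cnt[3, ] <- 0L
  expect_message(
    res <- wald_nb_test(cnt, md, "grp", c("b", "a")),
    "1 all-zero"
  )
  expect_equal(nrow(res), 4)
  expect_false("g3" %in% res$gene_id)
})

test_that("batch removal equalizes additive offsets and preserves treatment effects", {
  set.seed(12)
  base <- matrix(rnorm(50 * 8, mean = 8), nrow = 50)
  colnames(base) <- paste0("s", 1:8)
  batch <- rep(c("A", "B"), times = 4)
  # single batch: identity
  expect_equal(remove_batch_effect(base, rep("A", 8)), base)

  # pure additive offset per batch: batch means equalized to the grand mean
  off <- base + outer(rep(1, 50), ifelse(batch == "B", 2, 0))
  adj <- remove_batch_effect(off, batch)
  for (g in 1:5) {
    expect_equal(mean(adj[g, batch == "A"]), mean(adj[g, batch == "B"]),
                 tolerance = 1e-9)
    expect_equal(mean(adj[g, ]), mean(off[g, ]), tolerance = 1e-9)
  }

  # balanced treatment effect + batch offset: group difference untouched
  treat <- rep(c("c", "t"), each = 4)
  design <- stats::model.matrix(~treat)
  eff <- base + outer(rep(1, 50), ifelse(treat == "t", 1.5, 0)) +
    outer(rep(1, 50), ifelse(batch == "B", 2, 0))
  adj2 <- remove_batch_effect(eff, batch, design = design)
  d_before <- rowMeans(eff[, treat == "t"]) - rowMeans(eff[, treat == "c"])
  d_after <- rowMeans(adj2[, treat == "t"]) - rowMeans(adj2[, treat == "c"])
  expect_equal(d_after, d_before, tolerance = 1e-9)

  expect_error(remove_batch_effect(base, treat, design = design), "confounded")
})

test_that("ordination merges duplicates first and partitions variance", {
  set.seed(3)
  x <- matrix(rnorm(40 * 5), nrow = 40,
              dimnames = list(NULL, paste0("s", 1:5)))
  x <- cbind(x, s6 = x[, "s1"])   # exact duplicate of s1
  ord <- sample_ordination(x)
  dm <- as.matrix(ord$dist)
  expect_equal(dm["s1", "s6"], 0)
  first_merge <- ord$dendrogram$merge[1, ]
  expect_setequal(ord$dendrogram$labels[-first_merge], c("s1", "s6"))
  expect_equal(sum(ord$explained), 1, tolerance = 1e-12)
  expect_error(sample_ordination(x[, 1:2]), "at least 3")
})

test_that("entity separation dominates the first principal component", {
  # entity effect far above noise: a frontloading-only simulation with no
  # depth response, mirroring the ordination where the first axis carries
  # the chimeric status
  design <- sim_design(n_genes = 1000, seed = 19)
  params <- sim_params(response_lfc = 0, basal_shift_lfc = 3,
                       n_frontloaded = 300, n_higher_plasticity = 0,
                       n_both = 0, n_responsive_only = 0)
  sim <- simulate_counts(design, params)
  adj <- remove_batch_effect(normalized_log_counts(sim$counts),
                             sim$metadata$mother_colony)
  ord <- sample_ordination(adj)
  pc1 <- ord$pca_coords[, 1]
  chim <- sim$metadata$entity == "chimera"
  # silhouette-like check: groups separate along PC1
  gap <- abs(mean(pc1[chim]) - mean(pc1[!chim]))
  spread <- sd(pc1[chim]) + sd(pc1[!chim])
  expect_gt(gap, spread)
})
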