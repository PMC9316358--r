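test_that("classification rule reproduces the archetype patterns", {
  resp <- de_row(c("g1", "g2", "g3", "g4"), c(3, 2, 2, 2),
                 c(0.001, 0.001, 0.001, 0.5))
  basal <- de_row(c("g1", "g2", "g3", "g4"), c(2, 0.1, 2, 2),
                  c(0.001, 0.8, 0.001, 0.001))
  chim <- de_row(c("g1", "g2", "g3", "g4"), c(0.2, 4, 4, 4),
                 c(0.9, 0.001, 0.001, 0.001))
  out <- classify_frontloading(resp, basal, chim)
  # g4 is not responsive (fdr 0.5) and never enters
  expect_equal(out$gene_id, c("g1", "g2", "g3"))
  expect_equal(out$category[out$gene_id == "g1"], "FRONTLOADED")
  expect_equal(out$category[out$gene_id == "g2"], "HIGHER_PLASTICITY")
  expect_equal(out$category[out$gene_id == "g3"],
               "FRONTLOADED_AND_HIGHER_PLASTICITY")
})

test_that("opposite-direction amplification and null tables fall through", {
  # significant chimera response in the opposite direction: UNCLASSIFIED
  resp <- de_row("g1", 2, 0.001)
  basal <- de_row("g1", -1, 0.2)
  chim <- de_row("g1", -4, 0.001)
  out <- classify_frontloading(resp, basal, chim)
  expect_equal(out$category, "UNCLASSIFIED")
  # with the sign requirement switched off it counts as higher plasticity
  out2 <- classify_frontloading(resp, basal, chim,
                                require_sign_concordance = FALSE)
  expect_equal(out2$category, "HIGHER_PLASTICITY")

  # all-null responsive table: empty classification
  null_tab <- de_row(c("g1", "g2"), c(0, 0), c(0.9, 0.9))
  expect_equal(nrow(classify_frontloading(null_tab, null_tab, null_tab)), 0)

  # missing genes are named
  expect_error(classify_frontloading(de_row("g9", 2, 0.001), basal, chim), "g9")
})

test_that("classification is invariant to gene order", {
  set.seed(8)
  ids <- paste0("g", 1:50)
  resp <- de_row(ids, rnorm(50, 0, 2), runif(50))
  basal <- de_row(ids, rnorm(50, 0, 2), runif(50))
  chim <- de_row(ids, rnorm(50, 0, 2), runif(50))
  a <- classify_frontloading(resp, basal, chim)
  perm <- sample(50)
  b <- classify_frontloading(resp[perm, ], basal[rev(perm), ], chim[perm, ])
  b <- b[match(a$gene_id, b$gene_id), ]
  expect_equal(a$category, b$category)
})

test_that("DAPC recovers a planted discriminant direction", {
  set.seed(15)
  n <- 20
  dir_true <- c(1, 1) / sqrt(2)
  shift <- 4
  pts <- rbind(
    t(matrix(rnorm(2 * n), 2) + 0),
    t(matrix(rnorm(2 * n), 2) + shift * dir_true)
  )                                  # samples x 2 "genes"
  x <- t(pts)                        # genes x samples
  rownames(x) <- c("g1", "g2")
  colnames(x) <- paste0("s", seq_len(2 * n))
  groups <- rep(c("a", "b"), each = n)
  model <- fit_dapc(x, groups, n_pcs = 2)
  # back-map the discriminant to gene space and compare angles
  w <- drop(model$loadings %*% model$coef)
  w <- w / sqrt(sum(w^2))
  angle <- acos(pmin(abs(sum(w * dir_true)), 1)) * 180 / pi
  expect_lt(angle, 10)
})

test_that("DAPC model invariants: stored coordinates, sign symmetry, projection", {
  set.seed(16)
  x <- matrix(rnorm(30 * 8), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  x[, 5:8] <- x[, 5:8] + 1
  groups <- rep(c("a", "b"), each = 4)
  model <- fit_dapc(x, groups, n_pcs = 3)

  expect_equal(project_dapc(model, x), model$coords, tolerance = 1e-10,
               ignore_attr = TRUE)
  # swapping labels flips every coordinate (deterministic sign convention
  # re-anchors, so compare up to a global sign)
  model2 <- fit_dapc(x, rev(groups), n_pcs = 3)
  expect_equal(abs(model2$coords), abs(model$coords), tolerance = 1e-8)

  # projecting a training-group centroid returns that group's mean coordinate
  centroid <- rowMeans(x[, groups == "a"])
  expect_equal(unname(project_dapc(model, matrix(centroid))),
               unname(model$group_means[["a"]]), tolerance = 1e-10)
  # all-zero sample equals the projection of minus the center
  z <- project_dapc(model, matrix(0, nrow = 30))
  manual <- drop(crossprod(-model$center, model$loadings) %*% model$coef)
  expect_equal(unname(z), manual, tolerance = 1e-12)

  expect_error(fit_dapc(x, rep(c("a", "b", "c"), length.out = 8)), "two groups")
  expect_error(fit_dapc(x, c("a", rep("b", 7))), "at least 2")
  expect_error(fit_dapc(x, groups, n_pcs = 7), "n_pcs")
  expect_error(project_dapc(model, x[1:10, ]), "mismatch")
})

test_that("full-rank DAPC equals plain LDA up to sign", {
  set.seed(17)
  n <- 12
  x <- matrix(rnorm(6 * n), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
  x[, 7:12] <- x[, 7:12] + 1.5
  groups <- factor(rep(c("a", "b"), each = 6))
  model <- fit_dapc(x, groups, n_pcs = 6)
  lda_fit <- MASS::lda(t(x), grouping = groups)
  lda_coords <- drop(scale(t(x), center = colMeans(t(x)), scale = FALSE) %*%
                       lda_fit$scaling)
  ours <- model$coords / sd(model$coords)
  theirs <- lda_coords / sd(lda_coords)
  flip <- sign(sum(ours * theirs))
  expect_equal(ours, flip * theirs, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("plasticity metrics: degenerate equality and variance monotonicity", {
  md <- data.frame(
    sample_id = paste0("s", 1:8),
    entity = rep(c("chimera", "nonchimera"), each = 4),
    depth = rep(c("10m", "10m", "2m", "2m"), 2)
  )
  coords <- c(1, 2, 1, 2, 0, 4, 0, 4)
  m <- plasticity_metrics(coords, md)
  expect_equal(m$shift[m$entity == "chimera"], 0)
  expect_equal(m$overlap[m$entity == "chimera"], 1)

  # diversity grows with injected coordinate spread: scaling one entity's
  # coordinates scales its pooled within-condition variance quadratically
  set.seed(22)
  z <- rnorm(4)
  divs <- vapply(c(0.5, 1, 2, 4), function(s) {
    cc <- c(s * z, rnorm(4, 0, 0.1))
    plasticity_metrics(cc, md)$diversity[1]
  }, numeric(1))
  expect_false(is.unsorted(divs))

  md_bad <- md[md$depth == "10m", ]
  expect_error(plasticity_metrics(coords[md$depth == "10m"], md_bad),
               "empty entity x depth")
})

test_that("fit-and-project recovers the reduced chimera response pattern", {
  ps <- sim_preset("frontload_heavy", seed = 33)
  sim <- simulate_counts(ps$design, ps$params)
  adj <- remove_batch_effect(normalized_log_counts(sim$counts),
                             sim$metadata$mother_colony)
  dp <- dapc_plasticity(adj, sim$metadata)
  m <- dp$metrics
  expect_lt(m$shift[m$entity == "chimera"], m$shift[m$entity == "nonchimera"])
  # held-out samples from the training groups land nearer their own centroid
  design10 <- sim_design(replicates = c(chimera_10m = 2, chimera_2m = 2,
                                        nonchimera_10m = 10, nonchimera_2m = 10),
                         seed = 35)
  sim3 <- simulate_counts(design10, sim_preset("frontload_heavy")$params)
  adj3 <- remove_batch_effect(normalized_log_counts(sim3$counts),
                              sim3$metadata$mother_colony)
  nc <- which(sim3$metadata$entity == "nonchimera")
  hold <- nc[c(1:5, 11:15)]
  train <- setdiff(nc, hold)
  model <- fit_dapc(adj3[, train],
                    factor(sim3$metadata$depth[train], levels = c("10m", "2m")))
  proj <- project_dapc(model, adj3[, hold, drop = FALSE])
  own <- sim3$metadata$depth[hold]
  other <- ifelse(own == "10m", "2m", "10m")
  nearer <- abs(proj - model$group_means[own]) <
    abs(proj - model$group_means[other])
  expect_gte(mean(nearer), 0.9)
})
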