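#' Filter an OTU table by relative abundance and singletons
#'
#' Removes OTUs whose total count across samples is below `min_fraction` of
#' the grand total, and (optionally) singletons (total count 1).
#'
#' @param counts integer matrix, OTUs x samples.
#' @param min_fraction minimum total relative abundance in `[0, 1)`.
#' @param drop_singletons remove OTUs with a total count of 1.
#' @return filtered matrix; a warning is raised if nothing survives.
#' @export
filter_otu_table <- function(counts, min_fraction = 0.01,
                             drop_singletons = TRUE) {
  counts <- as.matrix(counts)
  if (min_fraction < 0 || min_fraction >= 1) fail("min_fraction must be in [0, 1)")
  totals <- rowSums(counts)
  keep <- totals / sum(totals) >= min_fraction
  if (drop_singletons) keep <- keep & totals > 1
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("empty OTU table after filtering", call. = FALSE)
  out
}

#' Per-sample alpha diversity: observed richness, Chao1, Shannon
#'
#' Observed richness counts OTUs with nonzero counts. Chao1 is the
#' bias-corrected estimator `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1/F2
#' the singleton and doubleton counts (it reduces to S_obs when F1 = 0 and
#' stays finite when F2 = 0). Shannon is `-sum p_i log p_i` over nonzero
#' proportions, natural log by default.
#'
#' @param counts integer matrix, OTUs x samples; all sample totals must be
#'   positive.
#' @param base logarithm base for Shannon (`exp(1)` or 2).
#' @return data.frame: sample_id, observed, chao1, shannon.
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) fail("zero-total sample in OTU table")
  shannon <- vegan::diversity(t(counts), index = "shannon", base = base)
  est <- vegan::estimateR(t(counts))
  data.frame(sample_id = colnames(counts),
             observed = as.integer(est["S.obs", ]),
             chao1 = unname(est["S.chao1", ]),
             shannon = unname(shannon),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y)` on the raw
#' counts (the measure is scale-sensitive by construction; the pipeline does
#' not rarefy by default).
#'
#' @param counts integer matrix, OTUs x samples (>= 2 samples).
#' @return symmetric matrix of dissimilarities with zero diagonal.
#' @export
bray_curtis_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) fail("need at least 2 samples")
  if (any(colSums(counts) == 0)) {
    warning("all-zero sample: Bray-Curtis undefined for its pairs", call. = FALSE)
  }
  as.matrix(vegan::vegdist(t(counts), method = "bray"))
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers the squared dissimilarities and eigendecomposes; axes are
#' ordered by eigenvalue and axes with negative eigenvalues are dropped with
#' a logged count (they arise when the dissimilarity is not
#' Euclidean-embeddable).
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @return list with `coords` (samples x axes), `eigenvalues` (all, ordered),
#'   `n_negative`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    fail("dissimilarity matrix must be square and symmetric")
  }
  n <- nrow(d)
  # cmdscale warns when fewer than k axes carry positive eigenvalues; the
  # eigenvalue handling below makes that explicit instead
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- cs$eig
  n_neg <- sum(eig < -1e-8 * max(abs(eig)))
  if (n_neg > 0) {
    message(sprintf("dropping %d negative-eigenvalue axis/axes", n_neg))
  }
  pos <- which(eig > 1e-8 * max(abs(eig)))
  coords <- cs$points[, seq_along(pos), drop = FALSE]
  rownames(coords) <- rownames(d)
  list(coords = coords, eigenvalues = eig, n_negative = n_neg)
}

#' Group tests on alpha-diversity indices
#'
#' One-way ANOVA of each index (observed, Chao1, Shannon) across the
#' grouping, with BH adjustment across the three indices. A two-factor
#' (entity + depth) decomposition is available behind a flag.
#'
#' @param report [alpha_diversity()] result.
#' @param metadata data.frame with sample_id and the grouping columns.
#' @param grouping column name(s): one column for one-way ANOVA over its
#'   levels (default the four entity x depth cells via `interaction`), two
#'   for the additive two-factor model.
#' @param two_factor fit the additive two-factor model instead of one-way
#'   ANOVA over the interaction groups.
#' @return data.frame: index, f_statistic, p_value, fdr.
#' @export
test_alpha_diversity <- function(report, metadata,
                                 grouping = c("entity", "depth"),
                                 two_factor = FALSE) {
  m <- merge(report, metadata, by = "sample_id")
  for (g in grouping) m[[g]] <- factor(m[[g]])
  if (!two_factor) {
    grp <- interaction(m[, grouping, drop = FALSE], drop = TRUE)
    if (nlevels(grp) < 2) fail("need at least 2 groups")
    if (any(table(grp) < 2)) fail("each group needs at least 2 samples")
  }
  idx <- c("observed", "chao1", "shannon")
  res <- lapply(idx, function(ix) {
    if (stats::var(m[[ix]]) == 0) {
      # no variation at all: nothing to explain
      return(data.frame(index = ix, f_statistic = 0, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    if (two_factor) {
      fit <- stats::aov(stats::reformulate(grouping, response = ix), data = m)
      tab <- summary(fit)[[1]]
      data.frame(index = ix,
                 f_statistic = tab[1, "F value"],
                 p_value = tab[1, "Pr(>F)"], stringsAsFactors = FALSE)
    } else {
      grp <- interaction(m[, grouping, drop = FALSE], drop = TRUE)
      fit <- stats::aov(m[[ix]] ~ grp)
      tab <- summary(fit)[[1]]
      data.frame(index = ix,
                 f_statistic = tab["grp", "F value"],
                 p_value = tab["grp", "Pr(>F)"], stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res$fdr <- bh_adjust(res$p_value)
  res
}

#' Full microbiome diversity report
#'
#' Filter, alpha diversity, Bray-Curtis, PCoA and the per-index group tests,
#' in the fixed order filter -> diversity (filtering changes alpha diversity,
#' so the order is part of the contract).
#'
#' @param counts OTU count matrix.
#' @param metadata sample metadata with the grouping columns.
#' @param min_fraction,drop_singletons passed to [filter_otu_table()].
#' @param grouping passed to [test_alpha_diversity()].
#' @return list with `filtered`, `alpha`, `bray_curtis`, `pcoa`, `tests`.
#' @export
microbiome_report <- function(counts, metadata, min_fraction = 0.01,
                              drop_singletons = TRUE,
                              grouping = c("entity", "depth")) {
  filtered <- filter_otu_table(counts, min_fraction, drop_singletons)
  alpha <- alpha_diversity(filtered)
  bc <- bray_curtis_matrix(filtered)
  ord <- pcoa(bc)
  tests <- test_alpha_diversity(alpha, metadata, grouping)
  list(filtered = filtered, alpha = alpha, bray_curtis = bc, pcoa = ord,
       tests = tests)
}
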