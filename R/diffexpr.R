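#' Median-of-ratios size factors
#'
#' For every gene with all-positive counts, each sample's count is divided by
#' the gene's geometric mean across samples; the sample's size factor is the
#' median of those ratios. Genes containing any zero are excluded from the
#' reference set, so adding such a gene leaves the factors unchanged.
#'
#' @param counts integer matrix, genes x samples.
#' @return positive numeric vector of per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) fail("no gene with all-positive counts: cannot form the reference")
  ref <- counts[all_pos, , drop = FALSE]
  log_geo <- rowMeans(log(ref))
  sf <- apply(ref, 2, function(col) exp(stats::median(log(col) - log_geo)))
  stats::setNames(sf, colnames(counts))
}

#' Normalized log counts (rlog stand-in)
#'
#' `log2(count / size_factor + 1)`: a monotone, variance-damping transform of
#' the normalized counts used for ordination, batch-effect removal and the
#' plasticity projection.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors optional precomputed factors.
#' @return numeric matrix of the same shape.
#' @export
normalized_log_counts <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  log2(sweep(as.matrix(counts), 2, size_factors, "/") + 1)
}

# model matrix for ~ condition + mother_colony on a metadata subset;
# condition level order fixes the contrast sign (second level vs first)
de_design_matrix <- function(metadata, condition, levels) {
  cond <- factor(metadata[[condition]], levels = levels)
  mm <- if (length(unique(metadata$mother_colony)) > 1) {
    stats::model.matrix(~ cond + factor(metadata$mother_colony))
  } else {
    stats::model.matrix(~ cond)
  }
  colnames(mm)[2] <- "condition"
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    fail("design matrix is rank deficient; aliased columns: %s",
         paste(aliased, collapse = ", "))
  }
  mm
}

#' Per-gene dispersion estimates with trend shrinkage
#'
#' Per gene, fitted means come from a Poisson log-linear fit of the counts on
#' the design (log size factors as offsets); the raw dispersion is the
#' leverage-corrected method-of-moments estimate
#' `sum((y - mu)^2 - (1 - h) mu) / sum((1 - h) mu^2)`, with `h` the hat
#' values of the weighted fit — the correction matters when the design uses
#' a sizable share of the samples' degrees of freedom, as the mother-colony
#' covariate does. Raw estimates are shrunk toward a mean-dispersion trend
#' `a0 + a1 / mean` (least squares through binned means of the raw
#' estimates) with a configurable weight, and floored at 1e-8. All-zero
#' genes receive the floor and a flag.
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors per-sample factors.
#' @param design model matrix (residual df must be >= 2).
#' @param shrink_weight weight of the trend in the weighted average. The
#'   default 0.85 corresponds to empirical-Bayes-style moderation with a
#'   prior worth about eleven degrees of freedom against the roughly two
#'   residual degrees of freedom the translocation design leaves per gene.
#' @return data.frame with dispersion, raw (unshrunk), trend, flagged.
#' @export
estimate_dispersions <- function(counts, size_factors, design,
                                 shrink_weight = 0.85) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  p <- ncol(design)
  if (n - p < 2) fail("fewer than 2 residual degrees of freedom")
  offs <- log(size_factors)
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  flagged <- base_mean == 0
  raw <- rep(NA_real_, nrow(counts))
  mom_pass <- function(pilot_disp) {
    out <- rep(NA_real_, nrow(counts))
    for (g in which(!flagged)) {
      y <- counts[g, ]
      fam <- if (pilot_disp[g] > 1e-8) {
        MASS::negative.binomial(theta = 1 / pilot_disp[g])
      } else {
        stats::poisson()
      }
      fit <- suppressWarnings(
        stats::glm.fit(design, y, family = fam, offset = offs)
      )
      mu <- pmax(fit$fitted.values, 1e-8)
      q <- qr.Q(fit$qr)[, seq_len(fit$qr$rank), drop = FALSE]
      h <- pmin(rowSums(q^2), 1 - 1e-6)
      # left unclamped: clamping at zero would bias the trend upward for
      # genes near the Poisson limit
      out[g] <- sum((y - mu)^2 - (1 - h) * mu) / sum((1 - h) * mu^2)
    }
    out
  }
  # pass 1 with Poisson working weights, pass 2 with NB weights at the
  # pooled pass-1 estimate (Poisson leverages under-correct where the
  # quadratic variance term dominates)
  raw <- mom_pass(rep(0, nrow(counts)))
  pilot <- max(stats::median(raw[!flagged], na.rm = TRUE), 0)
  raw <- mom_pass(rep(pilot, nrow(counts)))
  # trend through binned means of the raw estimates (robust to per-gene
  # noise); when the expression range is too narrow to anchor the 1/mean
  # term, or the unconstrained fit leaves the positive quadrant, fall back
  # to the constant trend
  trend <- rep(max(mean(raw[!flagged]), 0), nrow(counts))
  ok <- which(!flagged)
  if (length(ok) >= 50) {
    bins <- cut(rank(base_mean[ok], ties.method = "first"),
                breaks = 10, labels = FALSE)
    bm <- tapply(base_mean[ok], bins, mean)
    br <- tapply(raw[ok], bins, mean)
    if (max(bm) / min(bm) > 1.5) {
      a <- tryCatch(stats::coef(stats::lm(br ~ I(1 / bm))),
                    error = function(e) c(NA_real_, NA_real_))
      if (all(is.finite(a)) && all(a >= 0)) {
        trend <- a[1] + a[2] / pmax(base_mean, 1e-8)
      }
    }
  }
  disp <- (1 - shrink_weight) * raw + shrink_weight * trend
  disp <- pmax(disp, 1e-8)
  disp[flagged] <- 1e-8
  data.frame(dispersion = disp, raw = pmax(raw, 0), trend = trend,
             flagged = flagged, row.names = rownames(counts))
}

#' Negative-binomial Wald test for one contrast
#'
#' Fits, per gene, a negative-binomial log-linear model
#' `~ condition + mother_colony` by iteratively reweighted least squares with
#' the dispersion held fixed, using the log size factors as offsets. The Wald
#' statistic is the condition coefficient over its standard error; the
#' two-sided p-value comes from the standard normal. Fold changes are
#' reported in log2 units; `log2fc > 0` means higher in the first-named
#' level of `contrast`.
#'
#' @param counts integer matrix, genes x samples (all samples to be fitted —
#'   subset to the contrast's stratum first; [de_contrast()] does this).
#' @param metadata data.frame aligned with the columns of `counts`, with the
#'   condition column and `mother_colony`.
#' @param condition name of the metadata column to test.
#' @param contrast length-2 character: `c(level_up, level_ref)`; the
#'   coefficient is level_up vs level_ref.
#' @param size_factors optional; estimated from `counts` when missing.
#' @param dispersions optional per-gene vector; estimated when missing.
#' @return data.frame (one row per kept gene): gene_id, base_mean, log2fc,
#'   se, wald_stat, p_value, fdr, contrast. Genes with zero counts in all
#'   samples are dropped (a message reports how many).
#' @export
wald_nb_test <- function(counts, metadata, condition, contrast,
                         size_factors = NULL, dispersions = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(metadata)) fail("counts/metadata dimension mismatch")
  if (!all(colnames(counts) == metadata$sample_id)) {
    fail("counts columns and metadata sample_id must align")
  }
  lv <- metadata[[condition]]
  if (!all(contrast %in% lv)) fail("contrast levels absent from metadata")
  # reference level first so the coefficient is contrast[1] vs contrast[2]
  mm <- de_design_matrix(metadata, condition, levels = c(contrast[2], contrast[1]))

  keep <- rowSums(counts) > 0
  n_drop <- sum(!keep)
  if (n_drop > 0) message(sprintf("dropping %d all-zero gene(s)", n_drop))
  counts <- counts[keep, , drop = FALSE]

  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, size_factors, mm)$dispersion
  }
  offs <- log(size_factors)
  ci <- match("condition", colnames(mm))

  n_genes <- nrow(counts)
  beta <- se <- base_mean <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    fam <- MASS::negative.binomial(theta = 1 / max(dispersions[g], 1e-8))
    fit <- suppressWarnings(
      stats::glm.fit(mm, y, family = fam, offset = offs,
                     control = list(maxit = 50))
    )
    cov_u <- tryCatch(chol2inv(fit$qr$qr[seq_len(fit$qr$rank),
                                         seq_len(fit$qr$rank), drop = FALSE]),
                      error = function(e) NULL)
    if (!is.null(cov_u) && fit$qr$rank == ncol(mm)) {
      beta[g] <- fit$coefficients[ci]
      se[g] <- sqrt(cov_u[ci, ci])
    }
    base_mean[g] <- mean(y / size_factors)
  }
  log2fc <- beta / log(2)
  se2 <- se / log(2)
  stat <- log2fc / se2
  p <- 2 * stats::pnorm(-abs(stat))
  p[is.na(p)] <- 1
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             log2fc = log2fc, se = se2, wald_stat = stat, p_value = p,
             fdr = bh_adjust(p),
             contrast = paste(contrast, collapse = "_vs_"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run one of the study's four contrasts by stratum subsetting
#'
#' The entity contrasts (chimera vs non-chimera) are run within one depth;
#' the depth contrasts (2m vs 10m) within one entity — each as a separate
#' two-factor fit with the mother-colony covariate, as the design formula
#' `~ treatment + mother_colony` implies.
#'
#' @param counts full count matrix.
#' @param metadata full sample metadata.
#' @param what `"entity"` or `"depth"`.
#' @param within stratum level: a depth for `what = "entity"`, an entity for
#'   `what = "depth"`.
#' @return [wald_nb_test()] result; log2fc > 0 means higher in chimeras
#'   (entity contrasts) or at 2 m (depth contrasts).
#' @export
de_contrast <- function(counts, metadata, what = c("entity", "depth"), within) {
  what <- match.arg(what)
  stratum <- if (what == "entity") "depth" else "entity"
  keep <- metadata[[stratum]] == within
  if (!any(keep)) fail("no samples in stratum %s = %s", stratum, within)
  md <- droplevels(metadata[keep, , drop = FALSE])
  contrast <- if (what == "entity") c("chimera", "nonchimera") else c("2m", "10m")
  res <- wald_nb_test(counts[, keep, drop = FALSE], md, what, contrast)
  res$contrast <- paste0(res$contrast, "_at_", within)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `fdr_(i) = min_{j >= i} ( m * p_(j) / j )`, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) fail("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[o]))
  out[ok][o] <- adj
  out
}

#' Remove a batch effect from log-scale expression values
#'
#' Fits, per gene, a linear model with the batch and the retained design
#' columns and subtracts the fitted batch coefficients from the data,
#' leaving the retained-design effects untouched (the procedure behind
#' limma's removeBatchEffect, which is used here).
#'
#' @param log_counts numeric matrix, genes x samples (log scale).
#' @param batch vector of batch labels (mother colonies), one per sample.
#' @param design retained-design model matrix (default intercept only).
#' @return adjusted matrix, same shape.
#' @export
remove_batch_effect <- function(log_counts, batch,
                                design = matrix(1, ncol(log_counts), 1)) {
  log_counts <- as.matrix(log_counts)
  batch <- as.factor(batch)
  if (length(batch) != ncol(log_counts)) fail("one batch label per sample required")
  if (nlevels(batch) < 2) return(log_counts)
  bm <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  if (qr(cbind(design, bm))$rank < ncol(design) + ncol(bm)) {
    fail("batch is confounded with the retained design")
  }
  limma::removeBatchEffect(log_counts, batch = batch, design = design)
}

#' Sample ordination: distances, dendrogram and PCA
#'
#' Euclidean distances on the adjusted log counts, average-linkage
#' hierarchical clustering, and centered PCA with explained-variance
#' fractions.
#'
#' @param adjusted numeric matrix, genes x samples.
#' @return list with `dist` (dist object), `dendrogram` (hclust),
#'   `pca_coords` (samples x PCs), `explained` (variance fractions).
#' @export
sample_ordination <- function(adjusted) {
  adjusted <- as.matrix(adjusted)
  if (ncol(adjusted) < 3) fail("ordination needs at least 3 samples")
  x <- t(adjusted)
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "average")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(dist = d, dendrogram = hc, pca_coords = pc$x, explained = expl)
}
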