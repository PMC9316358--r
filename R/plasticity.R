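#' Classify stress-responsive genes into frontloading categories
#'
#' Starting from the genes that respond to the translocation in non-chimeras
#' (`responsive$fdr < alpha`), each gene is categorized from two further
#' contrasts:
#' * frontloaded flag: significantly higher basal expression in chimeras
#'   (`basal$fdr < alpha` and `basal$log2fc > 0`);
#' * higher-plasticity flag: a significant chimera response that is larger in
#'   magnitude than the non-chimera response and in the same direction
#'   (`chimera_response$fdr < alpha`, `|chimera| > |non-chimera|`, signs
#'   concordant).
#'
#' Both flags give FRONTLOADED_AND_HIGHER_PLASTICITY; only the first,
#' FRONTLOADED; only the second, HIGHER_PLASTICITY; a gene matching neither
#' (including an opposite-direction amplified response) is UNCLASSIFIED.
#' Each condition can be switched off, which widens the corresponding flag.
#'
#' @param responsive DE result for the non-chimera depth response (2m vs 10m).
#' @param basal DE result for chimera vs non-chimera at 10 m.
#' @param chimera_response DE result for the chimera depth response.
#' @param alpha FDR threshold, in (0, 1).
#' @param require_basal_significance,require_magnitude,require_sign_concordance
#'   individually switchable classification conditions.
#' @return data.frame: gene_id, category, and the log2fc/fdr pairs of the
#'   three contrasts; one row per responsive gene.
#' @export
classify_frontloading <- function(responsive, basal, chimera_response,
                                  alpha = 0.05,
                                  require_basal_significance = TRUE,
                                  require_magnitude = TRUE,
                                  require_sign_concordance = TRUE) {
  if (alpha <= 0 || alpha >= 1) fail("alpha must be in (0, 1)")
  sel <- responsive[!is.na(responsive$fdr) & responsive$fdr < alpha, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(data.frame(gene_id = character(0), category = character(0)))
  }
  miss_b <- setdiff(sel$gene_id, basal$gene_id)
  miss_c <- setdiff(sel$gene_id, chimera_response$gene_id)
  if (length(miss_b) + length(miss_c) > 0) {
    fail("genes missing from companion tables: %s",
         paste(unique(c(miss_b, miss_c)), collapse = ", "))
  }
  b <- basal[match(sel$gene_id, basal$gene_id), ]
  cr <- chimera_response[match(sel$gene_id, chimera_response$gene_id), ]

  front <- b$log2fc > 0
  if (require_basal_significance) front <- front & b$fdr < alpha

  plast <- cr$fdr < alpha
  if (require_magnitude) plast <- plast & abs(cr$log2fc) > abs(sel$log2fc)
  if (require_sign_concordance) plast <- plast & sign(cr$log2fc) == sign(sel$log2fc)

  front[is.na(front)] <- FALSE
  plast[is.na(plast)] <- FALSE
  category <- ifelse(front & plast, "FRONTLOADED_AND_HIGHER_PLASTICITY",
                     ifelse(front, "FRONTLOADED",
                            ifelse(plast, "HIGHER_PLASTICITY", "UNCLASSIFIED")))
  data.frame(gene_id = sel$gene_id, category = category,
             responsive_log2fc = sel$log2fc, responsive_fdr = sel$fdr,
             basal_log2fc = b$log2fc, basal_fdr = b$fdr,
             chimera_log2fc = cr$log2fc, chimera_fdr = cr$fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a two-group DAPC model
#'
#' Discriminant analysis of principal components: the training samples are
#' centered, reduced by PCA (singular value decomposition), and a linear
#' discriminant with pooled within-group covariance is fit on the retained PC
#' scores. With two groups there is a single discriminant axis. The model
#' stores everything needed to project new samples. The axis sign is fixed by
#' making the largest-magnitude discriminant loading positive.
#'
#' @param x numeric matrix, genes x training samples (adjusted log counts).
#' @param groups length-`ncol(x)` vector with exactly two levels and at least
#'   two samples each.
#' @param n_pcs number of PCs to retain, or a fraction in (0, 1): the
#'   smallest number of PCs explaining at least that variance fraction. The
#'   default keeps >= 80% of variance, capped at `n_train - 3` (and at least
#'   1).
#' @return object of class `dapc_model`.
#' @export
fit_dapc <- function(x, groups, n_pcs = 0.8) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (length(groups) != ncol(x)) fail("one group label per training sample required")
  if (nlevels(groups) != 2) fail("exactly two groups required")
  if (any(table(groups) < 2)) fail("each group needs at least 2 samples")
  n <- ncol(x)
  center <- rowMeans(x)
  xc <- t(x - center)                     # samples x genes
  sv <- svd(xc)
  expl <- sv$d^2 / sum(sv$d^2)
  max_rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_pcs < 1) {
    k <- which(cumsum(expl) >= n_pcs)[1]
    k <- min(k, max(n - 3, 1), max_rank)
  } else {
    if (n_pcs >= n - 1) fail("n_pcs must be < n_samples - 1")
    k <- min(as.integer(n_pcs), max_rank)
  }
  loadings <- sv$v[, seq_len(k), drop = FALSE]      # genes x k
  scores <- xc %*% loadings                          # samples x k

  # one-axis LDA on the PC scores, pooled within-group covariance
  m1 <- colMeans(scores[groups == levels(groups)[1], , drop = FALSE])
  m2 <- colMeans(scores[groups == levels(groups)[2], , drop = FALSE])
  w <- matrix(0, k, k)
  for (lv in levels(groups)) {
    s <- scores[groups == lv, , drop = FALSE]
    s <- sweep(s, 2, colMeans(s))
    w <- w + crossprod(s)
  }
  w <- w / (n - 2)
  coef <- solve(w, m2 - m1)
  coef <- coef / sqrt(sum(coef^2))
  if (coef[which.max(abs(coef))] < 0) coef <- -coef  # deterministic sign

  coords <- drop(scores %*% coef)
  group_means <- tapply(coords, groups, mean)
  structure(
    list(center = center, loadings = loadings, coef = coef,
         n_pcs = k, explained = expl[seq_len(k)],
         groups = groups, coords = coords, group_means = group_means,
         gene_ids = rownames(x)),
    class = "dapc_model"
  )
}

#' Project new samples onto a fitted DAPC discriminant axis
#'
#' Centers the new samples with the training center and applies the stored
#' PC loadings and discriminant coefficients.
#'
#' @param model a [fit_dapc()] result.
#' @param x numeric matrix, genes x new samples, sharing the model's gene
#'   universe and order.
#' @return named numeric vector of discriminant coordinates.
#' @export
project_dapc <- function(model, x) {
  x <- as.matrix(x)
  if (nrow(x) != length(model$center)) fail("gene universe mismatch")
  if (!is.null(model$gene_ids) && !is.null(rownames(x)) &&
      !all(rownames(x) == model$gene_ids)) {
    fail("gene ids or order differ from the training data")
  }
  drop(crossprod(x - model$center, model$loadings) %*% model$coef)
}

#' Plasticity metrics from discriminant coordinates
#'
#' Per entity: `shift` is the absolute difference between the mean
#' coordinate under stress (2 m) and control (10 m); `overlap` is the
#' symmetric range-overlap fraction (the fraction of stressed coordinates
#' inside the control range and vice versa, averaged); `diversity` is the
#' coordinate variance pooled within the two conditions.
#'
#' @param coords numeric vector of discriminant coordinates.
#' @param metadata data.frame aligned with `coords`, columns entity and
#'   depth; all four entity x depth cells must be non-empty.
#' @return data.frame with one row per entity: entity, shift, overlap,
#'   diversity.
#' @export
plasticity_metrics <- function(coords, metadata) {
  if (length(coords) != nrow(metadata)) fail("coords/metadata length mismatch")
  out <- lapply(unique(metadata$entity), function(ent) {
    ctl <- coords[metadata$entity == ent & metadata$depth == "10m"]
    str <- coords[metadata$entity == ent & metadata$depth == "2m"]
    if (length(ctl) == 0 || length(str) == 0) {
      fail("empty entity x depth cell for entity %s", ent)
    }
    inside <- function(v, ref) mean(v >= min(ref) & v <= max(ref))
    pooled_var <- function(a, b) {
      (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
        max(length(a) + length(b) - 2, 1)
    }
    data.frame(entity = ent,
               shift = abs(mean(str) - mean(ctl)),
               overlap = (inside(str, ctl) + inside(ctl, str)) / 2,
               diversity = pooled_var(ctl, str),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit-and-project plasticity analysis
#'
#' Fits the DAPC on the non-chimera samples with depth as the grouping (the
#' translocation axis), projects the chimera samples onto the discriminant
#' axis, and computes [plasticity_metrics()] for both entities.
#'
#' @param adjusted batch-adjusted log counts, genes x samples.
#' @param metadata sample metadata (sample_id, entity, depth) aligned with
#'   the columns of `adjusted`.
#' @param n_pcs passed to [fit_dapc()].
#' @return list with `model`, `coords` (all samples, training coordinates
#'   for non-chimeras, projections for chimeras) and `metrics`.
#' @export
dapc_plasticity <- function(adjusted, metadata, n_pcs = 0.8) {
  train <- metadata$entity == "nonchimera"
  model <- fit_dapc(adjusted[, train, drop = FALSE],
                    factor(metadata$depth[train], levels = c("10m", "2m")),
                    n_pcs = n_pcs)
  coords <- numeric(nrow(metadata))
  coords[train] <- model$coords
  coords[!train] <- project_dapc(model, adjusted[, !train, drop = FALSE])
  names(coords) <- metadata$sample_id
  list(model = model, coords = coords,
       metrics = plasticity_metrics(coords, metadata))
}
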