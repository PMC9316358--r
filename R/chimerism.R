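#' Classify a colony as chimeric from its microsatellite genotype
#'
#' A colony is called chimeric when at least one typed locus carries more
#' than two distinct alleles: sibling fusion partners share a mother, so only
#' a third allele at some locus proves two co-occurring genomes. Duplicate
#' allele entries are collapsed before counting.
#'
#' @param loci named list: locus -> vector of allele labels (fragment sizes).
#' @return list with `is_chimera` (logical) and `triggering_loci` (character
#'   vector of loci with > 2 distinct alleles).
#' @export
classify_microsat <- function(loci) {
  if (length(loci) == 0) fail("empty genotype: no typed loci")
  if (any(vapply(loci, length, 1L) == 0)) fail("allele list empty for a typed locus")
  n_alleles <- vapply(loci, function(a) length(unique(a)), 1L)
  trig <- names(n_alleles)[n_alleles > 2]
  list(is_chimera = length(trig) > 0, triggering_loci = trig)
}

#' Apply the microsatellite chimera rule to a long-format genotype table
#'
#' @param genotypes data.frame with columns sample_id, locus, allele.
#' @return data.frame with one row per sample: sample_id, is_chimera,
#'   triggering_loci (comma-joined).
#' @export
classify_microsat_table <- function(genotypes) {
  need <- c("sample_id", "locus", "allele")
  if (!all(need %in% names(genotypes))) {
    fail("genotype table must have columns: %s", paste(need, collapse = ", "))
  }
  out <- lapply(split(genotypes, genotypes$sample_id), function(g) {
    res <- classify_microsat(split(g$allele, g$locus))
    data.frame(sample_id = g$sample_id[1],
               is_chimera = res$is_chimera,
               triggering_loci = paste(res$triggering_loci, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' U counts, over all (x, y) pairs, the x > y pairs plus half the ties. The
#' exact two-sided p-value uses the null distribution of U (no ties); the
#' normal approximation applies the tie correction and, by default, a
#' continuity correction. In `auto` mode the exact route is used when
#' `n1 * n2 <= 400` and the data are tie-free.
#'
#' @param x,y numeric samples, both non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`; exact mode refuses ties.
#' @param alternative `"two.sided"` (default), `"greater"` (x stochastically
#'   larger) or `"less"`.
#' @param correct apply the continuity correction in the normal mode.
#' @return list with u_statistic, p_value, method, n1, n2.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal"),
                           alternative = c("two.sided", "greater", "less"),
                           correct = TRUE) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) fail("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (mode == "exact" && has_ties) fail("exact mode refuses tied data")
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = (n1 * n2 <= 400) && !has_ties)
  if (use_exact) {
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      # all observations identical: no evidence either way
      return(list(u_statistic = u, p_value = 1, method = "normal_approx",
                  n1 = n1, n2 = n2))
    }
    d <- u - mu
    cc <- if (correct) 0.5 else 0
    p <- if (alternative == "two.sided") {
      z <- (d - sign(d) * cc) / sqrt(sigma2)
      2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
    } else if (alternative == "greater") {
      stats::pnorm((d - cc) / sqrt(sigma2), lower.tail = FALSE)
    } else {
      stats::pnorm((-d - cc) / sqrt(sigma2), lower.tail = FALSE)
    }
    p <- min(1, p)
    method <- "normal_approx"
  }
  list(u_statistic = u, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Summarize MNP records and multiallelism for one sample's variant calls
#'
#' An MNP record is one whose REF spans at least two bases and whose ALT
#' alleles all have the same length as the REF (a short haplotype of SNPs).
#' The distinct-allele count of a record is taken from the sample's genotype
#' field when one is present (unique allele indices, REF included), else from
#' REF plus all ALTs. A record is multiallelic when its distinct-allele count
#' exceeds `allele_threshold`.
#'
#' @param vcf path to a VCF (v4.2) file or a `vcfR` object.
#' @param sample_id column to read genotypes from; defaults to the file's
#'   single sample; ignored (with allele counting from ALT) when the file
#'   carries no genotypes.
#' @param allele_threshold records with more than this many distinct alleles
#'   count as multiallelic. The default 2 matches the "more than two alleles"
#'   microsatellite rule; this is a required, logged analysis parameter.
#' @return data.frame row: sample_id, n_mnp, n_multiallelic,
#'   rel_multiallelic (0 with `rel_defined = FALSE` when no MNPs), n_skipped.
#' @export
extract_mnp_summary <- function(vcf, sample_id = NULL, allele_threshold = 2) {
  if (is.character(vcf)) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  if (!inherits(vcf, "vcfR")) fail("vcf must be a file path or a vcfR object")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  has_gt <- !is.null(vcf@gt) && !is.null(ncol(vcf@gt)) && ncol(vcf@gt) > 1
  gt_mat <- if (has_gt) vcfR::extract.gt(vcf, element = "GT") else NULL
  if (!is.null(gt_mat)) {
    if (is.null(sample_id)) {
      if (ncol(gt_mat) != 1) fail("multi-sample VCF: sample_id is required")
      sample_id <- colnames(gt_mat)[1]
    }
    if (!sample_id %in% colnames(gt_mat)) fail("sample %s absent from VCF", sample_id)
    gt <- gt_mat[, sample_id]
  } else {
    gt <- rep(NA_character_, length(ref))
    if (is.null(sample_id)) sample_id <- "sites_only"
  }

  n_mnp <- 0L; n_multi <- 0L; n_skipped <- 0L
  for (i in seq_along(ref)) {
    if (is.na(ref[i]) || is.na(alt[i]) || ref[i] == "" || alt[i] == "") {
      n_skipped <- n_skipped + 1L
      next
    }
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    if (nchar(ref[i]) < 2 || !all(nchar(alts) == nchar(ref[i]))) next
    n_mnp <- n_mnp + 1L
    n_alleles <- if (!is.na(gt[i])) {
      length(unique(strsplit(gt[i], "[/|]")[[1]]))
    } else {
      1L + length(alts)
    }
    if (n_alleles > allele_threshold) n_multi <- n_multi + 1L
  }
  if (n_skipped > 0) {
    warning(sprintf("%d malformed record(s) skipped in sample %s",
                    n_skipped, sample_id), call. = FALSE)
  }
  data.frame(sample_id = sample_id, n_mnp = n_mnp, n_multiallelic = n_multi,
             rel_multiallelic = if (n_mnp > 0) n_multi / n_mnp else 0,
             rel_defined = n_mnp > 0, n_skipped = n_skipped,
             stringsAsFactors = FALSE)
}

#' Test for multiallelic-MNP enrichment in chimeras
#'
#' Mann-Whitney test on the per-sample relative quantity of multiallelic
#' MNPs, chimeras versus non-chimeras. Two-sided by default; a one-sided
#' alternative (chimeras greater) is available.
#'
#' @param summaries data.frame of per-sample MNP summaries (from
#'   [extract_mnp_summary()], row-bound).
#' @param metadata data.frame with columns sample_id and entity
#'   (`chimera` / `nonchimera`).
#' @param alternative passed to [mann_whitney_u()]; x is the chimera group.
#' @return result of [mann_whitney_u()].
#' @export
test_multiallelic_enrichment <- function(summaries, metadata,
                                         alternative = "two.sided") {
  m <- merge(summaries, metadata[, c("sample_id", "entity")], by = "sample_id")
  xs <- m$rel_multiallelic[m$entity == "chimera"]
  ys <- m$rel_multiallelic[m$entity == "nonchimera"]
  if (length(xs) == 0 || length(ys) == 0) fail("both entity groups must be represented")
  mann_whitney_u(xs, ys, alternative = alternative)
}
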