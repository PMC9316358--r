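#' Build a filtered GO category index over a gene universe
#'
#' Restricts the annotation to the universe, optionally closes memberships
#' over `is_a` parent links (a gene annotated to a child term becomes a
#' member of every ancestor), and drops categories smaller than `smallest`
#' genes or larger than `largest` as a fraction of the universe.
#'
#' @param annotation a `go_annotation` object (see
#'   [simulate_go_annotation()] / [read_go_annotation()]).
#' @param universe character vector of analysis gene ids.
#' @param smallest minimum category size (genes).
#' @param largest maximum category size as a fraction of the universe,
#'   in (0, 1).
#' @param propagate close memberships over parent links.
#' @return object of class `go_index`: list with `categories` (named list of
#'   gene-id vectors), `names` (display names), `term_ids` (original term ids
#'   per category) and `universe`.
#' @export
build_go_index <- function(annotation, universe, smallest = 10,
                           largest = 0.1, propagate = TRUE) {
  if (length(universe) == 0) fail("empty gene universe")
  if (largest <= 0 || largest >= 1) fail("largest must be in (0, 1)")
  g2t <- annotation$gene2term
  g2t <- g2t[g2t$gene_id %in% universe, , drop = FALSE]
  members <- lapply(split(g2t$gene_id, g2t$term_id), unique)

  if (propagate && nrow(annotation$parents) > 0) {
    # ancestor closure: push each term's genes into all its ancestors
    up <- split(annotation$parents$parent, annotation$parents$child)
    ancestors <- function(tm) {
      seen <- character(0)
      frontier <- up[[tm]] %||% character(0)
      while (length(frontier) > 0) {
        seen <- union(seen, frontier)
        frontier <- unique(unlist(up[frontier], use.names = FALSE))
        frontier <- setdiff(frontier, seen)
      }
      seen
    }
    for (tm in names(members)) {
      for (anc in ancestors(tm)) {
        members[[anc]] <- union(members[[anc]] %||% character(0), members[[tm]])
      }
    }
  }

  max_size <- largest * length(universe)
  sizes <- vapply(members, length, 1L)
  members <- members[sizes >= smallest & sizes <= max_size]
  if (length(members) == 0) fail("no testable categories after filtering")
  nm <- names(members)
  display <- vapply(nm, function(tm) {
    unname(annotation$term_names[tm] %||% tm)
  }, character(1))
  structure(
    list(categories = members,
         names = stats::setNames(display, nm),
         term_ids = stats::setNames(as.list(nm), nm),
         universe = universe),
    class = "go_index"
  )
}

#' Merge near-duplicate GO categories by adaptive clustering
#'
#' Pairwise dissimilarity between categories is
#' `1 - |A intersect B| / min(|A|, |B|)` (overlap over the smaller set;
#' Jaccard available). Complete-linkage hierarchical clustering is cut at
#' `cut_height`; categories in one cluster are merged into a single category
#' whose member set is the union and whose display name joins the member
#' names. Merged categories are re-checked against the `largest` filter.
#'
#' @param index a [build_go_index()] result.
#' @param cut_height dendrogram cut height in `[0, 1]`.
#' @param method `"overlap"` (default) or `"jaccard"`.
#' @param largest maximum merged-category size as a fraction of the
#'   universe; merged categories above it are dropped.
#' @return a `go_index` with merged categories.
#' @export
cluster_go_terms <- function(index, cut_height = 0.5,
                             method = c("overlap", "jaccard"), largest = 0.1) {
  method <- match.arg(method)
  if (cut_height < 0 || cut_height > 1) fail("cut_height must be in [0, 1]")
  cats <- index$categories
  k <- length(cats)
  if (k < 2) return(index)
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      inter <- length(intersect(cats[[i]], cats[[j]]))
      denom <- if (method == "overlap") {
        min(length(cats[[i]]), length(cats[[j]]))
      } else {
        length(union(cats[[i]], cats[[j]]))
      }
      d[i, j] <- d[j, i] <- 1 - inter / denom
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cl <- stats::cutree(hc, h = cut_height)
  merged <- list(); mnames <- character(0); mterms <- list()
  for (grp in unique(cl)) {
    idx <- which(cl == grp)
    genes <- unique(unlist(cats[idx], use.names = FALSE))
    if (length(genes) > largest * length(index$universe)) next
    key <- paste(names(cats)[idx], collapse = "+")
    merged[[key]] <- genes
    mnames[key] <- paste(index$names[names(cats)[idx]], collapse = "; ")
    mterms[[key]] <- unlist(index$term_ids[names(cats)[idx]], use.names = FALSE)
  }
  if (length(merged) == 0) fail("no testable categories after clustering")
  structure(
    list(categories = merged, names = mnames, term_ids = mterms,
         universe = index$universe),
    class = "go_index"
  )
}

enrichment_frame <- function(index, delta, stat, p, n_strong) {
  res <- data.frame(
    category = names(index$categories),
    name = unname(index$names[names(index$categories)]),
    n = vapply(index$categories, length, 1L),
    n_strong = n_strong,
    delta_rank_or_odds = stat,
    delta_rank = delta,
    p_value = p,
    fdr = bh_adjust(p),
    direction = ifelse(delta > 0, "up", ifelse(delta < 0, "down", "none")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "members") <- index$categories
  res
}

#' Rank-based (Mann-Whitney) GO enrichment
#'
#' Genes are ranked ascending by the continuous measure (midranks for ties).
#' Per category, a two-sided Mann-Whitney test compares member against
#' non-member ranks; the delta-rank (mean member rank minus mean non-member
#' rank) is the effect size. BH adjustment is applied across categories.
#' `n_strong` counts members with `|measure| > strong_threshold`, a display
#' statistic for the x/y labels in enrichment figures, never a test input.
#'
#' @param measure named numeric vector (typically log2 fold changes) covering
#'   every universe gene.
#' @param index a `go_index`.
#' @param strong_threshold threshold for the `n_strong` display count.
#' @return data.frame with category, name, n, n_strong, delta_rank, p_value,
#'   fdr, direction; member sets attached as attribute `members`.
#' @export
mwu_enrichment <- function(measure, index, strong_threshold = 2) {
  universe <- index$universe
  if (!all(universe %in% names(measure))) {
    fail("measure missing for some universe genes")
  }
  measure <- measure[universe]
  r <- rank(measure)
  out <- lapply(names(index$categories), function(key) {
    memb <- universe %in% index$categories[[key]]
    if (all(memb)) fail("category %s equals the whole universe", key)
    delta <- mean(r[memb]) - mean(r[!memb])
    test <- mann_whitney_u(measure[memb], measure[!memb], mode = "normal")
    c(delta = delta, u = test$u_statistic, p = test$p_value,
      strong = sum(abs(measure[memb]) > strong_threshold))
  })
  m <- do.call(rbind, out)
  enrichment_frame(index, delta = m[, "delta"], stat = m[, "delta"],
                   p = m[, "p"], n_strong = as.integer(m[, "strong"]))
}

# two-sided Fisher exact p by hypergeometric summation: total probability of
# all tables no more likely than the observed one (fisher.test convention)
fisher_p_two_sided <- function(a, b, c, d) {
  K <- a + b          # members
  n1 <- a + c         # flagged
  N <- a + b + c + d
  lo <- max(0, n1 - (N - K)); hi <- min(K, n1)
  dens <- stats::dhyper(lo:hi, K, N - K, n1)
  obs <- stats::dhyper(a, K, N - K, n1)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Fisher exact GO enrichment for a binary gene flag
#'
#' Per category, tests the 2x2 member-by-flag table with a two-sided Fisher
#' exact p-value computed by hypergeometric tail summation. The reported
#' effect is the sample odds ratio; the delta-rank column carries the rank
#' effect of the binary flag so direction is comparable with
#' [mwu_enrichment()].
#'
#' @param flag named logical (or 0/1) vector covering the universe; must not
#'   be constant.
#' @param index a `go_index`.
#' @return data.frame as in [mwu_enrichment()] with the odds ratio in
#'   `delta_rank_or_odds`.
#' @export
fisher_enrichment <- function(flag, index) {
  universe <- index$universe
  if (!all(universe %in% names(flag))) fail("flag missing for some universe genes")
  flag <- as.logical(flag[universe])
  if (all(flag) || !any(flag)) fail("flag must not be constant over the universe")
  r <- rank(flag)
  out <- lapply(names(index$categories), function(key) {
    memb <- universe %in% index$categories[[key]]
    if (all(memb)) fail("category %s equals the whole universe", key)
    a <- sum(memb & flag); b <- sum(memb & !flag)
    c_ <- sum(!memb & flag); d <- sum(!memb & !flag)
    odds <- (a * d) / max(b * c_, .Machine$double.eps)
    c(delta = mean(r[memb]) - mean(r[!memb]),
      odds = odds, p = fisher_p_two_sided(a, b, c_, d), strong = a)
  })
  m <- do.call(rbind, out)
  enrichment_frame(index, delta = m[, "delta"], stat = m[, "odds"],
                   p = m[, "p"], n_strong = as.integer(m[, "strong"]))
}

#' Delta-rank comparison between two enrichment results
#'
#' Pairs categories present in both results — matched by member-set identity,
#' falling back to display name — and returns the Pearson correlation of
#' their delta-ranks together with the paired table.
#'
#' @param a,b results of [mwu_enrichment()] (delta-ranks are compared).
#' @return list with `r` (Pearson correlation) and `pairs` (data.frame
#'   category, delta_rank_a, delta_rank_b).
#' @export
delta_rank_correlation <- function(a, b) {
  key_of <- function(res) {
    members <- attr(res, "members")
    if (!is.null(members)) {
      vapply(res$category, function(k) {
        paste(sort(members[[k]]), collapse = "|")
      }, character(1))
    } else {
      res$name
    }
  }
  ka <- key_of(a); kb <- key_of(b)
  shared <- intersect(ka, kb)
  if (length(shared) < 3) fail("fewer than 3 shared categories")
  ia <- match(shared, ka); ib <- match(shared, kb)
  pairs <- data.frame(category = a$category[ia],
                      delta_rank_a = a$delta_rank[ia],
                      delta_rank_b = b$delta_rank[ib],
                      stringsAsFactors = FALSE)
  list(r = stats::cor(pairs$delta_rank_a, pairs$delta_rank_b), pairs = pairs)
}
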