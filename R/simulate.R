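#' Simulation design for a two-entity, two-depth translocation experiment
#'
#' Describes the experimental layout the count simulator reproduces: chimeric
#' and non-chimeric colonies kept at 10-m depth or translocated to 2-m depth,
#' each colony descending from one of a small set of mother colonies.
#'
#' @param n_genes number of genes to simulate.
#' @param replicates named integer vector with the number of colonies in each
#'   design cell; names must be `chimera_10m`, `chimera_2m`, `nonchimera_10m`,
#'   `nonchimera_2m`.
#' @param mothers character vector of mother-colony labels. Colonies are
#'   assigned to mothers cyclically over the ordered sample list, so every
#'   mother spans entities and depths and the batch covariate stays estimable.
#' @param seed integer seed; the same (design, params, seed) triple reproduces
#'   byte-identical output.
#' @return an object of class `cf_design`.
#' @export
sim_design <- function(n_genes = 2000,
                       replicates = c(chimera_10m = 5, chimera_2m = 5,
                                      nonchimera_10m = 5, nonchimera_2m = 5),
                       mothers = LETTERS[1:7],
                       seed = 1L) {
  cells <- c("chimera_10m", "chimera_2m", "nonchimera_10m", "nonchimera_2m")
  if (!is_count(n_genes) || n_genes < 1) fail("n_genes must be a positive integer")
  if (is.null(names(replicates)) || !setequal(names(replicates), cells)) {
    fail("replicates must be named with the four design cells: %s",
         paste(cells, collapse = ", "))
  }
  replicates <- replicates[cells]
  empty <- names(replicates)[replicates < 1]
  if (length(empty) > 0) fail("empty design cell: %s", paste(empty, collapse = ", "))
  if (length(mothers) < 1 || anyDuplicated(mothers)) {
    fail("mothers must be a non-empty vector of unique labels")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         replicates = as.integer(replicates) |> stats::setNames(cells),
         mothers = as.character(mothers),
         seed = as.integer(seed)),
    class = "cf_design"
  )
}

#' Simulation parameters: baseline expression, dispersion and planted effects
#'
#' Effect sizes are given in log2 units (the unit differential-expression
#' results are reported in) and converted to the natural-log scale internally,
#' where the negative-binomial means are additive.
#'
#' @param baseline_logmean_mean,baseline_logmean_sd mean and sd of the
#'   per-gene baseline natural-log mean expression.
#' @param dispersion common negative-binomial dispersion (variance =
#'   mu + mu^2 * dispersion); must be > 0.
#' @param batch_sd sd of the additive mother-colony effect on the ln scale,
#'   drawn independently per (gene, mother) pair.
#' @param response_lfc log2 fold change of stress-responsive genes in
#'   non-chimeras (2m vs 10m).
#' @param basal_shift_lfc constitutive log2 elevation of frontloaded genes in
#'   chimeras, applied at both depths.
#' @param plasticity_gain_lfc fractional gain of the chimera response for
#'   higher-plasticity genes: their chimera response is
#'   `response_lfc * (1 + plasticity_gain_lfc)`.
#' @param n_frontloaded,n_higher_plasticity,n_both,n_responsive_only number of
#'   genes planted in each category; the remainder of the universe is NULL.
#' @return an object of class `cf_params`.
#' @export
sim_params <- function(baseline_logmean_mean = log(100),
                       baseline_logmean_sd = 1,
                       dispersion = 0.1,
                       batch_sd = 0.5,
                       response_lfc = 2,
                       basal_shift_lfc = 2,
                       plasticity_gain_lfc = 1,
                       n_frontloaded = 60,
                       n_higher_plasticity = 60,
                       n_both = 60,
                       n_responsive_only = 200) {
  if (!is.numeric(dispersion) || dispersion <= 0) fail("dispersion must be > 0")
  if (batch_sd < 0) fail("batch_sd must be >= 0")
  eff <- c(response_lfc, basal_shift_lfc, plasticity_gain_lfc)
  if (!all(is.finite(eff))) fail("effect sizes must be finite")
  ns <- c(n_frontloaded, n_higher_plasticity, n_both, n_responsive_only)
  if (!all(vapply(ns, is_count, logical(1)))) fail("category counts must be non-negative integers")
  structure(
    list(baseline_logmean_mean = baseline_logmean_mean,
         baseline_logmean_sd = baseline_logmean_sd,
         dispersion = dispersion,
         batch_sd = batch_sd,
         response_lfc = response_lfc,
         basal_shift_lfc = basal_shift_lfc,
         plasticity_gain_lfc = plasticity_gain_lfc,
         n_frontloaded = as.integer(n_frontloaded),
         n_higher_plasticity = as.integer(n_higher_plasticity),
         n_both = as.integer(n_both),
         n_responsive_only = as.integer(n_responsive_only)),
    class = "cf_params"
  )
}

#' Named simulation presets
#'
#' `"paper_like"` emulates the study conditions: 2000 genes, 5 colonies per
#' entity-by-depth cell, 7 mother colonies, dispersion 0.1, a log2 response of
#' 2 in non-chimeras, a basal frontloading shift of 2, a plasticity gain of 1,
#' and 60/60/60/200 genes planted as FRONTLOADED / HIGHER_PLASTICITY /
#' FRONTLOADED_AND_HIGHER_PLASTICITY / RESPONSIVE_ONLY.
#'
#' `"frontload_heavy"` suppresses the extra chimera response (no
#' higher-plasticity or combined genes): chimeras then respond only through
#' the shared RESPONSIVE_ONLY genes, which reproduces the reduced chimera
#' plasticity pattern the projection analysis is meant to detect.
#'
#' @param name preset name.
#' @param seed integer seed stored in the design.
#' @return list with elements `design` and `params`.
#' @export
sim_preset <- function(name = c("paper_like", "frontload_heavy"), seed = 1L) {
  name <- match.arg(name)
  params <- switch(
    name,
    paper_like = sim_params(),
    frontload_heavy = sim_params(n_higher_plasticity = 0, n_both = 0)
  )
  list(design = sim_design(seed = seed), params = params)
}

plasticity_categories <- c("FRONTLOADED", "HIGHER_PLASTICITY",
                           "FRONTLOADED_AND_HIGHER_PLASTICITY",
                           "RESPONSIVE_ONLY", "NULL")

#' Simulate negative-binomial counts with planted frontloading archetypes
#'
#' Draws a gene-by-sample count matrix under the design's 2x2 layout with an
#' additive mother-colony batch effect and per-category planted effects:
#' FRONTLOADED genes carry a constitutive chimera elevation
#' (`basal_shift_lfc`, both depths) and do not respond in chimeras;
#' HIGHER_PLASTICITY genes respond in chimeras with
#' `response_lfc * (1 + plasticity_gain_lfc)`; FRONTLOADED_AND_HIGHER_PLASTICITY
#' genes combine both; RESPONSIVE_ONLY genes respond equally in both entities;
#' NULL genes carry no effect. All responsive categories respond with
#' `response_lfc` in non-chimeras. Each responsive gene's direction is drawn
#' up or down with equal probability (stress responses are a mix of over-
#' and under-expression, and a one-sided response set would also violate the
#' mostly-unchanged assumption behind median-of-ratios normalization); the
#' chimera response keeps the gene's direction, and the frontloading basal
#' shift is always an elevation.
#'
#' @param design a [sim_design()] object.
#' @param params a [sim_params()] object.
#' @return list with `counts` (integer matrix, genes x samples), `metadata`
#'   (data.frame: sample_id, entity, depth, mother_colony) and `truth`
#'   (data.frame: gene_id, category).
#' @export
simulate_counts <- function(design, params) {
  stopifnot(inherits(design, "cf_design"), inherits(params, "cf_params"))
  n_planted <- params$n_frontloaded + params$n_higher_plasticity +
    params$n_both + params$n_responsive_only
  if (n_planted > design$n_genes) {
    fail("planted categories (%d genes) exceed the universe (%d genes)",
         n_planted, design$n_genes)
  }

  cells <- names(design$replicates)
  entity <- sub("_(10m|2m)$", "", cells)
  depth <- sub("^(chimera|nonchimera)_", "", cells)
  metadata <- do.call(rbind, lapply(seq_along(cells), function(i) {
    n <- design$replicates[i]
    data.frame(sample_id = sprintf("%s_%d", cells[i], seq_len(n)),
               entity = entity[i], depth = depth[i],
               stringsAsFactors = FALSE)
  }))
  metadata$mother_colony <-
    design$mothers[(seq_len(nrow(metadata)) - 1L) %% length(design$mothers) + 1L]

  gene_ids <- sprintf("gene_%04d", seq_len(design$n_genes))
  category <- rep("NULL", design$n_genes)
  idx <- 0L
  for (cat in c("FRONTLOADED", "HIGHER_PLASTICITY",
                "FRONTLOADED_AND_HIGHER_PLASTICITY", "RESPONSIVE_ONLY")) {
    n_cat <- switch(cat,
                    FRONTLOADED = params$n_frontloaded,
                    HIGHER_PLASTICITY = params$n_higher_plasticity,
                    FRONTLOADED_AND_HIGHER_PLASTICITY = params$n_both,
                    RESPONSIVE_ONLY = params$n_responsive_only)
    if (n_cat > 0) category[idx + seq_len(n_cat)] <- cat
    idx <- idx + n_cat
  }
  truth <- data.frame(gene_id = gene_ids, category = category,
                      stringsAsFactors = FALSE)

  resp <- log2_to_ln(params$response_lfc)
  basal <- log2_to_ln(params$basal_shift_lfc)
  gain <- params$plasticity_gain_lfc
  is_responsive <- category != "NULL"
  is_front <- category %in% c("FRONTLOADED", "FRONTLOADED_AND_HIGHER_PLASTICITY")
  is_gain <- category %in% c("HIGHER_PLASTICITY", "FRONTLOADED_AND_HIGHER_PLASTICITY")

  # per-gene ln response in chimeras: none for pure frontloaded, amplified
  # for gain categories, equal for responsive-only
  chim_resp <- ifelse(category == "RESPONSIVE_ONLY", resp,
                      ifelse(is_gain, resp * (1 + gain), 0))
  nonchim_resp <- ifelse(is_responsive, resp, 0)
  basal_shift <- ifelse(is_front, basal, 0)

  with_seed(design$seed, {
    sign_g <- ifelse(stats::runif(design$n_genes) < 0.5, -1, 1)
    chim_resp <- chim_resp * sign_g
    nonchim_resp <- nonchim_resp * sign_g
    baseline <- stats::rnorm(design$n_genes, params$baseline_logmean_mean,
                             params$baseline_logmean_sd)
    batch <- matrix(stats::rnorm(design$n_genes * length(design$mothers),
                                 0, params$batch_sd),
                    nrow = design$n_genes,
                    dimnames = list(gene_ids, design$mothers))
    log_mu <- matrix(baseline, nrow = design$n_genes, ncol = nrow(metadata))
    for (j in seq_len(nrow(metadata))) {
      m <- metadata$mother_colony[j]
      chim <- metadata$entity[j] == "chimera"
      shallow <- metadata$depth[j] == "2m"
      log_mu[, j] <- log_mu[, j] + batch[, m] +
        (if (chim) basal_shift else 0) +
        (if (shallow) (if (chim) chim_resp else nonchim_resp) else 0)
    }
    counts <- matrix(
      stats::rnbinom(length(log_mu), mu = exp(log_mu), size = 1 / params$dispersion),
      nrow = design$n_genes,
      dimnames = list(gene_ids, metadata$sample_id)
    )
    storage.mode(counts) <- "integer"
    list(counts = counts, metadata = metadata, truth = truth)
  })
}

#' Simulate a gene-to-GO annotation with optional planted terms
#'
#' Random terms get sizes log-uniform between 5 and `0.2 * n_genes`; planted
#' terms are inserted with exactly the membership given. Optional parent
#' links connect random term pairs child -> lower-index parent, which cannot
#' form a cycle.
#'
#' @param n_genes size of the gene universe (ids `gene_0001`, ...).
#' @param n_terms number of random terms to draw.
#' @param planted named list of character vectors: term id -> member gene ids.
#' @param parent_fraction fraction of terms given a random parent term.
#' @param seed integer seed.
#' @return object of class `go_annotation`: list with `gene2term`
#'   (data.frame gene_id, term_id), `parents` (data.frame child, parent; may
#'   have 0 rows), `term_names` (named character).
#' @export
simulate_go_annotation <- function(n_genes, n_terms, planted = list(),
                                   parent_fraction = 0, seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1) fail("n_genes must be positive")
  if (!is_count(n_terms)) fail("n_terms must be a non-negative integer")
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  for (tm in names(planted)) {
    if (!all(planted[[tm]] %in% genes)) {
      fail("planted term %s contains genes outside the universe", tm)
    }
  }
  with_seed(seed, {
    maps <- list()
    if (n_terms > 0) {
      max_size <- max(5, floor(0.2 * n_genes))
      sizes <- pmin(n_genes, round(exp(stats::runif(n_terms, log(5), log(max_size)))))
      term_ids <- sprintf("GO:%07d", seq_len(n_terms))
      maps <- lapply(seq_len(n_terms), function(i) {
        data.frame(gene_id = sample(genes, sizes[i]), term_id = term_ids[i],
                   stringsAsFactors = FALSE)
      })
    } else {
      term_ids <- character(0)
    }
    for (tm in names(planted)) {
      if (length(planted[[tm]]) > 0) {
        maps <- c(maps, list(data.frame(gene_id = planted[[tm]], term_id = tm,
                                        stringsAsFactors = FALSE)))
        term_ids <- c(term_ids, tm)
      }
    }
    gene2term <- if (length(maps) > 0) {
      do.call(rbind, maps)
    } else {
      data.frame(gene_id = character(0), term_id = character(0))
    }
    parents <- data.frame(child = character(0), parent = character(0))
    if (parent_fraction > 0 && length(term_ids) > 1) {
      n_links <- floor(parent_fraction * length(term_ids))
      if (n_links > 0) {
        children <- sample(seq_along(term_ids)[-1], min(n_links, length(term_ids) - 1))
        parents <- data.frame(
          child = term_ids[children],
          parent = term_ids[vapply(children, function(i) sample.int(i - 1L, 1L), 1L)],
          stringsAsFactors = FALSE
        )
      }
    }
    structure(
      list(gene2term = gene2term, parents = parents,
           term_names = stats::setNames(term_ids, term_ids)),
      class = "go_annotation"
    )
  })
}

#' Simulate per-sample MNP variant tables with elevated chimera multiallelism
#'
#' Each sample receives `n_loci` MNP records (multi-base REF, same-length
#' ALTs) plus a handful of SNP records the downstream extractor must ignore.
#' A record is drawn multiallelic (3 or 4 distinct alleles in the genotype)
#' with probability `base_rate` in non-chimeras and
#' `base_rate + multiallelic_excess` in chimeras.
#'
#' @param n_chimera,n_nonchimera samples per entity.
#' @param n_loci MNP records per sample; must be positive.
#' @param multiallelic_excess additive excess multiallelic probability in
#'   chimeras; `base_rate + multiallelic_excess` must be <= 1.
#' @param base_rate multiallelic probability in non-chimeras.
#' @param n_snp extra SNP records per sample (not MNPs).
#' @param seed integer seed.
#' @return list with `samples` (data.frame sample_id, entity) and `records`
#'   (named list of per-sample data.frames with columns chrom, pos, ref, alt,
#'   gt).
#' @export
simulate_variant_table <- function(n_chimera, n_nonchimera, n_loci,
                                   multiallelic_excess, base_rate = 0.2,
                                   n_snp = 20, seed = 1L) {
  if (!is_count(n_loci) || n_loci < 1) fail("n_loci must be a positive integer")
  if (multiallelic_excess < 0) fail("multiallelic_excess must be >= 0")
  if (base_rate + multiallelic_excess > 1) fail("base_rate + excess exceeds 1")
  samples <- data.frame(
    sample_id = c(sprintf("chim_%02d", seq_len(n_chimera)),
                  sprintf("nonchim_%02d", seq_len(n_nonchimera))),
    entity = rep(c("chimera", "nonchimera"), c(n_chimera, n_nonchimera)),
    stringsAsFactors = FALSE
  )
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(len) paste(sample(bases, len, replace = TRUE), collapse = "")
  alt_same_len <- function(ref, k) {
    # k distinct ALT haplotypes of the same length as REF
    out <- character(0)
    while (length(out) < k) {
      cand <- rand_seq(nchar(ref))
      if (cand != ref && !(cand %in% out)) out <- c(out, cand)
    }
    out
  }
  with_seed(seed, {
    records <- lapply(seq_len(nrow(samples)), function(i) {
      p_multi <- base_rate +
        if (samples$entity[i] == "chimera") multiallelic_excess else 0
      multi <- stats::runif(n_loci) < p_multi
      n_alt <- ifelse(multi, ifelse(stats::runif(n_loci) < 0.8, 2L, 3L), 1L)
      ref_len <- sample(2:4, n_loci, replace = TRUE)
      mnp <- data.frame(
        chrom = "chr1",
        pos = seq_len(n_loci) * 1000L,
        ref = vapply(ref_len, rand_seq, character(1)),
        alt = NA_character_,
        gt = NA_character_,
        stringsAsFactors = FALSE
      )
      for (r in seq_len(n_loci)) {
        alts <- alt_same_len(mnp$ref[r], n_alt[r])
        mnp$alt[r] <- paste(alts, collapse = ",")
        mnp$gt[r] <- paste(0:n_alt[r], collapse = "/")
      }
      snp <- if (n_snp > 0) {
        data.frame(
          chrom = "chr1",
          pos = n_loci * 1000L + seq_len(n_snp) * 100L,
          ref = sample(bases, n_snp, replace = TRUE),
          alt = NA_character_, gt = "0/1",
          stringsAsFactors = FALSE
        )
      }
      if (n_snp > 0) {
        for (r in seq_len(n_snp)) {
          snp$alt[r] <- sample(setdiff(bases, snp$ref[r]), 1)
        }
      }
      rbind(mnp, snp)
    })
    names(records) <- samples$sample_id
    list(samples = samples, records = records)
  })
}

#' Simulate a HOBO-style temperature/light logger series
#'
#' Temperature follows a diel sinusoid (peak mid-afternoon) plus Gaussian
#' noise; light is a truncated sinusoid, zero at night, scaled to
#' `light_peak` at solar noon.
#'
#' @param temp_mean,temp_amplitude mean and half-range of the temperature
#'   sinusoid, degrees C.
#' @param light_peak maximum light, lux.
#' @param noise_sd sd of temperature noise, degrees C.
#' @param hours series length; must be > 0.
#' @param step_minutes sampling interval.
#' @param depth_label label stored with every record.
#' @param start first timestamp (local time, `YYYY-MM-DD HH:MM:SS`).
#' @param seed integer seed.
#' @return data.frame with columns timestamp (ISO-8601), temperature_C,
#'   light_lux, depth.
#' @export
simulate_logger <- function(temp_mean = 25, temp_amplitude = 0.5,
                            light_peak = 40000, noise_sd = 0.05,
                            hours = 48, step_minutes = 10,
                            depth_label = "10m",
                            start = "2021-06-01 00:00:00", seed = 1L) {
  if (!is.numeric(hours) || hours <= 0) fail("hours must be > 0")
  t0 <- as.POSIXct(start, tz = "UTC")
  mins <- seq(0, hours * 60, by = step_minutes)
  times <- t0 + mins * 60
  hour_of_day <- (as.numeric(times - t0, units = "hours") +
                    as.numeric(format(t0, "%H")) +
                    as.numeric(format(t0, "%M")) / 60) %% 24
  temp_clean <- temp_mean + temp_amplitude * sin(2 * pi * (hour_of_day - 9) / 24)
  light <- light_peak * pmax(0, sin(pi * (hour_of_day - 6) / 12))
  with_seed(seed, {
    temp <- temp_clean + stats::rnorm(length(mins), 0, noise_sd)
    data.frame(
      timestamp = format(times, "%Y-%m-%dT%H:%M:%S"),
      temperature_C = temp,
      light_lux = light,
      depth = depth_label,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a Dirichlet-multinomial OTU table
#'
#' Per-sample composition is drawn from a Dirichlet distribution centred on
#' the group's proportion vector (concentration `theta`), then counts from a
#' multinomial with the given library size. A nonzero `effect` tilts the
#' non-reference groups' proportions up for the first half of OTUs and down
#' for the second half (renormalised), giving a compositional group shift.
#'
#' @param n_samples_per_group named integer vector: group -> sample count.
#' @param n_otus number of OTUs.
#' @param base_proportions length-`n_otus` vector summing to 1; default
#'   uniform.
#' @param effect log-scale tilt applied to non-reference groups.
#' @param library_size reads per sample; must be positive.
#' @param theta Dirichlet concentration (larger = less overdispersion).
#' @param seed integer seed.
#' @return list with `counts` (matrix otus x samples) and `metadata`
#'   (data.frame sample_id, group).
#' @export
simulate_otu_table <- function(n_samples_per_group, n_otus = 50,
                               base_proportions = NULL, effect = 0,
                               library_size = 10000, theta = 50, seed = 1L) {
  if (library_size <= 0) fail("library size must be positive")
  if (is.null(names(n_samples_per_group))) fail("n_samples_per_group must be named")
  if (is.null(base_proportions)) base_proportions <- rep(1 / n_otus, n_otus)
  if (length(base_proportions) != n_otus) fail("base_proportions length mismatch")
  if (abs(sum(base_proportions) - 1) > 1e-8) fail("base_proportions must sum to 1")
  groups <- names(n_samples_per_group)
  tilt <- rep(c(1, -1), length.out = n_otus)
  with_seed(seed, {
    cols <- list()
    meta <- list()
    for (gi in seq_along(groups)) {
      p <- base_proportions
      if (gi > 1 && effect != 0) {
        p <- p * exp(effect * tilt)
        p <- p / sum(p)
      }
      for (s in seq_len(n_samples_per_group[gi])) {
        alpha <- p * theta
        w <- stats::rgamma(n_otus, shape = alpha, rate = 1)
        w <- w / sum(w)
        cols[[length(cols) + 1L]] <-
          as.integer(stats::rmultinom(1, size = library_size, prob = w))
        meta[[length(meta) + 1L]] <-
          data.frame(sample_id = sprintf("%s_%02d", groups[gi], s),
                     group = groups[gi], stringsAsFactors = FALSE)
      }
    }
    metadata <- do.call(rbind, meta)
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(sprintf("otu_%03d", seq_len(n_otus)),
                             metadata$sample_id)
    list(counts = counts, metadata = metadata)
  })
}

#' Simulate survivor counts over successive timepoints
#'
#' Survivors follow a binomial chain: the number alive at each timepoint is
#' binomial in the number alive at the previous one with the group's
#' per-interval survival rate, so counts are monotone non-increasing.
#'
#' @param n0_per_group starting colonies per group.
#' @param rate_chimera,rate_nonchimera per-interval survival probabilities in
#'   `[0, 1]`.
#' @param timepoints labels for the successive census times (months).
#' @param seed integer seed.
#' @return data.frame with columns group, timepoint, n_alive, n_total.
#' @export
simulate_survival_counts <- function(n0_per_group = 80, rate_chimera = 0.9,
                                     rate_nonchimera = 0.75,
                                     timepoints = c(6, 12), seed = 1L) {
  rates <- c(chimera = rate_chimera, nonchimera = rate_nonchimera)
  if (any(rates < 0 | rates > 1)) fail("survival rates must be in [0, 1]")
  with_seed(seed, {
    out <- list()
    for (g in names(rates)) {
      alive <- n0_per_group
      for (tp in timepoints) {
        alive <- stats::rbinom(1, alive, rates[[g]])
        out[[length(out) + 1L]] <-
          data.frame(group = g, timepoint = as.integer(tp),
                     n_alive = as.integer(alive),
                     n_total = as.integer(n0_per_group),
                     stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
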