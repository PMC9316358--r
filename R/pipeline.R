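# End-to-end orchestrator: reproduces the analysis graph (DE per contrast ->
# frontloading classification -> enrichment -> DAPC plasticity -> chimerism
# -> microbiome -> field statistics) on synthetic or user data, with fixed
# stage order and a single seed.

# position-weighted checksum so run reports can fingerprint inputs without
# an external digest dependency; changes in content or order change the value
fnv1a <- function(obj) {
  b <- as.double(serialize(obj, NULL, version = 2))
  i <- seq_along(b)
  h1 <- sum(b * ((i %% 251) + 1)) %% 4294967291
  h2 <- sum(b * ((i %% 241) + 7)) %% 4294967291
  sprintf("%08x%08x", as.integer(h1 %% 2147483647), as.integer(h2 %% 2147483647))
}

#' Pipeline configuration
#'
#' Either names a simulation preset (all inputs generated with known ground
#' truth) or points at user files. Thresholds are validated here and echoed
#' in the run report.
#'
#' @param preset simulation preset name (see [sim_preset()]), or NULL when
#'   `paths` is given.
#' @param seed integer seed; all pipeline randomness flows from it.
#' @param paths named list of input files (counts, metadata, go, vcf_dir,
#'   microsat, otu, otu_metadata, logger, survival); any subset may be given.
#' @param alpha FDR threshold for DE and classification.
#' @param go_smallest,go_largest,go_cut_height GO index filtering and
#'   clustering parameters.
#' @param mnp_allele_threshold multiallelic threshold (distinct alleles must
#'   exceed it).
#' @param otu_min_fraction OTU relative-abundance filter.
#' @param out_dir output directory.
#' @return validated config object (class `cf_config`).
#' @export
pipeline_config <- function(preset = "paper_like", seed = 1L, paths = list(),
                            alpha = 0.05, go_smallest = 10, go_largest = 0.1,
                            go_cut_height = 0.5, mnp_allele_threshold = 2,
                            otu_min_fraction = 0.01,
                            out_dir = tempfile("coralfront_run_")) {
  if (alpha <= 0 || alpha >= 1) fail("alpha must be in (0, 1)")
  if (go_largest <= 0 || go_largest >= 1) fail("go_largest must be in (0, 1)")
  if (go_cut_height < 0 || go_cut_height > 1) fail("go_cut_height must be in [0, 1]")
  if (otu_min_fraction < 0 || otu_min_fraction >= 1) {
    fail("otu_min_fraction must be in [0, 1)")
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) fail("input path does not exist: %s", p)
  }
  if (is.null(preset) && length(paths) == 0) fail("either a preset or paths required")
  structure(
    list(preset = preset, seed = as.integer(seed), paths = paths,
         alpha = alpha, go_smallest = go_smallest, go_largest = go_largest,
         go_cut_height = go_cut_height,
         mnp_allele_threshold = mnp_allele_threshold,
         otu_min_fraction = otu_min_fraction, out_dir = out_dir),
    class = "cf_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `paths` is a
#' nested mapping.
#'
#' @param path YAML file.
#' @return `cf_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Load (or simulate) and validate all pipeline inputs
#'
#' With a preset, every input is generated from the single config seed (the
#' expression/GO/variant/OTU/logger/survival generators get distinct derived
#' seeds so their draws are independent but reproducible). With paths, the
#' matching readers are applied with schema validation and cross-file
#' consistency checks (counts columns vs metadata samples).
#'
#' @param config a [pipeline_config()] object.
#' @return named list of in-memory datasets.
#' @export
load_inputs <- function(config) {
  if (!is.null(config$preset)) {
    ps <- sim_preset(config$preset, seed = config$seed)
    sim <- simulate_counts(ps$design, ps$params)
    truth_front <- sim$truth$gene_id[sim$truth$category == "FRONTLOADED"]
    planted <- list()
    if (length(truth_front) >= 20) {
      planted <- list("GO:PLANTED01" = truth_front[1:20])
    }
    go <- simulate_go_annotation(ps$design$n_genes, n_terms = 120,
                                 planted = planted, seed = config$seed + 101L)
    variants <- simulate_variant_table(
      n_chimera = 11, n_nonchimera = 9, n_loci = 200,
      multiallelic_excess = 0.3, seed = config$seed + 202L
    )
    otu <- simulate_otu_table(
      n_samples_per_group = stats::setNames(
        as.integer(ps$design$replicates),
        names(ps$design$replicates)
      ),
      n_otus = 60, effect = 0, seed = config$seed + 303L
    )
    logger <- rbind(
      simulate_logger(temp_mean = 25.4, temp_amplitude = 0.3,
                      light_peak = 12000, depth_label = "10m",
                      seed = config$seed + 404L),
      simulate_logger(temp_mean = 25.9, temp_amplitude = 0.9,
                      light_peak = 85000, depth_label = "2m",
                      seed = config$seed + 405L)
    )
    survival <- simulate_survival_counts(seed = config$seed + 506L)
    otu_meta <- otu$metadata
    otu_meta$entity <- sub("_(10m|2m)$", "", otu_meta$group)
    otu_meta$depth <- sub("^(chimera|nonchimera)_", "", otu_meta$group)
    list(counts = sim$counts, metadata = sim$metadata, truth = sim$truth,
         go = go, variants = variants, otu = otu$counts,
         otu_metadata = otu_meta, logger = logger, survival = survival)
  } else {
    p <- config$paths
    out <- list()
    if (!is.null(p$counts)) out$counts <- read_counts_tsv(p$counts)
    if (!is.null(p$metadata)) out$metadata <- read_metadata_csv(p$metadata)
    if (!is.null(out$counts) && !is.null(out$metadata)) {
      miss <- setdiff(colnames(out$counts), out$metadata$sample_id)
      if (length(miss) > 0) {
        fail("metadata missing count-matrix sample(s): %s",
             paste(miss, collapse = ", "))
      }
      out$metadata <- out$metadata[match(colnames(out$counts),
                                         out$metadata$sample_id), ]
    }
    if (!is.null(p$go)) out$go <- read_go_annotation(p$go, p$go_parents)
    if (!is.null(p$vcf_dir)) out$vcf_dir <- p$vcf_dir
    if (!is.null(p$microsat)) out$microsat <- read_microsat_csv(p$microsat)
    if (!is.null(p$otu)) out$otu <- read_otu_tsv(p$otu)
    if (!is.null(p$otu_metadata)) {
      out$otu_metadata <- utils::read.csv(p$otu_metadata, stringsAsFactors = FALSE)
    }
    if (!is.null(p$logger)) out$logger <- read_logger_csv(p$logger)
    if (!is.null(p$survival)) out$survival <- read_survival_csv(p$survival)
    out
  }
}

run_stage <- function(report, name, params, f) {
  res <- tryCatch(
    list(ok = TRUE, value = f()),
    error = function(e) list(ok = FALSE, error = conditionMessage(e))
  )
  report$stages[[name]] <- c(list(parameters = params), res[-1],
                             list(ok = res$ok))
  report
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: differential expression (four contrasts:
#' entity within each depth, depth within each entity), frontloading
#' classification, GO enrichment (rank-based per contrast plus Fisher on the
#' frontloaded set), batch-effect removal with ordination and DAPC
#' plasticity, the chimerism MNP test, the microbiome report, and field
#' statistics. Intermediates are written under the config's output
#' directory; a stage failure is recorded and its dependents skipped.
#'
#' @param config a [pipeline_config()] object.
#' @return a run report (class `cf_report`): per-stage parameters, headline
#'   outputs, warnings, and an inputs fingerprint.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(config)
  report <- structure(
    list(config = config[setdiff(names(config), "out_dir")],
         inputs_digest = fnv1a(inputs), stages = list()),
    class = "cf_report"
  )

  de <- NULL
  if (!is.null(inputs$counts)) {
    report <- run_stage(report, "differential_expression",
                        list(alpha = config$alpha), function() {
      contrasts <- list(
        entity_at_10m = c("entity", "10m"), entity_at_2m = c("entity", "2m"),
        depth_in_nonchimera = c("depth", "nonchimera"),
        depth_in_chimera = c("depth", "chimera")
      )
      res <- lapply(contrasts, function(ct) {
        suppressMessages(de_contrast(inputs$counts, inputs$metadata,
                                     ct[1], ct[2]))
      })
      for (nm in names(res)) {
        write_de_tsv(res[[nm]], file.path(config$out_dir, paste0("de_", nm, ".tsv")))
      }
      de <<- res
      list(deg_counts = vapply(res, function(r) sum(r$fdr < config$alpha), 1L))
    })
  }

  classification <- NULL
  if (!is.null(de)) {
    report <- run_stage(report, "classification",
                        list(alpha = config$alpha), function() {
      cls <- classify_frontloading(de$depth_in_nonchimera, de$entity_at_10m,
                                   de$depth_in_chimera, alpha = config$alpha)
      utils::write.table(cls, file.path(config$out_dir, "classification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      classification <<- cls
      list(category_counts = as.list(table(cls$category)),
           n_responsive = nrow(cls))
    })
  }

  if (!is.null(de) && !is.null(inputs$go)) {
    report <- run_stage(report, "enrichment",
                        list(smallest = config$go_smallest,
                             largest = config$go_largest,
                             cut_height = config$go_cut_height), function() {
      universe <- de$depth_in_nonchimera$gene_id
      index <- build_go_index(inputs$go, universe,
                              smallest = config$go_smallest,
                              largest = config$go_largest)
      index <- cluster_go_terms(index, config$go_cut_height,
                                largest = config$go_largest)
      mwu <- lapply(de, function(r) {
        measure <- stats::setNames(r$log2fc, r$gene_id)[universe]
        mwu_enrichment(measure, index)
      })
      for (nm in names(mwu)) {
        utils::write.table(
          mwu[[nm]], file.path(config$out_dir, paste0("enrich_mwu_", nm, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE
        )
      }
      headline <- list(
        enriched_counts = vapply(mwu, function(r) sum(r$fdr < config$alpha), 1L)
      )
      if (!is.null(classification) && nrow(classification) > 0) {
        flag <- stats::setNames(universe %in% classification$gene_id[
          classification$category %in%
            c("FRONTLOADED", "FRONTLOADED_AND_HIGHER_PLASTICITY")
        ], universe)
        if (any(flag) && !all(flag)) {
          fish <- fisher_enrichment(flag, index)
          utils::write.table(
            fish, file.path(config$out_dir, "enrich_fisher_frontloaded.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE
          )
          headline$fisher_enriched <- sum(fish$fdr < config$alpha)
        }
      }
      dr <- delta_rank_correlation(mwu$depth_in_nonchimera, mwu$depth_in_chimera)
      headline$delta_rank_r <- dr$r
      headline
    })
  }

  if (!is.null(inputs$counts)) {
    report <- run_stage(report, "plasticity", list(), function() {
      logc <- normalized_log_counts(inputs$counts)
      adj <- remove_batch_effect(logc, inputs$metadata$mother_colony)
      ord <- sample_ordination(adj)
      dp <- dapc_plasticity(adj, inputs$metadata)
      utils::write.table(
        data.frame(sample_id = names(dp$coords), coord = dp$coords),
        file.path(config$out_dir, "dapc_coords.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      list(metrics = dp$metrics, pc1_explained = ord$explained[1])
    })
  }

  if (!is.null(inputs$variants) || !is.null(inputs$vcf_dir)) {
    report <- run_stage(report, "chimerism",
                        list(allele_threshold = config$mnp_allele_threshold),
                        function() {
      if (!is.null(inputs$variants)) {
        vcf_dir <- file.path(config$out_dir, "vcf")
        write_vcf_per_sample(inputs$variants, vcf_dir)
        entity_map <- inputs$variants$samples
      } else {
        vcf_dir <- inputs$vcf_dir
        entity_map <- inputs$metadata[, c("sample_id", "entity")]
      }
      files <- list.files(vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
      summaries <- do.call(rbind, lapply(files, function(f) {
        extract_mnp_summary(f, allele_threshold = config$mnp_allele_threshold)
      }))
      test <- test_multiallelic_enrichment(summaries, entity_map)
      utils::write.table(summaries, file.path(config$out_dir, "mnp_summaries.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(u_statistic = test$u_statistic, p_value = test$p_value)
    })
  }

  if (!is.null(inputs$otu)) {
    report <- run_stage(report, "microbiome",
                        list(min_fraction = config$otu_min_fraction), function() {
      mb <- microbiome_report(inputs$otu, inputs$otu_metadata,
                              min_fraction = config$otu_min_fraction)
      list(n_otus_kept = nrow(mb$filtered),
           alpha_tests = mb$tests)
    })
  }

  if (!is.null(inputs$logger)) {
    report <- run_stage(report, "field_stats", list(), function() {
      env <- summarize_logger(inputs$logger)
      out <- list(env_summary = env)
      if (!is.null(inputs$survival)) {
        out$survival_tests <- survival_tests(inputs$survival)
      }
      out
    })
  }

  failed <- any(!vapply(report$stages, function(s) isTRUE(s$ok), logical(1)))
  report$ok <- !failed
  write_report(report, config$out_dir)
  report
}

#' Write a run report as JSON and a human-readable summary
#'
#' @param report a `cf_report` from [run_pipeline()].
#' @param dir output directory.
#' @return paths of the two files, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  txt <- c(sprintf("coralfront run (inputs %s)", report$inputs_digest), "")
  for (nm in names(report$stages)) {
    s <- report$stages[[nm]]
    txt <- c(txt, sprintf("stage %-25s %s", nm,
                          if (isTRUE(s$ok)) "ok" else paste("FAILED:", s$error)))
  }
  txt_path <- file.path(dir, "report.txt")
  writeLines(txt, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}
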