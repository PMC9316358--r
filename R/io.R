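# Readers and writers for every interchange format the pipeline consumes or
# produces. Writers and readers round-trip exactly; readers validate schemas
# and report the file and offending columns.

check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    fail("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  }
}

#' Write / read a gene-by-sample count matrix as TSV
#'
#' Genes as rows; the first column is `gene_id`.
#'
#' @param counts integer matrix with row and column names.
#' @param path file path.
#' @return `read_counts_tsv` returns the integer matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_columns(df, "gene_id", path)
  if (anyDuplicated(df$gene_id)) fail("%s: duplicate gene ids", path)
  if (anyDuplicated(names(df)[-1])) fail("%s: duplicate sample ids", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    fail("%s: counts must be non-negative integers", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Write / read sample metadata as CSV
#'
#' Columns: sample_id, entity, depth, mother_colony.
#'
#' @param metadata data.frame.
#' @param path file path.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "entity", "depth", "mother_colony"), path)
  if (anyDuplicated(df$sample_id)) fail("%s: duplicate sample ids", path)
  bad <- setdiff(unique(df$entity), c("chimera", "nonchimera"))
  if (length(bad) > 0) fail("%s: unknown entity value(s): %s", path,
                            paste(bad, collapse = ", "))
  df
}

#' Write per-sample variant records as single-sample VCF v4.2 files
#'
#' One file per sample (`<sample_id>.vcf`), with MNP and SNP records, a GT
#' genotype column, and a minimal but valid v4.2 header.
#'
#' @param sim result of [simulate_variant_table()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths.
#' @export
write_vcf_per_sample <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sim$samples$sample_id, function(sid) {
    rec <- sim$records[[sid]]
    path <- file.path(dir, paste0(sid, ".vcf"))
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=coralfront-simulator",
      "##contig=<ID=chr1>",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sid, sep = "\t")
    )
    body <- sprintf("%s\t%d\t.\t%s\t%s\t99\tPASS\t.\tGT\t%s",
                    rec$chrom, rec$pos, rec$ref, rec$alt, rec$gt)
    writeLines(c(header, body), path)
    path
  }, character(1))
  invisible(paths)
}

#' Write / read a gene-to-GO annotation
#'
#' Two-column TSV (gene_id, term_id); parent links, when present, go to a
#' companion two-column TSV (child, parent).
#'
#' @param annotation a `go_annotation` object.
#' @param path TSV path for the gene-term map.
#' @param parents_path optional TSV path for parent links.
#' @export
write_go_annotation <- function(annotation, path, parents_path = NULL) {
  utils::write.table(annotation$gene2term, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(parents_path) && nrow(annotation$parents) > 0) {
    utils::write.table(annotation$parents, parents_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_go_annotation
#' @export
read_go_annotation <- function(path, parents_path = NULL) {
  g2t <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(g2t, c("gene_id", "term_id"), path)
  parents <- data.frame(child = character(0), parent = character(0))
  if (!is.null(parents_path) && file.exists(parents_path)) {
    parents <- utils::read.delim(parents_path, stringsAsFactors = FALSE)
    check_columns(parents, c("child", "parent"), parents_path)
  }
  terms <- unique(c(g2t$term_id, parents$child, parents$parent))
  structure(
    list(gene2term = g2t, parents = parents,
         term_names = stats::setNames(terms, terms)),
    class = "go_annotation"
  )
}

#' Write / read an OTU table as TSV
#'
#' OTUs as rows; first column `otu_id`.
#'
#' @param counts integer matrix, OTUs x samples.
#' @param path file path.
#' @export
write_otu_tsv <- function(counts, path) {
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_tsv
#' @export
read_otu_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_columns(df, "otu_id", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(m < 0)) fail("%s: negative counts", path)
  storage.mode(m) <- "integer"
  rownames(m) <- df$otu_id
  m
}

#' Read a minimal BIOM-JSON (v1) OTU table
#'
#' Supports the dense and sparse matrix types of the classic JSON BIOM
#' format; only ids and counts are read.
#'
#' @param path file path.
#' @return integer matrix, OTUs x samples.
#' @export
read_biom_json <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- vapply(b$rows, function(r) r$id, character(1))
  cols <- vapply(b$columns, function(c) c$id, character(1))
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[i, ] <- as.integer(unlist(b$data[[i]]))
  } else {
    for (entry in b$data) {
      m[entry[[1]] + 1L, entry[[2]] + 1L] <- as.integer(entry[[3]])
    }
  }
  m
}

#' Write / read a logger series as CSV
#'
#' Columns: timestamp, temperature_C, light_lux, depth.
#'
#' @param series data.frame.
#' @param path file path.
#' @export
write_logger_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_logger_csv
#' @export
read_logger_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("timestamp", "temperature_C", "light_lux", "depth"), path)
  if (any(!is.finite(df$temperature_C))) fail("%s: non-finite temperature", path)
  if (any(df$light_lux < 0)) fail("%s: negative light", path)
  df
}

#' Write / read a survival count table as CSV
#'
#' Columns: group, timepoint, n_alive, n_total.
#'
#' @param survival data.frame.
#' @param path file path.
#' @export
write_survival_csv <- function(survival, path) {
  utils::write.csv(survival, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("group", "timepoint", "n_alive", "n_total"), path)
  if (any(df$n_alive < 0 | df$n_alive > df$n_total)) {
    fail("%s: n_alive outside [0, n_total]", path)
  }
  for (g in unique(df$group)) {
    s <- df[df$group == g, ]
    s <- s[order(s$timepoint), ]
    if (is.unsorted(rev(s$n_alive))) {
      fail("%s: n_alive increases over time for group %s", path, g)
    }
  }
  df
}

#' Write / read microsatellite genotypes as long-format CSV
#'
#' Columns: sample_id, locus, allele.
#'
#' @param genotypes data.frame.
#' @param path file path.
#' @export
write_microsat_csv <- function(genotypes, path) {
  utils::write.csv(genotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_microsat_csv
#' @export
read_microsat_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "locus", "allele"), path)
  df
}

#' Write a differential-expression result as TSV
#'
#' Columns: gene_id, base_mean, log2fc, se, wald_stat, p_value, fdr,
#' contrast. A header comment records the sign convention (log2fc > 0 means
#' higher in the first-named contrast level).
#'
#' @param result [wald_nb_test()] data.frame.
#' @param path file path.
#' @export
write_de_tsv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# log2fc > 0 means higher in the first-named contrast level", con)
  utils::write.table(result, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, c("gene_id", "log2fc", "p_value", "fdr"), path)
  df
}
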