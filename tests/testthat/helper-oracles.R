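# Independent oracles used across test files.

# Brute-force Mann-Whitney: enumerate every assignment of the pooled values
# to the two groups and measure how extreme the observed U is. Only valid
# without ties. Two-sided p by distance of U from its null mean.
mwu_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, u_of)
  m <- n1 * n2 / 2
  list(u = u_obs,
       p_two = mean(abs(u_all - m) >= abs(u_obs - m) - 1e-9),
       p_greater = mean(u_all >= u_obs - 1e-9))
}

# build a go_annotation from a named list term -> gene vector
make_annotation <- function(terms) {
  g2t <- do.call(rbind, lapply(names(terms), function(tm) {
    data.frame(gene_id = terms[[tm]], term_id = tm, stringsAsFactors = FALSE)
  }))
  structure(
    list(gene2term = g2t,
         parents = data.frame(child = character(0), parent = character(0)),
         term_names = stats::setNames(names(terms), names(terms))),
    class = "go_annotation"
  )
}

# a minimal DE-result row set for the classification rule tests
de_row <- function(gene, lfc, fdr) {
  data.frame(gene_id = gene, log2fc = lfc, fdr = fdr,
             stringsAsFactors = FALSE)
}

# hand-written VCF with three MNP records whose genotypes carry 2, 3 and 4
# distinct alleles, plus two SNP records
write_test_vcf <- function(path, sample = "s1", crlf = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    "chr1\t100\t.\tAT\tCG\t99\tPASS\t.\tGT\t0/1",
    "chr1\t200\t.\tGGA\tTTC,ACT\t99\tPASS\t.\tGT\t0/1/2",
    "chr1\t300\t.\tCA\tGT,TG,AC\t99\tPASS\t.\tGT\t0/1/2/3",
    "chr1\t400\t.\tA\tG\t99\tPASS\t.\tGT\t0/1",
    "chr1\t500\t.\tT\tC\t99\tPASS\t.\tGT\t0/1"
  )
  con <- file(path, "wb")
  writeLines(lines, con, sep = if (crlf) "\r\n" else "\n")
  close(con)
  path
}
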