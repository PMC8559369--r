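# small constructors used across test files

# genotype matrix from a character matrix of genotype strings
gm_from_strings <- function(gt, chrom = "chr1", pos = NULL, ref = "A",
                            alt = "G", filter = "PASS", gq = NULL,
                            dp = NULL, samples = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  pair <- parse_genotypes(as.vector(gt))
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      filter = rep_len(filter, n))
  genotype_matrix(sites, samples,
                  ga = matrix(pair[, "a"], n), gb = matrix(pair[, "b"], n),
                  gq = gq, dp = dp)
}

# random biallelic matrix for property tests (strings version kept too)
random_gm <- function(n_sites, n_samples, miss_rate = 0.15,
                      chrom = "chr1") {
  g <- sample(c("0/0", "0/1", "1/1"), n_sites * n_samples, replace = TRUE,
              prob = c(0.5, 0.3, 0.2))
  g[stats::runif(length(g)) < miss_rate] <- "./."
  gm_from_strings(matrix(g, n_sites, n_samples), chrom = chrom,
                  pos = sort(sample.int(10 * n_sites, n_sites)),
                  gq = matrix(sample(0:99, n_sites * n_samples, TRUE),
                              n_sites),
                  dp = matrix(sample(0:30, n_sites * n_samples, TRUE),
                              n_sites))
}

write_lines_tmp <- function(lines, ext = ".vcf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a tiny hand-written 2-sample VCF used by reader tests
tiny_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##contig=<ID=chr2>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "NA1", "NA2"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "G", "50", "PASS", ".",
            "GT:GQ:DP", "0/1:35:7", "./."), collapse = "\t"),
    paste(c("chr1", "200", ".", "C", "T,G", "50", "q10", ".",
            "GT:GQ:DP", "0|2:12:3", "1/1:99:30"), collapse = "\t"),
    paste(c("chr2", "50", ".", "CT", "C", "50", "PASS", ".",
            "GT:GQ:DP", "0/1:22:9", "0/0:18:4"), collapse = "\t"))
}
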