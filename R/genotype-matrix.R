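#' Construct a genotype matrix
#'
#' The central container of the package: a sites-by-samples collection of
#' diploid genotype calls together with per-call genotype quality (GQ) and
#' read depth (DP). Genotypes are stored as unordered pairs of allele
#' indices (0 = reference, k >= 1 = k-th alternate allele); phase is never
#' retained. A missing call is `NA` in both allele slots.
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (1-based integer position), `ref` (reference allele), `alt`
#'   (comma-separated alternate alleles) and optionally `filter` (site
#'   filter status, defaults to `"PASS"`).
#' @param samples character vector of sample identifiers.
#' @param ga,gb integer matrices (sites x samples) holding the smaller and
#'   larger allele index of each call; `NA` in both marks a missing call.
#' @param gq integer matrix of phred-scaled genotype qualities, `NA` where
#'   absent. Values are clamped to \[0, 99\].
#' @param dp integer matrix of read depths, `NA` where absent.
#' @param contigs character vector fixing the chromosome sort order;
#'   defaults to first appearance in `sites$chrom`.
#'
#' @return An object of class `genotype_matrix` with sites sorted by
#'   (contig order, position, ref, first alt).
#' @export
genotype_matrix <- function(sites, samples, ga, gb,
                            gq = NULL, dp = NULL, contigs = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  n_sites <- nrow(sites)
  n_samples <- length(samples)
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")

  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  if (is.null(sites$filter)) sites$filter <- "PASS"
  if (n_sites > 0 && any(sites$pos < 1L)) stop("positions must be >= 1")
  if (n_sites > 0) {
    bad <- !nzchar(sites$ref) | !nzchar(sites$alt)
    if (any(bad)) stop("empty ref or alt allele at site ", which(bad)[1])
  }
  sites$vtype <- variant_type(sites$ref, sites$alt)

  shape <- function(m) {
    if (is.null(m)) m <- matrix(NA_integer_, n_sites, n_samples)
    matrix(as.integer(m), n_sites, n_samples)
  }
  ga <- shape(ga)
  gb <- shape(gb)
  gq <- pmin(pmax(shape(gq), 0L), 99L)
  dp <- shape(dp)

  n_alts <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  if (any(gb > n_alts, na.rm = TRUE) || any(ga < 0L, na.rm = TRUE))
    stop("allele index out of range for the site's alt list")

  # normalise to unordered (sorted) pairs; half-calls were resolved upstream
  swap <- !is.na(ga) & !is.na(gb) & ga > gb
  if (any(swap)) {
    tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  }

  if (is.null(contigs)) contigs <- unique(sites$chrom)
  contigs <- union(as.character(contigs), sites$chrom)

  m <- structure(
    list(sites = sites, samples = samples, ga = ga, gb = gb,
         gq = gq, dp = dp, contigs = contigs),
    class = "genotype_matrix")
  sort_sites(m)
}

variant_type <- function(ref, alt) {
  alt_lens <- vapply(strsplit(alt, ",", fixed = TRUE),
                     function(a) max(nchar(a)), integer(1))
  ifelse(nchar(ref) == 1L & alt_lens == 1L, "SNV", "INDEL")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples\n",
              n_sites(x), n_samples(x)))
  cat(sprintf("  SNV %d / INDEL %d; missing calls %.1f%%\n",
              sum(x$sites$vtype == "SNV"), sum(x$sites$vtype == "INDEL"),
              100 * mean(is.na(x$ga))))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param m a `genotype_matrix`.
#' @return integer count.
#' @export
n_sites <- function(m) nrow(m$sites)

#' @rdname n_sites
#' @export
n_samples <- function(m) length(m$samples)

#' Site keys
#'
#' A site is keyed by (chrom, pos, ref, alt set); the alternate alleles are
#' sorted so the key is insensitive to ALT ordering. Records at the same
#' position with different allele sets are distinct sites.
#'
#' @param m a `genotype_matrix`.
#' @return character vector of keys, one per site.
#' @export
site_keys <- function(m) {
  alt_sorted <- vapply(strsplit(m$sites$alt, ",", fixed = TRUE),
                       function(a) paste(sort(a), collapse = ","),
                       character(1))
  paste(m$sites$chrom, m$sites$pos, m$sites$ref, alt_sorted, sep = ":")
}

sort_sites <- function(m) {
  first_alt <- sub(",.*$", "", m$sites$alt)
  ord <- order(match(m$sites$chrom, m$contigs), m$sites$pos,
               m$sites$ref, first_alt)
  subset_sites(m, ord)
}

subset_sites <- function(m, idx) {
  m$sites <- m$sites[idx, , drop = FALSE]
  rownames(m$sites) <- NULL
  m$ga <- m$ga[idx, , drop = FALSE]
  m$gb <- m$gb[idx, , drop = FALSE]
  m$gq <- m$gq[idx, , drop = FALSE]
  m$dp <- m$dp[idx, , drop = FALSE]
  m
}

set_missing <- function(m, which_calls) {
  m$ga[which_calls] <- NA_integer_
  m$gb[which_calls] <- NA_integer_
  m$gq[which_calls] <- NA_integer_
  m$dp[which_calls] <- NA_integer_
  m
}

#' Genotypes as strings
#'
#' @param m a `genotype_matrix`.
#' @return character matrix of unphased genotype strings (`"0/1"`),
#'   `"./."` for missing calls.
#' @export
genotype_strings <- function(m) {
  g <- matrix("./.", n_sites(m), n_samples(m),
              dimnames = list(NULL, m$samples))
  ok <- !is.na(m$ga)
  g[ok] <- paste0(m$ga[ok], "/", m$gb[ok])
  g
}

# dosage of non-reference alleles, NA for missing
alt_dosage <- function(m) {
  (m$ga > 0L) + (m$gb > 0L)
}

# TRUE where the call is non-missing and carries >= 1 alternate allele
is_variant_call <- function(m) {
  v <- !is.na(m$ga) & (m$ga > 0L | m$gb > 0L)
  v
}

#' Parse genotype strings into allele-index pairs
#'
#' Accepts phased (`"0|1"`) and unphased (`"0/1"`) diploid genotypes;
#' phase is discarded and the pair returned sorted. `"."`, `"./."` and
#' half-calls such as `"./1"` all map to a missing pair, as do haploid
#' entries.
#'
#' @param gt character vector of VCF genotype strings (`NA` allowed).
#' @return integer matrix with columns `a` and `b` (`a <= b`), `NA` rows
#'   for missing calls.
#' @export
parse_genotypes <- function(gt) {
  n <- length(gt)
  a <- rep(NA_integer_, n)
  b <- rep(NA_integer_, n)
  gt <- sub(":.*$", "", gt)           # tolerate full sample strings
  norm <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(norm, "/", fixed = TRUE)
  ok <- !is.na(gt) & lengths(parts) == 2L
  if (any(ok)) {
    pa <- vapply(parts[ok], `[`, character(1), 1L)
    pb <- vapply(parts[ok], `[`, character(1), 2L)
    full <- pa != "." & pb != "."
    ia <- suppressWarnings(as.integer(pa))
    ib <- suppressWarnings(as.integer(pb))
    keep <- full & !is.na(ia) & !is.na(ib)
    idx <- which(ok)[keep]
    a[idx] <- pmin(ia[keep], ib[keep])
    b[idx] <- pmax(ia[keep], ib[keep])
  }
  cbind(a = a, b = b)
}
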