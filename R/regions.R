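#' Read a BED file of genomic regions
#'
#' Reads a 3+ column BED file (0-based, half-open intervals) and returns
#' a normalized region set: per-chromosome sorted with overlapping and
#' book-ended intervals merged. `track`/`browser`/comment lines are
#' skipped.
#'
#' @param path BED file path.
#' @return A `region_set`: data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  ln <- ln[!grepl("^(track|browser|#)", ln)]
  if (length(ln) == 0L)
    return(region_set(data.frame(chrom = character(0),
                                 start = integer(0), end = integer(0))))
  tab <- utils::read.table(text = ln, header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(tab) < 3L) stop("BED file needs >= 3 columns: ", path)
  region_set(data.frame(chrom = as.character(tab[[1L]]),
                        start = as.integer(tab[[2L]]),
                        end = as.integer(tab[[3L]])))
}

#' Construct a normalized region set
#'
#' @param df data.frame with `chrom`, `start`, `end` in BED convention
#'   (0-based half-open).
#' @return A `region_set` with intervals sorted and merged via
#'   [GenomicRanges::reduce()].
#' @export
region_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$start >= df$end))
    stop("BED interval with start >= end at row ",
         which(df$start >= df$end)[1])
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end))
  gr <- GenomicRanges::reduce(gr)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

as_granges <- function(regions) {
  GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
}

#' Restrict a genotype matrix to regions
#'
#' Keeps exactly the sites whose 0-based position (`pos - 1`) falls in
#' some half-open interval of `regions`; the sample set is unchanged.
#' Idempotent.
#'
#' @param m a `genotype_matrix`.
#' @param regions a `region_set`.
#' @return The restricted `genotype_matrix`.
#' @export
restrict_to_regions <- function(m, regions) {
  stopifnot(inherits(m, "genotype_matrix"), inherits(regions, "region_set"))
  if (n_sites(m) == 0L || nrow(regions) == 0L)
    return(subset_sites(m, integer(0)))
  pts <- GenomicRanges::GRanges(
    m$sites$chrom, IRanges::IRanges(start = m$sites$pos, width = 1L))
  hit <- IRanges::overlapsAny(pts, as_granges(regions))
  subset_sites(m, which(hit))
}

# TRUE per site for membership in regions (used by stratification)
sites_in_regions <- function(m, regions) {
  if (n_sites(m) == 0L) return(logical(0))
  pts <- GenomicRanges::GRanges(
    m$sites$chrom, IRanges::IRanges(start = m$sites$pos, width = 1L))
  IRanges::overlapsAny(pts, as_granges(regions))
}
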