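#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (v4.2 dialect, plain text or gzipped) with
#' [vcfR::read.vcfR()] and converts it to a [genotype_matrix()]. One site
#' per record: multiallelic records are kept as single sites, never
#' decomposed. Phase is discarded; half-calls (e.g. `"./1"`) are treated
#' as missing. Chromosome order follows the header `##contig` lines, or
#' first appearance when absent.
#'
#' @param path VCF file path.
#' @param required_fields FORMAT fields that must be present on at least
#'   one record; subset of `c("GT", "GQ", "DP")`. `GT` is always required.
#' @param keep_filtered keep non-PASS sites (default `TRUE`); set `FALSE`
#'   to drop them at read time.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, required_fields = c("GT"), keep_filtered = TRUE) {
  required_fields <- match.arg(required_fields, c("GT", "GQ", "DP"),
                               several.ok = TRUE)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(v@gt) || ncol(v@gt) < 2L)
    stop("VCF has no sample columns: ", path)

  fmt <- v@gt[, 1L]
  for (f in union("GT", required_fields)) {
    if (!any(grepl(paste0("(^|:)", f, "(:|$)"), fmt)))
      stop("required FORMAT field '", f,
           "' absent from every record in ", path)
  }

  fix <- v@fix
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1L]

  gt <- vcfR::extract.gt(v, element = "GT")
  pair <- parse_genotypes(as.vector(gt))
  get_int <- function(el) {
    if (!any(grepl(paste0("(^|:)", el, "(:|$)"), fmt)))
      return(matrix(NA_integer_, n, length(samples)))
    x <- suppressWarnings(
      as.integer(as.vector(vcfR::extract.gt(v, element = el))))
    matrix(x, n, length(samples))
  }

  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    filter = filt,
    stringsAsFactors = FALSE)

  contigs <- vcf_header_contigs(v@meta)
  m <- genotype_matrix(
    sites, samples,
    ga = matrix(pair[, "a"], n, length(samples)),
    gb = matrix(pair[, "b"], n, length(samples)),
    gq = get_int("GQ"), dp = get_int("DP"),
    contigs = if (length(contigs)) contigs else NULL)
  if (!keep_filtered) m <- subset_sites(m, which(m$sites$filter == "PASS"))
  m
}

vcf_header_contigs <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  sub('^##contig=<ID=([^,>]+).*$', "\\1", ln)
}

#' Write a genotype matrix as VCF
#'
#' Emits a plain-text VCF v4.2 file carrying GT and, where any value is
#' present, GQ and DP FORMAT fields. Missing calls are written `"./."`.
#' The write/read round trip through [read_vcf()] reproduces the matrix
#' on all handled fields.
#'
#' @param m a `genotype_matrix`.
#' @param path output file path (plain text; pass through `bgzip` for
#'   tabix indexing).
#' @param extra_format optional named list with one entry: an integer
#'   sites-x-samples matrix emitted as an additional `Number=1` FORMAT
#'   tag, e.g. `list(IM = flags)`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, extra_format = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  ns <- n_sites(m)
  fields <- "GT"
  if (any(!is.na(m$gq))) fields <- c(fields, "GQ")
  if (any(!is.na(m$dp))) fields <- c(fields, "DP")
  extra_name <- NULL
  if (!is.null(extra_format)) {
    stopifnot(is.list(extra_format), length(extra_format) == 1L,
              !is.null(names(extra_format)))
    extra_name <- names(extra_format)
    fields <- c(fields, extra_name)
  }

  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", m$contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if ("GQ" %in% fields)
    hdr <- c(hdr, "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">")
  if ("DP" %in% fields)
    hdr <- c(hdr, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">")
  if (!is.null(extra_name)) {
    desc <- if (identical(extra_name, "IM"))
      "Imputation consistency flag" else extra_name
    hdr <- c(hdr, sprintf(
      "##FORMAT=<ID=%s,Number=1,Type=Integer,Description=\"%s\">",
      extra_name, desc))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", m$samples),
                      collapse = "\t"))

  cell <- genotype_strings(m)
  fmt_int <- function(x) ifelse(is.na(x), ".", as.character(x))
  if ("GQ" %in% fields) cell <- matrix(paste(cell, fmt_int(m$gq), sep = ":"),
                                       ns, n_samples(m))
  if ("DP" %in% fields) cell <- matrix(paste(cell, fmt_int(m$dp), sep = ":"),
                                       ns, n_samples(m))
  if (!is.null(extra_name)) {
    ex <- matrix(as.integer(extra_format[[1L]]), ns, n_samples(m))
    cell <- matrix(paste(cell, fmt_int(ex), sep = ":"), ns, n_samples(m))
  }

  body <- if (ns == 0L) character(0) else paste(
    m$sites$chrom, m$sites$pos, ".", m$sites$ref, m$sites$alt, ".",
    m$sites$filter, ".", paste(fields, collapse = ":"),
    apply(cell, 1L, paste, collapse = "\t"),
    sep = "\t")

  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
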