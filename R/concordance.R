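#' Match sites between two callsets
#'
#' Classifies site keys (chrom, pos, ref, alt set) of a test and a truth
#' callset into shared, test-only and truth-only via a merge over the
#' sorted site lists. Records at the same position with different
#' allele sets are distinct keys and never match.
#'
#' @param test,truth `genotype_matrix` objects.
#' @return A `site_match`: data.frame with one row per key in the union
#'   and columns `key`, `test_idx`, `truth_idx` (`NA` where absent).
#' @export
match_sites <- function(test, truth) {
  tk <- site_keys(test)
  gk <- site_keys(truth)
  keys <- union(tk, gk)
  out <- data.frame(
    key = keys,
    test_idx = match(keys, tk),
    truth_idx = match(keys, gk),
    stringsAsFactors = FALSE)
  class(out) <- c("site_match", "data.frame")
  out
}

#' Site-level recall and precision
#'
#' Recall is the number of true-positive variant sites divided by the
#' number of variant sites in the truth set; precision divides by the
#' number of variant sites in the test set. In per-sample mode a site
#' counts for a sample only when that sample's call is non-missing and
#' carries at least one alternate allele in the respective callset.
#' Undefined ratios (zero denominator) are reported as `NaN`.
#'
#' @param test,truth `genotype_matrix` objects over the same sample set.
#' @param match optional precomputed [match_sites()] result.
#' @param per_sample if `TRUE` (default) one row per sample plus a
#'   pooled row summing the counts; if `FALSE` only the pooled row.
#' @return data.frame with columns `sample`, `tp_sites`,
#'   `truth_only_sites`, `test_only_sites`, `recall`, `precision`. The
#'   pooled row has sample `"(pooled)"`.
#' @export
site_metrics <- function(test, truth, match = NULL, per_sample = TRUE) {
  check_samples(test, truth)
  truth <- align_columns(truth, test$samples)
  if (is.null(match)) match <- match_sites(test, truth)

  nk <- nrow(match)
  ns <- n_samples(test)
  vt <- matrix(FALSE, nk, ns)
  vg <- matrix(FALSE, nk, ns)
  has_t <- !is.na(match$test_idx)
  has_g <- !is.na(match$truth_idx)
  vt[has_t, ] <- is_variant_call(test)[match$test_idx[has_t], , drop = FALSE]
  vg[has_g, ] <- is_variant_call(truth)[match$truth_idx[has_g], , drop = FALSE]

  tp <- colSums(vt & vg)
  fn <- colSums(vg & !vt)
  fp <- colSums(vt & !vg)
  per <- data.frame(
    sample = test$samples, tp_sites = tp, truth_only_sites = fn,
    test_only_sites = fp, row.names = NULL, stringsAsFactors = FALSE)
  pooled <- data.frame(
    sample = "(pooled)", tp_sites = sum(tp), truth_only_sites = sum(fn),
    test_only_sites = sum(fp), stringsAsFactors = FALSE)
  out <- if (per_sample) rbind(per, pooled) else pooled
  out$recall <- out$tp_sites / (out$tp_sites + out$truth_only_sites)
  out$precision <- out$tp_sites / (out$tp_sites + out$test_only_sites)
  out
}

#' Genotype concordance (non-reference or minor-allele mode)
#'
#' Evaluated over sites shared between test and truth and calls
#' non-missing in both. In non-reference mode, pairs where both calls
#' are identical homozygous-reference are excluded from numerator and
#' denominator; all other compared pairs enter the denominator and the
#' numerator counts equal genotype pairs. In minor-allele mode the roles
#' of reference and alternate homozygotes are exchanged at sites whose
#' alternate-allele frequency exceeds 0.5, so the exclusion applies to
#' the major-allele homozygote match instead.
#'
#' @param test,truth `genotype_matrix` objects over the same sample set.
#' @param match optional precomputed [match_sites()] result.
#' @param mode `"nonref"` (default) or `"minor"`.
#' @param af for minor-allele mode: either `NULL` (alternate-allele
#'   frequencies computed from the truth cohort) or a numeric vector of
#'   alt AFs named by site key.
#' @param per_sample as in [site_metrics()].
#' @return data.frame with columns `sample`, `concordant`, `discordant`,
#'   `excluded_homref_pairs`, `concordance`.
#' @export
genotype_concordance <- function(test, truth, match = NULL,
                                 mode = c("nonref", "minor"),
                                 af = NULL, per_sample = TRUE) {
  mode <- match.arg(mode)
  check_samples(test, truth)
  truth <- align_columns(truth, test$samples)
  if (is.null(match)) match <- match_sites(test, truth)
  sh <- match[!is.na(match$test_idx) & !is.na(match$truth_idx), ,
              drop = FALSE]
  t_rows <- sh$test_idx
  g_rows <- sh$truth_idx
  ns <- n_samples(test)

  if (mode == "minor") {
    internal_af <- is.null(af)
    if (internal_af) {
      aft <- compute_af(truth, warn = FALSE)
      af <- stats::setNames(aft$af, aft$key)
    }
    site_af <- unname(af[sh$key])
    if (anyNA(site_af)) {
      if (!internal_af)
        stop("minor-allele mode: no allele frequency for ",
             sum(is.na(site_af)), " shared site(s)")
      site_af[is.na(site_af)] <- 0  # all-missing truth site: nothing compared
    }
  }

  ta <- test$ga[t_rows, , drop = FALSE]
  tb <- test$gb[t_rows, , drop = FALSE]
  pr <- remap_truth_alleles(test, truth, t_rows, g_rows)
  ga <- pr$a; gb <- pr$b

  both <- !is.na(ta) & !is.na(ga)
  equal <- both & ta == ga & tb == gb
  if (mode == "nonref") {
    excluded <- equal & ta == 0L & tb == 0L
  } else {
    flip <- matrix(site_af > 0.5, nrow(sh), ns)
    hom_major <- ifelse(flip, ta == 1L & tb == 1L, ta == 0L & tb == 0L)
    excluded <- equal & hom_major
  }
  conc <- colSums(equal & !excluded)
  disc <- colSums(both & !equal)
  excl <- colSums(excluded)

  per <- data.frame(
    sample = test$samples, concordant = conc, discordant = disc,
    excluded_homref_pairs = excl, row.names = NULL,
    stringsAsFactors = FALSE)
  pooled <- data.frame(
    sample = "(pooled)", concordant = sum(conc), discordant = sum(disc),
    excluded_homref_pairs = sum(excl), stringsAsFactors = FALSE)
  out <- if (per_sample) rbind(per, pooled) else pooled
  out$concordance <- out$concordant / (out$concordant + out$discordant)
  out
}

# remap truth allele indices onto the test site's alt ordering for the
# (rare) matched sites whose ALT columns list the same alleles in a
# different order; keys guarantee equal allele sets
remap_truth_alleles <- function(test, truth, t_rows, g_rows) {
  a <- truth$ga[g_rows, , drop = FALSE]
  b <- truth$gb[g_rows, , drop = FALSE]
  alt_t <- test$sites$alt[t_rows]
  alt_g <- truth$sites$alt[g_rows]
  differs <- which(alt_t != alt_g)
  for (r in differs) {
    map <- c(0L, match(strsplit(alt_g[r], ",", fixed = TRUE)[[1]],
                       strsplit(alt_t[r], ",", fixed = TRUE)[[1]]))
    a[r, ] <- map[a[r, ] + 1L]
    b[r, ] <- map[b[r, ] + 1L]
  }
  if (length(differs)) {
    sw <- !is.na(a) & a > b
    tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
  }
  list(a = a, b = b)
}

check_samples <- function(test, truth) {
  if (!setequal(test$samples, truth$samples))
    stop("test and truth callsets have different sample sets")
}

align_columns <- function(m, samples) {
  perm <- match(samples, m$samples)
  m$samples <- m$samples[perm]
  for (f in c("ga", "gb", "gq", "dp"))
    m[[f]] <- m[[f]][, perm, drop = FALSE]
  m
}

#' Stratified performance metrics
#'
#' Computes per-sample recall, precision and genotype concordance within
#' strata defined by minor-allele-frequency bins, per-sample coverage
#' bins, genomic regions, and the SNV/indel split. Region restriction is
#' applied to both callsets before site matching. Site MAF is taken from
#' the truth cohort (`min(AF, 1 - AF)`); test-only sites fall back to
#' the test-cohort MAF so false positives still land in a bin.
#'
#' @param test,truth `genotype_matrix` objects over the same sample set.
#' @param maf_bins numeric vector of strictly increasing MAF bin edges
#'   covering (0, 0.5\], e.g. `c(0, 0.02, 0.5)`; `NULL` for no MAF split.
#' @param coverage data.frame with columns `sample` and `mean_depth`
#'   (x-fold, deduplicated); required when `coverage_bins` given.
#'   Samples missing from the table are excluded with a warning.
#' @param coverage_bins strictly increasing depth bin edges (left-closed,
#'   right-open), e.g. `c(1, 2, 3, 5)`; `NULL` for no coverage split.
#' @param regions optional `region_set` restriction.
#' @param by_type if `TRUE`, compute SNVs and indels separately.
#' @param mode,af passed to [genotype_concordance()].
#' @return data.frame, one row per sample x stratum combination, with
#'   stratum label columns (`maf_bin`, `coverage_bin`, `vtype`) and
#'   metric columns of [site_metrics()] and [genotype_concordance()].
#' @export
stratified_metrics <- function(test, truth, maf_bins = NULL,
                               coverage = NULL, coverage_bins = NULL,
                               regions = NULL, by_type = FALSE,
                               mode = c("nonref", "minor"), af = NULL) {
  mode <- match.arg(mode)
  check_samples(test, truth)
  truth <- align_columns(truth, test$samples)
  if (!is.null(regions)) {
    test <- restrict_to_regions(test, regions)
    truth <- restrict_to_regions(truth, regions)
  }
  if (!is.null(maf_bins) && any(diff(maf_bins) <= 0))
    stop("maf_bins edges must be strictly increasing")
  if (!is.null(coverage_bins) && any(diff(coverage_bins) <= 0))
    stop("coverage_bins edges must be strictly increasing")

  # sample strata
  keep_samples <- test$samples
  cov_bin <- rep("all", length(keep_samples))
  if (!is.null(coverage_bins)) {
    if (is.null(coverage))
      stop("coverage table required when coverage_bins are given")
    d <- coverage$mean_depth[match(keep_samples, coverage$sample)]
    if (anyNA(d)) {
      missing <- keep_samples[is.na(d)]
      warning("no coverage entry for sample(s): ",
              paste(missing, collapse = ", "), "; excluded")
    }
    cb <- cut(d, breaks = coverage_bins, right = FALSE)
    keep <- !is.na(cb)
    keep_samples <- keep_samples[keep]
    cov_bin <- as.character(cb[keep])
    test <- align_columns(test, keep_samples)
    truth <- align_columns(truth, keep_samples)
    test$samples <- keep_samples; truth$samples <- keep_samples
  }

  # site strata: MAF bin x variant type, keyed over the union
  match_all <- match_sites(test, truth)
  site_maf_t <- site_maf_for(truth)
  site_maf_p <- site_maf_for(test)
  maf_union <- site_maf_t[match_all$key]
  fallback <- is.na(maf_union)
  maf_union[fallback] <- site_maf_p[match_all$key[fallback]]
  vtype_union <- ifelse(
    !is.na(match_all$truth_idx),
    truth$sites$vtype[match_all$truth_idx],
    test$sites$vtype[match_all$test_idx])

  maf_lab <- if (is.null(maf_bins)) rep("all", nrow(match_all)) else
    as.character(cut(maf_union, breaks = maf_bins, include.lowest = FALSE))
  type_lab <- if (by_type) vtype_union else rep("all", nrow(match_all))

  strata <- unique(data.frame(maf_bin = maf_lab, vtype = type_lab,
                              stringsAsFactors = FALSE))
  strata <- strata[!is.na(strata$maf_bin), , drop = FALSE]
  if (nrow(strata) == 0 || length(keep_samples) == 0) {
    return(empty_strat_result())
  }
  ord <- order(strata$vtype, strata$maf_bin)
  strata <- strata[ord, , drop = FALSE]

  res <- list()
  for (i in seq_len(nrow(strata))) {
    in_str <- !is.na(maf_lab) & maf_lab == strata$maf_bin[i] &
      type_lab == strata$vtype[i]
    mi <- match_all[in_str, , drop = FALSE]
    ti <- subset_sites(test, mi$test_idx[!is.na(mi$test_idx)])
    gi <- subset_sites(truth, mi$truth_idx[!is.na(mi$truth_idx)])
    sm <- site_metrics(ti, gi, per_sample = TRUE)
    gc <- genotype_concordance(ti, gi, mode = mode, af = af,
                               per_sample = TRUE)
    row <- merge(sm, gc, by = "sample", sort = FALSE)
    row$maf_bin <- strata$maf_bin[i]
    row$vtype <- strata$vtype[i]
    row$coverage_bin <- c(cov_bin, "all")[match(row$sample,
                                                c(keep_samples, "(pooled)"))]
    res[[i]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

site_maf_for <- function(m) {
  if (n_sites(m) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  tab <- compute_af(m, warn = FALSE)
  stats::setNames(tab$maf, tab$key)
}

empty_strat_result <- function() {
  data.frame(sample = character(0), tp_sites = integer(0),
             truth_only_sites = integer(0), test_only_sites = integer(0),
             recall = numeric(0), precision = numeric(0),
             concordant = integer(0), discordant = integer(0),
             excluded_homref_pairs = integer(0), concordance = numeric(0),
             maf_bin = character(0), vtype = character(0),
             coverage_bin = character(0), stringsAsFactors = FALSE)
}
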