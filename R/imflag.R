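#' Imputation-consistency (IM) flags
#'
#' Compares a GQ-filtered sequencing-based genotype with the genotype
#' after imputation and classifies each call:
#'
#' * `IM0` — not imputed, or imputed and identical to the filtered call;
#' * `IM1` — not inconsistent: the filtered call was missing, or every
#'   sequenced allele is still present after imputation (an allele may
#'   have *appeared*, which low coverage cannot rule out);
#' * `IM2` — inconsistent (an allele sequenced in the filtered call
#'   *disappeared* after imputation) and the filtered call was
#'   heterozygous;
#' * `IM3` — inconsistent and the filtered call was homozygous, i.e.
#'   imputation contradicts both observed allele copies.
#'
#' Genotypes are compared as unordered allele pairs; inconsistency is
#' decided on allele *sets*, so `0/1` imputed to `1/1` loses allele 0
#' and is `IM2` even though the copy number of allele 1 rose.
#'
#' @param filtered,imputed character vectors of genotype strings
#'   (`"0/1"`, `"1|1"`, `"./."`, `"."`). Recycled to a common length.
#' @return Integer vector of flags in `0:3`.
#' @examples
#' assign_im_flag("0/1", "0/1")  # 0
#' assign_im_flag("0/0", "0/1")  # 1
#' assign_im_flag("0/1", "1/1")  # 2
#' assign_im_flag("0/0", "1/1")  # 3
#' @export
assign_im_flag <- function(filtered, imputed) {
  n <- max(length(filtered), length(imputed))
  f <- parse_genotypes(rep_len(filtered, n))
  i <- parse_genotypes(rep_len(imputed, n))
  im_flag_pairs(f[, "a"], f[, "b"], i[, "a"], i[, "b"])
}

# vectorised flag rule on sorted allele-index pairs (NA pair = missing)
im_flag_pairs <- function(fa, fb, ia, ib) {
  f_miss <- is.na(fa)
  i_miss <- is.na(ia)
  if (any(f_miss & i_miss))
    stop("both filtered and imputed call missing at ",
         sum(f_miss & i_miss), " position(s)")
  flag <- integer(length(fa))
  # not imputed -> IM0; filtered missing -> IM1
  flag[!i_miss & f_miss] <- 1L
  both <- !i_miss & !f_miss
  identical_pair <- both & fa == ia & fb == ib
  subset_of_imputed <- both &
    (fa == ia | fa == ib) & (fb == ia | fb == ib)
  lost <- both & !subset_of_imputed
  flag[both & subset_of_imputed & !identical_pair] <- 1L
  flag[lost & fa != fb] <- 2L
  flag[lost & fa == fb] <- 3L
  flag
}

#' Merge sequencing-based and imputed callsets and flag consistency
#'
#' Re-merges the post-imputation callset with a pre-imputation
#' sequencing-based callset and assigns an IM flag to every call via
#' the rule of [assign_im_flag()]. In the refinement pipeline the
#' sequencing-based side is the *original unfiltered* callset: an
#' imputer that only fills gaps never contradicts the calls it kept,
#' so the informative comparisons are against the low-GQ calls the
#' filter blanked before imputation. Sites are matched by
#' (chrom, pos, ref, alt set); allele indices of the filtered call are
#' remapped when the two files order alternate alleles differently.
#' Sites present only in the filtered set are carried over with flag
#' `IM0` ("not imputed"). Sites at a matched (chrom, pos) whose ref or
#' alt set disagree are skipped with a warning (count in attribute
#' `skipped_sites`).
#'
#' @param filtered the sequencing-based pre-imputation
#'   `genotype_matrix` (in the pipeline, the original unfiltered
#'   callset).
#' @param imputed the post-imputation `genotype_matrix`; must have the
#'   same sample set (any order).
#' @return A `flagged_matrix`: list with `matrix` (the merged
#'   `genotype_matrix`) and `im` (integer sites-x-samples flag table;
#'   `NA` only where both calls are missing).
#' @export
merge_and_flag <- function(filtered, imputed) {
  stopifnot(inherits(filtered, "genotype_matrix"),
            inherits(imputed, "genotype_matrix"))
  if (!setequal(filtered$samples, imputed$samples))
    stop("filtered and imputed callsets have different sample sets")
  # align filtered columns to imputed sample order
  perm <- match(imputed$samples, filtered$samples)
  filtered$samples <- filtered$samples[perm]
  for (f in c("ga", "gb", "gq", "dp"))
    filtered[[f]] <- filtered[[f]][, perm, drop = FALSE]

  fk <- site_keys(filtered)
  ik <- site_keys(imputed)
  pos_key_f <- paste(filtered$sites$chrom, filtered$sites$pos)
  pos_key_i <- paste(imputed$sites$chrom, imputed$sites$pos)
  match_full <- match(fk, ik)
  # same position, different ref/alt representation: skip, don't carry
  mismatch <- is.na(match_full) & pos_key_f %in% pos_key_i
  n_skip <- sum(mismatch)
  if (n_skip > 0)
    warning(n_skip, " site(s) skipped: allele representation differs ",
            "between filtered and imputed callsets")

  only_f <- which(is.na(match_full) & !mismatch)
  ns_i <- n_sites(imputed)
  nsam <- n_samples(imputed)

  im <- matrix(NA_integer_, ns_i + length(only_f), nsam)
  out <- imputed
  if (length(only_f) > 0) {
    carry <- subset_sites(filtered, only_f)
    out$sites <- rbind(imputed$sites, carry$sites)
    for (f in c("ga", "gb", "gq", "dp"))
      out[[f]] <- rbind(imputed[[f]], carry[[f]])
    out$contigs <- union(imputed$contigs, carry$contigs)
  }

  # flags over imputed sites with a matched filtered site
  shared_f <- which(!is.na(match_full))
  if (length(shared_f) > 0) {
    rows_i <- match_full[shared_f]
    fa <- filtered$ga[shared_f, , drop = FALSE]
    fb <- filtered$gb[shared_f, , drop = FALSE]
    # remap filtered allele indices where alt ordering differs
    alt_f <- strsplit(filtered$sites$alt[shared_f], ",", fixed = TRUE)
    alt_i <- strsplit(imputed$sites$alt[rows_i], ",", fixed = TRUE)
    differs <- which(mapply(function(a, b) !identical(a, b), alt_f, alt_i))
    for (r in differs) {
      map <- c(0L, match(alt_f[[r]], alt_i[[r]]))  # index k -> map[k+1]
      fa[r, ] <- map[fa[r, ] + 1L]
      fb[r, ] <- map[fb[r, ] + 1L]
    }
    if (length(differs)) {          # remap can unsort the pair
      sw <- !is.na(fa) & fa > fb
      tmp <- fa[sw]; fa[sw] <- fb[sw]; fb[sw] <- tmp
    }
    ia <- imputed$ga[rows_i, , drop = FALSE]
    ib <- imputed$gb[rows_i, , drop = FALSE]
    defined <- !(is.na(fa) & is.na(ia))
    fl <- matrix(NA_integer_, length(shared_f), nsam)
    fl[defined] <- im_flag_pairs(fa[defined], fb[defined],
                                 ia[defined], ib[defined])
    im[rows_i, ] <- fl
  }
  # imputed-only sites: filtered call treated as missing -> IM1 where
  # the imputed call exists
  only_i <- setdiff(seq_len(ns_i),
                    if (length(shared_f)) match_full[shared_f] else integer(0))
  if (length(only_i) > 0) {
    blk <- matrix(NA_integer_, length(only_i), nsam)
    has <- !is.na(imputed$ga[only_i, , drop = FALSE])
    blk[has] <- 1L
    im[only_i, ] <- blk
  }
  # filtered-only sites: not imputed -> IM0 where the filtered call exists
  if (length(only_f) > 0) {
    blk <- matrix(NA_integer_, length(only_f), nsam)
    has <- !is.na(filtered$ga[only_f, , drop = FALSE])
    blk[has] <- 0L
    im[ns_i + seq_along(only_f), ] <- blk
  }

  ord <- order(match(out$sites$chrom, out$contigs), out$sites$pos,
               out$sites$ref, sub(",.*$", "", out$sites$alt))
  out <- subset_sites(out, ord)
  im <- im[ord, , drop = FALSE]
  structure(list(matrix = out, im = im, skipped_sites = n_skip),
            class = "flagged_matrix")
}

#' @export
print.flagged_matrix <- function(x, ...) {
  cat(sprintf("flagged_matrix: %d sites x %d samples\n",
              n_sites(x$matrix), n_samples(x$matrix)))
  tab <- table(factor(x$im, levels = 0:3, labels = paste0("IM", 0:3)))
  print(tab)
  invisible(x)
}

#' Drop calls by IM flag
#'
#' Sets to missing the calls whose flag is in `drop`. Only the
#' inconsistent classes `IM2`/`IM3` may be dropped — downstream
#' applications sensitive to genotype errors should drop `IM3` and
#' optionally `IM2`.
#'
#' @param fm a `flagged_matrix` from [merge_and_flag()].
#' @param drop subset of `c("IM2", "IM3")` (or integers `2:3`).
#' @return A `genotype_matrix` with the dropped calls set missing.
#' @export
filter_by_flag <- function(fm, drop = "IM3") {
  stopifnot(inherits(fm, "flagged_matrix"))
  if (length(drop) == 0) return(fm$matrix)
  if (is.character(drop)) drop <- as.integer(sub("^IM", "", drop))
  if (!all(drop %in% 2:3))
    stop("only IM2 and IM3 calls may be dropped")
  set_missing(fm$matrix, !is.na(fm$im) & fm$im %in% drop)
}

#' Write a flagged matrix as VCF with an IM FORMAT tag
#'
#' @param fm a `flagged_matrix`.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_flagged_vcf <- function(fm, path) {
  stopifnot(inherits(fm, "flagged_matrix"))
  write_vcf(fm$matrix, path, extra_format = list(IM = fm$im))
}
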