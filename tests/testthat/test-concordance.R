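# naive nested-loop oracle over genotype-string matrices; completely
# independent of the package's matrix code paths
oracle_metrics <- function(test, truth, mode = "nonref", af = NULL) {
  gt_t <- genotype_strings(test)
  gt_g <- genotype_strings(truth)
  kt <- site_keys(test)
  kg <- site_keys(truth)
  keys <- union(kt, kg)
  samples <- test$samples
  res <- list()
  for (s in samples) {
    tp <- fn <- fp <- conc <- disc <- excl <- 0L
    for (key in keys) {
      it <- match(key, kt)
      ig <- match(key, kg)
      vt <- vg <- FALSE
      if (!is.na(it)) {
        g <- gt_t[it, s]
        vt <- g != "./." && grepl("[1-9]", g)
      }
      if (!is.na(ig)) {
        g <- gt_g[ig, s]
        vg <- g != "./." && grepl("[1-9]", g)
      }
      if (vt && vg) tp <- tp + 1L
      if (vg && !vt) fn <- fn + 1L
      if (vt && !vg) fp <- fp + 1L
      if (!is.na(it) && !is.na(ig)) {
        a <- gt_t[it, s]; b <- gt_g[ig, s]
        if (a != "./." && b != "./.") {
          flip <- mode == "minor" && af[[key]] > 0.5
          hom_major <- if (flip) "1/1" else "0/0"
          if (a == b) {
            if (a == hom_major) excl <- excl + 1L else conc <- conc + 1L
          } else disc <- disc + 1L
        }
      }
    }
    res[[s]] <- data.frame(sample = s, tp = tp, fn = fn, fp = fp,
                           conc = conc, disc = disc, excl = excl)
  }
  do.call(rbind, res)
}

test_that("match_sites gives set semantics on keys incl. allele sets", {
  a <- gm_from_strings(matrix("0/1", 3, 1), pos = c(10L, 20L, 30L))
  b <- gm_from_strings(matrix("0/1", 3, 1), pos = c(20L, 30L, 40L))
  ms <- match_sites(a, b)
  shared <- ms$key[!is.na(ms$test_idx) & !is.na(ms$truth_idx)]
  expect_length(shared, 2L)
  expect_length(ms$key[is.na(ms$truth_idx)], 1L)
  expect_length(ms$key[is.na(ms$test_idx)], 1L)
  # same position, different alt set -> distinct keys
  c1 <- gm_from_strings(matrix("0/1", 1, 1), pos = 10L, alt = "G")
  c2 <- gm_from_strings(matrix("0/1", 1, 1), pos = 10L, alt = "T")
  ms2 <- match_sites(c1, c2)
  expect_true(all(is.na(ms2$test_idx) | is.na(ms2$truth_idx)))
  # identical inputs -> all shared
  ms3 <- match_sites(a, a)
  expect_true(all(!is.na(ms3$test_idx) & !is.na(ms3$truth_idx)))
})

test_that("per-sample recall and precision follow the site definitions", {
  # truth variant calls at 3 sites; test hits 2 of them plus 1 extra
  truth <- gm_from_strings(matrix(c("0/1", "0/1", "1/1", "0/0"), 4, 1),
                           pos = c(10L, 20L, 30L, 40L))
  test <- gm_from_strings(matrix(c("0/1", "0/0", "1/1", "0/1"), 4, 1),
                          pos = c(10L, 20L, 30L, 40L))
  sm <- site_metrics(test, truth)
  expect_equal(sm$recall[1], 2 / 3)
  expect_equal(sm$precision[1], 2 / 3)
  # test = truth -> both 1
  sm2 <- site_metrics(truth, truth, per_sample = FALSE)
  expect_equal(sm2$recall, 1)
  expect_equal(sm2$precision, 1)
  # empty test set -> recall 0, precision undefined
  empty <- gm_from_strings(matrix("0/0", 4, 1), pos = c(10L, 20L, 30L, 40L))
  sm3 <- site_metrics(empty, truth, per_sample = FALSE)
  expect_equal(sm3$recall, 0)
  expect_true(is.nan(sm3$precision))
})

test_that("non-reference concordance excludes equal hom-ref pairs only", {
  test <- gm_from_strings(matrix(c("0/0", "0/1", "1/1", "0/1"), 4, 1))
  truth <- gm_from_strings(matrix(c("0/0", "0/1", "0/1", "0/1"), 4, 1))
  gc <- genotype_concordance(test, truth, per_sample = FALSE)
  expect_equal(gc$concordance, 2 / 3)
  expect_equal(gc$excluded_homref_pairs, 1L)
  gc2 <- genotype_concordance(test, test, per_sample = FALSE)
  expect_equal(gc2$concordance, 1)
})

test_that("minor-allele mode flips the exclusion at AF > 0.5", {
  test <- gm_from_strings(matrix(c("1/1", "0/0"), 2, 1))
  truth <- gm_from_strings(matrix(c("1/1", "0/0"), 2, 1))
  af <- stats::setNames(c(0.8, 0.8), site_keys(test))
  gc <- genotype_concordance(test, truth, mode = "minor", af = af,
                             per_sample = FALSE)
  # (1/1, 1/1) at AF 0.8 is a hom-major match -> excluded;
  # (0/0, 0/0) at AF 0.8 is now a minor-allele match -> concordant
  expect_equal(gc$excluded_homref_pairs, 1L)
  expect_equal(gc$concordant, 1L)
  expect_error(
    genotype_concordance(test, truth, mode = "minor",
                         af = stats::setNames(0.8, site_keys(test)[1]),
                         per_sample = FALSE),
    "no allele frequency")
})

test_that("metrics equal the nested-loop oracle on random matrices", {
  set.seed(101)
  for (rep in 1:25) {
    ns <- sample(3:20, 1)
    nsam <- sample(2:5, 1)
    test <- random_gm(ns, nsam)
    truth <- random_gm(ns, nsam)
    # share a random subset of positions so all match classes occur
    truth$sites$pos[seq_len(min(3, ns))] <-
      test$sites$pos[seq_len(min(3, ns))] + sample(c(0L, 1L), min(3, ns),
                                                   replace = TRUE)
    orc <- oracle_metrics(test, truth)
    sm <- site_metrics(test, truth)
    gc <- genotype_concordance(test, truth)
    per_sm <- sm[sm$sample != "(pooled)", ]
    per_gc <- gc[gc$sample != "(pooled)", ]
    expect_equal(per_sm$tp_sites, orc$tp)
    expect_equal(per_sm$truth_only_sites, orc$fn)
    expect_equal(per_sm$test_only_sites, orc$fp)
    expect_equal(per_gc$concordant, orc$conc)
    expect_equal(per_gc$discordant, orc$disc)
    expect_equal(per_gc$excluded_homref_pairs, orc$excl)
  }
})

test_that("swapping test and truth swaps recall/precision, keeps NCR count", {
  set.seed(7)
  a <- random_gm(15, 3)
  b <- random_gm(15, 3)
  b$sites$pos <- a$sites$pos  # full site overlap
  f <- site_metrics(a, b, per_sample = FALSE)
  r <- site_metrics(b, a, per_sample = FALSE)
  expect_equal(f$recall, r$precision)
  expect_equal(f$precision, r$recall)
  expect_equal(genotype_concordance(a, b, per_sample = FALSE)$concordant,
               genotype_concordance(b, a, per_sample = FALSE)$concordant)
})

test_that("minor-allele mode equals non-reference mode when all AF <= 0.5", {
  set.seed(8)
  a <- random_gm(12, 4, miss_rate = 0.1)
  b <- a
  af <- stats::setNames(rep(0.3, 12), site_keys(a))
  nonref <- genotype_concordance(a, b, mode = "nonref")
  minor <- genotype_concordance(a, b, mode = "minor", af = af)
  expect_equal(minor, nonref)
})

test_that("pooled metrics are the count-weighted pooling of per-sample rows", {
  set.seed(9)
  a <- random_gm(18, 4)
  b <- random_gm(18, 4)
  b$sites$pos <- a$sites$pos
  sm <- site_metrics(a, b)
  per <- sm[sm$sample != "(pooled)", ]
  pool <- sm[sm$sample == "(pooled)", ]
  expect_equal(pool$tp_sites, sum(per$tp_sites))
  expect_equal(pool$recall,
               sum(per$tp_sites) / sum(per$tp_sites + per$truth_only_sites))
})

test_that("stratified metrics bin by coverage, MAF and variant type", {
  # two coverage bins with synthetic samples at 1.5x and 4.2x
  g <- matrix(c("0/1", "0/0", "0/1", "1/1",
                "0/0", "0/1", "0/1", "0/1"), 4, 2)
  test <- gm_from_strings(g, alt = c("G", "G", "GT", "G"))
  truth <- test
  cov <- data.frame(sample = c("S1", "S2"), mean_depth = c(1.5, 4.2))
  out <- stratified_metrics(test, truth, coverage = cov,
                            coverage_bins = c(1, 2, 4, 5))
  per <- out[out$sample != "(pooled)", ]
  expect_equal(per$coverage_bin[per$sample == "S1"], "[1,2)")
  expect_equal(per$coverage_bin[per$sample == "S2"], "[4,5)")
  # vtype split separates the indel site
  out2 <- stratified_metrics(test, truth, by_type = TRUE)
  expect_setequal(unique(out2$vtype), c("SNV", "INDEL"))
  # MAF bins assign sites by truth-cohort MAF, checked by hand recount:
  # with test = truth, each bin's tp count is (sites in bin) x (samples
  # with a variant call there)
  out3 <- stratified_metrics(test, truth, maf_bins = c(0, 0.3, 0.5))
  aft <- compute_af(truth)
  bins <- as.character(cut(aft$maf, c(0, 0.3, 0.5)))
  vmat <- genotype_strings(truth)
  for (b in unique(stats::na.omit(bins))) {
    rows <- match(aft$key[which(bins == b)], site_keys(truth))
    manual_tp <- sum(vmat[rows, , drop = FALSE] %in% c("0/1", "1/1"))
    pooled_b <- out3[out3$maf_bin == b & out3$sample == "(pooled)", ]
    expect_equal(pooled_b$tp_sites, manual_tp)
  }
  expect_equal(nrow(out3[out3$sample == "(pooled)", ]),
               length(unique(stats::na.omit(bins))))
  # sample without coverage entry is excluded with a warning
  expect_warning(
    out4 <- stratified_metrics(test, truth,
                               coverage = cov[1, , drop = FALSE],
                               coverage_bins = c(1, 2)),
    "no coverage")
  expect_false("S2" %in% out4$sample)
})

test_that("region restriction happens before matching", {
  test <- gm_from_strings(matrix("0/1", 3, 1), pos = c(50L, 150L, 250L))
  truth <- gm_from_strings(matrix("0/1", 3, 1), pos = c(50L, 150L, 350L))
  r <- region_set(data.frame(chrom = "chr1", start = 100L, end = 300L))
  out <- stratified_metrics(test, truth, regions = r)
  pool <- out[out$sample == "(pooled)", ]
  # only pos 150 (shared) and 250/350 (each side's own) considered;
  # 250 in-region (test-only), 350 out of region (dropped)
  expect_equal(pool$tp_sites, 1L)
  expect_equal(pool$truth_only_sites, 0L)
  expect_equal(pool$test_only_sites, 1L)
})
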