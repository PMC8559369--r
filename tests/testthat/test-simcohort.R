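# independent phred-GQ oracle: direct evaluation of the three biallelic
# genotype likelihoods for a given read pileup
oracle_call <- function(n_ref, n_alt, eps) {
  d <- n_ref + n_alt
  l <- c(rr = (1 - eps)^n_ref * eps^n_alt,
         het = 0.5^d,
         aa = eps^n_ref * (1 - eps)^n_alt)
  post <- l / sum(l)
  gt <- which.max(post)          # ties: first index = hom-ref preference
  gq <- min(99, round(-10 * log10(max(1 - post[gt], 1e-10))))
  list(gt = unname(gt) - 1L, gq = gq)
}

test_that("genotype calls and GQ match direct likelihood evaluation", {
  cg <- midpass:::call_genotypes
  cases <- expand.grid(n_ref = 0:8, n_alt = 0:8)
  cases <- cases[cases$n_ref + cases$n_alt > 0, ]
  for (eps in c(0.01, 0.05)) {
    orc <- mapply(function(r, a) unlist(oracle_call(r, a, eps)),
                  cases$n_ref, cases$n_alt)
    got <- cg(d = matrix(cases$n_ref + cases$n_alt),
              k = matrix(cases$n_alt), eps = eps)
    dosage <- got$ga + got$gb
    expect_equal(as.vector(dosage), unname(orc["gt", ]))
    expect_equal(as.vector(got$gq), unname(orc["gq", ]))
  }
  # the canonical pileup: 5 ref reads, no alt, eps 0.01
  o <- oracle_call(5, 0, 0.01)
  expect_equal(o$gt, 0L)
  expect_equal(o$gq, 15)
  g <- cg(d = matrix(5L), k = matrix(0L), eps = 0.01)
  expect_equal(as.vector(g$gq), 15)
})

test_that("zero depth gives a missing call; zero error a capped GQ", {
  cg <- midpass:::call_genotypes
  g0 <- cg(d = matrix(0L), k = matrix(0L), eps = 0.01)
  expect_true(is.na(g0$ga) && is.na(g0$gq))
  # eps = 0, both alleles observed: certain het at GQ 99
  g1 <- cg(d = matrix(4L), k = matrix(2L), eps = 0)
  expect_equal(as.vector(g1$ga + g1$gb), 1L)
  expect_equal(as.vector(g1$gq), 99L)
})

test_that("cohort generation is deterministic and mosaic-consistent", {
  cfg <- sim_config(n_samples = 12, n_sites = 60, seed = 5)
  s1 <- make_cohort(cfg)
  s2 <- make_cohort(cfg)
  expect_identical(s1, s2)
  o1 <- simulate_midpass(s1)
  o2 <- simulate_midpass(s2)
  expect_identical(o1, o2)
  # truth has no missing calls and dosage = hap1 + hap2
  expect_false(anyNA(s1$truth$ga))
  expect_equal(s1$truth$ga + s1$truth$gb, s1$hap1 + s1$hap2)
})

test_that("switch_rate 0 copies whole founder haplotypes", {
  cfg <- sim_config(n_samples = 8, n_sites = 40, n_founders = 2,
                    switch_rate = 0, seed = 9)
  sim <- make_cohort(cfg)
  for (h in seq_len(ncol(sim$hap1))) {
    expect_true(any(vapply(seq_len(2), function(f)
      all(sim$hap1[, h] == sim$founders[, f]), logical(1))))
  }
})

test_that("empirical truth AF converges to the founder AF", {
  cfg <- sim_config(n_samples = 1000, n_sites = 40, n_founders = 10,
                    af_spectrum = rep(0.3, 40), seed = 13)
  sim <- make_cohort(cfg)
  founder_af <- colMeans(t(sim$founders))
  emp <- rowMeans(sim$hap1 + sim$hap2) / 2
  se <- sqrt(founder_af * (1 - founder_af) / (2 * cfg$n_samples))
  # mosaic copying induces founder-resampling variance; 3 SE on the
  # haplotype-draw scale still bounds the drift at this size
  expect_true(mean(abs(emp - founder_af) <= 3 * sqrt(
    founder_af * (1 - founder_af) / (2 * 10))) > 0.9)
  expect_equal(mean(emp), mean(founder_af), tolerance = 0.05)
})

test_that("simulated depth and missingness follow the Poisson model", {
  cfg <- sim_config(n_samples = 50, n_sites = 200, coverage = 2,
                    error_rate = 0.01, seed = 21)
  obs <- simulate_midpass(make_cohort(cfg))
  expect_equal(mean(obs$dp), 2, tolerance = 0.05)
  expect_equal(mean(is.na(obs$ga)), exp(-2), tolerance = 0.02)
  # missing exactly where depth is zero
  expect_equal(is.na(obs$ga), obs$dp == 0L)
})

test_that("naive imputer: identity, unanimity and neighbour oracle", {
  # no missing calls -> identity
  m <- gm_from_strings(matrix(c("0/1", "1/1", "0/0", "0/1"), 2, 2))
  expect_equal(naive_impute(m), m)

  # unanimity: every other sample 1/1 across the window
  g <- matrix("1/1", 9, 6)
  g[5, 1] <- "./."
  mu <- gm_from_strings(g)
  expect_equal(genotype_strings(naive_impute(mu, window = 9))[5, 1],
               c(S1 = "1/1"))

  # 5-sample, 9-site cases: exhaustive brute-force reimplementation of
  # the neighbour search and majority vote
  brute_vote <- function(g, i, s, k) {
    agree <- sapply(seq_len(ncol(g)), function(j) {
      if (j == s) return(-Inf)
      ok <- g[, j] != "./." & g[, s] != "./."
      if (!any(ok)) return(-Inf)
      mean(g[ok, j] == g[ok, s])
    })
    nb <- order(agree, decreasing = TRUE)[seq_len(k)]
    nb <- nb[is.finite(agree[nb])]
    votes <- g[i, nb]
    votes <- votes[votes != "./."]
    pool <- if (length(votes)) votes else {
      ch <- g[i, -s]; ch[ch != "./."]
    }
    if (!length(pool)) return("0/0")
    tv <- table(pool)
    top <- names(tv)[tv == max(tv)]
    if (length(top) > 1 && length(votes)) {
      cohort <- g[i, ]; cohort <- cohort[cohort != "./."]
      cf <- table(cohort)[top]
      cf[is.na(cf)] <- 0
      top <- top[cf == max(cf)]
    }
    sort(top)[1]   # "0/0" < "0/1" < "1/1": smaller dosage first
  }
  set.seed(77)
  for (rep in 1:10) {
    g <- matrix(sample(c("0/0", "0/1", "1/1", "./."), 45, TRUE,
                       c(.35, .25, .25, .15)), 9, 5)
    g[5, 2] <- "./."
    mb <- gm_from_strings(g)
    out <- genotype_strings(naive_impute(mb, window = 9, k = 2))
    expect_equal(unname(out[5, 2]), brute_vote(g, 5, 2, 2))
  }
})

test_that("imputation fills everything and never changes observed calls", {
  cfg <- sim_config(n_samples = 30, n_sites = 120, coverage = 2,
                    error_rate = 0.02, seed = 31)
  obs <- simulate_midpass(make_cohort(cfg))
  filt <- gq_filter(obs, 17)$matrix
  imp <- naive_impute(filt)
  expect_false(anyNA(imp$ga))
  kept <- !is.na(filt$ga)
  expect_true(all(imp$ga[kept] == filt$ga[kept]))
  expect_true(all(imp$gb[kept] == filt$gb[kept]))
})

test_that("gq_sweep returns one row per threshold and selects by rule", {
  cfg <- sim_config(n_samples = 30, n_sites = 150, coverage = 4,
                    error_rate = 0.02, seed = 41)
  sim <- make_cohort(cfg)
  obs <- simulate_midpass(sim)
  sw <- gq_sweep(obs, sim$truth, thresholds = c(0, 10, 20))
  expect_equal(sw$threshold, c(0, 10, 20))
  expect_false(any(sw$failed))
  # pre-imputation call counts are non-increasing in the threshold
  expect_true(all(diff(sw$pre_impute_calls) <= 0))
  sel <- attr(sw, "selected")
  ok <- sw$recall >= max(sw$recall) - 0.005
  expect_equal(sel, sw$threshold[ok][which.max(sw$ncr[ok])])
  # imputer failure marks the row and the sweep continues
  boom <- function(m) stop("boom")
  expect_warning(sw1 <- gq_sweep(obs, sim$truth, thresholds = 0,
                                 imputer = boom), "failed")
  sw2 <- suppressWarnings(
    gq_sweep(obs, sim$truth, thresholds = c(0, 5), imputer = boom))
  expect_true(all(sw2$failed))
  expect_null(attr(sw2, "selected"))
})
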