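#' Simulator configuration
#'
#' Bundles all parameters of the synthetic mid-pass cohort generator.
#' The generative model is: a pool of founder haplotypes with a
#' neutral-like allele-frequency spectrum; each cohort haplotype is a
#' mosaic copy of founders (a Li-Stephens-flavoured process), which
#' gives the cohort the linkage disequilibrium that within-cohort
#' imputation exploits; sequencing draws a Poisson read depth per call
#' and error-prone allele reads, and genotypes are called from
#' genotype likelihoods.
#'
#' @param n_samples cohort size.
#' @param n_sites number of biallelic loci.
#' @param n_founders founder haplotype count (default 20).
#' @param switch_rate per-site probability of switching founder while
#'   copying (default 0.01; smaller = longer shared haplotypes).
#' @param coverage target sequencing depth, x-fold: a scalar or one
#'   value per sample (default 4, the mid-pass operating point).
#' @param error_rate per-read allele miscall probability (default 0.01).
#' @param af_spectrum `"neutral"` (site alt count over founders drawn
#'   with P(i) proportional to 1/i, i = 1..n_founders-1) or a numeric
#'   vector of per-site founder alt frequencies.
#' @param seed RNG seed (integer).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 100L, n_sites = 1000L,
                       n_founders = 20L, switch_rate = 0.01,
                       coverage = 4, error_rate = 0.01,
                       af_spectrum = "neutral", seed = 1L) {
  stopifnot(n_samples >= 1, n_sites >= 1, n_founders >= 2,
            switch_rate >= 0, switch_rate <= 1,
            all(coverage >= 0), error_rate >= 0, error_rate <= 1)
  if (!(length(coverage) %in% c(1L, n_samples)))
    stop("coverage must be a scalar or one value per sample")
  structure(list(
    n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
    n_founders = as.integer(n_founders), switch_rate = switch_rate,
    coverage = coverage, error_rate = error_rate,
    af_spectrum = af_spectrum, seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate a synthetic cohort with known truth
#'
#' Draws founder haplotypes, builds each sample's two haplotypes as
#' founder mosaics (switching founders between consecutive sites with
#' probability `switch_rate`), and sums the haplotype alleles into
#' diploid truth genotypes. Deterministic given the config (seed
#' included).
#'
#' @param config a [sim_config()].
#' @return A `sim_truth` list: `founders` (sites x founders 0/1
#'   matrix), `hap1`, `hap2` (sites x samples 0/1 matrices), `truth`
#'   (the truth `genotype_matrix`, no missing calls), `config`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_sites
  nf <- config$n_founders
  nh <- 2L * config$n_samples

  if (identical(config$af_spectrum, "neutral")) {
    counts <- 1:(nf - 1L)
    ac <- sample(counts, ns, replace = TRUE, prob = 1 / counts)
  } else {
    f <- rep_len(config$af_spectrum, ns)
    ac <- pmin(pmax(round(f * nf), 1L), nf - 1L)
  }
  founders <- matrix(0L, ns, nf)
  for (i in seq_len(ns))
    founders[i, sample.int(nf, ac[i])] <- 1L

  haps <- matrix(0L, ns, nh)
  for (h in seq_len(nh)) {
    sw <- if (ns > 1) stats::runif(ns - 1L) < config$switch_rate else logical(0)
    seg <- cumsum(c(1L, as.integer(sw)))
    src <- sample.int(nf, max(seg), replace = TRUE)
    haps[, h] <- founders[cbind(seq_len(ns), src[seg])]
  }
  hap1 <- haps[, seq(1L, nh, by = 2L), drop = FALSE]
  hap2 <- haps[, seq(2L, nh, by = 2L), drop = FALSE]
  g <- hap1 + hap2

  sites <- data.frame(
    chrom = "chr1", pos = seq_len(ns) * 100L,
    ref = "A", alt = "G", filter = "PASS", stringsAsFactors = FALSE)
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  truth <- genotype_matrix(
    sites, samples,
    ga = (g == 2L) * 1L,          # 0/0 -> (0,0), 0/1 -> (0,1), 1/1 -> (1,1)
    gb = (g >= 1L) * 1L,
    gq = matrix(99L, ns, config$n_samples),
    dp = matrix(30L, ns, config$n_samples))
  structure(list(founders = founders, hap1 = hap1, hap2 = hap2,
                 truth = truth, config = config),
            class = "sim_truth")
}

#' Simulate mid-pass sequencing and genotype calling
#'
#' For each (site, sample): depth `d ~ Poisson(coverage)`; each read
#' copies one of the two true alleles uniformly, then miscalls the
#' other allele with probability `error_rate`. Biallelic genotype
#' likelihoods are `L(hom) = prod over reads of (1 - e) or e` and
#' `L(het) = (1/2)^d`; with a flat prior the called genotype is the
#' posterior mode, `GQ = min(99, round(-10 log10(1 - posterior)))`,
#' `DP = d`, and `d = 0` yields a missing call. Ties are broken in the
#' order hom-ref < het < hom-alt.
#'
#' @param sim a `sim_truth` from [make_cohort()].
#' @param config optional [sim_config()] overriding `sim$config` (e.g.
#'   to re-sequence the same cohort at another coverage).
#' @return The observed `genotype_matrix` (GT/GQ/DP filled).
#' @export
simulate_midpass <- function(sim, config = NULL) {
  stopifnot(inherits(sim, "sim_truth"))
  if (is.null(config)) config <- sim$config
  set.seed(config$seed + 1L)
  ns <- config$n_sites
  nsam <- config$n_samples
  eps <- config$error_rate
  g <- sim$hap1 + sim$hap2                       # true dosage 0/1/2

  covm <- matrix(rep(config$coverage, each = ns), ns, nsam)
  d <- matrix(stats::rpois(ns * nsam, covm), ns, nsam)
  p_alt <- (g / 2) * (1 - eps) + (1 - g / 2) * eps
  k <- matrix(stats::rbinom(ns * nsam, d, p_alt), ns, nsam)

  called <- call_genotypes(d, k, eps)
  obs <- sim$truth
  obs$ga <- called$ga
  obs$gb <- called$gb
  obs$gq <- called$gq
  obs$dp <- d
  obs$dp[d == 0L] <- 0L
  obs
}

# likelihood-based diploid calls from depth d and alt-read count k
call_genotypes <- function(d, k, eps) {
  ll_rr <- (d - k) * log(1 - eps) + k * log(eps)
  ll_aa <- k * log(1 - eps) + (d - k) * log(eps)
  ll_het <- d * log(0.5)
  if (eps == 0) {                       # 0*log(0) limits
    ll_rr <- ifelse(k == 0, 0, -Inf)
    ll_aa <- ifelse(k == d, 0, -Inf)
  }
  mx <- pmax(ll_rr, ll_het, ll_aa)
  w_rr <- exp(ll_rr - mx); w_het <- exp(ll_het - mx); w_aa <- exp(ll_aa - mx)
  tot <- w_rr + w_het + w_aa
  # argmax with tie order hom-ref < het < hom-alt
  gt <- ifelse(w_rr >= w_het & w_rr >= w_aa, 0L,
               ifelse(w_het >= w_aa, 1L, 2L))
  post <- ifelse(gt == 0L, w_rr, ifelse(gt == 1L, w_het, w_aa)) / tot
  err <- pmax(1 - post, 1e-10)
  gq <- pmin(round(-10 * log10(err)), 99)
  miss <- d == 0L
  ga <- ifelse(miss, NA_integer_, as.integer(gt == 2L))
  gb <- ifelse(miss, NA_integer_, as.integer(gt >= 1L))
  gq[miss] <- NA_integer_
  list(ga = ga, gb = gb, gq = gq)
}
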