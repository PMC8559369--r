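#' Naive within-cohort nearest-neighbour imputation
#'
#' Fills every missing call by a majority vote among the `k` samples
#' that agree best with the target sample over a window of surrounding
#' sites. This is deliberately simple scaffolding that closes the
#' filter-impute-flag loop without external software; for a
#' haplotype-model imputer see [cluster_impute()], and for the
#' production path (Beagle, run without a reference panel on the cohort
#' itself) see [external_impute()].
#'
#' For a missing call at (site, sample): agreement of every other
#' sample is the fraction of identical genotypes over the `window`
#' sites centred on the site (counting only positions non-missing in
#' both); the `k` best-agreeing samples vote with their genotype at the
#' site; the majority genotype is imputed, ties broken toward the
#' higher-cohort-frequency genotype at that site and then toward the
#' smaller allele dosage. Samples with nothing to vote fall back to the
#' cohort-modal genotype, and an entirely missing site to homozygous
#' reference. Observed calls are never changed; imputed calls carry no
#' GQ.
#'
#' @param observed a `genotype_matrix` with missing calls to fill.
#' @param window odd number of sites in the agreement window
#'   (default 11).
#' @param k number of voting neighbours (default 5).
#' @return A `genotype_matrix` with no missing genotypes.
#' @export
naive_impute <- function(observed, window = 11L, k = 5L) {
  stopifnot(inherits(observed, "genotype_matrix"),
            window >= 1, window %% 2 == 1, k >= 1)
  m <- observed
  ns <- n_sites(m)
  nsam <- n_samples(m)
  code <- m$ga * 1000L + m$gb            # genotype equality token
  miss <- is.na(code)
  if (!any(miss)) return(m)
  k <- min(k, nsam - 1L)
  h <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(ns) - h, 1L)
  hi <- pmin(seq_len(ns) + h, ns)
  wsum <- function(x) {                  # windowed column sums
    cs <- apply(x, 2L, cumsum)
    cs[hi, , drop = FALSE] - rbind(0, cs)[lo, , drop = FALSE]
  }

  biallelic <- all(code %in% c(0L, 1L, 1001L) | miss)
  glev <- c(0L, 1L, 1001L)
  # per-site cohort genotype counts for tie-breaks and fallbacks
  if (biallelic) {
    sf <- vapply(glev, function(g) rowSums(code == g, na.rm = TRUE),
                 numeric(ns))
    if (ns == 1L) sf <- matrix(sf, 1L)
  }

  out_code <- code
  for (s in seq_len(nsam)) {
    rows <- which(miss[, s])
    if (length(rows) == 0) next
    obs_s <- !is.na(code[, s])
    valid <- (!miss) & obs_s
    eq <- valid & (code == code[, s])
    eq[is.na(eq)] <- FALSE
    nv <- wsum(valid * 1L)
    ne <- wsum(eq * 1L)
    agree <- ifelse(nv > 0, ne / nv, -1)
    agree[, s] <- -2                     # never vote for yourself

    A <- agree[rows, , drop = FALSE]
    nb <- matrix(0L, length(rows), k)
    ok <- matrix(FALSE, length(rows), k)
    for (kk in seq_len(k)) {             # vectorised top-k extraction
      j <- max.col(A, ties.method = "first")
      idx <- cbind(seq_along(rows), j)
      ok[, kk] <- A[idx] >= 0
      nb[, kk] <- j
      A[idx] <- -3
    }
    votes <- matrix(code[cbind(rep(rows, k), as.vector(nb))],
                    length(rows), k)
    votes[!ok] <- NA_integer_

    if (biallelic) {
      cnt <- vapply(glev, function(g) rowSums(votes == g, na.rm = TRUE),
                    numeric(length(rows)))
      if (length(rows) == 1L) cnt <- matrix(cnt, 1L)
      freq <- sf[rows, , drop = FALSE]
      # lexicographic (votes, cohort freq, smaller dosage) argmax
      score <- cnt * (4 * nsam) + freq + matrix(rep(c(2, 1, 0) / 8,
                                                    each = length(rows)),
                                                length(rows))
      pick <- max.col(score, ties.method = "first")
      out_code[rows, s] <- glev[pick]
    } else {
      for (r in seq_along(rows)) {
        i <- rows[r]
        v <- votes[r, ]
        v <- v[!is.na(v)]
        cohort <- code[i, ]
        cohort <- cohort[!is.na(cohort)]
        pool <- if (length(v)) v else cohort
        if (length(pool) == 0) { out_code[i, s] <- 0L; next }
        tv <- table(pool)
        top <- as.integer(names(tv)[tv == max(tv)])
        if (length(top) > 1L && length(v)) {
          cf <- table(cohort)[as.character(top)]
          cf[is.na(cf)] <- 0
          top <- top[cf == max(cf)]
        }
        out_code[i, s] <- min(top)
      }
    }
  }
  m$ga <- matrix(out_code %/% 1000L, ns, nsam)
  m$gb <- matrix(out_code %% 1000L, ns, nsam)
  m$gq[miss] <- NA_integer_
  m
}

#' Haplotype-cluster imputation
#'
#' Model-based within-cohort imputation: genotypes are modelled as
#' unordered pairs of `K` latent haplotype clusters, each cluster
#' carrying a per-site allele frequency, with cluster membership
#' switching along the chromosome at rate `jump` (a Li-Stephens-style
#' hidden Markov model in the spirit of fastPHASE and Beagle). The
#' cluster allele frequencies are fitted by EM over the whole cohort;
#' missing genotypes are then imputed from the posterior dosage
#' distribution. This pools evidence across all carriers of a shared
#' haplotype and therefore remains informative at the sparse call
#' densities left by stringent GQ filtering, where nearest-neighbour
#' voting has nothing to match on. Biallelic sites only.
#'
#' @param observed a `genotype_matrix` with missing calls to fill.
#' @param K number of haplotype clusters (default 20).
#' @param n_iter EM iterations (default 14).
#' @param jump per-site cluster switch probability (default 0.02).
#' @param seed seed for the cluster-frequency initialisation
#'   (default 1).
#' @return A `genotype_matrix` with no missing genotypes; imputed calls
#'   carry no GQ.
#' @export
cluster_impute <- function(observed, K = 20L, n_iter = 14L, jump = 0.02,
                           seed = 1L) {
  stopifnot(inherits(observed, "genotype_matrix"),
            K >= 2, n_iter >= 1, jump > 0, jump < 1)
  m <- observed
  if (any(m$gb > 1L, na.rm = TRUE))
    stop("cluster_impute handles biallelic sites only")
  g <- m$ga + m$gb                       # dosage with NA
  miss <- is.na(g)
  if (!any(miss)) return(m)
  ns <- n_sites(m)

  # deterministic jittered initialisation around the observed AF
  af <- rowMeans(g, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0.1
  set.seed(seed)
  theta0 <- matrix(pmin(pmax(af + stats::runif(ns * K, -0.2, 0.2),
                             0.02), 0.98), ns, K)
  gi <- g
  gi[miss] <- -1L
  dose <- cluster_impute_em(gi, theta0, af, as.integer(K),
                            as.integer(n_iter), jump)
  g[miss] <- dose[miss]
  m$ga <- (g == 2L) * 1L
  m$gb <- (g >= 1L) * 1L
  m$gq[miss] <- NA_integer_
  m
}

#' Run an external imputation command
#'
#' Writes the matrix to VCF, substitutes `{in}` and `{out}` in the
#' command template, runs it, and reads the result back. The default
#' template documents the production path: Beagle v5.1 run without a
#' reference panel with the `gt=` input parameter for within-cohort
#' imputation.
#'
#' @param m a `genotype_matrix` (GQ-filtered, missing calls to fill).
#' @param template shell command template containing `{in}` and
#'   `{out}` placeholders.
#' @param workdir directory for the intermediate files.
#' @return The imputed `genotype_matrix`.
#' @export
external_impute <- function(m,
    template = "java -jar beagle.27Apr20.b81.jar gt={in} out={out}",
    workdir = tempdir()) {
  fin <- file.path(workdir, "impute_in.vcf")
  fout <- file.path(workdir, "impute_out.vcf")
  write_vcf(m, fin)
  cmd <- gsub("{in}", fin, gsub("{out}", fout, template, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd)
  if (status != 0)
    stop("external imputer failed (exit ", status, "): ", cmd)
  # Beagle appends .vcf.gz to its out= prefix
  produced <- c(fout, paste0(fout, ".vcf.gz"), paste0(fout, ".gz"))
  produced <- produced[file.exists(produced)][1]
  if (is.na(produced)) stop("external imputer produced no output VCF")
  read_vcf(produced)
}
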