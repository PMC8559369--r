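#' Call-level genotype-quality filtering
#'
#' Sets to missing every call whose GQ is less than or equal to
#' `threshold`, and every call with no GQ at all; calls with
#' GQ > threshold pass through unchanged. Sites are never removed, so
#' the output keeps the full marker scaffold an imputation step needs.
#' The default threshold of 17 keeps calls with GQ > 17, the operating
#' point that balances recall, precision and non-reference concordance
#' for mid-pass cohorts.
#'
#' @param m a `genotype_matrix`.
#' @param threshold non-negative integer; calls with `GQ <= threshold`
#'   (or absent GQ) become missing.
#' @return A list with `matrix` (the filtered `genotype_matrix`) and
#'   `report` (data.frame per sample: `sample`, `set_missing`,
#'   `retained`; attribute `threshold`).
#' @export
gq_filter <- function(m, threshold = 17L) {
  stopifnot(inherits(m, "genotype_matrix"), threshold >= 0)
  threshold <- as.integer(threshold)
  present <- !is.na(m$ga)
  drop <- present & (is.na(m$gq) | m$gq <= threshold)
  report <- data.frame(
    sample = m$samples,
    set_missing = colSums(drop),
    retained = colSums(present & !drop),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "threshold") <- threshold
  list(matrix = set_missing(m, drop), report = report)
}

#' Prepare a high-coverage truth callset
#'
#' Restricts a high-coverage callset to the calls trusted as ground
#' truth: non-PASS sites are removed and calls with GQ <= 20 are set
#' missing, leaving PASS sites with GQ > 20 genotypes. Idempotent.
#'
#' @param m a `genotype_matrix` carrying site filter status and per-call
#'   GQ.
#' @return The truth `genotype_matrix`.
#' @export
prepare_truth <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"))
  if (is.null(m$sites$filter))
    stop("matrix carries no site filter status")
  m <- subset_sites(m, which(m$sites$filter == "PASS"))
  drop <- !is.na(m$ga) & (is.na(m$gq) | m$gq <= 20L)
  set_missing(m, drop)
}

#' Site-level call-rate filter
#'
#' Retains sites where the fraction of samples with a non-missing call
#' is at least `min_rate` (inclusive).
#'
#' @param m a `genotype_matrix`.
#' @param min_rate minimum acceptable call rate in \[0, 1\];
#'   default 0.5.
#' @return The filtered `genotype_matrix`.
#' @export
call_rate_filter <- function(m, min_rate = 0.5) {
  stopifnot(inherits(m, "genotype_matrix"),
            min_rate >= 0, min_rate <= 1)
  rate <- rowMeans(!is.na(m$ga))
  subset_sites(m, which(rate >= min_rate))
}
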