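#' GQ-threshold sweep
#'
#' Re-runs the filter-then-impute pipeline over a range of GQ
#' thresholds and scores each against a truth callset, reproducing the
#' threshold-selection experiment: too little filtering leaves
#' error-prone calls in place, too much starves the imputer of
#' markers, and the optimum lies between.
#'
#' For each threshold `t`: [gq_filter()] at `t`, then `imputer`, then
#' pooled recall/precision and non-reference concordance against
#' `truth`. The selected threshold maximises NCR among thresholds whose
#' recall is within `delta` of the best recall.
#'
#' @param observed the pre-imputation `genotype_matrix`.
#' @param truth the truth `genotype_matrix`.
#' @param thresholds integer vector of GQ thresholds to test.
#' @param imputer function `genotype_matrix -> genotype_matrix`
#'   (default [naive_impute()]).
#' @param delta recall tolerance for threshold selection
#'   (default 0.005).
#' @return data.frame with one row per threshold: `threshold`,
#'   `pre_impute_calls` (non-missing calls after filtering), `recall`,
#'   `precision`, `ncr`, `failed`; the chosen threshold in attribute
#'   `selected`.
#' @export
gq_sweep <- function(observed, truth, thresholds = 0:30,
                     imputer = naive_impute, delta = 0.005) {
  stopifnot(length(thresholds) >= 1)
  rows <- vector("list", length(thresholds))
  for (j in seq_along(thresholds)) {
    t <- thresholds[j]
    filt <- gq_filter(observed, t)$matrix
    row <- data.frame(threshold = t,
                      pre_impute_calls = sum(!is.na(filt$ga)),
                      recall = NA_real_, precision = NA_real_,
                      ncr = NA_real_, failed = FALSE)
    imp <- tryCatch(imputer(filt), error = function(e) e)
    if (inherits(imp, "error")) {
      row$failed <- TRUE
      warning("imputer failed at threshold ", t, ": ",
              conditionMessage(imp))
    } else {
      sm <- site_metrics(imp, truth, per_sample = FALSE)
      gc <- genotype_concordance(imp, truth, per_sample = FALSE)
      row$recall <- sm$recall
      row$precision <- sm$precision
      row$ncr <- gc$concordance
    }
    rows[[j]] <- row
  }
  out <- do.call(rbind, rows)
  ok <- !out$failed & is.finite(out$ncr) & is.finite(out$recall)
  if (any(ok)) {
    cand <- ok & out$recall >= max(out$recall[ok]) - delta
    sel <- out$threshold[cand][which.max(out$ncr[cand])]
    attr(out, "selected") <- sel
  }
  out
}
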