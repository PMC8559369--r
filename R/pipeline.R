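#' Run the full refinement pipeline
#'
#' Orchestrates the end-to-end strategy: call-level GQ filtering,
#' within-cohort imputation, consistency flagging, flag-based call
#' dropping, and (when a truth callset is available) concordance
#' evaluation. Intermediate files are retained in `out_dir` and every
#' stage's parameters go to the run log.
#'
#' @param config either a YAML file path or a named list with entries:
#'   \describe{
#'     \item{input}{path to the pre-imputation VCF, or `NULL` when
#'       `simulate` is given.}
#'     \item{simulate}{optional list of [sim_config()] arguments; when
#'       present the cohort is simulated and the truth written too.}
#'     \item{truth}{optional truth VCF path (prepared via
#'       [prepare_truth()] unless `truth_prepared = TRUE`).}
#'     \item{regions}{optional high-confidence BED path.}
#'     \item{gq_threshold}{call-filter threshold (default 17).}
#'     \item{drop_flags}{IM flags to drop (default `"IM3"`; empty
#'       vector to keep all).}
#'     \item{call_rate}{site call-rate filter applied to the truth set
#'       (default 0.5).}
#'     \item{imputer}{`"naive"`, `"cluster"`, or an external command
#'       template with `{in}`/`{out}` placeholders.}
#'     \item{seed}{RNG seed (default 1).}
#'   }
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the output paths and the metrics
#'   data.frame (`NULL` without a truth set).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(gq_threshold = 17L, drop_flags = "IM3",
                   call_rate = 0.5, imputer = "naive", seed = 1L,
                   truth_prepared = FALSE)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$input) && is.null(config$simulate))
    stop("config needs either an input VCF or a simulate block")
  if (!is.null(config$truth) && is.character(config$truth) &&
      !file.exists(config$truth))
    stop("truth VCF not found: ", config$truth)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("midpass %s", as.character(utils::packageVersion("midpass")))
  cfg_tmp <- tempfile()
  saveRDS(config[order(names(config))], cfg_tmp)
  logf("config sha/md5 %s", unname(tools::md5sum(cfg_tmp)))
  unlink(cfg_tmp)
  for (k in names(config))
    logf("  %s = %s", k, paste(format(config[[k]]), collapse = " "))

  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config, utils::modifyList(
      config$simulate, list(seed = config$seed)))
    sim <- make_cohort(sc)
    observed <- simulate_midpass(sim)
    truth <- sim$truth
    write_vcf(truth, file.path(out_dir, "truth.vcf"))
    write_vcf(observed, file.path(out_dir, "observed.vcf"))
    logf("simulated cohort: %d samples x %d sites", sc$n_samples,
         sc$n_sites)
  } else {
    observed <- read_vcf(config$input, required_fields = c("GT", "GQ"))
    if (!is.null(config$truth)) {
      truth <- read_vcf(config$truth, required_fields = c("GT", "GQ"))
      if (!isTRUE(config$truth_prepared)) truth <- prepare_truth(truth)
    }
  }

  fr <- gq_filter(observed, config$gq_threshold)
  filtered <- fr$matrix
  filtered_path <- file.path(out_dir, "filtered.vcf")
  write_vcf(filtered, filtered_path)
  utils::write.table(fr$report, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("gq_filter t=%d: %d calls set missing",
       config$gq_threshold, sum(fr$report$set_missing))

  imputed <- switch(
    config$imputer,
    naive = naive_impute(filtered),
    cluster = cluster_impute(filtered, seed = config$seed),
    external_impute(filtered, template = config$imputer,
                    workdir = out_dir))
  logf("imputation (%s) complete",
       if (config$imputer %in% c("naive", "cluster"))
         config$imputer else "external")

  # flags compare the imputed calls with the original sequencing-based
  # calls (the unfiltered set), so calls blanked by the GQ filter still
  # testify about allele loss
  fm <- merge_and_flag(observed, imputed)
  flagged_path <- file.path(out_dir, "flagged.vcf")
  write_flagged_vcf(fm, flagged_path)
  final <- filter_by_flag(fm, config$drop_flags)
  logf("flags: %s", paste(sprintf("IM%d=%d", 0:3,
       vapply(0:3, function(f) sum(fm$im == f, na.rm = TRUE),
              integer(1))), collapse = " "))

  metrics <- NULL
  metrics_path <- NULL
  if (!is.null(truth)) {
    truth_eval <- call_rate_filter(truth, config$call_rate)
    if (!is.null(config$regions)) {
      reg <- read_bed(config$regions)
      final <- restrict_to_regions(final, reg)
      truth_eval <- restrict_to_regions(truth_eval, reg)
    }
    sm <- site_metrics(final, truth_eval)
    gc <- genotype_concordance(final, truth_eval)
    metrics <- merge(sm, gc, by = "sample", sort = FALSE)
    metrics_path <- file.path(out_dir, "metrics.tsv")
    utils::write.table(format(metrics, digits = 10), metrics_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pooled <- metrics[metrics$sample == "(pooled)", ]
    logf("pooled recall=%.4f precision=%.4f ncr=%.4f",
         pooled$recall, pooled$precision, pooled$concordance)
  }

  invisible(list(filtered = filtered_path, flagged = flagged_path,
                 metrics_path = metrics_path, metrics = metrics,
                 log = log_path))
}
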