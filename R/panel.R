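#' Per-site allele frequencies and call rates
#'
#' Counts alternate alleles over non-missing diploid calls:
#' `AF = alt allele count / (2 x non-missing calls)`, with
#' `MAF = min(AF, 1 - AF)`. For multiallelic sites the count pools all
#' alternate alleles (the simulator and pipeline are biallelic; the
#' pooled figure is the non-reference frequency).
#'
#' @param m a `genotype_matrix`.
#' @param warn warn about sites with zero non-missing calls (excluded).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `af`, `maf`, `call_rate`.
#' @export
compute_af <- function(m, warn = TRUE) {
  stopifnot(inherits(m, "genotype_matrix"))
  nn <- rowSums(!is.na(m$ga))
  alt_count <- rowSums(alt_dosage(m), na.rm = TRUE)
  af <- alt_count / (2 * nn)
  out <- data.frame(
    chrom = m$sites$chrom, pos = m$sites$pos, ref = m$sites$ref,
    alt = m$sites$alt, key = site_keys(m),
    af = af, maf = pmin(af, 1 - af),
    call_rate = nn / n_samples(m),
    row.names = NULL, stringsAsFactors = FALSE)
  undef <- nn == 0L
  if (any(undef)) {
    if (warn)
      warning(sum(undef), " site(s) with no non-missing calls excluded ",
              "from the AF table")
    out <- out[!undef, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a reference-panel allele-frequency table
#'
#' Tab-separated table with columns `chrom`, `pos`, `ref`, `alt`, `af`
#' (header optional when the columns are in this order).
#'
#' @param path TSV file path.
#' @return data.frame with those columns plus `key` and `maf`.
#' @export
read_af_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "ref", "alt", "af") %in% names(tab))) {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 5) stop("panel table needs columns chrom, pos, ref, alt, af")
    names(tab)[1:5] <- c("chrom", "pos", "ref", "alt", "af")
  }
  if (any(tab$af < 0 | tab$af > 1)) stop("panel AF outside [0, 1]")
  alt_sorted <- vapply(strsplit(as.character(tab$alt), ",", fixed = TRUE),
                       function(a) paste(sort(a), collapse = ","),
                       character(1))
  tab$key <- paste(tab$chrom, tab$pos, tab$ref, alt_sorted, sep = ":")
  if (anyDuplicated(tab$key)) stop("duplicated site key in panel table")
  tab$maf <- pmin(tab$af, 1 - tab$af)
  tab
}

#' Classify cohort variants against a reference panel
#'
#' A cohort variant is evaluated only when it is common in the cohort
#' (cohort MAF strictly greater than `cohort_min_maf`). Evaluated
#' variants absent from the panel are `absent`; present with panel MAF
#' strictly below `panel_rare_max` are `rare`; otherwise
#' `common_in_panel`. Boundary values fall outside the common and rare
#' classes (strict inequalities).
#'
#' @param cohort cohort AF table from [compute_af()] (needs `key`,
#'   `maf`).
#' @param panel panel AF table from [read_af_table()] or any data.frame
#'   with `key` and `maf`.
#' @param cohort_min_maf cohort commonness gate (default 0.05).
#' @param panel_rare_max panel rarity bound (default 0.01).
#' @return factor vector over
#'   `c("absent", "rare", "common_in_panel", "not_evaluated")`, one per
#'   cohort row.
#' @export
classify_novelty <- function(cohort, panel, cohort_min_maf = 0.05,
                             panel_rare_max = 0.01) {
  stopifnot(all(c("key", "maf") %in% names(cohort)),
            all(c("key", "maf") %in% names(panel)))
  panel_maf <- panel$maf[match(cohort$key, panel$key)]
  cls <- rep("not_evaluated", nrow(cohort))
  eval_ok <- cohort$maf > cohort_min_maf
  cls[eval_ok & is.na(panel_maf)] <- "absent"
  cls[eval_ok & !is.na(panel_maf) & panel_maf < panel_rare_max] <- "rare"
  cls[eval_ok & !is.na(panel_maf) & panel_maf >= panel_rare_max] <-
    "common_in_panel"
  factor(cls, levels = c("absent", "rare", "common_in_panel",
                         "not_evaluated"))
}

# fixed consequence-term lists (VEP vocabulary)
consequence_terms <- list(
  coding = c("frameshift_variant", "inframe_deletion", "inframe_insertion",
             "missense_variant", "start_lost", "stop_gained", "stop_lost",
             "stop_retained_variant", "synonymous_variant"),
  regulatory = c("5_prime_UTR_variant", "3_prime_UTR_variant",
                 "mature_miRNA_variant", "regulatory_region_variant",
                 "splice_acceptor_variant", "splice_donor_variant",
                 "splice_region_variant", "TF_binding_site_variant",
                 "TFBS_ablation"),
  other = c("downstream_gene_variant", "intergenic_variant",
            "intron_variant", "non_coding_transcript_exon_variant",
            "upstream_gene_variant"))
stopifnot(!anyDuplicated(unlist(consequence_terms)))

#' Classify a consequence term into a functional class
#'
#' Exact-match lookup of VEP-style consequence terms against fixed
#' coding / regulatory / other term lists; anything else is
#' `unclassified`. When a variant carries several `&`- or `,`-joined
#' terms the most severe class wins, with precedence
#' coding > regulatory > other > unclassified.
#'
#' @param term character vector of consequence terms (possibly
#'   `&`/`,`-joined).
#' @return factor over
#'   `c("coding", "regulatory", "other", "unclassified")`.
#' @export
classify_consequence <- function(term) {
  lv <- c("coding", "regulatory", "other", "unclassified")
  one <- function(t) {
    if (is.na(t) || !nzchar(t)) return("unclassified")
    parts <- strsplit(t, "[&,]")[[1]]
    if (any(parts %in% consequence_terms$coding)) return("coding")
    if (any(parts %in% consequence_terms$regulatory)) return("regulatory")
    if (any(parts %in% consequence_terms$other)) return("other")
    "unclassified"
  }
  factor(vapply(term, one, character(1), USE.NAMES = FALSE), levels = lv)
}

#' Summarise panel-novel variation
#'
#' Tallies evaluated cohort variants (novelty class `absent` or `rare`)
#' by variant type and functional class. Indels outside the
#' high-confidence region set are excluded; all SNVs are retained
#' regardless of region.
#'
#' @param af_table cohort AF table from [compute_af()] (needs `chrom`,
#'   `pos`, `key`).
#' @param novelty novelty classes from [classify_novelty()], parallel to
#'   `af_table` rows.
#' @param vtype character vector (`"SNV"`/`"INDEL"`) parallel to rows.
#' @param consequence optional consequence terms parallel to rows
#'   (classified via [classify_consequence()]); `NULL` counts everything
#'   as `unclassified`.
#' @param regions optional high-confidence `region_set` for the indel
#'   rule; `NULL` keeps all indels.
#' @return data.frame of counts over novelty x vtype x class (zero rows
#'   included for the `absent`/`rare` strata).
#' @export
novelty_summary <- function(af_table, novelty, vtype, consequence = NULL,
                            regions = NULL) {
  stopifnot(nrow(af_table) == length(novelty),
            nrow(af_table) == length(vtype))
  keep <- novelty %in% c("absent", "rare")
  if (!is.null(regions)) {
    gr <- GenomicRanges::GRanges(
      af_table$chrom, IRanges::IRanges(start = af_table$pos, width = 1L))
    in_reg <- IRanges::overlapsAny(gr, as_granges(regions))
    keep <- keep & (vtype == "SNV" | in_reg)
  }
  cls <- if (is.null(consequence))
    factor(rep("unclassified", nrow(af_table)),
           levels = levels(classify_consequence(character(0)))) else
    classify_consequence(consequence)
  tab <- table(
    novelty = factor(novelty[keep], levels = c("absent", "rare")),
    vtype = factor(vtype[keep], levels = c("SNV", "INDEL")),
    class = cls[keep])
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  out
}
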