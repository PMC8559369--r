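---
title: "Genotype refinement and benchmarking for mid-pass WGS: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype refinement and benchmarking for mid-pass WGS: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mid-pass whole-genome sequencing (roughly 1--7x mean depth) buys cohort
size at the cost of per-site evidence. At these depths many genotype
calls rest on one or two reads: heterozygotes are frequently observed
through only one allele, and the phred-scaled genotype quality (GQ) of
even correct calls is low. The standard remedy is a three-stage
refinement: (i) discard calls whose GQ falls at or below a threshold,
(ii) fill the resulting gaps by within-cohort imputation, which
exploits haplotype sharing among the study samples themselves (no
external reference panel), and (iii) flag imputed genotypes that
contradict the sequencing evidence they replaced. `midpass` implements
this refinement together with the machinery needed to evaluate it.

## Containers and conventions

All operations act on a `genotype_matrix`: a sites-by-samples table of
unordered diploid allele-index pairs plus per-call GQ and depth. VCF
positions are 1-based; BED intervals are 0-based half-open, so a site
is inside an interval when `pos - 1` lies in `[start, end)`.
Multiallelic records stay single sites; a site is keyed by
(chrom, pos, ref, alt *set*), so records at one position with
different allele sets never match each other. Half-calls (`./1`) are
treated as missing: they are undefined under the diploid comparison
rules and any other choice would leak ill-defined genotypes into the
metrics. Phase is always discarded.

## Call filtering

`gq_filter()` sets to missing every call with `GQ <= t` (default
`t = 17`, keeping calls with GQ > 17) and every call without a GQ;
sites are never removed, because the imputation step consumes the full
marker scaffold. The call-rate filter (`call_rate_filter()`, default
50%) is inclusive: a site at exactly the minimum rate is kept. The
truth-set preparation (`prepare_truth()`) keeps PASS sites and calls
with GQ > 20, the conventional operating point for high-coverage
(~30x) reference callsets.

## Consistency flags

After imputation, `merge_and_flag()` compares each imputed call with
the sequencing-based call at the same site, on allele *sets*. In the
pipeline the sequencing-based side is the *original unfiltered*
callset: an imputer that only fills gaps never contradicts the calls
it kept, so the informative comparisons are exactly against the
low-GQ calls the filter blanked before imputation. The classes:

* **IM0** -- not imputed, or identical to the filtered call;
* **IM1** -- not inconsistent: the filtered call was missing, or every
  sequenced allele survived (an allele may have appeared -- at low
  depth the second allele of a heterozygote is often simply unseen);
* **IM2** -- an observed allele disappeared and the filtered call was
  heterozygous;
* **IM3** -- an observed allele disappeared and the filtered call was
  homozygous, i.e. imputation contradicts both observed copies.

Sets rather than multisets drive the rule: `0/1` imputed to `1/1`
loses allele 0 and is IM2 even though the copy number of allele 1
rose. `filter_by_flag()` only ever drops IM2/IM3 -- the inconsistent
classes -- because dropping "consistent" calls has no rationale and is
rejected as a configuration error.

## Performance metrics

Recall and precision are site-level: per sample, a site counts when
the call is non-missing and carries at least one alternate allele.
Recall divides true-positive variant sites by the truth set's variant
sites; precision divides by the test set's. Non-reference concordance
(NCR) is genotype-level, computed over sites shared by both callsets
and calls non-missing in both: pairs where both calls are identical
homozygous-reference are excluded from numerator and denominator;
every other compared pair enters the denominator. Truth-only sites
therefore reduce recall but not NCR, and missing-in-test calls at
shared sites are skipped rather than counted discordant -- the site
metrics and the genotype metric answer different questions, and mixing
them double-counts missingness. In minor-allele mode the
reference/alternate homozygote roles are exchanged at sites with
alternate AF > 0.5 (AF from the truth cohort by default), so the
exclusion applies to the major-allele match; with all AF at or below
0.5 the two modes coincide.

Stratification (`stratified_metrics()`) bins sites by truth-cohort MAF
(`min(AF, 1-AF)`; test-only sites fall back to the test-cohort MAF so
false positives still land in a bin), samples by mean coverage
(left-closed bins), restricts to high-confidence regions before
matching, and can split SNVs from indels. The default MAF bin edge of
2% reflects the threshold at which array-plus-panel imputation and
mid-pass sequencing exchange ranks in precision.

## The synthetic cohort

`make_cohort()` draws `n_founders` (default 20) founder haplotypes
whose per-site alternate-allele counts follow the neutral-like
spectrum P(i) proportional to 1/i -- rare variants dominate, as in real
site-frequency spectra. Each sample haplotype is a mosaic copy of
founders, switching founders between consecutive sites with
probability `switch_rate` (default 0.01, i.e. founder segments of
~100 sites): a Li--Stephens-flavoured process that produces the
linkage disequilibrium within-cohort imputation relies on, with two
parameters instead of a coalescent.

`simulate_midpass()` then sequences each call: depth
`d ~ Poisson(coverage)`; each read copies one of the two true alleles
uniformly and miscalls it with probability `error_rate` (default
0.01, roughly a Q20 read after mapping); biallelic genotype
likelihoods `L(hom) = (1-e)^matching * e^mismatching`,
`L(het) = (1/2)^d`; flat-prior posterior; GT is the posterior mode
(ties resolved hom-ref < het < hom-alt, which only matters at tiny
depths); `GQ = min(99, round(-10 log10(1 - posterior)))`; `d = 0`
yields a missing call. Because the prior is flat, a clean homozygote
needs d of about 6 reads to clear GQ 17 (the het likelihood `2^-d`
decays at ~3 GQ per read). Production callers fold cohort allele
frequencies into the prior and so emit higher GQ at the same depth;
the simulator's GQ scale therefore runs *low*, which shifts the
optimal filter threshold downward (see below) but leaves the
phred calibration intact -- simulated calls in a GQ stratum err at
close to the nominal `10^(-GQ/10)` rate.

What the simulator does **not** model: indels (multiallelic and indel
code paths are exercised by constructed fixtures instead), mapping
artifacts, duplicate reads, batch effects, related samples, and
population structure. Passing simulation-based tests therefore shows
the pipeline's logic and its qualitative responses to depth and
filtering, not the absolute accuracy obtainable on real cohorts.

Determinism: every generator and the pipeline are pure functions of
(config, seed); `make_cohort()` seeds R's RNG at entry and
`simulate_midpass()` at `seed + 1`, so each stage is independently
reproducible. A single stream with fixed iteration order was chosen
over per-sample sub-streams: it gives the same bit-reproducibility
with less machinery.

## Imputation

Two imputers are included, and the production path is documented as an
external command template (`external_impute()`, defaulting to the
Beagle v5.1 invocation with `gt=` input and no reference panel).

`naive_impute()` is transparent scaffolding: for each missing call,
the `k` (default 5) samples agreeing best with the target over a
`window` (default 11 sites; agreement = fraction of identical
genotypes among sites observed in both) vote with their genotype at
the site; majority wins, ties break toward the cohort-frequent
genotype and then the smaller dosage. Its weakness is structural:
agreement must be estimated from positions observed in *both* samples
(density squared), and the best-agreeing neighbours usually share one
haplotype, not two, so the majority genotype is systematically wrong
at heterozygous sites. At the call densities left by stringent GQ
filtering it degenerates toward cohort-modal imputation.

`cluster_impute()` is the package's model-based imputer: a diploid
hidden Markov model in the fastPHASE/Beagle family. Genotypes are
unordered pairs of `K` (default 20) latent haplotype clusters; cluster
`k` carries a per-site allele probability; each haplotype switches
cluster with probability `jump` (default 0.02) per site. Cluster
allele probabilities are fitted by EM over the whole cohort
(`n_iter = 14`, with a deterministic jittered initialisation around
the observed allele frequencies); missing calls are imputed by the
posterior-mode dosage. The M-step shrinks each cluster's allele
probability toward the site's observed allele frequency, so sites
with no anchoring data revert to the AF prior rather than drifting to
0.5 and being imputed heterozygous across the board. Transitions
factorise per haplotype, so the K^2-state forward--backward costs
O(K^2) per site (implemented in C++). Because it pools evidence over
all carriers of a haplotype, it stays informative at scaffold
densities where pairwise matching has nothing to match on. The
defaults put `K` at the generative founder count and run EM to
convergence on the shipped designs; under-iterated fits leave the
imputer's quality still climbing with scaffold density, which
visibly distorts the coverage-response curves.

## The threshold sweep and what it reproduces

`gq_sweep()` re-runs filter-then-impute over a threshold grid and
scores each against truth. Too little filtering leaves error-prone
calls in place; too much starves the imputer; the NCR curve rises and
falls with an interior maximum. The selected threshold maximises NCR
subject to recall within `delta = 0.005` of the best -- the "optimal
balance" rule is a declared package choice, since balancing
recall/precision/NCR admits many formalisations. On simulated
mid-pass cohorts the optimum falls at GQ ~5 rather than ~17; this is
the flat-prior GQ scale at work (see above), not a different
phenomenon -- the sweep procedure, not the number 17, transfers across
GQ conventions. Downstream experiments (coverage response, flag
evaluation) therefore run at the sweep-established threshold, exactly
as the real pipeline establishes its threshold before the coverage
analysis.

Problem sizes used in the shipped experiments: sweeps and coverage
designs run at 200--240 samples by 2,000 sites; calibration checks at
500 by 2,000; unit fixtures are at most tens of sites. The sweep
cohort follows the harsher read-error setting (5%) under which the
filtering/imputation trade-off is sharpest; the coverage experiment
runs at the generator's default 1% error so that the coverage
response reflects imputation, not raw-call noise-cleaning. These sizes
make every stochastic check stable under its fixed seed while keeping
the full suite comfortably reproducible on a laptop.

## Reference-panel comparison

`compute_af()` counts alternate alleles over non-missing calls;
`classify_novelty()` gates cohort variants at cohort MAF strictly
greater than 5%, then classes them against the panel: absent, rare
(panel MAF strictly below 1%), or common-in-panel; boundary values
fall outside the common/rare classes because the inequalities are
strict. Consequence terms are an exact-match lookup of the fixed
coding/regulatory/other VEP term lists (disjointness asserted at
load); with several terms per variant the most severe class wins
(coding > regulatory > other), a declared choice since only one class
per variant is reported. The novelty summary excludes indels outside
the high-confidence regions and keeps all SNVs, mirroring how
false-positive-prone indel calls are handled in panel-novelty
analyses.

## Degenerate inputs and numerical notes

Zero-depth calls are missing; a sample with nothing to vote receives
the cohort-modal genotype and an entirely missing site homozygous
reference. Undefined ratios (empty truth, empty test, no compared
pairs) are reported as `NaN`, never silently zero. GQ posteriors are
floored at 1e-10 before the log so the cap at 99 engages cleanly.
Forward--backward passes renormalise per site. All tie-breaks
(argmax genotype, neighbour ranking, vote counts) are specified and
first-index deterministic.

## Known limitations

* The simulator is biallelic SNV-only; indel behaviour is covered by
  constructed fixtures, not generated data.
* `cluster_impute()` assumes biallelic sites and refuses otherwise.
* Site matching is exact on (chrom, pos, ref, alt set): no indel
  left-normalisation or haplotype-aware (hap.py-style) matching.
* The naive imputer is scaffolding, not a baseline worth reporting
  against; use the cluster imputer or Beagle for anything substantive.
* With the flat-prior GQ model, absolute GQ values -- and hence the
  numeric optimum of the threshold sweep -- are not directly
  comparable to production-caller GQ scales.
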