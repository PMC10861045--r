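---
title: "Estimating germline mutation rates from trio sequencing, and what they imply for population size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating germline mutation rates from trio sequencing, and what they imply for population size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomu)
```

## The problem

A germline de novo mutation (DNM) is a variant carried by an offspring but
by neither parent. Sequencing mother-father-offspring trios at high depth
lets one count DNMs directly and convert the count into a per-site
per-generation mutation rate

$$\mu = \frac{nb_{DNM} - nb_{FP}}{2\,C\,(1 - FNR)},$$

where $nb_{DNM}$ is the number of candidate DNMs surviving the trio-level
filters, $nb_{FP}$ the number of those later classed false positive, $C$
the number of *callable* sites (positions where a DNM could have been
detected had it occurred), and $FNR$ the false-negative rate of the
detection filters. The factor 2 counts the two transmitted genomes per
offspring.

`triomu` implements this estimator end to end for diploid trio cohorts —
the motivating design is seven biparental families with two sibling
offspring each (14 trios) sequenced to roughly 60X — together with the
mutation-spectrum summaries (transition:transversion ratio, CpG context,
parent-of-origin phasing and the paternal:maternal ratio $\alpha$) and a
population-size layer: equilibrium $N_e = \pi / (4\mu)$, harmonic and
arithmetic means of externally inferred $N_e$ trajectories, bootstrap
census sizes $N_c$ from reef survey tables, and $N_e/N_c$ ratios.

## The detection cascade

Candidates pass through ordered, auditable stages; each stage can only
remove candidates and each rejection carries a reason.

1. **Site filters** (`apply_site_filters`): a site fails if QD < 2.0,
   FS > 20.0, MQ < 40.0, MQRankSum outside (−2, 4), ReadPosRankSum
   outside (−3, 3), or SOR > 3.0. Missing annotations pass — the caller
   convention — and missingness stays visible in the record.
2. **Mendelian violations** (`detect_mendelian_violations`): an offspring
   allele present in neither parental called genotype. The canonical DNM
   configuration (hom-ref × hom-ref parents, het offspring) is flagged;
   other violations are recorded but never validated.
3. **Trio-level filters** (`trio_candidate_filter`): both parents hom-ref
   with zero alternate allelic depth (AD = 0), offspring het, GQ strictly
   above 70 in all three, each sample's depth strictly inside
   (0.5, 2) × its *own* mean depth, and offspring allelic balance in
   [0.3, 0.7]. GQ and DP comparisons are strict inequalities exactly as
   conventionally printed. Whether the AB bounds are inclusive is not a
   settled convention, so it is a config switch (`ab_inclusive`,
   default inclusive); both readings are exercised in the tests.
4. **Independent recall** (`independent_recall`): the trio is re-genotyped
   from raw allelic depths by the package's binomial genotype-likelihood
   caller (error rate 0.005 by default). Concordance between two
   independent genotyping routes is the idea; shelling out to external
   callers is deliberately avoided so the package runs self-contained,
   and the recall model is exposed so an external-caller adapter can
   replace it.
5. **Population screen** (`population_screen`): candidates present in a
   population polymorphism table (same position *and* same alternate
   allele; positional matching by flag) are segregating variants, not
   DNMs.
6. **Curation heuristics** (`curation_heuristics`): automated,
   individually switchable proxies for visual inspection — raw parental
   alternate reads, proximity to the nearest other candidate (default
   10 bp), candidate clustering (> 2 per 100 bp), sibling genotype
   contradiction, extreme strand/position bias, and depth anomalies.
   Visual curation criteria are never fully mechanisable; these proxies
   are explicit, tunable stand-ins, and on noisy real data they should be
   reviewed per cohort. The proximity proxy measures distance to other
   *candidates* (plus any supplied known-variant positions), not to every
   segregating site — at percent-scale heterozygosity the latter would
   reject most of the genome, which cannot be the intent of a
   mis-mapping heuristic.

## Callable sites and the false-negative rate

$C$ counts positions at which both parents are called hom-ref and all
three samples pass the GQ and DP rules (`count_callable_sites`). Because
the same GQ/DP rules gate both candidacy and callability, numerator and
denominator of $\hat\mu$ are measured under identical filters.

For simulated genomes where materialising per-base records is pointless,
`estimate_trio_callable` counts the explicitly simulated (variant) sites
exactly and measures the callable fraction of the exchangeable invariant
remainder on a seeded Monte-Carlo sample (20,000 positions by default,
giving a relative error on $C$ well below 1%), scaling it to the genome
length.

The FNR is estimated by spike-in simulation (`estimate_fnr`): true het
DNM sites are drawn under the read model (offspring
$AD_{alt} \sim \mathrm{Bin}(DP, 1/2)$; parents hom-ref with error-rate
alternate reads) and pushed through the candidate rules. Two design
choices matter:

- The FNR is computed *conditional on* the GQ/DP callability rules.
  Losses to GQ/DP are already absorbed by $C$; counting them again in
  the FNR would correct twice.
- The parental AD = 0 rule is part of the spiked trio. At 60X with a
  per-read error of $10^{-3}$, each truly hom-ref parent shows at least
  one alternate read at roughly 6% of sites, so about 11% of true DNMs
  are rejected through no fault of the offspring's evidence. This is the
  dominant false-negative channel at these settings, and the estimator
  is biased low by exactly that fraction unless the FNR includes it.
  Every component (`detect`, `parent_ad`, `gq`, `dp`, `ab`) is
  individually switchable, which also makes the exact binomial oracle for
  the AB-only case testable: with depth fixed at 60 and only AB enabled,
  the FNR converges to $P(X \notin [18, 42])$, $X \sim \mathrm{Bin}(60, 1/2)$.

Whether a single cohort-wide FNR or per-trio FNRs are appropriate depends
on how homogeneous depth is across trios; the package default is
cohort-wide (one spike-in under the cohort's depth model), matching the
single-number convention, and per-trio values can be obtained by calling
`estimate_fnr` with per-trio depth parameters.

## Cohort mean and confidence interval

`cohort_rate_and_ci` reports the arithmetic mean of per-trio rates with a
95% percentile bootstrap over trios (default 10,000 resamples; the trios
are the exchangeable units) and a Student t-interval for comparison. The
bootstrap is the default because per-trio rates are few, skewed and
bounded below by zero. With sparse counts (a handful of DNMs per cohort)
the percentile bootstrap is known to undercover, and a cohort whose
pipeline validates zero DNMs necessarily yields the degenerate interval
[0, 0]; this matters for the recovery study below. Sibling-shared DNMs
count once per offspring — each offspring's rate uses its own DNM list —
so per-trio estimates remain identically distributed.

## What the synthetic cohorts emulate

`sim_config()` defaults encode the motivating study design: 7 families ×
2 offspring, parental heterozygosity $\pi$ = 0.0108, true rate
$\mu = 9.13\times10^{-9}$, sibling-sharing fraction 0.19, 60X depth,
transition:transversion weight 47/16 (so the planted spectrum converges
to ti/tv ≈ 2.94).

- **Genomes** are infinite-sites and biallelic: each parent is
  heterozygous at a site independently with probability `pi_true`; no
  tri-allelic sites exist, matching datasets in which multi-allelic sites
  are absent after filtering. Sites are unlinked (no LD), which is
  irrelevant to the rate estimator but means the simulated fragments used
  for phasing carry more informative sites than real short reads would.
- **Sibling sharing** is modelled as family-level mosaic events:
  shared events arise at rate `share_fraction * 2 L mu` per family and
  appear identically in both siblings (same position, allele and parental
  haplotype); private events make up the rest. This keeps the expected
  DNM count per offspring at exactly `2 L mu` — the naive "copy an
  offspring's DNM to its sibling" construction would inflate per-offspring
  counts by the sharing fraction — while the expected shared fraction of
  DNM instances equals `share_fraction`.
- **Depth** is negative binomial with variance
  `mean_depth + depth_dispersion * mean_depth^2` (Poisson at dispersion
  0). The default dispersion 0.03 gives a per-site standard deviation of
  about 13 reads at 60X (index of dispersion ≈ 2.8), a typical
  short-read WGS spread.
- **Reads** are summarised at allelic-depth level: alternate depth is
  binomial with success 1/2 for hets and `base_error_rate` (default
  0.001) for homozygotes; genotypes and GQ come from the binomial
  genotype-likelihood model, with GQ the Phred-scaled gap between the
  best and second-best genotype, capped at 99. An exact error rate of 0
  is honoured with hard-zero likelihoods, giving a genuinely noiseless
  limit. No read-level FASTQ/BAM is simulated; read-back phasing uses
  synthetic haplotype fragments instead.
- **Site annotations** (QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR) are
  drawn from Gaussian nulls at least six standard deviations inside the
  pass region of every default site filter, so clean sites essentially
  never fail a site filter; `artifact_rate` flips a chosen fraction of
  sites into a failing region to exercise the filters.
- **Reef surveys** draw reef-year densities lognormally around regime
  means — baseline 300 per km² (~3 per ha) and outbreak 150,000 per km²
  (~1,500 per ha) — with the regime mean preserved as the distribution
  mean, plus optional roster subsampling.

What passing tests on these cohorts do *not* show: robustness to
alignment artefacts, mapping-quality pathologies, indel-adjacent errors
or reference bias — the features visual curation targets in real data.
The artifact-injection knob probes the site filters, not those upstream
processes.

## Numerical and scaling choices

- Coordinates are 1-based inclusive in VCF records and 0-based half-open
  in interval containers (callable masks, BED); the conventions are fixed
  by round-trip tests.
- Genotype-likelihood ties resolve to the lower genotype code; phasing
  conflicts resolve to `unknown`, never majority vote.
- The recovery study in the test suite simulates 100 cohorts of 14 trios
  at `genome_length = 1e7` with $\mu = 9.13\times10^{-9}$, 60X depth and
  error 0.001, and thins the background heterozygosity to
  `pi_true = 0.002`. The background only supplies inert segregating
  sites at these depths (parents carrying the alternate are excluded
  from candidacy and callability by the same rules at any $\pi$), so the
  estimator's behaviour is unchanged while each cohort simulates in a
  few seconds; the per-cohort bootstrap uses 2,000 resamples. At these
  settings each offspring carries on average
  $2 L \mu \approx 0.18$ true DNMs, so a cohort averages only ~2.6 DNM
  instances — the sparse-count regime discussed above, in which a
  noticeable minority of cohorts validate zero DNMs and their [0, 0]
  intervals cannot cover the truth. Nominal 95% coverage is therefore
  not attainable at this problem size regardless of implementation, a
  limitation of the study conditions rather than of the estimator; the
  grand mean across cohorts remains unbiased.
- The FNR spike-ins in the recovery study use 50,000 draws
  (Monte-Carlo standard error ≈ 0.15 percentage points) and callability
  sampling uses 20,000 positions per trio.

## Population-size layer

$\pi$ is estimated from called parental genotypes by unbiased sample
heterozygosity — per site $2p(1-p)\,m/(m-1)$ over the $m$ sampled
alleles, averaged over all assayed sites — rather than from genotype
likelihoods; at 60X simulated depth genotype error is negligible, which
is precisely where the two approaches agree. Multi-allelic sites are
excluded with a reported count. Equilibrium $N_e$ is the exact ratio
$\pi/(4\mu)$. Trajectory summaries take harmonic means (the
drift-relevant average, dominated by minima) over coalescent-scale
windows and arithmetic means over recent LD-based windows; generation
time scaling of trajectory time axes is left to the caller (the
motivating taxon uses 2 years per generation).

Census sizes follow the survey-bootstrap design: per monitored year, the
mean reef-level density and a 95% interval from 500 bootstrap
pseudo-samples of the reef roster, all scaled by the habitat area
(default 14,199 km²); across years, harmonic means of the annual 2.5th
and 97.5th percentile series give the long-run $N_c$ bounds. Manta-tow
counts convert to densities through a linear regression whose
coefficients must be calibrated per survey programme — the built-in
coefficients are a documented placeholder (identity through the origin)
— with optional prediction noise that shrinks with the number of tows.

## Known limitations

- Single-nucleotide DNMs only; indels and structural variants are out of
  scope, as are parental-age effects (no parental ages are modelled).
- The curation stage is a proxy battery, not a substitute for inspecting
  alignments in real data.
- The unlinked-sites simulation makes phasing easier than on real reads;
  phasing accuracy on simulated cohorts is an upper bound.
- $N_e$ trajectory inference itself (coalescent or LD-based) is consumed
  as tables, never re-implemented.
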