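---
title: "Detecting selective sweeps from two-population genotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps from two-population genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altisweep)
```

## The problem

When a population colonises a new environment — here, the canonical example is
grey wolves adapting to high-altitude hypoxia on the Qinghai-Tibet plateau —
positive selection at an adaptive locus drags linked variation to fixation.
Two genome-wide signatures result: nucleotide diversity drops locally in the
selected (highland) population, and allele frequencies at the locus diverge
between the selected and the unselected (lowland) population. `altisweep`
implements a windowed scan that joins the two signatures, plus the quality
control, candidate filtering, association and linkage-disequilibrium steps
that turn outlier windows into individual candidate SNPs.

The cohort design the package targets is a small number of diploid genomes in
four subpopulations mapping onto two altitude classes: Tibet and Qinghai
(highland) versus Xinjiang and Inner Mongolia (lowland). The default scheme is
nine samples (2 + 2 highland, 2 + 3 lowland); a 35-sample panel layout is
available through `default_samples(panel = TRUE)`.

## The scan statistics

Within overlapping windows of 100 kb advanced in 20-kb steps (defaults in
`scan_config()`), two statistics are computed from sites that pass both mask
layers and are genotyped in **all** samples:

* **F_ST** — the Weir–Cockerham (1984) variance-component estimator. Per site
  the among-population component $a$ and within-population components $b$, $c$
  are computed from the two classes' allele frequencies, diploid sample sizes
  and observed heterozygosities; the window estimate is the *ratio of
  averages* $\sum a / \sum (a+b+c)$. Sites monomorphic across both classes are
  skipped; a window whose denominator is zero is ineligible. A fixed
  difference between the classes yields $F_{ST} = 1$ for any sample sizes.
* **θπ ratio** — per-population nucleotide diversity is the unbiased pairwise
  estimator $2k(n-k)/(n(n-1))$ summed over segregating sites and divided by
  the window's *callable* positions (all reference positions minus
  genome-level exclusions such as CpG sites), so invariant sequence
  participates in the denominator. The window ratio defaults to
  $\theta_\pi^{low} / \theta_\pi^{high}$ so that its upper tail marks
  diversity **loss** in the highland class. Published figures sometimes
  print the symbols the other way round while applying an upper-tail rule
  that only makes sense for low/high; both orientations are supported
  (`ratio_orientation`) and the default is low/high. The package documents
  this as its own choice, not as a claim about any particular figure's
  intent. Windows whose denominator diversity is zero are ineligible rather
  than infinite, keeping the percentile transform finite; their count is
  reported.

Each statistic is turned into an empirical percentile (average rank / N ×
100, ascending, ties share a value). The per-window product of the two
percentiles is re-ranked to the **joint percentile**; windows in the top 5%
of the joint percentile are outlier windows (`outlier_mode =
"joint_product"`). A marginal-intersection mode (top tail in both statistics
separately) is provided because the two rules are both in circulation; the
joint product is the default. The minimal F_ST and ratio among flagged
windows are reported as the *implied marginal thresholds*, the quantities a
study would print as "windows with F_ST > x and ratio > y".

Outlier windows within 200 kb of each other are merged, with the intervening
sequence, into outlier regions (inclusive at exactly 200 kb); genes overlap a
region with ≥ 1 bp of their span. `sweep_scan()` packages the whole
computation as a fitted object with `print()`, `summary()` and `plot()`
methods.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_size` | 100,000 | bp | window width |
| `step` | 20,000 | bp | window increment |
| `top_fraction` | 0.05 | — | outlier tail on the joint percentile |
| `secondary_fraction` | 0.01 | — | stricter tail, reported only |
| `merge_gap` | 200,000 | bp | max gap joined into one region |
| `min_callable_sites` | 10% of window | positions | eligibility floor |

`min_callable_sites` has no single established convention; 10% of the window
keeps sparsely callable windows out of the ranking denominator while not
discarding moderately masked ones. Windows failing it carry no percentile
fields and are excluded from all ranking denominators.

## Quality control

`apply_filters()` is a declarative two-layer chain mirroring the usual
genome-filter / sample-filter split: genome-level stages mark whole sites
(CpG-dinucleotide exclusion — both the C and the G are flagged, and the
positions are removed from callable totals — and per-site missingness),
sample-level stages mark individual genotypes (depth and genotype-quality
bounds, active only when the matrix carries DP/GQ). Published pipelines often
leave the numeric thresholds of such filters in supplementary protocols; the
chain therefore exposes named stages without inventing default thresholds
beyond CpG and missingness. Filtering is idempotent and reports per-stage
removal counts.

Per-sample heterozygosity is the ratio of passing heterozygous calls to *all*
passing sites — variant and invariant alike — which is why the container
tracks callable totals. Ti/Tv counts a site once per sample carrying the
alternative allele (transitions A↔G, C↔T); ~2.3 is the expected mammalian
genome-wide value and serves as a call-quality anchor. Genotype concordance
is per genotype class over sites non-missing in both call sets. The
ancestry screen flags a sample as admixed when it carries < 90% of the
diagnostic alleles at ancestry-informative markers.

## Candidate SNPs, association, LD

The highland genotype pattern is the fixed-difference configuration expected
under a completed sweep with Qinghai intermediate: Tibet all homozygous
alternative, Qinghai heterozygous or homozygous alternative, lowland
homozygous reference — with ≥ 3 lowland hom-ref and no lowland hom-alt in
scan mode, or all lowland hom-ref in strict (re-sequencing) mode. Missing
genotypes never satisfy a requirement. Strict hits are a subset of scan hits
by construction.

Association per site is the allelic Pearson chi-square (2 alleles per
diploid, no continuity correction, 1 df) on the highland-vs-lowland 2×2
table; genotype tables and an optional Fisher exact p accompany it because
small cohorts often have expected counts below 5. LD r² is available three
ways: direct phased haplotype counting, EM estimation of two-locus haplotype
frequencies from unphased genotypes (double heterozygotes apportioned each
step; fixed point to 1e-10 or 1000 iterations), and the composite
genotype-dosage correlation. When no double heterozygote is present, phase is
unambiguous and EM reproduces phased counting exactly. Pruning follows the
standard 50-SNP/5-step/r² > 0.2 sliding rule; because the published setting
does not say which SNP of a violating pair to drop, the package removes the
lower-minor-allele-frequency member (tie: later position) and audits the
result. Complete-LD groups are connected components over edges with
r² ≥ 1 − 1e-9; with missing data r² = 1 is not transitive, so components are
reported as computed.

## Variant effects, catalogs, enrichment

`classify_effect()` does a strand-aware codon lookup against the reference
and the transcript's CDS intervals: synonymous/nonsynonymous inside CDS (with
`S214T`-style amino-acid naming, standard genetic code), 5'/3' UTR inside
exons outside CDS, intron within the transcript span, intergenic otherwise.
Across overlapping transcripts the worst consequence wins (nonsynonymous >
synonymous > UTR > intron) so every SNP receives exactly one category.

Catalog deduplication merges genes from two annotation sources when spans
overlap and either names match (case-insensitive, version suffixes stripped —
an exact rule chosen because string-similarity thresholds are not
specifiable from the merged-catalog description) or some transcript pair
shares > 60% of its exons, counted against the transcript with fewer exons.
ORF intactness requires ATG, terminal stop, length ≡ 0 mod 3 and no internal
stop. Ortholog-alignment QC fails rows with > 10% gaps or < 60% identity to
the reference row; the gap threshold is a parameter because 10% and 15% both
appear in published descriptions of this filter.

Enrichment is a local hypergeometric upper tail per term with
Benjamini–Hochberg correction; a term is reported when it holds ≥ 5
*selected* genes (the "≥ 5" rule is ambiguous between selected and annotated
genes; selected matches how web-service result rows are filtered) and
corrected p ≤ 0.05.

## The simulator: what it emulates and what it does not

`simulate_cohort()` is an analytic, seedable generator — not a coalescent.
Sites are placed by a Poisson process; a shared ancestral alternative-allele
frequency is drawn Uniform(0.05, 0.95) per site, and each population's
frequency follows a Balding–Nichols Beta draw around it with F equal to the
`divergence` parameter (default 0.1, a typical subspecies-level value).
Because the within-population expected heterozygosity under that draw is
$2p(1-p)(1-F)$ and $E[2p(1-p)] = 0.365$ exactly for the uniform ancestral
law, the site density is $\theta / (0.365\,(1-F))$ per bp, so the cohort's
realized per-site heterozygosity targets `theta`. Genotypes are
Hardy–Weinberg within populations; mutations follow a Ti/Tv = 2.3 spectrum.

A sweep interval modifies the highland frequency deterministically: an
additive boost toward the alternative allele (`sweep_divergence_boost`,
default 0.3) followed by an analytic shrink of heterozygosity by
`sweep_diversity_factor` (default 0.05), moving the frequency toward its
nearest fixation boundary. With factor 1 and boost 0 the transformation is
the identity, giving a proper null. No quantitative sweep magnitude is
prescribed by the genome-scan literature the defaults emulate; the values
chosen produce the qualitative pattern such studies report (highland
diversity roughly halved genome-wide being the observed extreme, near-total
loss inside the swept interval) and were fixed once as the package's study
conditions. Planted causal SNPs overwrite genotypes at the sites nearest the
sweep centre with the highland pattern, so pattern-filter recovery is
testable against ground truth (`sim_truth`).

The simulator does **not** model linkage (sites are independent draws), so
haplotype-based statistics would see nothing; recombination maps, demographic
histories and background selection are likewise absent. Passing tests
therefore demonstrate the correctness of the windowed statistics, ranking and
filtering machinery under the stated frequency model — not calibration of the
scan's false-discovery behaviour on real, linked, demographically structured
genomes, where empirical-percentile outlierness is a ranking, not a test.

## Numerical choices and degenerate inputs

* F_ST and r² are computed in double precision; the fixed-difference limit is
  exact for balanced sample sizes and agrees to ~1e-16 otherwise.
* Percentiles use average ranks, so ties share values and a window set with
  all-equal statistics flags nothing (warned) rather than flagging
  everything.
* Ratio denominators of zero, empty genotype classes, zero transversions and
  samples with no genotyped markers all yield `NA` with a documented meaning,
  never silent zeros.
* EM initialises at linkage equilibrium; monomorphic sites are excluded from
  LD rather than given r² = 0.
* All internal coordinates are 0-based half-open; VCF is written 1-based,
  GFF3 1-based inclusive, BED 0-based half-open.

## Problem sizes used in the shipped checks

The test-suite study design is the default configuration itself: nine
diploids, one 20-Mb contig, θ = 0.001 (≈ 55,000–58,000 segregating sites),
one 300-kb sweep, ten replicate seeds — sizes at which a full
simulate-scan-filter cycle takes under a second and the suite's statistical
assertions (sweep-region overlap in ≥ 9/10 seeds, 100% planted-SNP recovery,
Ti/Tv within ±0.1 at ~100k sites) have comfortable margins. Oracle
comparisons run on hundreds of randomized miniature windows instead of full
genomes because the estimators are site-separable: agreement at 50 sites to
1e-12 implies agreement at genome scale.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)          # 20 Mb, nine samples, one 300-kb sweep
sim <- simulate_cohort(cfg)
scan <- sweep_scan(sim$matrix)
print(scan)
#> Two-population selective sweep scan
#>   windows: 996 (996 eligible, 0 ineligible)
#>   window 100 kb / step 20 kb, top fraction 0.05 (joint_product mode)
#>   outlier windows: 50; outlier regions: 14
#>   implied marginal thresholds: F_ST > 0.118, diversity ratio > 1.045
plot(scan)

# the planted 9.85-10.15 Mb sweep is covered by the top-scoring region
subset(scan$regions, start < 10150000 & end > 9850000)
#>   contig   start      end n_windows max_pct_joint
#> 7   chr1 9760000 10240000        20           100

# association at the three planted causal SNPs
key <- paste(sim$matrix$sites$contig, sim$matrix$sites$pos)
planted <- match(paste(sim$truth$causal_snps$contig,
                       sim$truth$causal_snps$pos), key)
association_table(sim$matrix, planted)
#>   contig      pos     chi2           p freq_alt_high freq_alt_low freq_diff
#> 1   chr1  9999796 10.81125 0.001008852         0.875          0.1     0.775
#> 2   chr1  9999842 10.81125 0.001008852         0.875          0.1     0.775
#> 3   chr1 10000083 10.81125 0.001008852         0.875          0.1     0.775
```

With only nine diploids the scan-mode pattern filter is permissive (hundreds
of genome-wide hits at this divergence); in practice its output is
intersected with outlier regions and an a-priori gene list, which is exactly
what `candidate_report()` does.

## Known limitations

* Unlinked-site simulation (above) — no haplotype structure, no LD decay.
* The filter chain carries no default depth/quality thresholds; users of real
  VCFs must supply their own.
* Effect classification handles biallelic SNPs only; indels and multiallelic
  records are dropped at VCF import.
* The external damaging-verdict consensus (`consensus_predictors()`) treats
  predictor outputs as opaque categorical codes; it does not run the
  predictors.
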