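---
title: "Methods: genome diversity analysis of resequenced variety panels"
author: "chickdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome diversity analysis of resequenced variety panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chickdiv)
```

## Scope

`chickdiv` reconstructs, as tested reusable code, the analysis stack used to
study temporal genome-diversity trends in panels of re-sequenced crop
varieties — the motivating system is chickpea (*Cicer arietinum*), a highly
selfing legume whose cultivated varieties split into the desi and kabuli
market types and are conventionally grouped into release-period cohorts
(RP1: released before 1993, RP2: 1993–2002, RP3: after 2002).  The stack
covers variant filtering and effect annotation, read-depth CNV and
presence/absence (PAV) calling, windowed diversity statistics with
selection-signature scans, population-structure inference, and LD /
haplotype-block analysis.  Every stage is validated against a synthetic
panel generator that plants known truth (mutations, sweeps, balancing
regions, CNVs, PAV dropouts, admixture proportions) and returns it as a
ledger.

## The synthetic panel generator

### Variant model

Sites are drawn per chromosome as a Poisson process with expectation
$\theta L a_1(2n)$, where $\theta$ is the pairwise-diversity rate per bp
(default 0.002), $L$ the chromosome length and
$a_1(n) = \sum_{i=1}^{n-1} 1/i$.  Each site receives an ancestral derived
count $i \in \{1, \dots, 2n-1\}$ with probability $\propto 1/i$ — the
standard neutral frequency spectrum.  With a single subpopulation the $i$
derived alleles are placed on haplotypes by exact assignment, so the
realized sample spectrum *is* the neutral spectrum and
$E[\pi] = E[\theta_w] = \theta$ holds exactly; this configuration is the
substrate for all neutrality calibrations.  With $K > 1$ subpopulations,
subpopulation frequencies follow a Balding–Nichols model
$p_k \sim \mathrm{Beta}\!\left(p_0 \tfrac{1-F}{F}, (1-p_0)\tfrac{1-F}{F}\right)$
around the ancestral frequency ($F$ = `divergence`, default 0.1), each
sample's ancestry vector is Dirichlet(`admix_alpha`, default 0.2), and
genotypes are binomial in the ancestry-weighted frequency.

Selfing is modelled as specified for the genotype path: a heterozygote is
collapsed to a random homozygote with probability equal to the selfing rate
(default 0.98, appropriate for chickpea).  This mechanism reproduces the
near-total homozygosity of a selfing panel and gives heterozygosity that
decreases monotonically in the selfing rate, but it *distorts the sampled
frequency spectrum*: a singleton carried by a heterozygote disappears with
probability $\approx s/2$, which depresses $\theta_w$ relative to $\pi$
and pushes Tajima's $D$ positive.  For that reason the neutral
calibrations (mean Tajima's $D$ within $\pm 0.3$ of zero; $\pi/\theta_w$
within $[0.9, 1.1]$) are run under the random-mating configuration
(`selfing = 0`, one subpopulation), where the estimators' textbook
expectations apply.  Passing those calibrations demonstrates correctness
of the statistics under the exchangeable-haplotype model — it does not
claim that a real selfing panel has $E[D] = 0$ (it does not).

### Planted features

*Sweeps* thin site density and multiply minor-allele counts by a factor
(panel-wide), or shrink one subpopulation's frequencies toward fixation
(subpopulation-specific) — the latter creates the joint high-FST /
high-$|\Delta\pi|$ signal targeted by the differentiation scan.
*Balancing regions* pull frequencies toward 0.5 with a configurable
strength.  *CNV events* multiply a sample's expected depth by the true
copy number (relative scale, 1 = reference state); *PAV dropouts* use a
multiplier of 0.05; planted insertion-type regions are at multiplier 0.05
for all samples except planted carriers.  Depth per 1-kb bin is
Poisson(mean depth × multiplier); per-site depths are drawn the same way.
Overlapping planted structural events within one sample are a
configuration error.

### Linkage

The default independent-site model generates no physical LD (only the
weak covariance induced by structure), which is appropriate for the
diversity, structure and filtering modules but makes LD decay and
haplotype blocks degenerate.  The optional founder-mosaic mode
(`linkage = list(n_founders, recomb_rate, hotspots)`) draws
`n_founders` founder haplotypes per subpopulation site-wise from the
subpopulation frequencies and builds each sampled haplotype as a mosaic
of founders, switching to a random founder between adjacent sites with
probability $1 - e^{-\rho \,\mathrm{gap}}$ (hotspot intervals add extra
intensity).  Selfing is realized as autozygosity: the second haplotype is
a copy of the first with probability `selfing`.  This yields $r^2$
decaying on the scale of $1/(2\rho)$ bp toward a background of order
$1/n_\mathrm{founders}$, which is all the LD module needs.  It is
deliberately not a recombination-explicit coalescent; long-range
haplotype sharing, mutation–recombination correlations and demography
are not represented.

### What the generator does not emulate

Real chromosome lengths and gene density, alignment and mapping
artifacts, GC-biased coverage, genotype-likelihood uncertainty, linked
selection outside the planted regions, and realistic demography.  Tests
passing on this generator validate the *estimators and calling rules*,
not the end-to-end behaviour on real short-read data.

## Variant filtering and annotation

The filtering cascade retains a site when (i) pooled depth across samples
lies inside the policy range, (ii) mean relative copy number — site depth
divided by the sample's genome-wide mean, averaged over samples — is at
most 1.5 (a repeat-region guard), (iii) the missing-genotype ratio is at
most 0.5, and (iv) the panel alternate-allele frequency is neither 0 nor
1.  The canonical pooled-depth range [78, 2500] was calibrated for a
129-sample panel at roughly 10× depth; `filter_policy()` keeps those
literal bounds when `n_samples == 129` and otherwise scales to
0.6×–20× of (n samples × mean depth), so the rule stays reproducible yet
usable on toy panels.  Filtering is idempotent and emits a per-site
reason ledger.

Genic context is exonic (inside any CDS), intronic (inside a gene span
but no CDS) or intergenic.  Coding effects translate the reference and
alternate codon with the standard nuclear code — silent if the amino acid
is unchanged, nonsense if the alternate codon gains a stop, missense
otherwise; reverse-strand genes use the reverse complement; indels are
`not-applicable` by construction.  dN/dS uses Nei–Gojobori site counting:
each codon position contributes the fraction of its three possible
changes that are synonymous; changes to a stop count as non-synonymous
unless the amino acid is preserved.  The ratio is
(non-synonymous substitutions / N sites) ÷ (synonymous substitutions /
S sites), with an NA sentinel when no synonymous substitution exists.
The group Venn partition assigns each site to the subset of cohorts in
which its alternate allele is observed among non-missing calls; the
$2^k - 1$ cell counts sum to the site total, the same conservation
property that underlies the cohort summary table.

## CNV calling

Depth bins are treated as Poisson counts.  Homogeneous initial windows
grow greedily left to right: a bin joins the current window while the
exact conditional test of equal Poisson rates
($x_1 \mid x_1 + x_2 \sim \mathrm{Binomial}(x_1 + x_2, t_1/(t_1+t_2))$)
is non-significant at `alpha` (default 0.01), Bonferroni-adjusted per
chromosome.  Adjacent windows are then merged under the same test in
exactly two passes.  Copy number is segment mean depth divided by the
sample's modal bin depth — the mode resists contamination of the
baseline by large CNVs, at the cost of ±1 jitter from Poisson mode ties
at desk-scale bin counts.  Only amplifications are reported (rounded
CN ≥ 2, i.e. estimated copy number above the reference state); adjacent
retained segments with equal rounded CN are merged.  Depth-loss segments
are deliberately left to the PAV module.  Two limiting behaviours are
worth noting: with `adjust = "none"` and `alpha` → 1 a bin joins only
when the exact test returns $p = 1$, so the track fragments to (nearly)
singleton bins; and a deterministic rescaling of a count track is no
longer Poisson, so segmentation boundaries may shift — the CN estimation
step itself is exactly scale-invariant.

## PAV and gene loss

A deletion-type region is absent in a sample when its mean depth is
strictly below 10% of that sample's genome-wide mean; an insertion-type
region is present when strictly above 50%.  Both thresholds are strict
inequalities, so a region at exactly 10% is present.  A group is flagged
for a region when strictly more than three of its samples carry the
region's variant state; groups of at most four samples can never be
flagged and trigger a warning.  A gene is lost in a sample when the
fraction of its span covered at depth ≥ 1 is below 10%; coverage is
approximated bin-wise (a bin counts as covered when its mean depth is at
least 1), since per-base depth is not modelled.  The cross-sample
absence spectrum reports genes lost in exactly 1, 2, 3 and more than 3
varieties.

## Diversity statistics and scans

Diploid genotypes are haploidized site-wise: a homozygote contributes two
identical haplotypes, a heterozygote one of each, missing genotypes are
dropped (pairwise deletion).  With $x$ alternate alleles among $m$
haplotypes, per-site diversity is the unbiased $x(m-x)/\binom{m}{2}$;
window $\pi$ sums this over sites and divides by the window length.
$\theta_w = S/(a_1(n) L)$ with $S$ the segregating-site count and $n$ the
rounded window-average haploid sample size.  Tajima's $D$ uses the
standard $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ normalization; Fu &
Li's $D^*$ is the no-outgroup, singleton-based statistic with the
corrected variance terms, a singleton being a segregating site at which
either allele is carried by exactly one haplotype.  Monomorphic windows
report $\pi = \theta_w = 0$ and NA for $D$ and $D^*$.  FST is Hudson's
estimator with within-group sampling correction, combined across sites
as a ratio of sums — the form robust to unequal sample sizes; windows
with zero denominator report NA.  Note that with frequencies *forced*
identical in two groups the correction makes the estimate slightly
negative, of order $-1/n$; its null expectation of zero applies to
random splits of one population.

The differentiation scan selects windows lying simultaneously in the top
`top_fraction` of the FST ranking and of the $|\Delta\pi|$ ranking
(default 0.05 each; with strongly correlated statistics the joint
selection spans roughly a few percent of the genome) and merges adjacent
selected windows.  The Tajima's-$D$ region scan flags the most extreme
`flag_quantile` (default 0.1) of windows in the requested direction,
merges contiguous flagged windows, discards regions shorter than
`min_span` (default 150 kb), and — under the default permutation method —
keeps a region only if its merged span exceeds what random placement of
the same flags produces (permutation null of the maximum run span,
BH-adjusted across candidate regions at $\alpha = 0.05$).  A per-window
empirical-rank test was rejected at the design stage: when a sweep spans
more than $\alpha$ of all windows, within-genome ranks can never clear a
BH threshold of 0.05, whereas run-length clustering separates genuine
regions from scattered tail windows under the same within-genome
permutation logic.

## Population structure

The genetic distance is allele-sharing: $d = 1 - \mathrm{IBS}$ with IBS
the mean shared-allele fraction over sites non-missing in both samples.
Neighbor-joining is the Saitou–Nei agglomeration with the standard
Q-criterion; a negative branch length is clamped to zero and transferred
to its sibling branch so the pair's summed length is preserved.  On any
additive matrix the generating tree is recovered exactly (tested by
Robinson–Foulds distance 0 and path-length agreement over random trees).
Trees are unrooted `ape::phylo` objects.

PCA centers each SNP and scales by $\sqrt{p(1-p)}$ (Patterson
normalization; missing genotypes mean-imputed), eigendecomposes the
sample covariance, and tests each leading eigenvalue against the
Tracy–Widom law with the effective-marker correction estimated from the
eigenvalue dispersion.  TW(1) tail probabilities use the shifted-gamma
moment-matching approximation (shape 46.446, scale 0.18605, shift
9.8480), accurate to about $2\times10^{-3}$ at the 5% point; the
conventional critical values 0.9793 (5%) and 2.0234 (1%) are tabulated.
A panel with no polymorphic SNP is rejected as an error.

Admixture proportions maximize the binomial likelihood
$g_{ij} \sim \mathrm{Binomial}(2, \sum_k q_{ik} f_{kj})$ by EM, with the
log-likelihood non-decreasing at every iteration, seeded random
restarts, a 10,000-iteration default cap and a tolerance-based stop.
$K = 1$ reduces to the closed form (F = observed frequencies).  By
default only SNPs with minor-allele frequency ≥ 0.05 enter the fit
(`min_maf`): under a neutral spectrum most sites are rare, carry almost
no ancestry information, and dominate both runtime and estimation error.
The binomial model assumes random mating within ancestral populations; a
selfing panel violates this (genotypes are mostly 0/2), which roughly
halves the effective information but leaves the ancestry fractions
identifiable — recovery error on the standard test conditions (24
samples, 3 subpopulations, divergence 0.25, Dirichlet(0.2) admixture,
~1,700 common SNPs) is a mean absolute Q error of about 0.04–0.08.

## Linkage disequilibrium

Haplotype frequencies for a site pair are obtained by composite counting:
every genotype pair except the double heterozygote resolves its two
haplotypes unambiguously; double heterozygotes split between the two
phases by a two-locus EM.  In a selfing panel double heterozygotes are
rare, so almost all pairs are exact counts.  $r^2 = D^2/(p_A q_A p_B q_B)$
and $D' = |D|/D_\mathrm{max}$.  The LD-decay profile is the mean $r^2$
per distance bin, smoothed by decreasing isotonic regression; the decay
distance is defined operationally as the midpoint of the first bin at
which the smoothed curve falls below half of its maximum — stated
explicitly because several incompatible decay criteria circulate in the
literature.  Haplotype blocks follow the D′ confidence-interval method:
the 90% interval of $|D'|$ is computed on a 101-point grid from the
haplotype-level likelihood (unambiguous counts plus the double-het
mixture term); a pair is strong LD when the interval lower bound is at
least 0.70 and the upper bound at least 0.98, strong recombination when
the upper bound is below 0.90, uninformative otherwise.  A block is a
SNP run whose outermost pair is strong LD and in which at least 95% of
informative pairs are strong LD; blocks are accepted greedily, longest
span first, without overlap, within a configurable maximum span.  Using
the haplotype-level likelihood (rather than a Hardy–Weinberg genotype
likelihood) is a deliberate choice for selfing panels, where genotype
frequencies are far from HWE.

## Cohort summaries and the pipeline

`build_summary()` produces the cohort × category table (SNPs and indels
split exonic/intronic/intergenic plus totals, CNV and PAV counts) for
the full panel, each market type and each release period, with the
additivity invariant — every total equals the sum of its categories —
enforced by construction and checkable with `check_additivity()`.  A
variant belongs to a cohort when its alternate allele is observed there;
this convention makes sub-cohort counts never exceed the panel's.  The
package ships the reference count table of a published 129-variety
chickpea panel (`chickpea_variant_counts()`,
`chickpea_indel_partition()`) as plain-text fixtures; the acceptance
suite verifies that the recomputed totals reproduce the printed totals
and the printed insertion percentage (51.14%) exactly.

`run_pipeline()` executes simulate → filter → annotate → cnv → pav →
stats → scan → structure → ld → report, writing TSV/VCF/GFF3/bedGraph
outputs and a JSON manifest.  All randomness derives from the
configuration seed, so reruns are byte-identical; a rerun regenerates
only the stages at or after the first missing output file.  The demo
configuration (two 200-kb chromosomes, 24 samples, one sweep, one
balancing region, two CNVs, two PAV dropouts, founder-mosaic linkage)
runs in about a minute on one core.

## Problem sizes and numerical choices

Test and acceptance workloads were sized for interactive use on a single
core: neutrality calibration uses 100 independent 1-Mb, 20-sample panels
(about one minute); planted-recovery suites use 10 seeds each of 250 kb –
2 Mb panels; the admixture benchmark is one 400-kb, 24-sample panel with
two EM restarts.  Numerical details: exact binomial tests are used for
all Poisson rate comparisons (no asymptotics); EM frequencies are clamped
to $[10^{-6}, 1-10^{-6}]$ and likelihood ratios guarded at $10^{-12}$;
allele-frequency boundary rounding in the admixture and genotype models
is clamped into $[0, 1]$; undefined statistics are NA sentinels, never
infinities; ties in the CNV modal depth resolve to the smallest mode;
and all interval arithmetic is 0-based half-open internally, converted
to 1-based only in VCF/GFF3 writers.

## Known limitations

The generator's calibration properties hold for the configurations
stated above, not for arbitrary parameter corners.  The CNV caller
targets amplifications of moderate length at ~10× depth; single-bin
events at low depth are below its detection floor by design.  The
Tracy–Widom approximation is a moment-matched surrogate, adequate for
screening axes, not for precise tail probabilities beyond the 0.1%
level.  Haplotype-block estimation is quadratic in SNPs per span and is
meant to be run on thinned or windowed panels.  The dN/dS summary counts
segregating sites, not fixed substitutions against an outgroup, so its
values are within-panel polymorphism ratios rather than divergence-based
rates.
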