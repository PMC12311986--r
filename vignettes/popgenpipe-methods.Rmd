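---
title: "Methods and design of the popgenpipe analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the popgenpipe analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popgenpipe implements the population-genomic toolkit used in conservation
genomics of small, fragmented populations: hard genotype filtering,
outgroup polarization, mutational-load quantification (additive load and
the R_xy frequency-ratio statistic), diversity and inbreeding statistics
(windowed pi, per-individual heterozygosity, runs of homozygosity, LD
decay), selection scans (Tajima's D, Weir–Cockerham FST, XP-EHH, and a
two-track candidate-window intersection), and individual-level structure
analysis (p-distance NJ trees with bootstrap, genotype PCA). A forward
Wright–Fisher simulator generates inputs with known truth for every
stage; the test suite is built on recovering that truth.

This vignette records the models, the parameter choices that matter, and
the design decisions taken where conventions differ between tools.

## Data model and coordinates

All stages share one container, the `genotype_matrix`: samples by sites,
with alternate-allele dosages in {0, 1, 2, NA}, optional per-genotype
depth, and optional phased haplotypes. VCF input and output are 1-based
inclusive; all internal windowing is 0-based half-open (a site at 1-based
position p belongs to window `floor((p-1)/w)`), and emitted tables
convert back to 1-based inclusive coordinates. Invariant sites are
carried with `ALT = "."` so diversity denominators can include
monomorphic sequence. Half-calls (`./1`) and genotypes referencing a
third allele are treated as missing — the conservative reading used by
common VCF filtering tools. Multiallelic records are flagged on input and
removed (not split) by the biallelic filter. Sites absent from the input
are never assumed invariant; windowed statistics report the number of
sites actually used so coverage gaps stay visible.

## Filtering

`apply_filters()` applies rules in a fixed order: indels, multiallelic
records, GATK-style INFO fail-expressions (e.g. `QD < 2.0`), site
quality, genotype depth masking, site missingness, excess observed
heterozygosity, minor-allele frequency. Depth masking precedes the
missingness evaluation because the upstream tools apply `--minDP` and
`--max-missing` in one pass; consequently filtering is idempotent and the
per-rule removal counts sum exactly to the number of sites removed. Two
named presets carry the parameter sets typical of the two stages of such
pipelines: `"genotyping"` (INFO hard filters, `--minDP 4`, `--minQ 70`,
biallelic SNPs only) and `"diversity"` (`--minDP 5`, `--minQ 30`,
`--max-missing 0.8`, observed heterozygosity at most 0.6). Whether such
published filter sets were composed or applied independently is usually
not stated; both presets are exposed and neither implies the other.
`max_missing` follows the VCFtools convention: it is the minimum fraction
of called genotypes, not the maximum missing fraction.

## Polarization

`infer_ancestral()` uses strict outgroup parsimony: a site is polarized
only when the outgroup genotype is homozygous for the reference or the
alternate allele; that allele becomes the ancestral state and ingroup
dosages are recoded to count derived alleles (`2 - dosage` where the
reference is derived). Outgroup-heterozygous, outgroup-missing and
multiallelic sites are dropped with per-site reasons rather than
majority-called, which avoids biased polarization at shared
polymorphisms. Maximum-likelihood ancestral-state inference with a
substitution-rate model is an alternative; parsimony was chosen because
its failure modes are explicit (the drop report) and because the
simulator can make it exact — its outgroup carries only ancestral states
at segregating sites. Outgroup private divergence sites, when simulated,
are deliberately mispolarized by parsimony exactly as they would be on
real data; they are monomorphic-derived in the ingroup and therefore
cancel from R_xy (their `f(1-f)` terms are zero), but users of the
additive load on real single-outgroup data should know they inflate all
samples equally.

## Mutational load and R_xy

Variants are stratified by consequence: nonsynonymous variants with a
SIFT score strictly below 0.05 are putatively deleterious, at or above
0.05 tolerated; synonymous variants pass through. The per-individual
additive load is `2 x (homozygous derived) + (heterozygous)` — each
derived allele counts once; missing genotypes contribute nothing.

R_xy compares cumulative cross-population frequency products over a
category C:

$$
\mathrm{Freq}_x = \sum_{i \in C} f_{ix} (1 - f_{iy}), \qquad
\mathrm{Freq}_y = \sum_{i \in C} f_{iy} (1 - f_{ix}), \qquad
R_{xy} = \mathrm{Freq}_x / \mathrm{Freq}_y,
$$

with `f = d/n` the derived-allele frequency among called alleles.
`R_xy = 1` means no frequency change; above 1, the category is
relatively enriched in population x. Three decisions were open:

* **Site set.** The default uses every category site with defined
  frequencies in both populations and the derived allele present in at
  least one of them — the form the printed sums require. A strict mode
  (`site_policy = "private"`) restricts to sites whose derived allele
  occurs in exactly one population, covering the stricter reading of
  "sites unique to each species".
* **Confidence interval.** A leave-one-block-out jackknife over 100
  contiguous genomic blocks (configurable), the standard for this
  statistic's lineage; the 95% interval is `rxy ± 1.96 SE_jack` on the
  ratio scale by default, with a log-scale option for ratios far from 1.
* **Per-individual comparisons.** Both Welch's t and the Mann–Whitney U
  test are exposed on the load comparison; either is defensible at these
  sample sizes and neither is privileged.

## Diversity and heterozygosity

Windowed pi uses the ratio-of-sums estimator: per site with `n_a`
reference and `n_b` alternate called alleles, mismatching pairs
`n_a n_b` over comparisons `C(n_a+n_b, 2)`; window pi is summed
mismatches over summed comparisons (10 kb nonoverlapping windows by
default). Invariant sites contribute comparisons only. Ratio-of-sums is
robust to missingness heterogeneity, unlike averaging per-site pi.
Per-individual heterozygosity follows the VCFtools `--het` conventions:
expected homozygosity per site is `1 - 2p(1-p) n/(n-1)` from all called
samples, and `F = (O_hom - E_hom)/(n_sites - E_hom)`. Because the
denominator for a "percent heterozygosity" is ambiguous in most reports
(called sites versus covered bp), the output carries counts so either
rate can be formed. Region stratification assigns each site one class
with precedence CDS > intron > intergenic (intron = inside a gene span
but not in any CDS), the three classes reported alongside the whole
genome in this literature.

## Runs of homozygosity

`detect_roh()` implements the PLINK-style sliding scan with the
parameter set tuned for low-density data: 50-SNP windows tolerating 2
heterozygous and 5 missing calls; a SNP is eligible when at least 5% of
covering windows pass; segments need 50 SNPs, 300 kb, at most 50 kb per
SNP on average, and no gap above 1000 kb. Two behaviors are unspecified
by the original tool's documentation and are fixed here, locked by an
independent exhaustive oracle in the tests: (1) only full windows count,
so chromosomes with fewer SNPs than the window yield no calls and edge
SNPs use the windows that do cover them; (2) eligible runs are split at
oversized gaps first, then trimmed to start and end on homozygous
non-missing calls, then checked against the thresholds. Fidelity is to
the stated parameter semantics, not bit-compatibility with any
implementation. `F_ROH` divides summed segment length by an explicit
`genome_length_bp` argument — assembly length versus callable length is
an analysis decision the caller must make consciously. Length classes
are half-open and lower-inclusive: [100, 500), [500, 1000), [1000, ∞) kb.

## Linkage disequilibrium

`composite_r2()` is the squared Pearson correlation of dosages over
jointly called samples — the phase-free composite form, appropriate for
unphased genotypes; a phased-haplotype r² is provided for simulator
cross-checks. The decay curve averages r² over all intra-chromosome
pairs within 500 kb, in 1 kb bins by default (both configurable; the
source pipelines do not state them), after screening sites at MAF > 0.05
and missingness < 10%. For unlinked sites the curve flattens at the
sampling floor, approximately `1/(n-1)` for n diploids. LD pruning
follows the `--indep-pairwise 50 5 0.2` greedy rule: within 50-SNP
windows stepped by 5, the later site of any pair with r² > 0.2 is
removed; deterministic in input order.

## Selection scans

**Tajima's D** per window: `S` segregating sites, mean pairwise
difference count `sum(n_a n_b / C(n, 2))`, Watterson's `S/a1`, and the
1989 normalizing constants. With missing data the window `n` is the
minimum called-allele count across used sites (conservative); sites with
fewer than 4 called alleles are excluded. Windows with `S = 0` are NA.
Because the variance normalization is an asymptotic fit, per-window D at
small S carries a small negative bias; the neutrality checks in the test
suite therefore use chromosome-scale windows where S is large.

**FST** is the Weir–Cockerham (1984) estimator: per-site variance
components a, b, c with the window estimate `sum(a)/sum(a+b+c)`;
per-site components are also emitted. It is exactly 1 on fixed
differences, symmetric under population swap, and unbiased around 0 for
samples of one pool (slightly negative values are expected and correct).

**XP-EHH**: at each core SNP, EHH(x) = `sum_h C(n_h,2)/C(N,2)` over
distinct extended haplotypes from the core to distance x, traced in both
directions until EHH < 0.05 (the standard truncation default; the
threshold is exposed) or the chromosome end; iHH is the trapezoid
integral over physical distance — no genetic map is assumed. The raw
score `ln(iHH_a/iHH_b)` is normalized genome-wide to zero mean and unit
variance; the per-window statistic is the maximum |normalized score|,
two-sided, in 50 kb nonoverlapping windows. Both the per-window
reduction (max versus mean) and the tail direction are conventions, not
published choices, and are config-exposed.

**Intersection**: the top 1% of windows per track by value, intersected
by at least 1 bp of genomic overlap, with genes joined from GFF3. The
function takes any two tracks, so a two-method consensus design
(e.g. a composite-likelihood scan crossed with XP-EHH) is representable
with whatever second track is available — here FST x XP-EHH.

## Trees and ordination

The p-distance between individuals is the allele-sharing distance
`sum |g_i - g_j| / (2 n_joint)`, missing data handled pairwise; the
triangle inequality is not guaranteed under heterogeneous missingness
and is not asserted. NJ agglomeration is delegated to `ape::nj`
(Studier–Keppler criterion); negative branch lengths are clamped to zero
and flagged. Bootstrap support resamples sites with replacement (100
replicates by default) and counts bipartition recovery; sites are put in
canonical (chrom, pos) order before resampling so supports do not depend
on input column order. PCA mean-imputes missing dosages per site,
centers by `2p` and scales by `sqrt(p(1-p))` (Patterson scaling,
optional), eigendecomposes the sample covariance, and fixes signs so
each component's largest-magnitude score is positive; monomorphic sites
are dropped as uninformative.

## The synthetic-data generator

The simulator is a forward diploid Wright–Fisher model in C++: an
ancestral population is burned in for 8N generations to mutation–drift
equilibrium, splits into two descendants with independent, possibly
time-varying sizes, per-generation binomial mutation under infinite
sites on a finite coordinate grid (re-mutation collisions are skipped
and counted), uniform recombination, and optional partial selfing to
produce inbred, ROH-rich individuals. A forward simulator was chosen
over a coalescent because planted tracts, selfing and arbitrary size
trajectories are then trivial to express; the price is desk scale
(N up to about 10^3, L up to about 10^6), which is all the tests need.

The default scenario mirrors the study system the pipeline targets: two
populations split from a common ancestor (N = 500), one through a
bottleneck (N = 50) with partial selfing (0.2) — low diversity, long
homozygous tracts — the other large (N = 300); ten sampled diploids per
population plus one outgroup individual. Because a real per-generation
mutation rate (about 1.1e-8 in these species) would leave a desk-scale
sequence monomorphic, mutation is scaled to `mu = 1e-6` with `L = 1e5`,
giving `theta = 4 N mu = 2e-3` — the order of magnitude of nucleotide
diversity observed in small wild ungulates — and all recovery
expectations are stated in terms of theta.

The outgroup is emitted homozygous-ancestral at every segregating site,
making parsimony polarization exact by construction, plus a Poisson
number of private divergence sites (suppressible with
`outgroup_divergence = 0`) for VCF realism. Direct samplers complement
the forward model where analytic truth is needed: `sample_from_freqs()`
draws genotypes from given frequencies with inbreeding F
(`P(het) = 2p(1-p)(1-F)`), `annotate_categories()` plants per-category
frequency multipliers so the true category-level R_xy is computable in
closed form before sampling, and `plant_roh()` writes homozygous tracts
of known extent. Simulated data are idealized in ways real data are
not: no genotyping error, no depth-dependent missingness, no reference
bias, free-floating category assignment independent of genomic position.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated models, not robustness to artifacts of real
sequencing.

## Problem sizes and numerical choices in the test suite

The suite checks exactness where exactness is possible (worked examples
against enumeration oracles, bit-identical ROH calls on 2,000-SNP
fixtures, byte-identical reruns under a fixed seed) and stochastic
recovery elsewhere, at sizes chosen to give the assertions comfortable
margins: pi recovery runs ten seeds of the full N = 500 / L = 1e5
equilibrium model (expected within 15% of theta on the 10-seed mean);
R_xy shift recovery uses 2,000 annotated sites and twenty seeds (within
3 jackknife SEs in at least 18); the planted-sweep check runs ten seeds
of a 500 kb chromosome with a 50 kb fixed haplotype (top-1% |XP-EHH|
window in at least 8). Tajima's-D neutrality is asserted on
chromosome-scale windows, where the estimator's small-S negative bias is
negligible. Jackknife pseudovalues that are non-finite (possible when a
block carries an entire frequency sum) are dropped with the block count
reported; the CI is NA if fewer than two remain.

## Known limitations

Strict-parsimony polarization drops outgroup-heterozygous sites rather
than modeling them. The additive load is the only load model (no
recessive or realized load). XP-EHH uses physical distance; in genomes
with strong recombination-rate variation a genetic map would change
window rankings. The ROH caller targets stated parameter semantics, not
bit-compatibility with PLINK's undocumented edge behaviors. The
simulator's infinite-sites approximation skips colliding mutations,
slightly deflating diversity at high `mu L`; collision counts are
reported in the truth ledger so this is auditable.
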