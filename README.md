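# popgenpipe

Conservation population genomics from multi-sample VCFs, for the common
setting of two closely related, recently diverged populations — one of
them small, bottlenecked and inbred — plus an outgroup individual.
The package is aimed at analysts who have genotypes (and optionally a
variant-effect annotation and a GFF3) and want the standard battery of
genome-health statistics as tested, scriptable R functions rather than a
chain of command-line tools: genotype filtering, allele polarization,
mutational load, diversity and inbreeding, linkage disequilibrium,
selection scans, and individual-level structure.

What it computes:

* **Filtering** — GATK-style INFO hard filters and VCFtools-style
  site/genotype screens (`--remove-indels --max-alleles 2 --minDP
  --minQ --max-missing`, excess-heterozygosity, MAF), with named presets
  and an auditable per-rule removal report; PLINK-style
  `--indep-pairwise` LD pruning.
* **Polarization** — strict outgroup parsimony assigning
  ancestral/derived states, with per-site drop reasons and derived-dosage
  recoding.
* **Mutational load** — per-individual additive load
  (2 × homozygous derived + heterozygous) per SIFT-based category
  (deleterious < 0.05, tolerated, synonymous), and the between-population
  frequency-ratio statistic

  R_xy = Σ<sub>i∈C</sub> f<sub>ix</sub>(1−f<sub>iy</sub>) / Σ<sub>i∈C</sub> f<sub>iy</sub>(1−f<sub>ix</sub>),

  with 95% confidence intervals from a leave-one-block-out jackknife
  over contiguous genomic blocks. R_xy > 1 means the category's derived
  alleles are relatively enriched in population x.
* **Diversity and inbreeding** — missing-data-aware windowed π
  (ratio of sums, invariant sites in the denominator, 10 kb windows),
  per-individual heterozygosity and method-of-moments F,
  region-stratified heterozygosity (CDS / intron / intergenic),
  PLINK-style run-of-homozygosity detection
  (`--homozyg-snp 50 --homozyg-kb 300 --homozyg-density 50
  --homozyg-gap 1000`, 50-SNP windows, het 2 / missing 5, threshold
  0.05), F_ROH and ROH length classes (100–500, 500–1000, >1000 kb).
* **LD** — composite (genotype) r² and distance-binned decay curves.
* **Selection scans** — windowed Tajima's D, Weir–Cockerham FST,
  XP-EHH (EHH traced to 0.05, trapezoid iHH, genome-normalized scores,
  50 kb windows), and the top-1% two-track candidate intersection with
  GFF3 gene joins.
* **Structure** — genotype p-distances, neighbor-joining trees with
  site-bootstrap support, genotype PCA with Patterson scaling.
* **Synthetic data** — a forward Wright–Fisher simulator (C++) with
  bottlenecks, selfing, an exact-parsimony outgroup, planted ROH tracts
  and planted per-category frequency shifts, so every estimator is
  tested against known truth.

## Worked example: recovering a planted load shift

Plant a deleterious-specific frequency shift (derived-allele frequencies
halved in population y), sample genotypes, polarize against the
outgroup, and estimate R_xy:

```r
library(popgenpipe)
set.seed(1)
p  <- runif(2000, 0.1, 0.9)
ac <- annotate_categories(p, p, shift = list(deleterious = c(1, 0.5)))
gm <- sample_from_freqs(ac$freqs_x, ac$freqs_y, 10, 10)
gm
#> genotype_matrix: 21 samples x 2000 sites
#>   contigs: chr1
#>   invariant sites: 0 | phased: FALSE | depth: FALSE
#>   populations: outgroup (n=1), popX (n=10), popY (n=10)

pm <- infer_ancestral(gm, "outgroup")
rxy(pm, ac$annotation, "popX", "popY", "deleterious", n_blocks = 50)
#> R_popX/popY [deleterious]: 3.7014 (95% CI 3.3965-4.0062)
#>   Freq_x = 146.4725, Freq_y = 39.5725 over 423 sites (0 excluded), 50 blocks

ac$truth[ac$truth$category == "deleterious", ]
#>      category n_sites   freq_x   freq_y      rxy
#> 3 deleterious     423 143.7813 41.03482 3.503886
```

The estimate (3.70, CI 3.40–4.01) brackets nothing but sampling noise
around the analytic truth (3.50) computed from the planted frequencies
before genotype sampling: deleterious derived alleles are ~3.5-fold
enriched in population x relative to y, exactly as planted. The same
shift shows up in the per-individual additive load:

```r
loads <- additive_load(pm, ac$annotation, categories = "deleterious")
aggregate(additive_load ~ substr(sample, 1, 1), data = loads, FUN = mean)
#>   substr(sample, 1, 1) additive_load
#> 1                    X         416.2
#> 2                    Y         202.4
```

An end-to-end demonstration — simulate two diverged populations, filter,
polarize, compute every statistic and write per-stage TSVs plus a
consolidated report — is one call (or `popgenpipe paper-pipeline` via
the script in `inst/scripts/`):

```r
run_pipeline(out_dir = "demo_out", seed = 42)
```

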