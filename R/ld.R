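#' Composite (genotype-based) linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of alternate-allele dosages across the
#' jointly called samples — the phase-free composite (Rogers-Huff) form,
#' appropriate for unphased genotypes. Symmetric in its arguments and
#' invariant to swapping allele labels at either site.
#'
#' @param dosages_a,dosages_b equal-length dosage vectors (0/1/2/NA).
#' @return r-squared in `[0, 1]`, or `NA` when fewer than two jointly
#'   called samples remain or either site is monomorphic among them.
#' @export
composite_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Phased-haplotype r-squared
#'
#' Classical haplotype-frequency r-squared from phased 0/1 haplotypes;
#' available for simulator cross-checks when phase is known.
#'
#' @param h_a,h_b equal-length 0/1 haplotype allele vectors.
#' @return r-squared, or `NA` if either site is monomorphic.
#' @export
haplotype_r2 <- function(h_a, h_b) {
  ok <- !is.na(h_a) & !is.na(h_b)
  a <- h_a[ok]; b <- h_b[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' LD decay curve
#'
#' Averages [composite_r2()] over all intra-chromosome site pairs within
#' `max_dist_bp`, binned by physical distance. Sites are pre-filtered on
#' minor-allele frequency and missingness (computed within the chosen
#' population).
#'
#' @param gm a variant-only [genotype_matrix()] with sorted positions.
#' @param population population label.
#' @param max_dist_bp maximum pair separation (default 500 kb).
#' @param bin_bp distance-bin width (default 1 kb); bins are half-open
#'   `[lo, hi)`.
#' @param maf_min retain sites with MAF strictly above this (default 0.05).
#' @param max_missing retain sites with missing-genotype fraction strictly
#'   below this (default 0.1).
#' @return object of class `ld_decay_curve`: data frame `dist_lo_bp`,
#'   `dist_hi_bp`, `mean_r2`, `n_pairs`; attributes `population`,
#'   `max_dist_bp`. Empty (with a warning) when no pair qualifies.
#' @export
ld_decay <- function(gm, population, max_dist_bp = 5e5, bin_bp = 1000,
                     maf_min = 0.05, max_missing = 0.1) {
  samp <- population_samples(gm, population)
  gm <- subset_samples(gm, samp)
  af <- alt_frequency(gm)
  maf <- pmin(af$freq, 1 - af$freq)
  miss <- colMeans(is.na(gm$dosage))
  keep <- !is.na(maf) & maf > maf_min & miss < max_missing
  gm <- subset_sites(gm, keep)

  n_bins <- ceiling(max_dist_bp / bin_bp)
  sum_r2 <- n_pairs <- numeric(n_bins)
  for (cc in unique(gm$chrom)) {
    idx <- which(gm$chrom == cc)
    pos <- gm$pos[idx]
    for (i in seq_along(idx)) {
      j <- i + 1L
      while (j <= length(idx) && pos[j] - pos[i] <= max_dist_bp) {
        r2 <- composite_r2(gm$dosage[, idx[i]], gm$dosage[, idx[j]])
        if (!is.na(r2)) {
          b <- min(n_bins, (pos[j] - pos[i]) %/% bin_bp + 1L)
          sum_r2[b] <- sum_r2[b] + r2
          n_pairs[b] <- n_pairs[b] + 1L
        }
        j <- j + 1L
      }
    }
  }
  if (sum(n_pairs) == 0) warning("no qualifying site pairs for LD decay")
  out <- data.frame(dist_lo_bp = (seq_len(n_bins) - 1L) * bin_bp,
                    dist_hi_bp = seq_len(n_bins) * bin_bp,
                    mean_r2 = ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_),
                    n_pairs = as.integer(n_pairs))
  structure(out, population = population, max_dist_bp = max_dist_bp,
            class = c("ld_decay_curve", "data.frame"))
}
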