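#' Polarize alleles against an outgroup individual
#'
#' Assigns ancestral/derived states by strict outgroup parsimony: a site is
#' polarized if and only if the outgroup genotype is homozygous for the
#' reference or the alternate allele; that allele is taken as ancestral.
#' Sites where the outgroup is missing or heterozygous are dropped with a
#' reason, as are multiallelic records (where a homozygous outgroup call
#' may involve a third allele the dosage coding cannot represent).
#' Likelihood-based ancestral-state models fitting a substitution-rate
#' matrix exist for this task; the parsimony rule used here is exact
#' whenever the outgroup lineage carries the ancestral allele, which the
#' package's simulator guarantees by construction, and its failure modes
#' are surfaced as per-site drop reasons rather than silent assignments.
#'
#' The returned derived-allele dosage counts derived alleles per ingroup
#' genotype: equal to the alternate dosage where the alternate allele is
#' derived, `2 - dosage` where the reference is derived; missing stays
#' missing. The outgroup sample is excluded from the ingroup matrix.
#'
#' @param gm a [genotype_matrix()] containing the outgroup sample.
#' @param outgroup_sample sample id of the outgroup individual.
#' @return an object of class `polarized_matrix`: list with `base` (the
#'   ingroup [genotype_matrix()] restricted to polarized sites),
#'   `derived_dosage` (samples x polarized sites), `derived_is_alt`,
#'   `ancestral` (allele strings), `dropped` (data frame `chrom`, `pos`,
#'   `reason`) and `outgroup_sample`.
#' @export
infer_ancestral <- function(gm, outgroup_sample) {
  if (!outgroup_sample %in% gm$samples)
    stop("outgroup sample not found: ", outgroup_sample)
  og <- gm$dosage[match(outgroup_sample, gm$samples), ]
  multi <- is_multiallelic(gm)
  reason <- rep(NA_character_, n_sites(gm))
  reason[multi] <- "outgroup_third_allele"
  reason[!multi & is.na(og)] <- "outgroup_missing"
  reason[!multi & !is.na(og) & og == 1L] <- "outgroup_het"
  keep <- is.na(reason)

  ingroup <- setdiff(gm$samples, outgroup_sample)
  base <- subset_samples(subset_sites(gm, keep), ingroup)
  derived_is_alt <- og[keep] == 0L
  dd <- base$dosage
  flip <- which(!derived_is_alt)
  if (length(flip)) dd[, flip] <- 2L - dd[, flip, drop = FALSE]
  ancestral <- ifelse(derived_is_alt, base$ref,
                      ifelse(base$alt == ".", base$ref, base$alt))
  dropped <- data.frame(chrom = gm$chrom[!keep], pos = gm$pos[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(base = base, derived_dosage = dd,
                 derived_is_alt = derived_is_alt, ancestral = ancestral,
                 dropped = dropped, outgroup_sample = outgroup_sample),
            class = "polarized_matrix")
}

#' @export
print.polarized_matrix <- function(x, ...) {
  cat("polarized_matrix:", nrow(x$derived_dosage), "ingroup samples x",
      ncol(x$derived_dosage), "polarized sites\n")
  cat("  outgroup:", x$outgroup_sample, "|",
      nrow(x$dropped), "sites dropped")
  if (nrow(x$dropped))
    cat(" (", paste(sprintf("%s: %d", names(table(x$dropped$reason)),
                            table(x$dropped$reason)), collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Per-site derived-allele frequency in one population
#'
#' For each polarized site, `f = d / n` where `d` is the number of derived
#' alleles and `n` the number of called alleles (two per called diploid
#' genotype) among the population's samples. Sites where every genotype is
#' missing are flagged undefined (`f = NA`) and excluded by downstream
#' consumers.
#'
#' @param pm a [infer_ancestral()] result.
#' @param population population label (looked up in the base matrix's
#'   population map).
#' @return data frame with `chrom`, `pos`, `d`, `n`, `f`, `defined`.
#' @export
derived_site_frequency <- function(pm, population) {
  samp <- population_samples(pm$base, population)
  dd <- pm$derived_dosage[match(samp, pm$base$samples), , drop = FALSE]
  n <- 2L * colSums(!is.na(dd))
  d <- colSums(dd, na.rm = TRUE)
  data.frame(chrom = pm$base$chrom, pos = pm$base$pos,
             d = d, n = n, f = ifelse(n > 0, d / n, NA_real_),
             defined = n > 0, row.names = NULL)
}

#' INFO strings recording the ancestral allele
#'
#' For serializing a polarized matrix back to VCF: per-site `AA=` tags to
#' pass as `extra_info` to [write_vcf()].
#'
#' @param pm a [infer_ancestral()] result.
#' @return character vector, one `AA=<allele>` string per polarized site.
#' @export
polarized_vcf_info <- function(pm) paste0("AA=", pm$ancestral)
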