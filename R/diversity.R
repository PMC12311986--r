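# Window assignment: internal windowing is 0-based half-open, i.e. site at
# 1-based position p falls in window floor((p-1)/w). Reported coordinates
# are 1-based inclusive.
window_index <- function(pos, window_bp) (pos - 1L) %/% as.integer(window_bp)

window_bounds <- function(chrom, widx, window_bp, contig_lengths = NULL) {
  start <- widx * window_bp + 1L
  end <- (widx + 1L) * window_bp
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[chrom]
    end <- ifelse(!is.na(len), pmin(end, as.integer(len)), end)
  }
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

new_window_track <- function(df, statistic) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, statistic = statistic,
            class = c("window_track", "data.frame"))
}

#' @export
print.window_track <- function(x, ...) {
  cat("window_track [", attr(x, "statistic"), "]: ", nrow(x), " windows, ",
      sum(!is.na(x$value)), " with defined values\n", sep = "")
  NextMethod()
}

#' Windowed nucleotide diversity with missing data and invariant sites
#'
#' Estimates pi in nonoverlapping windows as a ratio of sums: per site,
#' with `n_a` reference/ancestral and `n_b` alternate called alleles,
#' the site contributes `n_a * n_b` mismatching allele pairs and
#' `choose(n_a + n_b, 2)` comparisons; window pi is the summed mismatches
#' over summed comparisons. Invariant sites contribute comparisons only,
#' so uncalled or missing genotypes deflate the denominator instead of
#' biasing the estimate; windows with no comparisons get `NA`. Sites absent
#' from the input entirely are not assumed invariant — `n_sites_used`
#' makes coverage gaps visible.
#'
#' @param gm a [genotype_matrix()], ideally retaining invariant sites
#'   (all-sites VCF).
#' @param population population label; samples of that population are used.
#' @param window_bp window size in bp (default 10000, nonoverlapping).
#' @return a `window_track` data frame: `chrom`, `start`, `end` (1-based
#'   inclusive), `value`, `n_sites_used`, `n_comparisons`.
#' @export
windowed_pi <- function(gm, population, window_bp = 10000) {
  if (window_bp <= 0) stop("window_bp must be positive")
  samp <- population_samples(gm, population)
  d <- gm$dosage[match(samp, gm$samples), , drop = FALSE]
  n_called <- 2L * colSums(!is.na(d))
  n_b <- colSums(d, na.rm = TRUE)
  n_a <- n_called - n_b
  diffs <- as.numeric(n_a) * as.numeric(n_b)
  comps <- choose(n_called, 2)
  widx <- window_index(gm$pos, window_bp)
  key <- paste(gm$chrom, widx, sep = "\r")
  agg <- function(x) tapply(x, key, sum)
  sdiffs <- agg(diffs); scomps <- agg(comps)
  n_used <- tapply(n_called > 0, key, sum)
  parts <- strsplit(names(sdiffs), "\r", fixed = TRUE)
  chroms <- vapply(parts, `[`, character(1), 1)
  wi <- as.integer(vapply(parts, `[`, character(1), 2))
  wb <- window_bounds(chroms, wi, as.integer(window_bp), gm$contig_lengths)
  wb$value <- ifelse(scomps > 0, sdiffs / scomps, NA_real_)
  wb$n_sites_used <- as.integer(n_used)
  wb$n_comparisons <- as.numeric(scomps)
  new_window_track(wb, "pi")
}

#' Genome-wide pi from a window track
#'
#' Pools the per-window numerators and denominators (ratio of sums), which
#' is the same estimate as computing a single genome-sized window.
#'
#' @param track output of [windowed_pi()].
#' @return single numeric value.
#' @export
genome_pi <- function(track) {
  num <- sum(track$value * track$n_comparisons, na.rm = TRUE)
  den <- sum(track$n_comparisons[!is.na(track$value)])
  if (den == 0) return(NA_real_)
  num / den
}

#' Per-individual heterozygosity and inbreeding coefficient
#'
#' Per sample, over variant sites with a called genotype: observed
#' heterozygote and homozygote counts, expected homozygote count under
#' Hardy-Weinberg using per-site allele frequencies from all called
#' samples with the small-sample correction
#' `E[hom] = 1 - 2 p (1 - p) n / (n - 1)` (n = called alleles at the
#' site), and the method-of-moments inbreeding coefficient
#' `F = (obs_hom - exp_hom) / (n_called_sites - exp_hom)`.
#'
#' @param gm a variant-only [genotype_matrix()] (invariant sites are
#'   ignored with a message if present).
#' @return data frame per sample: `sample`, `n_het`, `n_called_sites`,
#'   `het_rate`, `observed_hom`, `expected_hom`, `f_stat`. Samples with no
#'   called genotypes get an NA row with a warning.
#' @export
individual_heterozygosity <- function(gm) {
  if (any(is_invariant(gm))) {
    message("ignoring ", sum(is_invariant(gm)), " invariant sites")
    gm <- subset_sites(gm, !is_invariant(gm))
  }
  d <- gm$dosage
  af <- alt_frequency(gm)
  n <- af$n_called
  p <- af$freq
  exp_hom_site <- ifelse(n >= 2, 1 - 2 * p * (1 - p) * n / (n - 1), NA_real_)
  called <- !is.na(d)
  usable <- called & rep(n >= 2, each = nrow(d))
  n_called_sites <- rowSums(usable)
  n_het <- rowSums(d == 1L & usable, na.rm = TRUE)
  obs_hom <- n_called_sites - n_het
  exp_hom <- as.vector(usable %*% ifelse(is.na(exp_hom_site), 0, exp_hom_site))
  out <- data.frame(
    sample = gm$samples, n_het = n_het, n_called_sites = n_called_sites,
    het_rate = ifelse(n_called_sites > 0, n_het / n_called_sites, NA_real_),
    observed_hom = obs_hom, expected_hom = exp_hom,
    f_stat = ifelse(n_called_sites > exp_hom,
                    (obs_hom - exp_hom) / (n_called_sites - exp_hom), NA_real_),
    row.names = NULL)
  if (any(out$n_called_sites == 0))
    warning("sample(s) with zero called sites: ",
            paste(out$sample[out$n_called_sites == 0], collapse = ", "))
  out
}

#' Read gene/CDS regions from a GFF3 file
#' @param path GFF3 path.
#' @return list of two `GRanges`: `cds` and `gene`.
#' @export
read_gff_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  list(cds = gr[gr$type == "CDS"],
       gene = gr[gr$type %in% c("gene", "mRNA")])
}

#' Heterozygosity stratified by genomic region class
#'
#' Assigns every site one class with precedence CDS > intron > intergenic
#' (intron = inside a gene span but not in any CDS) and reports
#' per-sample heterozygote rates per class, plus the whole-genome rate.
#'
#' @param gm a variant-only [genotype_matrix()].
#' @param gff GFF3 path or the list returned by [read_gff_regions()].
#' @return data frame: `sample`, `region`, `n_het`, `n_called_sites`,
#'   `het_rate`. Classes with zero sites give NA rows with a warning.
#' @export
region_stratified_het <- function(gm, gff) {
  if (is.character(gff)) gff <- read_gff_regions(gff)
  sites <- GenomicRanges::GRanges(gm$chrom, IRanges::IRanges(gm$pos, gm$pos))
  in_cds <- IRanges::overlapsAny(sites, gff$cds)
  in_gene <- IRanges::overlapsAny(sites, gff$gene)
  region <- ifelse(in_cds, "CDS", ifelse(in_gene, "intron", "intergenic"))
  d <- gm$dosage
  one_class <- function(name, idx) {
    if (!length(idx)) {
      warning("no sites in region class: ", name)
      return(data.frame(sample = gm$samples, region = name, n_het = NA_integer_,
                        n_called_sites = NA_integer_, het_rate = NA_real_))
    }
    dd <- d[, idx, drop = FALSE]
    nc <- rowSums(!is.na(dd))
    nh <- rowSums(dd == 1L, na.rm = TRUE)
    data.frame(sample = gm$samples, region = name, n_het = nh,
               n_called_sites = nc,
               het_rate = ifelse(nc > 0, nh / nc, NA_real_))
  }
  out <- rbind(
    one_class("whole_genome", seq_len(n_sites(gm))),
    one_class("CDS", which(region == "CDS")),
    one_class("intron", which(region == "intron")),
    one_class("intergenic", which(region == "intergenic")))
  rownames(out) <- NULL
  out
}
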