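#' Genotype matrix container
#'
#' The central data structure shared by all pipeline stages: an ordered set of
#' biallelic (or invariant) sites with per-sample alternate-allele dosages,
#' optional per-genotype read depth, and optional phased haplotypes.
#'
#' Dosage codes count copies of the alternate allele: 0 (hom ref), 1 (het),
#' 2 (hom alt), `NA` (missing). Invariant sites carry `alt = "."` and can only
#' hold dosage 0 or `NA`. Coordinates are 1-based inclusive, matching VCF;
#' all internal windowing converts to 0-based half-open.
#'
#' @param dosage integer matrix, samples in rows, sites in columns.
#' @param chrom,pos,ref,alt per-site vectors (length = number of columns).
#'   `alt = "."` marks an invariant site; a comma in `alt` marks a
#'   multiallelic record (kept on input, removed by [apply_filters()]).
#' @param samples sample identifiers; default `rownames(dosage)`.
#' @param populations named character vector mapping sample to population
#'   label; may be `NULL` until a population-aware stage needs it.
#' @param qual numeric site quality (VCF QUAL), `NA` allowed.
#' @param info optional data frame of per-site numeric INFO values
#'   (e.g. QD, MQ, FS), one row per site.
#' @param depth optional integer matrix of per-genotype read depth,
#'   same shape as `dosage`.
#' @param hap1,hap2 optional 0/1 matrices of phased alleles, same shape as
#'   `dosage`; where present, `hap1 + hap2` must equal `dosage`.
#' @param contig_lengths optional named numeric vector of contig lengths
#'   (used when writing VCF headers and by windowed statistics).
#'
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref, alt,
                            samples = rownames(dosage),
                            populations = NULL,
                            qual = NULL, info = NULL, depth = NULL,
                            hap1 = NULL, hap2 = NULL,
                            contig_lengths = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n_site <- ncol(dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  stopifnot(length(chrom) == n_site, length(pos) == n_site,
            length(ref) == n_site, length(alt) == n_site,
            length(samples) == nrow(dosage))
  if (any(pos < 1, na.rm = TRUE)) stop("site positions must be >= 1")
  alt <- as.character(alt)
  alt[is.na(alt) | alt == ""] <- "."
  inv <- alt == "."
  bad <- !inv & alt == ref
  if (any(bad)) stop("alt equal to ref at variant site(s): ",
                     paste(head(which(bad)), collapse = ", "))
  if (any(dosage[, inv, drop = FALSE] %in% c(1L, 2L)))
    stop("invariant sites must have dosage 0 or missing")
  if (!is.null(hap1)) {
    stopifnot(!is.null(hap2), all(dim(hap1) == dim(dosage)),
              all(dim(hap2) == dim(dosage)))
    storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
    s <- hap1 + hap2
    if (any(s != dosage, na.rm = TRUE))
      stop("haplotype pair sums disagree with dosage")
  }
  if (!is.null(populations)) populations <- check_populations(populations, samples)
  if (is.null(qual)) qual <- rep(NA_real_, n_site)
  dimnames(dosage) <- list(samples, NULL)
  if (!is.null(depth)) dimnames(depth) <- list(samples, NULL)
  if (!is.null(hap1)) {
    dimnames(hap1) <- list(samples, NULL)
    dimnames(hap2) <- list(samples, NULL)
  }
  gm <- structure(list(
    samples = samples, populations = populations,
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = alt,
    qual = as.numeric(qual), info = info,
    dosage = dosage, depth = depth, hap1 = hap1, hap2 = hap2,
    contig_lengths = contig_lengths), class = "genotype_matrix")
  gm
}

check_populations <- function(populations, samples) {
  if (is.data.frame(populations)) {
    populations <- stats::setNames(as.character(populations[[2]]),
                                   as.character(populations[[1]]))
  }
  extra <- setdiff(names(populations), samples)
  if (length(extra))
    stop("population map names sample(s) absent from the data: ",
         paste(extra, collapse = ", "))
  missing_pop <- setdiff(samples, names(populations))
  if (length(missing_pop))
    stop("samples missing from population map: ",
         paste(missing_pop, collapse = ", "))
  populations[samples]
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      length(x$pos), "sites\n")
  cat("  contigs:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("  invariant sites:", sum(is_invariant(x)),
      "| phased:", !is.null(x$hap1),
      "| depth:", !is.null(x$depth), "\n")
  if (!is.null(x$populations))
    cat("  populations:", paste(sprintf("%s (n=%d)",
        names(table(x$populations)), table(x$populations)), collapse = ", "), "\n")
  invisible(x)
}

#' Site and sample accessors / subsetting
#'
#' @param gm a [genotype_matrix()].
#' @return `n_sites()`/`n_samples()` return counts; `is_invariant()` and
#'   `is_multiallelic()` logical per-site vectors; `subset_sites()` and
#'   `subset_samples()` new `genotype_matrix` objects.
#' @export
n_sites <- function(gm) length(gm$pos)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_sites
#' @export
is_invariant <- function(gm) gm$alt == "."

#' @rdname n_sites
#' @export
is_multiallelic <- function(gm) grepl(",", gm$alt, fixed = TRUE)

#' @rdname n_sites
#' @param idx integer or logical index over sites.
#' @export
subset_sites <- function(gm, idx) {
  gm$chrom <- gm$chrom[idx]; gm$pos <- gm$pos[idx]
  gm$ref <- gm$ref[idx]; gm$alt <- gm$alt[idx]; gm$qual <- gm$qual[idx]
  if (!is.null(gm$info)) gm$info <- gm$info[idx, , drop = FALSE]
  gm$dosage <- gm$dosage[, idx, drop = FALSE]
  for (f in c("depth", "hap1", "hap2"))
    if (!is.null(gm[[f]])) gm[[f]] <- gm[[f]][, idx, drop = FALSE]
  gm
}

#' @rdname n_sites
#' @param keep sample ids (or index) to retain.
#' @export
subset_samples <- function(gm, keep) {
  if (is.character(keep)) {
    missing_s <- setdiff(keep, gm$samples)
    if (length(missing_s)) stop("unknown sample(s): ",
                                paste(missing_s, collapse = ", "))
    keep <- match(keep, gm$samples)
  }
  gm$samples <- gm$samples[keep]
  if (!is.null(gm$populations)) gm$populations <- gm$populations[keep]
  gm$dosage <- gm$dosage[keep, , drop = FALSE]
  for (f in c("depth", "hap1", "hap2"))
    if (!is.null(gm[[f]])) gm[[f]] <- gm[[f]][keep, , drop = FALSE]
  gm
}

#' Samples belonging to one population
#' @param gm a [genotype_matrix()].
#' @param population population label to look up.
#' @return character vector of sample ids.
#' @export
population_samples <- function(gm, population) {
  if (is.null(gm$populations)) stop("genotype matrix carries no population map")
  s <- gm$samples[gm$populations == population]
  if (!length(s)) stop("unknown or empty population: ", population)
  s
}

#' Per-site alternate allele frequency
#'
#' Frequency of the alternate allele among called (non-missing) genotypes.
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional subset of samples to use.
#' @return list with `freq` (NA where no genotype is called), `n_called`
#'   (called allele count, 2 per called diploid genotype) and `n_alt`.
#' @export
alt_frequency <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[match(samples, gm$samples), , drop = FALSE]
  n_called <- 2L * colSums(!is.na(d))
  n_alt <- colSums(d, na.rm = TRUE)
  list(freq = ifelse(n_called > 0, n_alt / n_called, NA_real_),
       n_called = n_called, n_alt = n_alt)
}
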