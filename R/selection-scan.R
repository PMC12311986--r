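#' Tajima (1989) normalizing constants
#' @param n number of sampled alleles (>= 2).
#' @return named list `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Per window: `S` segregating sites among used sites, mean pairwise
#' difference count `pi_hat = sum n_a n_b / choose(n_s, 2)` (each site with
#' its own called-allele count `n_s`), Watterson's `theta_W = S / a1`, and
#' `D = (pi_hat - theta_W) / sqrt(e1 S + e2 S (S - 1))` with the constants
#' of [tajima_constants()]. With missing data the window's `n` for the
#' constants is the minimum called-allele count across used sites
#' (conservative); `per_site_n = TRUE` instead averages constants weighted
#' per site is not offered — sites with fewer than 4 called alleles are
#' excluded. Windows with `S = 0` get `NA`.
#'
#' @param gm a variant-only [genotype_matrix()].
#' @param population population label.
#' @param window_bp nonoverlapping window size (default 50 kb, matching
#'   the cross-population scan grid).
#' @param min_alleles minimum called alleles for a site to be used
#'   (default 4).
#' @return a `window_track` (`value` = D, `n_sites_used` = S).
#' @export
tajimas_d <- function(gm, population, window_bp = 50000, min_alleles = 4) {
  samp <- population_samples(gm, population)
  if (length(samp) < 2) stop("need at least two samples")
  d <- gm$dosage[match(samp, gm$samples), , drop = FALSE]
  n_called <- 2L * colSums(!is.na(d))
  n_b <- colSums(d, na.rm = TRUE)
  n_a <- n_called - n_b
  used <- n_called >= min_alleles & !is_invariant(gm)
  widx <- window_index(gm$pos, window_bp)
  key <- paste(gm$chrom, widx, sep = "\r")
  ukeys <- unique(key)
  rows <- lapply(ukeys, function(k) {
    i <- which(key == k & used)
    if (!length(i)) return(c(NA_real_, 0L))
    seg <- n_a[i] > 0 & n_b[i] > 0
    S <- sum(seg)
    if (S == 0) return(c(NA_real_, 0L))
    pi_hat <- sum(n_a[i] * n_b[i] / choose(n_called[i], 2))
    n <- min(n_called[i])
    k_ <- tajima_constants(n)
    theta_w <- S / k_$a1
    v <- k_$e1 * S + k_$e2 * S * (S - 1)
    c((pi_hat - theta_w) / sqrt(v), S)
  })
  vals <- do.call(rbind, rows)
  parts <- strsplit(ukeys, "\r", fixed = TRUE)
  wb <- window_bounds(vapply(parts, `[`, character(1), 1),
                      as.integer(vapply(parts, `[`, character(1), 2)),
                      as.integer(window_bp), gm$contig_lengths)
  wb$value <- vals[, 1]
  wb$n_sites_used <- as.integer(vals[, 2])
  wb$n_comparisons <- NA_real_
  new_window_track(wb, "tajimas_d")
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# n1, n2: called individuals; p1, p2: alt-allele frequencies; h1, h2:
# observed heterozygote frequencies. Returns cbind(a, b, c).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  nc <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- n_bar / nc *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  cbind(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST
#'
#' Per-site variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) following
#' Weir and Cockerham's 1984 estimator; the window estimate is the ratio
#' of sums `sum(a) / sum(a + b + c)`. Sites need at least one called
#' individual in each population and three overall.
#'
#' @param gm a variant-only [genotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @param window_bp nonoverlapping window size (default 50 kb).
#' @return a `window_track` (`value` = FST); per-site components in
#'   `attr(, "per_site")`.
#' @export
wc_fst <- function(gm, pop_a, pop_b, window_bp = 50000) {
  da <- gm$dosage[match(population_samples(gm, pop_a), gm$samples), , drop = FALSE]
  db <- gm$dosage[match(population_samples(gm, pop_b), gm$samples), , drop = FALSE]
  n1 <- colSums(!is.na(da)); n2 <- colSums(!is.na(db))
  p1 <- ifelse(n1 > 0, colSums(da, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(db, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(da == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(db == 1L, na.rm = TRUE) / n2, NA_real_)
  usable <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3 & !is_invariant(gm)
  comp <- matrix(NA_real_, n_sites(gm), 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  comp[usable, ] <- wc_components(n1[usable], p1[usable], h1[usable],
                                  n2[usable], p2[usable], h2[usable])
  widx <- window_index(gm$pos, window_bp)
  key <- paste(gm$chrom, widx, sep = "\r")
  ukeys <- unique(key)
  rows <- vapply(ukeys, function(k) {
    i <- which(key == k & usable)
    if (!length(i)) return(c(NA_real_, 0))
    num <- sum(comp[i, "a"])
    den <- sum(comp[i, ])
    c(if (den > 0) num / den else NA_real_, length(i))
  }, numeric(2))
  parts <- strsplit(ukeys, "\r", fixed = TRUE)
  wb <- window_bounds(vapply(parts, `[`, character(1), 1),
                      as.integer(vapply(parts, `[`, character(1), 2)),
                      as.integer(window_bp), gm$contig_lengths)
  wb$value <- rows[1, ]
  wb$n_sites_used <- as.integer(rows[2, ])
  wb$n_comparisons <- NA_real_
  tr <- new_window_track(wb, "wc_fst")
  attr(tr, "per_site") <- data.frame(chrom = gm$chrom, pos = gm$pos, comp)
  tr
}

#' Build phased haplotype sets for the cross-population haplotype scan
#'
#' Extracts the phased 0/1 haplotypes of two populations, keeping only
#' sites where every haplotype of both populations is present (no missing
#' alleles) and the site is variant.
#'
#' @param gm a phased [genotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @return object of class `haplotype_set`: per-chromosome list with
#'   `pos` and matrices `a`, `b` (haplotypes x sites).
#' @export
haplotype_set <- function(gm, pop_a, pop_b) {
  if (is.null(gm$hap1)) stop("genotype matrix carries no phased haplotypes")
  ia <- match(population_samples(gm, pop_a), gm$samples)
  ib <- match(population_samples(gm, pop_b), gm$samples)
  ha <- rbind(gm$hap1[ia, , drop = FALSE], gm$hap2[ia, , drop = FALSE])
  hb <- rbind(gm$hap1[ib, , drop = FALSE], gm$hap2[ib, , drop = FALSE])
  ok <- colSums(is.na(ha)) == 0 & colSums(is.na(hb)) == 0 & !is_invariant(gm)
  chroms <- unique(gm$chrom)
  out <- lapply(chroms, function(cc) {
    i <- which(ok & gm$chrom == cc)
    if (is.unsorted(gm$pos[i])) stop("positions not sorted on ", cc)
    list(pos = gm$pos[i], a = ha[, i, drop = FALSE], b = hb[, i, drop = FALSE])
  })
  names(out) <- chroms
  structure(out, pop_a = pop_a, pop_b = pop_b,
            contig_lengths = gm$contig_lengths, class = "haplotype_set")
}

# EHH decay from a core outward in one direction.
# h: haplotype matrix (N x S for this chromosome); core: core site index;
# dir: +1 right / -1 left. Returns list(pos_idx, ehh) for traced sites
# starting at the core.
ehh_trace <- function(h, core, dir, min_ehh) {
  n <- nrow(h)
  denom <- choose(n, 2)
  cls <- match(h[, core], unique(h[, core]))
  ehh <- sum(choose(tabulate(cls), 2)) / denom
  idx <- core
  vals <- ehh
  j <- core + dir
  while (ehh >= min_ehh && j >= 1 && j <= ncol(h)) {
    cls <- cls * 2L + h[, j]
    cls <- match(cls, unique(cls))
    ehh <- sum(choose(tabulate(cls), 2)) / denom
    idx <- c(idx, j); vals <- c(vals, ehh)
    j <- j + dir
  }
  list(idx = idx, ehh = vals)
}

# Trapezoid integral of EHH over physical distance in one direction,
# truncated after the first point below min_ehh (its trapezoid included).
ihh_one_side <- function(h, pos, core, dir, min_ehh) {
  tr <- ehh_trace(h, core, dir, min_ehh)
  if (length(tr$idx) < 2) return(0)
  x <- abs(pos[tr$idx] - pos[core])
  sum(diff(x) * (utils::head(tr$ehh, -1) + utils::tail(tr$ehh, -1)) / 2)
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' At each core SNP the extended-haplotype homozygosity
#' `EHH(x) = sum_h choose(n_h, 2) / choose(N, 2)` (classes h are distinct
#' haplotypes over the sites from the core to distance x) is traced in
#' both directions until it falls below `min_ehh` or the chromosome ends;
#' `iHH` is the trapezoid integral of EHH over physical distance, summed
#' over directions. The raw score is `ln(iHH_a / iHH_b)`, normalized
#' genome-wide to zero mean and unit variance. The per-window statistic is
#' the maximum absolute normalized score (two-sided); cores where either
#' integral is zero are skipped and counted.
#'
#' @param haps a [haplotype_set()] (or a phased [genotype_matrix()], in
#'   which case `pop_a`/`pop_b` must be given).
#' @param pop_a,pop_b population labels when `haps` is a genotype matrix.
#' @param min_ehh EHH truncation threshold (default 0.05).
#' @param window_bp nonoverlapping window size (default 50 kb).
#' @return a `window_track` (`value` = max |normalized score|); per-core
#'   scores in `attr(, "scores")`, skipped-core count in
#'   `attr(, "n_skipped")`.
#' @export
xpehh <- function(haps, pop_a = NULL, pop_b = NULL, min_ehh = 0.05,
                  window_bp = 50000) {
  if (inherits(haps, "genotype_matrix"))
    haps <- haplotype_set(haps, pop_a, pop_b)
  scores <- list()
  n_skipped <- 0L
  for (cc in names(haps)) {
    hs <- haps[[cc]]
    s <- length(hs$pos)
    if (s == 0) next
    if (nrow(hs$a) < 4 || nrow(hs$b) < 4)
      stop("need at least 4 haplotypes per population")
    raw <- rep(NA_real_, s)
    for (core in seq_len(s)) {
      ia <- ihh_one_side(hs$a, hs$pos, core, +1L, min_ehh) +
            ihh_one_side(hs$a, hs$pos, core, -1L, min_ehh)
      ib <- ihh_one_side(hs$b, hs$pos, core, +1L, min_ehh) +
            ihh_one_side(hs$b, hs$pos, core, -1L, min_ehh)
      if (ia == 0 || ib == 0) { n_skipped <- n_skipped + 1L; next }
      raw[core] <- log(ia / ib)
    }
    scores[[cc]] <- data.frame(chrom = cc, pos = hs$pos, raw = raw)
  }
  sc <- do.call(rbind, scores)
  ok <- !is.na(sc$raw)
  mu <- mean(sc$raw[ok]); sdv <- stats::sd(sc$raw[ok])
  sc$norm <- (sc$raw - mu) / sdv
  widx <- window_index(sc$pos, window_bp)
  key <- paste(sc$chrom, widx, sep = "\r")
  ukeys <- unique(key)
  rows <- vapply(ukeys, function(k) {
    i <- which(key == k & ok)
    if (!length(i)) return(c(NA_real_, 0))
    c(max(abs(sc$norm[i])), length(i))
  }, numeric(2))
  parts <- strsplit(ukeys, "\r", fixed = TRUE)
  wb <- window_bounds(vapply(parts, `[`, character(1), 1),
                      as.integer(vapply(parts, `[`, character(1), 2)),
                      as.integer(window_bp), attr(haps, "contig_lengths"))
  wb$value <- rows[1, ]
  wb$n_sites_used <- as.integer(rows[2, ])
  wb$n_comparisons <- NA_real_
  tr <- new_window_track(wb, "xpehh")
  attr(tr, "scores") <- sc
  attr(tr, "n_skipped") <- n_skipped
  tr
}

#' Intersect the top windows of two selection-scan tracks
#'
#' Takes the top-`quantile` windows of each track by value (NA windows
#' excluded), intersects them by genomic overlap of at least 1 bp, and
#' optionally lists genes overlapping the intersection. Any pair of tracks
#' may be supplied — e.g. an FST track against an XP-EHH track — so a
#' two-method consensus design is reproduced regardless of which scans
#' produced the tracks.
#'
#' @param track_a,track_b `window_track` objects on the same genome.
#' @param quantile upper tail fraction (default 0.01 = top 1%).
#' @param gene_annotation optional `GRanges` of genes (or the list from
#'   [read_gff_regions()], whose `gene` element is used).
#' @return object of class `candidate_regions`: list with `windows_a`,
#'   `windows_b` (top sets), `intersection` (overlap intervals) and
#'   `genes` (character vector, possibly empty).
#' @export
top_intersect <- function(track_a, track_b, quantile = 0.01,
                          gene_annotation = NULL) {
  stopifnot(quantile > 0, quantile < 1)
  if (!nrow(track_a) || !nrow(track_b)) stop("empty window track")
  top_set <- function(tr) {
    v <- tr$value
    if (all(is.na(v))) stop("window track has no defined values")
    thr <- stats::quantile(v, 1 - quantile, na.rm = TRUE, names = FALSE)
    tr[!is.na(v) & v >= thr, , drop = FALSE]
  }
  wa <- top_set(track_a); wb <- top_set(track_b)
  ga <- GenomicRanges::GRanges(wa$chrom, IRanges::IRanges(wa$start, wa$end))
  gb <- GenomicRanges::GRanges(wb$chrom, IRanges::IRanges(wb$start, wb$end))
  ov <- GenomicRanges::findOverlaps(ga, gb)
  inter <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(ov)],
                                     gb[S4Vectors::subjectHits(ov)])
  inter <- GenomicRanges::reduce(inter)
  genes <- character(0)
  if (!is.null(gene_annotation) && length(inter)) {
    gr <- if (is.list(gene_annotation) && !methods::is(gene_annotation, "GRanges"))
      gene_annotation$gene else gene_annotation
    hit <- gr[IRanges::overlapsAny(gr, inter)]
    nm <- if (!is.null(hit$Name)) hit$Name else if (!is.null(hit$ID)) hit$ID
          else as.character(seq_along(hit))
    genes <- unique(stats::na.omit(nm))
  }
  structure(list(
    windows_a = wa, windows_b = wb,
    intersection = if (length(inter)) data.frame(
      chrom = as.character(GenomicRanges::seqnames(inter)),
      start = GenomicRanges::start(inter),
      end = GenomicRanges::end(inter)) else
        data.frame(chrom = character(0), start = integer(0), end = integer(0)),
    genes = genes, quantile = quantile,
    track_a = attr(track_a, "statistic"), track_b = attr(track_b, "statistic")),
    class = "candidate_regions")
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat(sprintf("candidate_regions: top %.1f%% of %s (%d windows) x %s (%d windows)\n",
              100 * x$quantile, x$track_a, nrow(x$windows_a),
              x$track_b, nrow(x$windows_b)))
  cat("  intersection:", nrow(x$intersection), "region(s);",
      length(x$genes), "gene(s)\n")
  invisible(x)
}
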