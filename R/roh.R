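#' Parameters for run-of-homozygosity detection
#'
#' Defaults are the sliding-window parameter set tuned for low-density SNP
#' data: segments need at least 50 SNPs and 300 kb, at most one SNP per
#' 50 kb on average, no inter-SNP gap above 1000 kb; the scanning window is
#' 50 SNPs wide, tolerates 2 heterozygous and 5 missing calls, and a SNP is
#' eligible when at least 5% of the windows covering it pass.
#'
#' @param min_snps_in_segment,min_length_kb,min_density_kb_per_snp,max_gap_kb
#'   segment-level thresholds.
#' @param window_snps,window_max_het,window_max_missing,window_hit_threshold
#'   scanning-window settings.
#' @return object of class `roh_params`.
#' @export
roh_params <- function(min_snps_in_segment = 50, min_length_kb = 300,
                       min_density_kb_per_snp = 50, max_gap_kb = 1000,
                       window_snps = 50, window_max_het = 2,
                       window_max_missing = 5, window_hit_threshold = 0.05) {
  p <- list(min_snps_in_segment = min_snps_in_segment,
            min_length_kb = min_length_kb,
            min_density_kb_per_snp = min_density_kb_per_snp,
            max_gap_kb = max_gap_kb, window_snps = window_snps,
            window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            window_hit_threshold = window_hit_threshold)
  if (any(unlist(p) <= 0)) stop("all ROH parameters must be positive")
  if (p$window_hit_threshold > 1) stop("window_hit_threshold must be in (0, 1]")
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan per sample and chromosome. A window of
#' `window_snps` consecutive SNPs passes when it contains at most
#' `window_max_het` heterozygous and `window_max_missing` missing calls.
#' Each SNP's hit fraction is the share of passing windows among the full
#' windows covering it; SNPs with fraction at or above
#' `window_hit_threshold` are eligible. Maximal runs of eligible SNPs are
#' split wherever the gap between adjacent SNPs exceeds `max_gap_kb`, then
#' trimmed so they start and end on homozygous non-missing calls, and kept
#' if they satisfy the SNP-count, length and density thresholds.
#' Chromosomes with fewer SNPs than `window_snps` have no full windows and
#' yield no calls. Edge SNPs are covered by fewer full windows; only full
#' windows are used.
#'
#' @param gm a variant-only [genotype_matrix()] with per-chromosome sorted
#'   positions.
#' @param samples samples to scan (default all).
#' @param params a [roh_params()].
#' @return data frame of segments: `sample`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`.
#' @export
detect_roh <- function(gm, samples = NULL, params = roh_params()) {
  if (is.null(samples)) samples <- gm$samples
  out <- list()
  for (cc in unique(gm$chrom)) {
    idx <- which(gm$chrom == cc)
    pos <- gm$pos[idx]
    if (is.unsorted(pos, strictly = FALSE))
      stop("positions not sorted on chromosome ", cc)
    for (s in samples) {
      g <- gm$dosage[match(s, gm$samples), idx]
      segs <- roh_scan_one(g, pos, params)
      if (nrow(segs)) {
        segs$sample <- s; segs$chrom <- cc
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_bp = integer(0)))
  res <- do.call(rbind, out)
  res[, c("sample", "chrom", "start_bp", "end_bp", "n_snps", "length_bp")]
}

roh_scan_one <- function(g, pos, p) {
  empty <- data.frame(start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_bp = integer(0))
  s <- length(g); w <- p$window_snps
  if (s < w) return(empty)
  is_het <- !is.na(g) & g == 1L
  is_mis <- is.na(g)
  ch <- c(0, cumsum(is_het)); cm <- c(0, cumsum(is_mis))
  n_win <- s - w + 1L
  st <- seq_len(n_win)
  pass <- (ch[st + w] - ch[st]) <= p$window_max_het &
          (cm[st + w] - cm[st]) <= p$window_max_missing
  cp <- c(0, cumsum(pass))
  j <- seq_len(s)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, n_win)
  frac <- (cp[hi + 1L] - cp[lo]) / (hi - lo + 1L)
  eligible <- frac >= p$window_hit_threshold

  runs <- rle_runs(eligible)
  segs <- list()
  for (k in seq_len(nrow(runs))) {
    piece_idx <- runs$start[k]:runs$end[k]
    gaps <- diff(pos[piece_idx])
    cut_after <- which(gaps > p$max_gap_kb * 1000)
    bounds <- c(0, cut_after, length(piece_idx))
    for (b in seq_len(length(bounds) - 1L)) {
      part <- piece_idx[(bounds[b] + 1L):bounds[b + 1L]]
      hom <- !is.na(g[part]) & g[part] != 1L
      if (!any(hom)) next
      part <- part[min(which(hom)):max(which(hom))]
      n_snps <- length(part)
      len <- pos[part[n_snps]] - pos[part[1L]] + 1L
      if (n_snps >= p$min_snps_in_segment &&
          len >= p$min_length_kb * 1000 &&
          len / n_snps <= p$min_density_kb_per_snp * 1000)
        segs[[length(segs) + 1L]] <- data.frame(
          start_bp = pos[part[1L]], end_bp = pos[part[n_snps]],
          n_snps = n_snps, length_bp = as.integer(len))
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Genomic fraction in runs of homozygosity (F_ROH)
#'
#' @param segments output of [detect_roh()].
#' @param genome_length_bp denominator length in bp. Whether this should be
#'   the assembly length or the callable length is an analysis decision;
#'   it is therefore a required explicit argument.
#' @param samples samples to report (default: those present in `segments`).
#' @return data frame `sample`, `n_segments`, `total_bp`, `f_roh`.
#' @export
froh <- function(segments, genome_length_bp, samples = NULL) {
  if (genome_length_bp <= 0) stop("genome_length_bp must be positive")
  if (is.null(samples)) samples <- unique(segments$sample)
  out <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s, ]
    for (cc in unique(seg$chrom)) {
      sc <- seg[seg$chrom == cc, ]
      sc <- sc[order(sc$start_bp), ]
      if (nrow(sc) > 1 && any(sc$start_bp[-1] <= sc$end_bp[-nrow(sc)]))
        stop("overlapping ROH segments for sample ", s, " on ", cc)
    }
    data.frame(sample = s, n_segments = nrow(seg),
               total_bp = sum(as.numeric(seg$length_bp)),
               f_roh = sum(as.numeric(seg$length_bp)) / genome_length_bp)
  })
  do.call(rbind, out)
}

#' Bin ROH segments into length classes
#'
#' Classes are half-open and lower-inclusive in kb: `[100, 500)`,
#' `[500, 1000)`, `[1000, Inf)`. Segments below 100 kb (impossible under
#' the default 300 kb minimum) are reported as `unclassed`.
#'
#' @param segments output of [detect_roh()].
#' @return data frame `sample`, `class`, `n`, `total_bp`.
#' @export
bin_roh_lengths <- function(segments) {
  kb <- segments$length_bp / 1000
  cls <- cut(kb, breaks = c(-Inf, 100, 500, 1000, Inf), right = FALSE,
             labels = c("unclassed", "100-500kb", "500-1000kb", ">1000kb"))
  out <- expand.grid(sample = unique(segments$sample),
                     class = levels(cls), stringsAsFactors = FALSE)
  out$n <- mapply(function(s, cl)
    sum(segments$sample == s & cls == cl), out$sample, out$class)
  out$total_bp <- mapply(function(s, cl)
    sum(as.numeric(segments$length_bp[segments$sample == s & cls == cl])),
    out$sample, out$class)
  out[out$class != "unclassed" | out$n > 0, ]
}
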