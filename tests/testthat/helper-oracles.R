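# Independent brute-force oracles. These deliberately re-derive each
# statistic from first principles (explicit enumeration, no shared code
# with the package internals).

# Nucleotide diversity by exhaustive allele-pair enumeration.
oracle_pi <- function(dosage) {
  total_diff <- 0; total_pairs <- 0
  for (j in seq_len(ncol(dosage))) {
    g <- dosage[, j]
    alleles <- unlist(lapply(g[!is.na(g)], function(d) switch(d + 1,
      c(0L, 0L), c(0L, 1L), c(1L, 1L))))
    n <- length(alleles)
    if (n < 2) next
    pr <- utils::combn(n, 2)
    total_diff <- total_diff +
      sum(alleles[pr[1, ]] != alleles[pr[2, ]])
    total_pairs <- total_pairs + ncol(pr)
  }
  if (total_pairs == 0) return(NA_real_)
  total_diff / total_pairs
}

# ROH scan re-implemented naively with explicit loops, following the same
# documented rule order (full windows only; eligibility by hit fraction;
# runs split at gaps, trimmed to homozygous ends, then thresholded).
oracle_roh <- function(g, pos, p) {
  s <- length(g); w <- p$window_snps
  segs <- data.frame(start_bp = integer(0), end_bp = integer(0),
                     n_snps = integer(0), length_bp = integer(0))
  if (s < w) return(segs)
  pass <- logical(s - w + 1)
  for (st in seq_len(s - w + 1)) {
    win <- g[st:(st + w - 1)]
    pass[st] <- sum(win == 1, na.rm = TRUE) <= p$window_max_het &&
      sum(is.na(win)) <= p$window_max_missing
  }
  eligible <- logical(s)
  for (j in seq_len(s)) {
    cover <- intersect(seq_len(s - w + 1), (j - w + 1):j)
    eligible[j] <- mean(pass[cover]) >= p$window_hit_threshold
  }
  j <- 1
  while (j <= s) {
    if (!eligible[j]) { j <- j + 1; next }
    k <- j
    while (k < s && eligible[k + 1]) k <- k + 1
    run <- j:k
    # split at gaps
    pieces <- list(); cur <- run[1]
    for (q in run[-1]) {
      if (pos[q] - pos[cur[length(cur)]] > p$max_gap_kb * 1000) {
        pieces[[length(pieces) + 1]] <- cur; cur <- q
      } else cur <- c(cur, q)
    }
    pieces[[length(pieces) + 1]] <- cur
    for (piece in pieces) {
      hom <- which(!is.na(g[piece]) & g[piece] != 1)
      if (!length(hom)) next
      piece <- piece[min(hom):max(hom)]
      n_snps <- length(piece)
      len <- pos[piece[n_snps]] - pos[piece[1]] + 1
      if (n_snps >= p$min_snps_in_segment &&
          len >= p$min_length_kb * 1000 &&
          len / n_snps <= p$min_density_kb_per_snp * 1000)
        segs <- rbind(segs, data.frame(start_bp = pos[piece[1]],
                                       end_bp = pos[piece[n_snps]],
                                       n_snps = n_snps,
                                       length_bp = as.integer(len)))
    }
    j <- k + 1
  }
  segs
}

# Tajima's D from haplotype rows: pairwise-difference enumeration for
# pi-hat, constants computed inline from their published definitions.
oracle_tajima_from_haps <- function(haps) {
  n <- nrow(haps)
  seg <- apply(haps, 2, function(x) length(unique(x)) > 1)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pr <- utils::combn(n, 2)
  pi_hat <- mean(apply(pr, 2, function(ij)
    sum(haps[ij[1], ] != haps[ij[2], ])))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# EHH at a fixed extension by explicit haplotype-string class counting.
oracle_ehh <- function(haps, cols) {
  cls <- apply(haps[, cols, drop = FALSE], 1, paste, collapse = "")
  n <- nrow(haps)
  sum(choose(table(cls), 2)) / choose(n, 2)
}

# Greedy LD pruning by brute force on one window covering all sites.
oracle_prune_window <- function(dosage, r2_max) {
  removed <- logical(ncol(dosage))
  for (i in seq_len(ncol(dosage) - 1)) {
    if (removed[i]) next
    for (j in (i + 1):ncol(dosage)) {
      if (removed[j]) next
      r2 <- suppressWarnings(stats::cor(dosage[, i], dosage[, j],
                                        use = "pairwise")^2)
      if (!is.na(r2) && r2 > r2_max) removed[j] <- TRUE
    }
  }
  which(!removed)
}
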