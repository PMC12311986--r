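#' Pairwise p-distance matrix from genotypes
#'
#' Allele-sharing distance between individuals:
#' `d(i, j) = sum |g_i - g_j| / (2 * n_jointly_called)`, with sites where
#' either genotype is missing excluded pairwise. Bounded in `[0, 1]`,
#' symmetric with zero diagonal; the triangle inequality is not guaranteed
#' under heterogeneous missingness.
#'
#' @param gm a variant-only [genotype_matrix()].
#' @return object of class `p_distance_matrix`: list with `labels`, `d`
#'   (symmetric matrix) and `n_sites_used` (pairwise counts).
#' @export
p_distance <- function(gm) {
  m <- n_samples(gm)
  d <- matrix(0, m, m, dimnames = list(gm$samples, gm$samples))
  nu <- matrix(0L, m, m, dimnames = list(gm$samples, gm$samples))
  g <- gm$dosage
  for (i in seq_len(m)) {
    nu[i, i] <- sum(!is.na(g[i, ]))
    for (j in seq_len(m)) {
      if (j <= i) next
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      n <- sum(ok)
      if (n == 0) stop("no jointly called sites for pair ",
                       gm$samples[i], " / ", gm$samples[j])
      d[i, j] <- d[j, i] <- sum(abs(g[i, ok] - g[j, ok])) / (2 * n)
      nu[i, j] <- nu[j, i] <- n
    }
  }
  structure(list(labels = gm$samples, d = d, n_sites_used = nu),
            class = "p_distance_matrix")
}

#' Write a distance matrix in square PHYLIP format
#' @param dm a [p_distance()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$labels)), con)
  for (i in seq_along(dm$labels))
    writeLines(paste(c(formatC(dm$labels[i], width = -10),
                       sprintf("%.6f", dm$d[i, ])), collapse = " "), con)
  invisible(path)
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler criterion, as implemented in
#' `ape`). Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to zero and flagged via the `clamped` attribute.
#'
#' @param dm a [p_distance()] result or a symmetric numeric matrix.
#' @return an `ape` `phylo` tree (unrooted).
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "p_distance_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("need at least 3 labels")
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix not symmetric")
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- sum(neg)
  tree
}

#' Bootstrap support for the NJ tree
#'
#' Resamples sites with replacement, recomputes the p-distance matrix and
#' NJ tree per replicate, and reports for each internal edge of the
#' original tree the percentage of replicates containing the same
#' bipartition. Supports are invariant to input site order.
#'
#' @param gm a variant-only [genotype_matrix()].
#' @param n_reps number of replicates (default 100).
#' @param seed optional RNG seed.
#' @return the original tree with `node.label` set to supports in
#'   `[0, 100]` (root label empty).
#' @export
bootstrap_support <- function(gm, n_reps = 100, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  # canonical site order so resampling ignores input column order
  gm <- subset_sites(gm, order(gm$chrom, gm$pos))
  main <- nj_tree(p_distance(gm))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n_sites(gm), n_sites(gm), replace = TRUE)
    reps[[r]] <- nj_tree(p_distance(subset_sites(gm, idx)))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / n_reps, 1)
  main
}

#' Principal component analysis of genotype dosages
#'
#' Missing dosages are mean-imputed per site; sites are centered by twice
#' the alternate-allele frequency and, under the default Patterson
#' scaling, divided by `sqrt(p (1 - p))`. Scores come from the
#' eigendecomposition of the sample covariance of the standardized matrix.
#' Sign convention: the largest-magnitude loading of each component is
#' positive. Monomorphic sites are dropped (they carry no information and
#' have zero scale).
#'
#' @param gm a variant-only, MAF-filtered [genotype_matrix()].
#' @param n_components number of components (default
#'   `min(samples - 1, 10)`).
#' @param scaling `"patterson"` (default) or `"none"`.
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions) and `scaling`.
#' @export
pca_genotypes <- function(gm, n_components = NULL,
                          scaling = c("patterson", "none")) {
  scaling <- match.arg(scaling)
  m <- n_samples(gm)
  g <- gm$dosage
  p <- alt_frequency(gm)$freq
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  if (is.null(n_components)) n_components <- min(m - 1L, 10L)
  if (n_components > min(m - 1L, ncol(g)))
    stop("n_components exceeds min(samples - 1, sites)")
  for (j in seq_len(ncol(g)))
    g[is.na(g[, j]), j] <- 2 * p[j]
  x <- sweep(g, 2, 2 * p)
  if (scaling == "patterson")
    x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  cv <- stats::cov(t(x))
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(n_components), drop = FALSE]
  scores <- sweep(scores, 2, sqrt(ev[seq_len(n_components)] * (m - 1)), "*")
  for (k in seq_len(n_components)) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- gm$samples
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores, explained = ev / sum(ev), scaling = scaling)
}
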