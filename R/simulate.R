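#' Configuration for the two-population Wright-Fisher simulation
#'
#' Defines the generative scenario every recovery test is checked against:
#' an ancestral diploid population evolved to mutation-drift equilibrium,
#' a split into two descendant populations with independent (possibly
#' time-varying) sizes — one of them bottlenecked and partially selfing to
#' produce elevated inbreeding and long homozygous tracts — and an
#' outgroup lineage carrying only ancestral states at segregating sites
#' plus private divergence sites, so strict-parsimony polarization is
#' exact by construction.
#'
#' The default scale is a desk-scale genome: `N = 500`, `mu = 1e-6` per
#' site per generation, `L = 1e5` bp per contig, giving equilibrium
#' diversity `theta = 4 N mu = 2e-3` — the order of magnitude observed in
#' small wild ungulate populations. Real-genome per-generation mutation
#' rates (about `1.1e-8` in these species) would leave a desk-scale
#' sequence nearly monomorphic, so mutation is scaled up and all
#' expectations are stated in terms of `theta`.
#'
#' @param n_anc ancestral diploid size.
#' @param n_x,n_y descendant sizes; scalars or per-generation vectors of
#'   length `t_split` (bottleneck trajectories).
#' @param t_split generations since the split.
#' @param mu per-site per-generation mutation rate.
#' @param L contig length in bp.
#' @param n_chrom number of contigs (each simulated independently).
#' @param sample_x,sample_y sampled diploids per population.
#' @param selfing_x,selfing_y per-generation selfing probability in each
#'   descendant population (inbreeding level).
#' @param recomb per-bp per-generation recombination probability.
#' @param burnin ancestral burn-in generations (default `8 * n_anc`).
#' @param outgroup_divergence outgroup private divergence sites are drawn
#'   as Poisson with mean `2 * mu * L * outgroup_divergence` generations
#'   (default `2 * t_split`). Set 0 to guarantee the outgroup matches the
#'   reference genome-wide, making strict-parsimony polarization exact.
#' @param emit_invariant also emit every non-segregating position as an
#'   invariant site (`ALT = "."`), producing an all-sites matrix for
#'   missing-data-aware diversity (default `FALSE`).
#' @param seed RNG seed recorded in all outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_anc = 500, n_x = 50, n_y = 300, t_split = 200,
                       mu = 1e-6, L = 1e5, n_chrom = 2,
                       sample_x = 10, sample_y = 10,
                       selfing_x = 0.2, selfing_y = 0,
                       recomb = 1e-7, burnin = NULL,
                       outgroup_divergence = NULL,
                       emit_invariant = FALSE, seed = 1) {
  if (is.null(burnin)) burnin <- 8L * n_anc
  if (is.null(outgroup_divergence)) outgroup_divergence <- 2L * t_split
  stopifnot(n_anc >= 1, all(n_x >= 1), all(n_y >= 1), t_split >= 0,
            mu >= 0, mu <= 1, recomb >= 0, recomb <= 1, L >= 1)
  structure(list(n_anc = n_anc, n_x = n_x, n_y = n_y, t_split = t_split,
                 mu = mu, L = L, n_chrom = n_chrom, sample_x = sample_x,
                 sample_y = sample_y, selfing_x = selfing_x,
                 selfing_y = selfing_y, recomb = recomb, burnin = burnin,
                 outgroup_divergence = outgroup_divergence,
                 emit_invariant = emit_invariant, seed = seed),
            class = "sim_config")
}

expand_traj <- function(n, t_split) {
  if (t_split == 0) return(integer(0))
  if (length(n) == 1) rep(as.integer(n), t_split)
  else as.integer(rep(n, length.out = t_split))
}

#' Simulate two diverged populations with an outgroup
#'
#' Runs the forward Wright-Fisher model of [sim_config()] per contig and
#' assembles a phased [genotype_matrix()]: `sample_x` diploids of
#' population `popX`, `sample_y` of `popY`, and one outgroup individual
#' (`outgroup`) that is homozygous ancestral at every segregating site
#' and homozygous derived at its own private divergence sites. The REF
#' allele is the ancestral state at every simulated site, so derived
#' dosage equals alternate dosage — which [infer_ancestral()] must
#' recover.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (phased `genotype_matrix` including the
#'   outgroup, population map set) and `truth` (list: the config, realized
#'   per-population derived-allele frequencies, expected `theta`,
#'   collision/substitution counts, planted ROH — empty here).
#' @export
simulate_two_pops <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  traj_x <- expand_traj(cfg$n_x, cfg$t_split)
  traj_y <- expand_traj(cfg$n_y, cfg$t_split)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  per_chrom <- lapply(chroms, function(cc) {
    r <- wf_sim_cpp(cfg$n_anc, cfg$burnin, traj_x, traj_y,
                    cfg$mu, cfg$recomb, cfg$L,
                    cfg$selfing_x, cfg$selfing_y,
                    cfg$sample_x, cfg$sample_y, 10L)
    n_og <- stats::rpois(1, 2 * cfg$mu * cfg$L * cfg$outgroup_divergence)
    og_pos <- setdiff(sample.int(cfg$L, min(n_og, cfg$L)), r$pos)
    r$og_pos <- sort(og_pos)
    r$chrom <- cc
    r
  })
  samples <- c(paste0("X", seq_len(cfg$sample_x)),
               paste0("Y", seq_len(cfg$sample_y)), "outgroup")
  populations <- stats::setNames(
    c(rep("popX", cfg$sample_x), rep("popY", cfg$sample_y), "outgroup"),
    samples)
  n_tot <- length(samples)

  build_chrom <- function(r) {
    s_seg <- length(r$pos)
    s_og <- length(r$og_pos)
    hap1 <- matrix(0L, n_tot, s_seg + s_og)
    hap2 <- matrix(0L, n_tot, s_seg + s_og)
    seg_cols <- seq_len(s_seg)
    hx <- r$hap_x; hy <- r$hap_y
    for (i in seq_len(cfg$sample_x)) {
      hap1[i, seg_cols] <- hx[2 * i - 1, ]
      hap2[i, seg_cols] <- hx[2 * i, ]
    }
    for (i in seq_len(cfg$sample_y)) {
      hap1[cfg$sample_x + i, seg_cols] <- hy[2 * i - 1, ]
      hap2[cfg$sample_x + i, seg_cols] <- hy[2 * i, ]
    }
    if (s_og) {
      og_cols <- s_seg + seq_len(s_og)
      hap1[n_tot, og_cols] <- 1L
      hap2[n_tot, og_cols] <- 1L
    }
    pos <- c(r$pos, r$og_pos)
    if (isTRUE(cfg$emit_invariant)) {
      inv_pos <- setdiff(seq_len(cfg$L), pos)
      h1 <- matrix(0L, n_tot, length(pos) + length(inv_pos))
      h2 <- matrix(0L, n_tot, length(pos) + length(inv_pos))
      h1[, seq_along(pos)] <- hap1
      h2[, seq_along(pos)] <- hap2
      variant <- c(rep(TRUE, length(pos)), rep(FALSE, length(inv_pos)))
      pos <- c(pos, inv_pos)
      hap1 <- h1; hap2 <- h2
    } else variant <- rep(TRUE, length(pos))
    ord <- order(pos)
    list(pos = pos[ord], variant = variant[ord],
         hap1 = hap1[, ord, drop = FALSE],
         hap2 = hap2[, ord, drop = FALSE])
  }
  built <- lapply(per_chrom, build_chrom)
  pos <- unlist(lapply(built, `[[`, "pos"))
  variant <- unlist(lapply(built, `[[`, "variant"))
  chrom <- rep(chroms, vapply(built, function(b) length(b$pos), integer(1)))
  hap1 <- do.call(cbind, lapply(built, `[[`, "hap1"))
  hap2 <- do.call(cbind, lapply(built, `[[`, "hap2"))
  # ancestral (REF) fixed as A, derived (ALT) as G at every variant site
  gm <- genotype_matrix(
    dosage = hap1 + hap2, chrom = chrom, pos = pos,
    ref = rep("A", length(pos)), alt = ifelse(variant, "G", "."),
    samples = samples, populations = populations,
    hap1 = hap1, hap2 = hap2,
    contig_lengths = stats::setNames(rep(cfg$L, cfg$n_chrom), chroms))
  fx <- alt_frequency(gm, samples = samples[populations == "popX"])
  fy <- alt_frequency(gm, samples = samples[populations == "popY"])
  truth <- list(
    config = unclass(cfg), seed = cfg$seed,
    theta = 4 * cfg$n_anc * cfg$mu,
    freq_x = fx$freq, freq_y = fy$freq,
    n_collisions = sum(vapply(per_chrom, `[[`, integer(1), "n_collisions")),
    n_substitutions = sum(vapply(per_chrom, `[[`, integer(1), "n_substitutions")),
    planted_roh = list())
  list(genotypes = gm, truth = truth)
}

#' Sample genotype matrices directly from derived-allele frequencies
#'
#' Independent-site genotype sampler with inbreeding: at derived
#' frequency `p` and inbreeding coefficient `F`, genotype probabilities
#' are `P(het) = 2 p (1 - p) (1 - F)` with the heterozygote deficit moved
#' to both homozygotes. Sites are laid out on one contig; an all-ancestral
#' outgroup individual is appended so the matrix can be polarized through
#' the standard pipeline path.
#'
#' @param freqs_x,freqs_y equal-length derived-allele frequency vectors.
#' @param n_x,n_y diploids sampled per population.
#' @param f_x,f_y inbreeding coefficients in `[0, 1]`.
#' @param spacing_bp distance between consecutive sites (default 100).
#' @param chrom contig name (default "chr1").
#' @param outgroup append the all-ancestral outgroup individual
#'   (default `TRUE`).
#' @return a [genotype_matrix()] (populations `popX`, `popY`, and
#'   `outgroup` if requested); REF is ancestral at every site.
#' @export
sample_from_freqs <- function(freqs_x, freqs_y, n_x, n_y,
                              f_x = 0, f_y = 0, spacing_bp = 100,
                              chrom = "chr1", outgroup = TRUE) {
  if (length(freqs_x) != length(freqs_y))
    stop("frequency vectors must have equal length")
  stopifnot(all(freqs_x >= 0 & freqs_x <= 1), all(freqs_y >= 0 & freqs_y <= 1),
            f_x >= 0, f_x <= 1, f_y >= 0, f_y <= 1)
  s <- length(freqs_x)
  draw <- function(p, n, f) {
    p0 <- (1 - p)^2 + f * p * (1 - p)
    p1 <- 2 * p * (1 - p) * (1 - f)
    g <- vapply(seq_len(s), function(i)
      sample.int(3L, n, replace = TRUE,
                 prob = c(p0[i], p1[i], max(0, 1 - p0[i] - p1[i]))) - 1L,
      integer(n))
    matrix(as.integer(g), nrow = n, ncol = s)
  }
  gx <- draw(freqs_x, n_x, f_x)
  gy <- draw(freqs_y, n_y, f_y)
  d <- rbind(gx, gy)
  samples <- c(paste0("X", seq_len(n_x)), paste0("Y", seq_len(n_y)))
  pops <- c(rep("popX", n_x), rep("popY", n_y))
  if (outgroup) {
    d <- rbind(d, rep(0L, s))
    samples <- c(samples, "outgroup")
    pops <- c(pops, "outgroup")
  }
  genotype_matrix(
    dosage = d, chrom = rep(chrom, s),
    pos = as.integer(seq_len(s)) * as.integer(spacing_bp),
    ref = rep("A", s), alt = rep("G", s),
    samples = samples, populations = stats::setNames(pops, samples),
    contig_lengths = stats::setNames((s + 1) * spacing_bp, chrom))
}

#' Plant homozygous tracts into a sample's genotypes
#'
#' Ground-truth generator for the ROH detector: inside each interval the
#' sample's genotypes are set homozygous — reference unless the site is
#' fixed for the alternate allele among the other samples, in which case
#' homozygous alternate. Genotypes outside the intervals are untouched.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample id to modify.
#' @param intervals data frame with `chrom`, `start`, `end` (1-based
#'   inclusive); must not overlap each other.
#' @return the modified matrix; planted intervals accumulate in
#'   `attr(, "planted_roh")`.
#' @export
plant_roh <- function(gm, sample, intervals) {
  i <- match(sample, gm$samples)
  if (is.na(i)) stop("unknown sample: ", sample)
  if (nrow(intervals)) {
    for (cc in unique(intervals$chrom)) {
      iv <- intervals[intervals$chrom == cc, ]
      iv <- iv[order(iv$start), ]
      if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
        stop("overlapping intervals")
    }
    af <- alt_frequency(gm)
    for (k in seq_len(nrow(intervals))) {
      inside <- gm$chrom == intervals$chrom[k] &
        gm$pos >= intervals$start[k] & gm$pos <= intervals$end[k]
      fixed_alt <- !is.na(af$freq) & af$freq == 1
      gm$dosage[i, inside] <- ifelse(fixed_alt[inside], 2L, 0L)
      if (!is.null(gm$hap1)) {
        a <- ifelse(fixed_alt[inside], 1L, 0L)
        gm$hap1[i, inside] <- a; gm$hap2[i, inside] <- a
      }
    }
  }
  if (nrow(intervals))
    attr(gm, "planted_roh") <- rbind(attr(gm, "planted_roh"),
                                     cbind(sample = sample, intervals))
  gm
}

#' Assign variant categories and planted frequency shifts
#'
#' Randomly assigns each site to a functional category (synonymous,
#' tolerated nonsynonymous, deleterious; the remainder unannotated) and
#' applies per-category multipliers to the two populations' derived-allele
#' frequencies (clipped to `[0, 1]`) *before* genotype sampling, so the
#' true category-level `Freq_x`, `Freq_y` and `R_xy` are known
#' analytically from the adjusted frequencies. Deleterious sites get SIFT
#' scores below 0.05, tolerated sites above.
#'
#' @param freqs_x,freqs_y baseline derived-allele frequency vectors.
#' @param fractions named proportions for `synonymous`,
#'   `tolerated_nonsynonymous`, `deleterious`; must sum to at most 1.
#' @param shift named list: per category a length-2 vector `c(x, y)` of
#'   frequency multipliers (default: no shift).
#' @param spacing_bp,chrom site layout, matching [sample_from_freqs()].
#' @return list with `annotation` (an `annotation_table`), `freqs_x`,
#'   `freqs_y` (adjusted), and `truth` (data frame per category:
#'   analytic `freq_x`, `freq_y`, `rxy` over sites segregating in either
#'   population).
#' @export
annotate_categories <- function(freqs_x, freqs_y,
                                fractions = c(synonymous = 0.5,
                                              tolerated_nonsynonymous = 0.3,
                                              deleterious = 0.2),
                                shift = list(), spacing_bp = 100,
                                chrom = "chr1") {
  stopifnot(length(freqs_x) == length(freqs_y))
  if (sum(fractions) > 1 + 1e-12) stop("category fractions must sum to <= 1")
  for (mlt in shift)
    if (any(mlt < 0)) stop("negative frequency multiplier")
  s <- length(freqs_x)
  cats <- c(names(fractions), "unannotated")
  probs <- c(fractions, max(0, 1 - sum(fractions)))
  category <- sample(cats, s, replace = TRUE, prob = probs)
  for (cat in names(shift)) {
    i <- category == cat
    freqs_x[i] <- pmin(1, pmax(0, freqs_x[i] * shift[[cat]][1]))
    freqs_y[i] <- pmin(1, pmax(0, freqs_y[i] * shift[[cat]][2]))
  }
  sift <- rep(NA_real_, s)
  sift[category == "deleterious"] <-
    stats::runif(sum(category == "deleterious"), 0, 0.0499)
  sift[category == "tolerated_nonsynonymous"] <-
    stats::runif(sum(category == "tolerated_nonsynonymous"), 0.05, 1)
  ann <- classify_variants(data.frame(
    chrom = chrom, pos = seq_len(s) * spacing_bp,
    ref = "A", alt = "G", category = category, sift_score = sift,
    stringsAsFactors = FALSE))
  truth <- do.call(rbind, lapply(setdiff(cats, "unannotated"), function(cat) {
    i <- category == cat & (freqs_x + freqs_y) > 0
    fx <- sum(freqs_x[i] * (1 - freqs_y[i]))
    fy <- sum(freqs_y[i] * (1 - freqs_x[i]))
    data.frame(category = cat, n_sites = sum(i), freq_x = fx, freq_y = fy,
               rxy = if (fy > 0) fx / fy else NA_real_)
  }))
  list(annotation = ann, freqs_x = freqs_x, freqs_y = freqs_y, truth = truth)
}

#' Write a toy GFF3 annotation
#'
#' Emits `genes_per_contig` evenly spaced genes per contig, each with two
#' CDS exons separated by an intron, leaving intergenic space between
#' genes — enough structure to exercise region-stratified statistics.
#'
#' @param contig_lengths named vector of contig lengths.
#' @param path output path.
#' @param genes_per_contig genes per contig (default 3).
#' @return `path`, invisibly.
#' @export
write_toy_gff <- function(contig_lengths, path, genes_per_contig = 3) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  gid <- 0L
  for (cc in names(contig_lengths)) {
    len <- contig_lengths[[cc]]
    span <- floor(len / genes_per_contig)
    for (g in seq_len(genes_per_contig)) {
      gid <- gid + 1L
      g_start <- (g - 1L) * span + floor(span / 4)
      g_end <- g_start + floor(span / 2)
      e1_end <- g_start + floor(span / 8)
      e2_start <- g_end - floor(span / 8)
      nm <- sprintf("gene%03d", gid)
      writeLines(c(
        sprintf("%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                cc, g_start, g_end, nm, nm),
        sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds1;Parent=%s",
                cc, g_start, e1_end, nm, nm),
        sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds2;Parent=%s",
                cc, e2_start, g_end, nm, nm)), con)
    }
  }
  invisible(path)
}

#' Write all simulation outputs to a directory
#'
#' Emits the phased VCF (including the outgroup), a population map TSV, a
#' toy GFF3, and the truth ledger as JSON; every file records the seed.
#'
#' @param sim result of [simulate_two_pops()].
#' @param dir output directory (created if needed).
#' @param annotation optional `annotation_table` to write alongside.
#' @return named list of written paths.
#' @export
write_sim_outputs <- function(sim, dir, annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- sim$genotypes
  paths <- list(vcf = file.path(dir, "simulated.vcf"),
                popmap = file.path(dir, "population_map.tsv"),
                gff = file.path(dir, "annotation.gff3"),
                truth = file.path(dir, "sim_truth.json"))
  write_vcf(gm, paths$vcf)
  writeLines(c("# sample\tpopulation",
               paste(gm$samples, gm$populations, sep = "\t")), paths$popmap)
  write_toy_gff(gm$contig_lengths, paths$gff)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(annotation)) {
    paths$annotation <- file.path(dir, "variant_annotation.tsv")
    write_tsv(annotation, paths$annotation,
              params = list(), seed = sim$truth$seed)
  }
  paths
}
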