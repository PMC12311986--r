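#' Filter configuration
#'
#' Collects the site- and genotype-level hard filters applied by
#' [apply_filters()]. Every threshold defaults to `NULL` (rule disabled);
#' [filter_preset()] returns the two named parameter sets used at the
#' SNP-calling and the diversity stage of the pipeline.
#'
#' @param info_thresholds list of length-3 vectors `c(field, comparator,
#'   value)`; a site is removed when `INFO[field] comparator value` is TRUE
#'   (GATK-style fail expressions, e.g. `c("QD", "<", 2.0)`). Sites where
#'   the field is missing pass the rule, but a field absent at every site
#'   is an error.
#' @param min_gt_depth genotypes with read depth below this are set missing
#'   before site-level missingness is evaluated (VCFtools `--minDP`).
#' @param min_site_qual remove sites with QUAL below this (`--minQ`).
#' @param max_missing VCFtools `--max-missing` convention: minimum fraction
#'   of genotypes that must be called; a site whose called fraction is
#'   below this is removed. In `[0, 1]`.
#' @param biallelic_only remove multiallelic records (`--max-alleles 2`).
#' @param drop_indels remove records whose REF or ALT allele is longer than
#'   one base (`--remove-indels`).
#' @param max_obs_het remove variant sites whose observed heterozygote
#'   fraction among called genotypes exceeds this (excess-heterozygosity
#'   screen; e.g. 0.6).
#' @param min_maf remove variant sites with minor-allele frequency not
#'   above this (retain MAF > `min_maf`); invariant sites are also removed
#'   when this rule is active.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(info_thresholds = NULL, min_gt_depth = NULL,
                          min_site_qual = NULL, max_missing = NULL,
                          biallelic_only = FALSE, drop_indels = FALSE,
                          max_obs_het = NULL, min_maf = NULL) {
  for (f in c("max_missing", "max_obs_het")) {
    v <- get(f)
    if (!is.null(v) && (v < 0 || v > 1)) stop(f, " must lie in [0, 1]")
  }
  if (!is.null(min_maf) && (min_maf < 0 || min_maf > 0.5))
    stop("min_maf must lie in [0, 0.5]")
  structure(list(info_thresholds = info_thresholds,
                 min_gt_depth = min_gt_depth, min_site_qual = min_site_qual,
                 max_missing = max_missing, biallelic_only = biallelic_only,
                 drop_indels = drop_indels, max_obs_het = max_obs_het,
                 min_maf = min_maf), class = "filter_config")
}

#' @rdname filter_config
#' @param name `"genotyping"` (GATK INFO hard filters + `--remove-indels
#'   --max-alleles 2 --minDP 4 --minQ 70`) or `"diversity"`
#'   (`--remove-indels --minQ 30 --minDP 5 --max-missing 0.8` plus the
#'   observed-heterozygosity > 0.6 screen). Whether the original analyses
#'   composed the two sets or applied them independently is not knowable
#'   from their description; both are exposed and neither implies the other.
#' @export
filter_preset <- function(name = c("genotyping", "diversity")) {
  name <- match.arg(name)
  switch(name,
    genotyping = filter_config(
      info_thresholds = list(c("QD", "<", "2.0"), c("MQ", "<", "40.0"),
                             c("FS", ">", "60.0"), c("SOR", ">", "3.0"),
                             c("MQRankSum", "<", "-12.5"),
                             c("ReadPosRankSum", "<", "-8.0")),
      drop_indels = TRUE, biallelic_only = TRUE,
      min_gt_depth = 4, min_site_qual = 70),
    diversity = filter_config(
      drop_indels = TRUE, biallelic_only = TRUE,
      min_site_qual = 30, min_gt_depth = 5,
      max_missing = 0.8, max_obs_het = 0.6))
}

#' Apply hard filters to a genotype matrix
#'
#' Rules are applied in a fixed order — indels, multiallelic records, INFO
#' thresholds, site quality, genotype depth masking, site missingness,
#' excess observed heterozygosity, minor-allele frequency — and the report
#' counts removals per rule in that order, so the counts sum to
#' `sites_in - sites_out`. Depth masking happens before missingness is
#' evaluated, mirroring VCFtools' one-pass `--minDP --max-missing`
#' semantics. Filtering is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return list with `genotypes` (filtered matrix) and `report` (data frame
#'   of `rule`, `removed`, plus the count of depth-masked genotypes as an
#'   attribute `genotypes_masked`).
#' @export
apply_filters <- function(gm, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  if (n_sites(gm) == 0L) stop("empty genotype matrix")
  report <- data.frame(rule = character(0), removed = integer(0))
  note <- function(rule, removed)
    rbind(report, data.frame(rule = rule, removed = as.integer(removed)))
  drop_sites <- function(g, bad) subset_sites(g, !bad)

  if (isTRUE(cfg$drop_indels)) {
    bad <- nchar(gm$ref) > 1L |
      vapply(strsplit(gm$alt, ",", fixed = TRUE),
             function(a) any(nchar(a) > 1L & a != "."), logical(1))
    report <- note("indel", sum(bad)); gm <- drop_sites(gm, bad)
  }
  if (isTRUE(cfg$biallelic_only)) {
    bad <- is_multiallelic(gm)
    report <- note("multiallelic", sum(bad)); gm <- drop_sites(gm, bad)
  }
  if (!is.null(cfg$info_thresholds)) {
    bad <- rep(FALSE, n_sites(gm))
    for (th in cfg$info_thresholds) {
      field <- th[[1]]; op <- th[[2]]; val <- as.numeric(th[[3]])
      x <- if (!is.null(gm$info) && field %in% names(gm$info))
        gm$info[[field]] else rep(NA_real_, n_sites(gm))
      if (all(is.na(x)))
        stop("INFO field absent at every site: ", field)
      hit <- switch(op, "<" = x < val, "<=" = x <= val,
                    ">" = x > val, ">=" = x >= val,
                    stop("unknown comparator: ", op))
      bad <- bad | (!is.na(hit) & hit)
    }
    report <- note("info_threshold", sum(bad)); gm <- drop_sites(gm, bad)
  }
  if (!is.null(cfg$min_site_qual)) {
    bad <- !is.na(gm$qual) & gm$qual < cfg$min_site_qual
    report <- note("site_qual", sum(bad)); gm <- drop_sites(gm, bad)
  }
  n_masked <- 0L
  if (!is.null(cfg$min_gt_depth) && !is.null(gm$depth)) {
    mask <- !is.na(gm$depth) & gm$depth < cfg$min_gt_depth &
      !is.na(gm$dosage)
    n_masked <- sum(mask)
    gm$dosage[mask] <- NA_integer_
    if (!is.null(gm$hap1)) { gm$hap1[mask] <- NA_integer_; gm$hap2[mask] <- NA_integer_ }
  }
  if (!is.null(cfg$max_missing)) {
    called <- colMeans(!is.na(gm$dosage))
    bad <- called < cfg$max_missing
    report <- note("missingness", sum(bad)); gm <- drop_sites(gm, bad)
  }
  if (!is.null(cfg$max_obs_het)) {
    n_called <- colSums(!is.na(gm$dosage))
    n_het <- colSums(gm$dosage == 1L, na.rm = TRUE)
    het_frac <- ifelse(n_called > 0, n_het / n_called, 0)
    bad <- het_frac > cfg$max_obs_het
    report <- note("excess_het", sum(bad)); gm <- drop_sites(gm, bad)
  }
  if (!is.null(cfg$min_maf)) {
    af <- alt_frequency(gm)$freq
    maf <- pmin(af, 1 - af)
    bad <- is.na(maf) | maf <= cfg$min_maf
    report <- note("maf", sum(bad)); gm <- drop_sites(gm, bad)
  }
  attr(report, "genotypes_masked") <- n_masked
  list(genotypes = gm, report = report)
}

#' Prune sites in linkage disequilibrium
#'
#' PLINK-style `--indep-pairwise` greedy pruning: within each sliding
#' window of `window_snps` sites advanced by `step_snps`, the later member
#' of any surviving pair with composite r-squared above `r2_max` is
#' removed. Deterministic given input site order; windows never span
#' chromosomes.
#'
#' @param gm a variant-only, biallelic [genotype_matrix()].
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps window step in SNPs (default 5).
#' @param r2_max prune threshold on [composite_r2()] (default 0.2).
#' @return the pruned [genotype_matrix()].
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  if (any(is_invariant(gm)) || any(is_multiallelic(gm)))
    stop("ld_prune expects a biallelic, variant-only matrix")
  removed <- rep(FALSE, n_sites(gm))
  for (cc in unique(gm$chrom)) {
    idx <- which(gm$chrom == cc)
    s <- length(idx)
    starts <- unique(c(seq(1L, max(1L, s - 1L), by = step_snps)))
    for (st in starts) {
      win <- idx[st:min(st + window_snps - 1L, s)]
      win <- win[!removed[win]]
      if (length(win) < 2L) next
      for (i in seq_len(length(win) - 1L)) {
        if (removed[win[i]]) next
        for (j in seq((i + 1L), length(win))) {
          if (removed[win[j]]) next
          r2 <- composite_r2(gm$dosage[, win[i]], gm$dosage[, win[j]])
          if (!is.na(r2) && r2 > r2_max) removed[win[j]] <- TRUE
        }
      }
    }
  }
  subset_sites(gm, !removed)
}
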