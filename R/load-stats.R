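variant_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Classify variants into functional-load categories
#'
#' Builds the annotation table driving load stratification. Nonsynonymous
#' variants with a SIFT score below 0.05 are classified putatively
#' deleterious; nonsynonymous variants at or above 0.05 are tolerated;
#' synonymous variants pass through; anything else is `unannotated`.
#'
#' @param raw data frame with key columns `chrom`, `pos`, `ref`, `alt` and
#'   either a `category` column (values `synonymous`, `nonsynonymous`,
#'   or an already-final category) or a logical `nonsynonymous` column;
#'   nonsynonymous rows need a `sift_score` in `[0, 1]`.
#' @param sift_deleterious score threshold: strictly below it is
#'   deleterious (default 0.05).
#' @return data frame of class `annotation_table` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `category`, `sift_score`.
#' @export
classify_variants <- function(raw, sift_deleterious = 0.05) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(raw)))
  key <- variant_key(raw$chrom, raw$pos, raw$ref, raw$alt)
  if (!"sift_score" %in% names(raw)) raw$sift_score <- NA_real_
  nonsyn <-
    if ("nonsynonymous" %in% names(raw)) raw$nonsynonymous
    else if ("category" %in% names(raw)) raw$category == "nonsynonymous"
    else rep(FALSE, nrow(raw))
  category <- rep("unannotated", nrow(raw))
  if ("category" %in% names(raw)) {
    known <- c("synonymous", "tolerated_nonsynonymous", "deleterious")
    category[raw$category %in% known] <- raw$category[raw$category %in% known]
  }
  scored <- nonsyn & !is.na(raw$sift_score)
  category[scored & raw$sift_score < sift_deleterious] <- "deleterious"
  category[scored & raw$sift_score >= sift_deleterious] <- "tolerated_nonsynonymous"
  out <- data.frame(chrom = raw$chrom, pos = raw$pos, ref = raw$ref,
                    alt = raw$alt, category = category,
                    sift_score = raw$sift_score, stringsAsFactors = FALSE)
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- unique(key[dup][vapply(key[dup], function(k)
      length(unique(out$category[key == k])) > 1L, logical(1))])
    if (length(conflict))
      stop("conflicting categories for variant key(s): ",
           paste(conflict, collapse = ", "))
    out <- out[!dup, ]
  }
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Read an annotation table from TSV
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt` and category /
#'   SIFT columns accepted by [classify_variants()].
#' @param ... passed to [classify_variants()].
#' @return an `annotation_table`.
#' @export
read_annotation <- function(path, ...) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  classify_variants(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#",
                                      stringsAsFactors = FALSE), ...)
}

join_annotation <- function(pm, ann) {
  match(variant_key(pm$base$chrom, pm$base$pos, pm$base$ref, pm$base$alt),
        variant_key(ann$chrom, ann$pos, ann$ref, ann$alt))
}

#' Per-individual additive mutational load
#'
#' For each sample and category, counts heterozygous and homozygous-derived
#' genotypes over polarized sites and reports the additive load
#' `2 * n_hom_derived + n_het` (each derived allele counts once). Missing
#' genotypes contribute nothing.
#'
#' @param pm a [infer_ancestral()] result.
#' @param ann an `annotation_table` ([classify_variants()]).
#' @param categories categories to report (default: all present in `ann`).
#' @return data frame `sample`, `category`, `n_het`, `n_hom_derived`,
#'   `additive_load`.
#' @export
additive_load <- function(pm, ann, categories = NULL) {
  m <- join_annotation(pm, ann)
  site_cat <- ifelse(is.na(m), NA_character_, ann$category[m])
  if (is.null(categories)) categories <- unique(ann$category)
  out <- lapply(categories, function(cat) {
    idx <- which(!is.na(site_cat) & site_cat == cat)
    if (!length(idx))
      warning("no polarized sites in category: ", cat)
    dd <- pm$derived_dosage[, idx, drop = FALSE]
    n_het <- rowSums(dd == 1L, na.rm = TRUE)
    n_hom <- rowSums(dd == 2L, na.rm = TRUE)
    data.frame(sample = pm$base$samples, category = cat,
               n_het = n_het, n_hom_derived = n_hom,
               additive_load = 2L * n_hom + n_het, row.names = NULL)
  })
  do.call(rbind, out)
}

#' R_xy: between-population derived-allele frequency ratio
#'
#' For a variant category C the statistic compares cumulative
#' cross-population frequency products:
#' `Freq_x = sum_{i in C} f_ix (1 - f_iy)` and
#' `Freq_y = sum_{i in C} f_iy (1 - f_ix)`, with `R_xy = Freq_x / Freq_y`.
#' A value of 1 means no frequency change between populations; above 1, the
#' category's derived alleles are relatively enriched in population x
#' (equivalently depleted in y); below 1 the reverse. The 95% confidence
#' interval comes from a leave-one-out jackknife over contiguous genomic
#' blocks of sites.
#'
#' @param pm a [infer_ancestral()] result (population map required).
#' @param ann an `annotation_table`.
#' @param pop_x,pop_y population labels (x in the numerator products).
#' @param category variant category to evaluate.
#' @param n_blocks number of contiguous jackknife blocks (default 100;
#'   capped at the number of usable sites).
#' @param site_policy `"segregating"` (default) uses every category site
#'   with defined frequency in both populations and the derived allele
#'   present in at least one of them — the form the cumulative sums
#'   require; `"private"` restricts to sites whose derived allele occurs
#'   in exactly one of the two populations (the strict reading of
#'   "sites unique to each species").
#' @param ci_scale `"ratio"` (default): normal-approximation CI
#'   `rxy +/- 1.96 SE_jack`; `"log"`: CI formed on the log scale and
#'   exponentiated.
#' @return object of class `rxy_result`: `category`, `freq_x`, `freq_y`,
#'   `rxy`, `se`, `ci_low`, `ci_high`, `n_sites`, `n_excluded`, `n_blocks`.
#' @export
rxy <- function(pm, ann, pop_x, pop_y, category, n_blocks = 100,
                site_policy = c("segregating", "private"),
                ci_scale = c("ratio", "log")) {
  site_policy <- match.arg(site_policy)
  ci_scale <- match.arg(ci_scale)
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  m <- join_annotation(pm, ann)
  in_cat <- !is.na(m) & ann$category[m] == category
  if (!any(in_cat)) stop("no polarized sites in category: ", category)
  fx <- derived_site_frequency(pm, pop_x)
  fy <- derived_site_frequency(pm, pop_y)
  usable <- in_cat & fx$defined & fy$defined
  seg <- usable & (fx$d + fy$d > 0)
  use <- if (site_policy == "segregating") seg
         else usable & xor(fx$d > 0, fy$d > 0)
  n_excluded <- sum(in_cat) - sum(use)
  idx <- which(use)
  idx <- idx[order(pm$base$chrom[idx], pm$base$pos[idx])]
  tx <- fx$f[idx] * (1 - fy$f[idx])
  ty <- fy$f[idx] * (1 - fx$f[idx])
  freq_x <- sum(tx); freq_y <- sum(ty)
  if (freq_y == 0) stop("ratio undefined: Freq_pop-y is zero for category ",
                        category)
  point <- freq_x / freq_y

  g <- min(n_blocks, length(idx))
  block <- ceiling(seq_along(idx) / (length(idx) / g))
  bx <- tapply(tx, block, sum); by <- tapply(ty, block, sum)
  loo <- (freq_x - bx) / (freq_y - by)
  loo <- loo[is.finite(loo)]
  g_eff <- length(loo)
  if (g_eff >= 2) {
    if (ci_scale == "log") {
      se_log <- sqrt((g_eff - 1) / g_eff * sum((log(loo) - mean(log(loo)))^2))
      se <- se_log * point
      ci <- exp(log(point) + c(-1, 1) * 1.96 * se_log)
    } else {
      se <- sqrt((g_eff - 1) / g_eff * sum((loo - mean(loo))^2))
      ci <- point + c(-1, 1) * 1.96 * se
    }
  } else {
    se <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  structure(list(category = category, pop_x = pop_x, pop_y = pop_y,
                 freq_x = freq_x, freq_y = freq_y, rxy = point, se = se,
                 ci_low = ci[1], ci_high = ci[2],
                 n_sites = length(idx), n_excluded = n_excluded,
                 n_blocks = g, site_policy = site_policy,
                 ci_scale = ci_scale), class = "rxy_result")
}

#' @export
print.rxy_result <- function(x, ...) {
  cat(sprintf("R_%s/%s [%s]: %.4f (95%% CI %.4f-%.4f)\n",
              x$pop_x, x$pop_y, x$category, x$rxy, x$ci_low, x$ci_high))
  cat(sprintf("  Freq_x = %.4f, Freq_y = %.4f over %d sites (%d excluded), %d blocks\n",
              x$freq_x, x$freq_y, x$n_sites, x$n_excluded, x$n_blocks))
  invisible(x)
}

#' Compare per-individual load between two populations
#'
#' Convenience wrapper for the per-individual load comparison: Welch's
#' two-sample t-test or the Mann-Whitney U test on a chosen load measure.
#' Both tests are offered because either is defensible for small-sample
#' load counts; neither is privileged.
#'
#' @param loads output of [additive_load()].
#' @param populations named vector sample -> population.
#' @param pop_x,pop_y the two populations to compare.
#' @param category category to test.
#' @param measure `"additive_load"`, `"n_het"` or `"n_hom_derived"`.
#' @param test `"welch"` or `"mann-whitney"`.
#' @return the `htest` object.
#' @export
compare_load <- function(loads, populations, pop_x, pop_y, category,
                         measure = "additive_load",
                         test = c("welch", "mann-whitney")) {
  test <- match.arg(test)
  sub <- loads[loads$category == category, ]
  x <- sub[[measure]][populations[sub$sample] == pop_x]
  y <- sub[[measure]][populations[sub$sample] == pop_y]
  if (test == "welch") stats::t.test(x, y)
  else stats::wilcox.test(x, y, exact = FALSE)
}
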