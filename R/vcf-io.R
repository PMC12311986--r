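#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (plain or gzipped) with `vcfR` and converts it to
#' the package's [genotype_matrix()] container. Record order is preserved.
#' Multiallelic records are kept but flagged (see [is_multiallelic()]) so
#' [apply_filters()] can remove them; `ALT = "."` records become invariant
#' sites when `keep_invariant = TRUE`. Fully or half-missing genotypes
#' (`./.`, `.`, `./1`) map to missing dosage. Phased `0|1`-style genotypes
#' additionally populate the haplotype slots.
#'
#' @param path VCF file path.
#' @param population_map optional named character vector (sample ->
#'   population) or two-column data frame; every mapped sample must be in the
#'   VCF header.
#' @param keep_invariant keep `ALT = "."` records as invariant sites
#'   (default `TRUE`); otherwise they are dropped.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, population_map = NULL, keep_invariant = TRUE) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no genotype columns")
  fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(f) "GT" %in% f, logical(1))))
    stop("GT missing from FORMAT in one or more records")
  samples <- colnames(gt)[-1]

  alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."
  keep <- rep(TRUE, nrow(fix))
  if (!keep_invariant) keep <- alt != "."

  gts <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gts))) gts <- matrix(gts, nrow = nrow(fix),
                                       dimnames = list(NULL, samples))
  parsed <- parse_gt_strings(gts)            # sites x samples
  dosage <- t(parsed$dosage)                 # samples x sites
  hap1 <- hap2 <- NULL
  if (parsed$any_phased) { hap1 <- t(parsed$hap1); hap2 <- t(parsed$hap2) }

  depth <- NULL
  if (any(vapply(fmt, function(f) "DP" %in% f, logical(1)))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = nrow(fix))
    depth <- t(dp)
    storage.mode(depth) <- "integer"
    rownames(depth) <- samples
  }

  info <- parse_info_numeric(fix[, "INFO"])
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  contig_lengths <- parse_contig_lengths(v@meta)
  gm <- genotype_matrix(
    dosage = dosage[, keep, drop = FALSE],
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"], alt = alt[keep],
    samples = samples, populations = population_map,
    qual = qual[keep],
    info = if (!is.null(info)) info[keep, , drop = FALSE] else NULL,
    depth = if (!is.null(depth)) depth[, keep, drop = FALSE] else NULL,
    hap1 = if (!is.null(hap1)) hap1[, keep, drop = FALSE] else NULL,
    hap2 = if (!is.null(hap2)) hap2[, keep, drop = FALSE] else NULL,
    contig_lengths = contig_lengths)
  gm
}

# GT string matrix (sites x samples) -> dosage and optional phased haplotypes.
# Half-calls and any allele code > 1 are treated as missing dosage.
parse_gt_strings <- function(gts) {
  dim_g <- dim(gts)
  g <- as.vector(gts)
  g[is.na(g)] <- "./."
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", g)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", g)
  haploid <- !grepl("[/|]", g)
  a1[haploid] <- g[haploid]; a2[haploid] <- g[haploid]
  n1 <- suppressWarnings(as.integer(a1))
  n2 <- suppressWarnings(as.integer(a2))
  bad <- is.na(n1) | is.na(n2) | n1 > 1L | n2 > 1L
  dosage <- n1 + n2
  dosage[bad] <- NA_integer_
  phased <- grepl("|", g, fixed = TRUE) & !bad
  h1 <- h2 <- rep(NA_integer_, length(g))
  h1[phased] <- n1[phased]; h2[phased] <- n2[phased]
  shape <- function(x) { dim(x) <- dim_g; x }
  list(dosage = shape(dosage),
       hap1 = shape(h1), hap2 = shape(h2),
       any_phased = any(phased))
}

# Extract every INFO key with at least one numeric value into a data frame.
parse_info_numeric <- function(info_str) {
  info_str[is.na(info_str)] <- "."
  kv <- strsplit(info_str, ";", fixed = TRUE)
  keys <- unique(unlist(lapply(kv, function(p) sub("=.*$", "", p[grepl("=", p)]))))
  keys <- setdiff(keys, c("", "."))
  if (!length(keys)) return(NULL)
  out <- lapply(keys, function(k) {
    pat <- paste0("(?:^|;)", k, "=([^;]*)")
    m <- regmatches(info_str, regexpr(pat, info_str, perl = TRUE))
    val <- rep(NA_character_, length(info_str))
    has <- grepl(pat, info_str, perl = TRUE)
    val[has] <- sub(pat, "\\1", regmatches(info_str,
                    regexpr(pat, info_str, perl = TRUE)), perl = TRUE)
    suppressWarnings(as.numeric(val))
  })
  names(out) <- keys
  numeric_keys <- vapply(out, function(x) any(!is.na(x)), logical(1))
  if (!any(numeric_keys)) return(NULL)
  as.data.frame(out[numeric_keys], optional = TRUE)
}

parse_contig_lengths <- function(meta) {
  cl <- grep("^##contig=", meta, value = TRUE)
  if (!length(cl)) return(NULL)
  id <- sub(".*ID=([^,>]+).*", "\\1", cl)
  has_len <- grepl("length=", cl)
  len <- rep(NA_real_, length(cl))
  len[has_len] <- as.numeric(sub(".*length=([0-9]+).*", "\\1", cl[has_len]))
  stats::setNames(len, id)
}

#' Write a genotype matrix as VCF
#'
#' Emits a VCF v4.2 text file that round-trips through [read_vcf()] to an
#' equal matrix. Invariant sites are written with `ALT = "."`; phased
#' haplotypes (when present and non-missing) with the `|` separator; depth
#' as a `DP` FORMAT field; numeric INFO columns (including the `AA`
#' ancestral-allele tag written by [polarized_vcf_info()]) as INFO.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text; `.gz` suffix writes gzip).
#' @param extra_info optional character vector of per-site INFO strings
#'   appended to the numeric INFO fields (e.g. `AA=G`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, extra_info = NULL) {
  n <- n_sites(gm)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  meta <- c("##fileformat=VCFv4.2",
            paste0("##source=popgenpipe_", as.character(utils::packageVersion("popgenpipe"))),
            "##coordinates=1-based inclusive")
  contigs <- gm$contig_lengths
  if (is.null(contigs)) {
    cs <- unique(gm$chrom)
    contigs <- stats::setNames(vapply(cs, function(cc)
      max(gm$pos[gm$chrom == cc]), numeric(1)), cs)
  }
  meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  if (!is.null(gm$info))
    meta <- c(meta, sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
      names(gm$info), names(gm$info)))
  if (!is.null(extra_info))
    meta <- c(meta, "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">")
  meta <- c(meta,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(gm$depth))
    meta <- c(meta, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  writeLines(meta, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  info_str <- rep(".", n)
  if (!is.null(gm$info)) {
    parts <- vapply(seq_len(n), function(i) {
      v <- unlist(gm$info[i, , drop = TRUE])
      ok <- !is.na(v)
      if (!any(ok)) return(".")
      paste(sprintf("%s=%s", names(gm$info)[ok],
                    format(v[ok], trim = TRUE, scientific = FALSE)),
            collapse = ";")
    }, character(1))
    info_str <- parts
  }
  if (!is.null(extra_info)) {
    stopifnot(length(extra_info) == n)
    info_str <- ifelse(info_str == ".", extra_info,
                       paste(info_str, extra_info, sep = ";"))
  }
  gt_str <- format_gt_strings(gm)
  fmt <- if (is.null(gm$depth)) "GT" else "GT:DP"
  qual <- ifelse(is.na(gm$qual), ".",
                 format(gm$qual, trim = TRUE, scientific = FALSE))
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, qual, "PASS",
                info_str, fmt, sep = "\t")
  writeLines(paste(body, gt_str, sep = "\t"), con)
  invisible(path)
}

format_gt_strings <- function(gm) {
  n <- n_sites(gm); m <- n_samples(gm)
  d <- gm$dosage
  g <- matrix("./.", m, n)
  g[!is.na(d) & d == 0L] <- "0/0"
  g[!is.na(d) & d == 1L] <- "0/1"
  g[!is.na(d) & d == 2L] <- "1/1"
  if (!is.null(gm$hap1)) {
    ph <- !is.na(gm$hap1) & !is.na(gm$hap2)
    g[ph] <- paste0(gm$hap1[ph], "|", gm$hap2[ph])
  }
  if (!is.null(gm$depth)) {
    dp <- ifelse(is.na(gm$depth), ".", as.character(gm$depth))
    g <- matrix(paste0(g, ":", dp), nrow(g), ncol(g))
  }
  apply(g, 2, paste, collapse = "\t")
}

#' Read a two-column population map (sample TAB population)
#' @param path TSV path; lines starting with `#` are skipped.
#' @return named character vector, sample -> population.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("no such population map file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "population"),
                          comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(df$population, df$sample)
}

#' Write a table or window track as TSV with a provenance header
#'
#' Header comment lines record the package version, the seed and a hash of
#' the parameter list, so every output file is traceable to its run.
#'
#' @param x data frame (e.g. a window track, load summary or ROH table).
#' @param path output path.
#' @param params named list of parameters to record (hashed and echoed).
#' @param seed seed to record, if any.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, params = list(), seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# popgenpipe ", as.character(utils::packageVersion("popgenpipe"))),
    paste0("# seed=", if (is.null(seed)) "NA" else seed),
    paste0("# config_hash=", config_hash(params)),
    paste0("# params=", paste(names(params),
           vapply(params, function(p) paste(format(p), collapse = ","),
                  character(1)), sep = "=", collapse = "; "))), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stable MD5 hash of a parameter list
#' @param params named list.
#' @return 32-character hash string.
#' @export
config_hash <- function(params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(params[order(names(params))]), tf)
  unname(tools::md5sum(tf))
}
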