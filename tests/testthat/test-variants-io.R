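test_that("read_vcf parses genotypes, missingness, phase, invariant sites and DP", {
  path <- write_fixture_vcf(withr::local_tempfile(fileext = ".vcf"))
  gm <- read_vcf(path)

  expect_s3_class(gm, "genotype_matrix")
  expect_equal(gm$samples, c("sampA", "sampB", "sampC"))
  expect_equal(n_sites(gm), 5L)
  expect_equal(gm$pos, c(100L, 200L, 300L, 400L, 500L))

  # plain genotypes and the fully missing "./."
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(gm$dosage[, 2]), c(NA_integer_, 0L, 1L))
  # invariant record
  expect_true(is_invariant(gm)[3])
  expect_equal(unname(gm$dosage[, 3]), c(0L, 0L, 0L))
  # phased entries populate haplotypes and sum to the dosage
  expect_equal(unname(gm$hap1[, 4]), c(0L, 1L, 0L))
  expect_equal(unname(gm$hap2[, 4]), c(1L, 1L, 0L))
  expect_equal(unname(gm$dosage[, 4]), c(1L, 2L, 0L))
  # multiallelic record flagged; allele-2 and half calls are missing
  expect_true(is_multiallelic(gm)[5])
  expect_equal(unname(gm$dosage[, 5]), c(0L, NA_integer_, NA_integer_))
  # DP and INFO
  expect_equal(unname(gm$depth[, 1]), c(12L, 9L, 20L))
  expect_equal(gm$info$QD[2], 1.5)
  expect_true(is.na(gm$info$QD[3]))
  expect_equal(gm$contig_lengths[["chr1"]], 10000)

  # invariant records dropped on request
  expect_equal(n_sites(read_vcf(path, keep_invariant = FALSE)), 4L)
  # population map naming an absent sample errors with the name
  expect_error(read_vcf(path, population_map = c(sampA = "p1", nope = "p2")),
               "nope")
})

test_that("read_vcf rejects records without GT", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t1\t.\tA\tG\t50\tPASS\t.\tDP\t7"), path)
  expect_error(read_vcf(path), "GT")
})

test_that("VCF writing round-trips through read_vcf", {
  sim <- simulate_two_pops(sim_config(n_anc = 60, t_split = 20, n_x = 20,
                                      n_y = 30, mu = 2e-5, L = 5000,
                                      n_chrom = 2, sample_x = 4, sample_y = 4,
                                      emit_invariant = TRUE, seed = 3))
  gm <- sim$genotypes
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, population_map = gm$populations)

  expect_equal(back$dosage, gm$dosage)
  expect_equal(back$hap1[, !is_invariant(gm)], gm$hap1[, !is_invariant(gm)])
  expect_equal(back$pos, gm$pos)
  expect_equal(back$chrom, gm$chrom)
  expect_equal(back$ref, gm$ref)
  expect_equal(back$alt, gm$alt)
  # invariant sites serialized as ALT="."
  expect_true(any(is_invariant(back)))
  expect_identical(is_invariant(back), is_invariant(gm))
})

test_that("apply_filters implements each rule and reports removals in order", {
  # 10 samples, 6 sites; site 2 has 7/10 hets (excess heterozygosity),
  # sites 5 and 6 have 3/10 missing genotypes
  d <- matrix(0L, 10, 6)
  d[1:5, 1] <- 1L
  d[1:7, 2] <- 1L
  d[, 3] <- c(rep(2L, 9), 0L)
  d[1:2, 4] <- 1L
  d[1:3, 5] <- NA_integer_
  d[8:10, 6] <- NA_integer_
  gm <- make_gm(d)

  res <- apply_filters(gm, filter_config(max_obs_het = 0.6))
  expect_equal(n_sites(res$genotypes), 5L)
  expect_false(200L %in% res$genotypes$pos)
  expect_equal(res$report$removed[res$report$rule == "excess_het"], 1L)

  res <- apply_filters(gm, filter_config(max_missing = 0.8))
  expect_equal(n_sites(res$genotypes), 4L)

  # empty configuration is the identity
  res <- apply_filters(gm, filter_config())
  expect_identical(res$genotypes$dosage, gm$dosage)
  expect_equal(nrow(res$report), 0L)

  # removal counts account exactly for sites_in - sites_out
  cfg <- filter_config(max_missing = 0.8, max_obs_het = 0.6, min_maf = 0.05)
  res <- apply_filters(gm, cfg)
  expect_equal(sum(res$report$removed), n_sites(gm) - n_sites(res$genotypes))

  # idempotence
  res2 <- apply_filters(res$genotypes, cfg)
  expect_identical(res2$genotypes$dosage, res$genotypes$dosage)
  expect_equal(sum(res2$report$removed), 0L)
})

test_that("genotype depth masking precedes the missingness filter", {
  d <- matrix(1L, 5, 2)
  dp <- matrix(10L, 5, 2)
  dp[1:2, 1] <- 2L  # two genotypes at site 1 below minDP
  gm <- make_gm(d, depth = dp)
  res <- apply_filters(gm, filter_config(min_gt_depth = 4, max_missing = 0.8))
  # site 1 drops below 80% called only after masking
  expect_equal(n_sites(res$genotypes), 1L)
  expect_equal(attr(res$report, "genotypes_masked"), 2L)
  # remaining site untouched
  expect_false(anyNA(res$genotypes$dosage))
})

test_that("INFO threshold rules follow fail-expression semantics", {
  d <- matrix(0L, 4, 3); d[1, ] <- 1L
  gm <- make_gm(d, info = data.frame(QD = c(1.0, 25, NA), MQ = c(60, 35, 50)))
  res <- apply_filters(gm, filter_config(
    info_thresholds = list(c("QD", "<", 2), c("MQ", "<", 40))))
  expect_equal(res$genotypes$pos, 300L)  # missing INFO value passes
  expect_equal(res$report$removed[res$report$rule == "info_threshold"], 2L)
  expect_error(
    apply_filters(gm, filter_config(info_thresholds = list(c("FS", ">", 60)))),
    "FS")
})

test_that("filter presets carry the two published parameter sets", {
  g <- filter_preset("genotyping")
  expect_equal(g$min_gt_depth, 4)
  expect_equal(g$min_site_qual, 70)
  expect_true(g$drop_indels && g$biallelic_only)
  d <- filter_preset("diversity")
  expect_equal(d$min_gt_depth, 5)
  expect_equal(d$min_site_qual, 30)
  expect_equal(d$max_missing, 0.8)
  expect_equal(d$max_obs_het, 0.6)
})

test_that("ld_prune removes later members of high-r2 pairs, greedily", {
  set.seed(42)
  base <- sample(0:2, 12, replace = TRUE)
  d <- cbind(base, base, sample(0:2, 12, replace = TRUE))
  gm <- make_gm(d)
  pruned <- ld_prune(gm, window_snps = 3, step_snps = 1, r2_max = 0.2)
  expect_equal(pruned$pos[1], 100L)
  expect_false(200L %in% pruned$pos)  # duplicate (r2 = 1) removed

  # pairwise-independent sites survive untouched
  d0 <- cbind(c(0, 0, 1, 1, 2, 2, 0, 1, 2), c(0, 1, 2, 2, 0, 1, 1, 2, 0))
  gm0 <- make_gm(d0)
  expect_equal(n_sites(ld_prune(gm0, 2, 1, 0.9)), 2L)

  expect_error(ld_prune(gm, window_snps = 1), "window_snps")
})

test_that("ld_prune agrees with the exhaustive-pair oracle and leaves no hot pair", {
  set.seed(7)
  for (rep in 1:5) {
    base <- sample(0:2, 20, replace = TRUE)
    d <- cbind(base,
               ifelse(stats::runif(20) < 0.9, base, sample(0:2, 20, TRUE)),
               sample(0:2, 20, TRUE),
               ifelse(stats::runif(20) < 0.8, base, sample(0:2, 20, TRUE)),
               sample(0:2, 20, TRUE))
    gm <- make_gm(d)
    kept <- ld_prune(gm, window_snps = 5, step_snps = 1, r2_max = 0.2)
    expect_equal(match(kept$pos, gm$pos), oracle_prune_window(d, 0.2))
    # invariant: no surviving within-window pair exceeds the threshold
    if (n_sites(kept) > 1) {
      pairs <- utils::combn(n_sites(kept), 2)
      r2s <- apply(pairs, 2, function(ij)
        composite_r2(kept$dosage[, ij[1]], kept$dosage[, ij[2]]))
      expect_true(all(is.na(r2s) | r2s <= 0.2))
    }
  }
})

test_that("write_tsv records provenance headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(x = 1:3), path, params = list(a = 1), seed = 99)
  lines <- readLines(path)
  expect_match(lines[2], "seed=99")
  expect_match(lines[3], "config_hash=[0-9a-f]{32}")
  expect_equal(config_hash(list(a = 1)), config_hash(list(a = 1)))
})
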