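test_that("Tajima's D reproduces the worked 4-haplotype example", {
  # haplotypes {00, 00, 11, 01} as two diploids: S1 = 00/00, S2 = 11/01
  h1 <- rbind(c(0L, 0L), c(1L, 1L))
  h2 <- rbind(c(0L, 0L), c(0L, 1L))
  gm <- make_gm(h1 + h2, hap1 = h1, hap2 = h2,
                populations = stats::setNames(c("p1", "p1"), c("S1", "S2")))
  tr <- tajimas_d(gm, "p1", window_bp = 1000, min_alleles = 4)
  want <- oracle_tajima_from_haps(rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 1)))
  expect_equal(tr$value, want, tolerance = 1e-9)
  expect_equal(round(tr$value, 2), 0.59)
  expect_equal(tr$n_sites_used, 2L)

  # no segregating sites -> NA
  gm0 <- make_gm(matrix(2L, 3, 2),
                 populations = stats::setNames(rep("p1", 3), paste0("S", 1:3)))
  expect_true(is.na(tajimas_d(gm0, "p1", 1000)$value))
  expect_error(tajimas_d(subset_samples(gm, "S1"), "p1"), "two samples")
})

test_that("Tajima's D tracks the oracle across random windows", {
  set.seed(71)
  for (rep in 1:4) {
    n_hap <- 8
    haps <- matrix(rbinom(n_hap * 15, 1, stats::runif(1, 0.2, 0.6)),
                   n_hap, 15)
    h1 <- haps[seq(1, n_hap, 2), , drop = FALSE]
    h2 <- haps[seq(2, n_hap, 2), , drop = FALSE]
    gm <- make_gm(h1 + h2,
                  populations = stats::setNames(rep("p1", n_hap / 2),
                                                paste0("S", seq_len(n_hap / 2))))
    got <- tajimas_d(gm, "p1", window_bp = 10000)$value
    want <- oracle_tajima_from_haps(haps)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("mean Tajima's D is near zero for neutral equilibrium simulations", {
  # chromosome-sized windows keep S large enough for the normalization;
  # three independent contigs per seed reduce between-seed variance
  ds <- vapply(1:10, function(s) {
    sim <- simulate_two_pops(sim_config(n_anc = 120, t_split = 0, mu = 5e-6,
                                        L = 4e4, n_chrom = 3, sample_x = 10,
                                        sample_y = 1, seed = s))
    gm <- subset_samples(sim$genotypes, paste0("X", 1:10))
    mean(tajimas_d(gm, "popX", window_bp = 4e4)$value, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.3)
})

test_that("Weir-Cockerham FST is exact on fixed differences and the printed toy", {
  pops <- two_pop_map(5, 5)
  dfix <- rbind(matrix(2L, 5, 3), matrix(0L, 5, 3))
  rownames(dfix) <- names(pops)
  fixed <- make_gm(dfix, populations = pops)
  tr <- wc_fst(fixed, "popX", "popY", window_bp = 10000)
  expect_equal(tr$value, 1)

  # 5v5 diploids, one site, p_x = 0.8 (dosages 2,2,2,1,1; h = 2/5),
  # p_y = 0.2 (0,0,0,1,1): hand-evaluated variance components give
  # a = 0.165, b = -0.025, c = 0.2 -> FST = 0.165/0.34
  d <- matrix(c(2L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, 1L, 1L), 10, 1)
  rownames(d) <- names(pops)
  toy <- make_gm(d, populations = pops)
  tr2 <- wc_fst(toy, "popX", "popY", window_bp = 1000)
  expect_equal(tr2$value, 0.165 / 0.34, tolerance = 1e-12)
  ps <- attr(tr2, "per_site")
  expect_equal(ps$a, 0.165, tolerance = 1e-12)
  expect_equal(ps$b, -0.025, tolerance = 1e-12)
  expect_equal(ps$c, 0.2, tolerance = 1e-12)

  # population swap leaves FST unchanged
  tr3 <- wc_fst(toy, "popY", "popX", window_bp = 1000)
  expect_equal(tr3$value, tr2$value)
})

test_that("null FST is centered on zero for samples of one pool", {
  set.seed(73)
  fsts <- vapply(1:10, function(s) {
    p <- stats::runif(300, 0.1, 0.9)
    gm <- sample_from_freqs(p, p, 8, 8, outgroup = FALSE)
    mean(wc_fst(gm, "popX", "popY", window_bp = 40000)$value, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fsts)), 0.02)
})

test_that("EHH decay matches the haplotype-class counting oracle", {
  # 8 haplotypes x 5 SNPs with distinct class structure
  haps <- rbind(c(0, 0, 0, 0, 0),
                c(0, 0, 0, 0, 1),
                c(0, 0, 1, 0, 1),
                c(0, 1, 1, 0, 0),
                c(1, 1, 1, 1, 0),
                c(1, 1, 0, 1, 0),
                c(1, 0, 0, 1, 1),
                c(1, 0, 0, 0, 1))
  storage.mode(haps) <- "integer"
  tr <- popgenpipe:::ehh_trace(haps, core = 1L, dir = +1L, min_ehh = 0)
  for (k in seq_along(tr$idx))
    expect_equal(tr$ehh[k], oracle_ehh(haps, 1:tr$idx[k]))
  trl <- popgenpipe:::ehh_trace(haps, core = 4L, dir = -1L, min_ehh = 0)
  for (k in seq_along(trl$idx))
    expect_equal(trl$ehh[k], oracle_ehh(haps, trl$idx[k]:4))
})

test_that("XP-EHH contracts: zero on identical sets, sign flip, normalization", {
  set.seed(74)
  sim <- simulate_two_pops(sim_config(n_anc = 80, t_split = 30, n_x = 40,
                                      n_y = 40, mu = 1e-5, L = 3e4,
                                      n_chrom = 2, sample_x = 6, sample_y = 6,
                                      seed = 4))
  gm <- subset_samples(sim$genotypes,
                       setdiff(sim$genotypes$samples, "outgroup"))
  # identical haplotype sets: raw score 0 at every core
  hs <- haplotype_set(gm, "popX", "popX")
  tr_same <- xpehh(hs, window_bp = 10000)
  expect_true(all(abs(attr(tr_same, "scores")$raw) < 1e-12, na.rm = TRUE))

  tr_ab <- xpehh(gm, "popX", "popY", window_bp = 10000)
  tr_ba <- xpehh(gm, "popY", "popX", window_bp = 10000)
  sa <- attr(tr_ab, "scores"); sb <- attr(tr_ba, "scores")
  expect_equal(sa$raw, -sb$raw)
  # normalized scores have mean 0 and unit SD by construction
  expect_lt(abs(mean(sa$norm, na.rm = TRUE)), 1e-9)
  expect_lt(abs(stats::sd(sa$norm, na.rm = TRUE) - 1), 1e-9)
})

test_that("a population fixed for one extended haplotype scores positive", {
  set.seed(75)
  sim <- simulate_two_pops(sim_config(n_anc = 60, t_split = 20, n_x = 30,
                                      n_y = 30, mu = 2e-5, L = 2e4,
                                      n_chrom = 1, sample_x = 6, sample_y = 6,
                                      seed = 8))
  gm <- subset_samples(sim$genotypes,
                       setdiff(sim$genotypes$samples, "outgroup"))
  gm <- plant_fixed_haplotype(gm, "popX", "chr1", 1, 2e4)
  tr <- xpehh(gm, "popX", "popY", window_bp = 2e4)
  sc <- attr(tr, "scores")
  interior <- sc$pos > 2000 & sc$pos < 18000 & !is.na(sc$raw)
  expect_true(all(sc$raw[interior] > 0))
})

test_that("top-window intersection honors quantiles, overlap and gene joins", {
  mk_track <- function(values) {
    n <- length(values)
    popgenpipe:::new_window_track(data.frame(
      chrom = "chr1", start = (seq_len(n) - 1L) * 1000L + 1L,
      end = seq_len(n) * 1000L, value = values,
      n_sites_used = 1L, n_comparisons = NA_real_), "toy")
  }
  set.seed(76)
  base <- stats::runif(200)
  va <- base; vb <- stats::runif(200)
  planted <- c(13, 77, 150)
  va[planted] <- 10 + seq_along(planted)
  vb[planted] <- 20 + seq_along(planted)
  # quantile 0.015 keeps ceiling(3) top windows per track
  res <- top_intersect(mk_track(va), mk_track(vb), quantile = 0.015)
  expect_equal(sort(res$windows_a$start), sort((planted - 1L) * 1000L + 1L))
  expect_equal(nrow(res$intersection), 3L)
  expect_equal(sort(res$intersection$start), sort((planted - 1L) * 1000L + 1L))

  # identical tracks intersect to the top set itself
  res2 <- top_intersect(mk_track(va), mk_track(va), quantile = 0.015)
  expect_equal(nrow(res2$intersection), 3L)
  # disjoint top sets give an empty intersection
  vc <- base; vc[c(2, 50, 180)] <- 99
  res3 <- top_intersect(mk_track(va), mk_track(vc), quantile = 0.015)
  expect_equal(nrow(res3$intersection), 0L)

  # genes overlapping the intersection are listed
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(12500, 99000), c(12700, 99500)),
    Name = c("geneHit", "geneMiss"))
  res4 <- top_intersect(mk_track(va), mk_track(vb), quantile = 0.015,
                        gene_annotation = genes)
  expect_equal(res4$genes, "geneHit")
  expect_error(top_intersect(mk_track(va)[0, ], mk_track(vb)), "empty")
})
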