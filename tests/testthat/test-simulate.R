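test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_anc = 50, t_split = 15, n_x = 20, n_y = 25, mu = 2e-5,
                    L = 5000, n_chrom = 2, sample_x = 4, sample_y = 4,
                    seed = 13)
  s1 <- simulate_two_pops(cfg)
  s2 <- simulate_two_pops(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$genotypes$pos, s2$genotypes$pos)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_outputs(s1, d1); write_sim_outputs(s2, d2)
  for (f in c("simulated.vcf", "population_map.tsv", "annotation.gff3",
              "sim_truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # a different seed gives different data
  s3 <- simulate_two_pops(sim_config(n_anc = 50, t_split = 15, n_x = 20,
                                     n_y = 25, mu = 2e-5, L = 5000,
                                     n_chrom = 2, sample_x = 4, sample_y = 4,
                                     seed = 14))
  expect_false(identical(s1$genotypes$pos, s3$genotypes$pos))
})

test_that("emitted VCF re-reads to the in-memory matrix", {
  sim <- simulate_two_pops(sim_config(n_anc = 40, t_split = 10, n_x = 15,
                                      n_y = 15, mu = 2e-5, L = 4000,
                                      n_chrom = 1, sample_x = 3, sample_y = 3,
                                      seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_sim_outputs(sim, dir)
  back <- read_vcf(paths$vcf,
                   population_map = read_population_map(paths$popmap))
  expect_equal(back$dosage, sim$genotypes$dosage)
  expect_equal(back$hap1, sim$genotypes$hap1)
  expect_equal(back$pos, sim$genotypes$pos)
  expect_equal(unname(back$populations), unname(sim$genotypes$populations))
})

test_that("descendant bottleneck reduces diversity relative to the sister", {
  set.seed(91)
  wins <- 0L
  for (s in 1:6) {
    sim <- simulate_two_pops(sim_config(n_anc = 150, n_x = 12, n_y = 150,
                                        t_split = 80, mu = 5e-6, L = 3e4,
                                        n_chrom = 1, sample_x = 8,
                                        sample_y = 8, seed = s))
    gm <- subset_samples(sim$genotypes,
                         setdiff(sim$genotypes$samples, "outgroup"))
    pi_x <- genome_pi(windowed_pi(gm, "popX", 10000))
    pi_y <- genome_pi(windowed_pi(gm, "popY", 10000))
    if (pi_x < pi_y) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("no divergence means statistically exchangeable populations", {
  set.seed(92)
  sim <- simulate_two_pops(sim_config(n_anc = 200, t_split = 0, mu = 5e-6,
                                      L = 5e4, n_chrom = 1, sample_x = 10,
                                      sample_y = 10, seed = 6))
  gm <- subset_samples(sim$genotypes,
                       setdiff(sim$genotypes$samples, "outgroup"))
  fst <- wc_fst(gm, "popX", "popY", window_bp = 5e4)
  expect_lt(abs(fst$value), 0.05)
})

test_that("direct frequency sampling respects inbreeding", {
  set.seed(93)
  p <- rep(0.5, 600)
  g1 <- sample_from_freqs(p, p, 30, 5, f_x = 1, outgroup = FALSE)
  expect_equal(sum(g1$dosage[paste0("X", 1:30), ] == 1L), 0L)
  g0 <- sample_from_freqs(p, p, 30, 5, f_x = 0, outgroup = FALSE)
  het <- mean(g0$dosage[paste0("X", 1:30), ] == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / (30 * 600)) + 0.01)
  expect_error(sample_from_freqs(p, p[-1], 2, 2), "equal length")
})

test_that("planting ROH tracts is exact and respects fixed-alt sites", {
  set.seed(94)
  p <- stats::runif(50, 0.2, 0.8)
  p[7] <- 1  # fixed derived site
  gm <- sample_from_freqs(p, p, 3, 3, outgroup = FALSE)
  gm0 <- plant_roh(gm, "X1", data.frame(chrom = character(0),
                                        start = numeric(0), end = numeric(0)))
  expect_identical(gm0$dosage, gm$dosage)

  gm2 <- plant_roh(gm, "X1", data.frame(chrom = "chr1", start = 1, end = 2500))
  inside <- gm2$pos <= 2500
  expect_true(all(gm2$dosage["X1", inside] %in% c(0L, 2L)))
  expect_equal(unname(gm2$dosage["X1", 7]), 2L)  # fixed-alt site stays homozygous alt
  expect_identical(gm2$dosage["X2", ], gm$dosage["X2", ])
  expect_identical(gm2$dosage["X1", !inside], gm$dosage["X1", !inside])
  expect_equal(nrow(attr(gm2, "planted_roh")), 1L)

  expect_error(plant_roh(gm, "X1", data.frame(chrom = "chr1",
                                              start = c(1, 100),
                                              end = c(200, 300))),
               "overlapping")
  expect_error(plant_roh(gm, "nope", data.frame(chrom = "chr1", start = 1,
                                                end = 2)), "nope")
})

test_that("category annotation plants analytically known frequency shifts", {
  set.seed(95)
  p <- stats::runif(4000, 0.1, 0.9)
  ac <- annotate_categories(p, p,
                            fractions = c(synonymous = 0.5,
                                          tolerated_nonsynonymous = 0.3,
                                          deleterious = 0.2),
                            shift = list(deleterious = c(1, 0.5)))
  # multinomial category counts within 4 sigma
  counts <- table(ac$annotation$category)
  for (cat in c("synonymous", "tolerated_nonsynonymous", "deleterious")) {
    frac <- c(synonymous = 0.5, tolerated_nonsynonymous = 0.3,
              deleterious = 0.2)[[cat]]
    expect_lt(abs(counts[[cat]] - 4000 * frac), 4 * sqrt(4000 * frac))
  }
  # unshifted categories have true rxy 1; the shifted one is computable
  tr <- ac$truth
  expect_equal(tr$rxy[tr$category == "synonymous"], 1)
  del <- ac$annotation$category == "deleterious"
  fx <- ac$freqs_x[del]; fy <- ac$freqs_y[del]
  expect_equal(tr$rxy[tr$category == "deleterious"],
               sum(fx * (1 - fy)) / sum(fy * (1 - fx)))
  expect_gt(tr$rxy[tr$category == "deleterious"], 1)
  # deleterious SIFT scores sit strictly below the cutoff
  expect_true(all(ac$annotation$sift_score[del] < 0.05))

  expect_error(annotate_categories(p, p, shift = list(deleterious = c(-1, 1))),
               "negative")
  expect_error(annotate_categories(p, p, fractions = c(synonymous = 0.9,
                                                       deleterious = 0.2)),
               "sum")
})

test_that("equilibrium diversity approaches 4 N mu", {
  set.seed(96)
  pis <- vapply(1:3, function(s) {
    sim <- simulate_two_pops(sim_config(n_anc = 100, t_split = 0, mu = 5e-6,
                                        L = 5e4, n_chrom = 1, sample_x = 8,
                                        sample_y = 1, emit_invariant = TRUE,
                                        seed = s + 50))
    gm <- subset_samples(sim$genotypes, paste0("X", 1:8))
    gm$populations <- stats::setNames(rep("popX", 8), gm$samples)
    genome_pi(windowed_pi(gm, "popX", 10000))
  }, numeric(1))
  theta <- 4 * 100 * 5e-6
  expect_lt(abs(mean(pis) - theta) / theta, 0.3)
})
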