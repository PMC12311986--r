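pm_from_derived <- function(dd, pops, spacing = 100L) {
  # wrap a derived-dosage matrix (rows = samples) into a polarized matrix
  # by the standard route: append an all-ancestral outgroup and polarize
  d <- rbind(dd, outgroup = rep(0L, ncol(dd)))
  pops <- c(pops, outgroup = "outgroup")
  gm <- make_gm(d, pos = seq_len(ncol(dd)) * spacing,
                populations = pops[rownames(d)])
  infer_ancestral(gm, "outgroup")
}

ann_all <- function(n, category, spacing = 100L) {
  classify_variants(data.frame(chrom = "chr1", pos = seq_len(n) * spacing,
                               ref = "A", alt = "G", category = category,
                               stringsAsFactors = FALSE))
}

test_that("SIFT-based classification uses a strict 0.05 cutoff", {
  raw <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                    category = c("nonsynonymous", "nonsynonymous",
                                 "synonymous", "weird"),
                    sift_score = c(0.04, 0.05, NA, NA))
  ann <- classify_variants(raw)
  expect_equal(ann$category,
               c("deleterious", "tolerated_nonsynonymous", "synonymous",
                 "unannotated"))

  dup <- rbind(raw, transform(raw[1, ], sift_score = 0.9))
  expect_error(classify_variants(dup), "conflicting")
})

test_that("additive load counts each derived allele once", {
  # sample A: 2 hom-derived + 3 het deleterious sites -> load 7
  dd <- rbind(A = c(2L, 2L, 1L, 1L, 1L, 0L),
              B = c(0L, 0L, 1L, 2L, NA, 2L))
  pm <- pm_from_derived(dd, stats::setNames(c("p1", "p1"), c("A", "B")))
  ann <- ann_all(6, "deleterious")
  ld <- additive_load(pm, ann)
  expect_equal(ld$additive_load[ld$sample == "A"], 7L)
  expect_equal(ld$n_het[ld$sample == "A"], 3L)
  expect_equal(ld$n_hom_derived[ld$sample == "A"], 2L)
  # missing genotypes contribute nothing: B has 1 het + 2 hom = 5
  expect_equal(ld$additive_load[ld$sample == "B"], 5L)

  # all-ancestral sample scores zero in every category
  dd0 <- rbind(A = rep(0L, 4), B = c(1L, 1L, 2L, 0L))
  pm0 <- pm_from_derived(dd0, stats::setNames(c("p1", "p1"), c("A", "B")))
  ld0 <- additive_load(pm0, ann_all(4, rep(c("synonymous", "deleterious"), 2)))
  expect_true(all(ld0$additive_load[ld0$sample == "A"] == 0L))

  # invariance to site and sample order
  perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
  pmp <- pm_from_derived(dd[, perm], stats::setNames(c("p1", "p1"), c("A", "B")))
  annp <- ann_all(6, "deleterious")
  ldp <- additive_load(pmp, annp)
  expect_equal(ldp$additive_load[order(ldp$sample)],
               ld$additive_load[order(ld$sample)])

  expect_warning(additive_load(pm, ann, categories = "synonymous"), "synonymous")
})

test_that("rxy matches hand-evaluated frequency sums", {
  # popX: 2 diploids, popY: 2 diploids over 2 deleterious sites with
  # f_x = (0.5, 0.5) and f_y = (0.25, 0)
  dd <- rbind(X1 = c(2L, 1L), X2 = c(0L, 1L),
              Y1 = c(1L, 0L), Y2 = c(0L, 0L))
  pm <- pm_from_derived(dd, two_pop_map(2, 2))
  ann <- ann_all(2, "deleterious")
  r <- rxy(pm, ann, "popX", "popY", "deleterious", n_blocks = 2)
  expect_equal(r$freq_x, 0.5 * 0.75 + 0.5 * 1)     # 0.875
  expect_equal(r$freq_y, 0.25 * 0.5 + 0)           # 0.125
  expect_equal(r$rxy, 7)

  # single site fixed in x, absent in y: ratio undefined
  dd2 <- rbind(X1 = 2L, X2 = 2L, Y1 = 0L, Y2 = 0L)
  pm2 <- pm_from_derived(dd2, two_pop_map(2, 2))
  expect_error(rxy(pm2, ann_all(1, "deleterious"), "popX", "popY",
                   "deleterious", n_blocks = 2), "ratio undefined")
  expect_error(rxy(pm, ann, "popX", "popY", "nope"), "nope")
})

test_that("identical per-site frequencies give rxy of exactly 1", {
  set.seed(11)
  n_sites <- 20
  counts <- sample(0:9, n_sites, replace = TRUE)
  gt_from_counts <- function(k) {
    g <- integer(5)
    g[seq_len(k %/% 2)] <- 2L
    if (k %% 2) g[k %/% 2 + 1] <- 1L
    g
  }
  gx <- vapply(counts, gt_from_counts, integer(5))
  dd <- rbind(gx, gx)
  rownames(dd) <- c(paste0("X", 1:5), paste0("Y", 1:5))
  pm <- pm_from_derived(dd, two_pop_map(5, 5))
  r <- rxy(pm, ann_all(n_sites, "deleterious"), "popX", "popY",
           "deleterious", n_blocks = 5)
  expect_identical(r$rxy, 1)
  expect_true(r$ci_low <= 1 && r$ci_high >= 1)
})

test_that("rxy is antisymmetric and its CI brackets the point estimate", {
  set.seed(3)
  gm <- sample_from_freqs(stats::runif(300, 0.1, 0.9),
                          stats::runif(300, 0.1, 0.9), 6, 6)
  pm <- infer_ancestral(gm, "outgroup")
  ann <- ann_all(300, "synonymous")
  rxy_xy <- rxy(pm, ann, "popX", "popY", "synonymous", n_blocks = 20)
  rxy_yx <- rxy(pm, ann, "popY", "popX", "synonymous", n_blocks = 20)
  expect_equal(rxy_xy$rxy * rxy_yx$rxy, 1)
  expect_true(rxy_xy$ci_low <= rxy_xy$rxy && rxy_xy$rxy <= rxy_xy$ci_high)
  expect_equal(rxy_xy$n_sites + rxy_xy$n_excluded, 300)
})

test_that("permuting population labels drives rxy to 1 within its CI", {
  set.seed(17)
  hits <- 0L
  for (s in 1:5) {
    p <- stats::runif(400, 0.15, 0.85)
    gm <- sample_from_freqs(p, p, 8, 8)   # one pool, arbitrary labels
    pm <- infer_ancestral(gm, "outgroup")
    r <- rxy(pm, ann_all(400, "deleterious"), "popX", "popY",
             "deleterious", n_blocks = 25)
    if (r$ci_low <= 1 && 1 <= r$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("site policies and log-scale intervals behave", {
  dd <- rbind(X1 = c(2L, 0L, 1L), X2 = c(2L, 0L, 1L),
              Y1 = c(0L, 1L, 1L), Y2 = c(0L, 1L, 0L))
  pm <- pm_from_derived(dd, two_pop_map(2, 2))
  ann <- ann_all(3, "deleterious")
  r_all <- rxy(pm, ann, "popX", "popY", "deleterious", n_blocks = 2)
  r_priv <- rxy(pm, ann, "popX", "popY", "deleterious", n_blocks = 2,
                site_policy = "private")
  expect_equal(r_all$n_sites, 3)
  expect_equal(r_priv$n_sites, 2)   # third site segregates in both
  # log-scale CI stays positive and keeps the same point estimate
  set.seed(21)
  gm <- sample_from_freqs(stats::runif(200, 0.1, 0.9),
                          stats::runif(200, 0.1, 0.9), 5, 5)
  pml <- infer_ancestral(gm, "outgroup")
  annl <- ann_all(200, "deleterious")
  r_ratio <- rxy(pml, annl, "popX", "popY", "deleterious", n_blocks = 20)
  r_log <- rxy(pml, annl, "popX", "popY", "deleterious", n_blocks = 20,
               ci_scale = "log")
  expect_equal(r_log$rxy, r_ratio$rxy)
  expect_true(r_log$ci_low > 0)
})

test_that("between-population load comparison exposes both tests", {
  set.seed(8)
  dd <- rbind(matrix(sample(1:2, 80, TRUE), 4, 20),
              matrix(sample(0:1, 80, TRUE), 4, 20))
  rownames(dd) <- c(paste0("X", 1:4), paste0("Y", 1:4))
  pm <- pm_from_derived(dd, two_pop_map(4, 4))
  loads <- additive_load(pm, ann_all(20, "deleterious"))
  welch <- compare_load(loads, pm$base$populations, "popX", "popY",
                        "deleterious", test = "welch")
  mw <- compare_load(loads, pm$base$populations, "popX", "popY",
                     "deleterious", test = "mann-whitney")
  expect_s3_class(welch, "htest")
  expect_lt(welch$p.value, 0.05)
  expect_lt(mw$p.value, 0.05)
})
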