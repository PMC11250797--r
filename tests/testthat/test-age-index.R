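# PRC2-AgeIndex computation and companion statistics.

test_that("the index hits its bounds on all-0 and all-1 methylomes", {
  hp <- make_regions("chr1", c(0, 1000), c(500, 1500))
  m0 <- make_meth("chr1", c(100, 200, 1200), beta = c(0, 0, 0))
  m1 <- make_meth("chr1", c(100, 200, 1200), beta = c(1, 1, 1))
  expect_equal(compute_index(m0, hp)$index, 0)
  expect_equal(compute_index(m1, hp)$index, 1)
})

test_that("pooled_cpg and region_mean weightings differ as documented", {
  hp <- make_regions("chr1", c(0, 1000), c(500, 1500))
  m <- make_meth("chr1", c(100, 200, 1200), beta = c(0.2, 0.4, 0.6))
  expect_equal(compute_index(m, hp, "pooled_cpg")$index, 0.4)
  expect_equal(compute_index(m, hp, "region_mean")$index, 0.45)
  res <- compute_index(m, hp)
  expect_equal(res$n_regions_covered, 2)
  expect_equal(res$n_cpgs_used, 3)
})

test_that("uncovered regions are excluded and counted, not imputed", {
  hp <- make_regions("chr1", c(0, 5000), c(500, 6000))
  m <- make_meth("chr1", c(100, 200), beta = c(0.2, 0.4))
  res <- compute_index(m, hp)
  expect_equal(res$index, 0.3)
  expect_equal(res$n_regions_covered, 1)
  expect_error(compute_index(make_meth("chr2", 1, beta = 0.5), hp),
               "no covered CpG")
})

test_that("pooled index is invariant to region order and splitting", {
  set.seed(61)
  m <- make_meth("chr1", sort(sample.int(1e5, 500)), beta = runif(500))
  hp <- make_regions("chr1", c(0, 40000), c(30000, 90000))
  split_hp <- make_regions("chr1", c(0, 15000, 40000), c(15000, 30000, 90000))
  i1 <- compute_index(m, hp, "pooled_cpg")$index
  i2 <- compute_index(m, split_hp, "pooled_cpg")$index
  i3 <- compute_index(m, hp[2:1, ], "pooled_cpg")$index
  expect_equal(i2, i1)
  expect_equal(i3, i1)
})

test_that("adding a constant to every beta shifts the index by that constant", {
  set.seed(67)
  m <- make_meth("chr1", sort(sample.int(1e5, 300)), beta = runif(300, 0.1, 0.6))
  hp <- make_regions("chr1", 0, 1e5)
  base <- compute_index(m, hp)$index
  m2 <- m
  m2$sites$beta <- m$sites$beta + 0.3
  expect_equal(compute_index(m2, hp)$index, base + 0.3)
})

test_that("per-chromosome indices equal chromosome-restricted global indices", {
  set.seed(71)
  m <- make_meth(rep(c("chr1", "chr2"), each = 200),
                 c(sort(sample.int(1e5, 200)), sort(sample.int(1e5, 200))),
                 beta = runif(400))
  hp <- make_regions(c("chr1", "chr1", "chr2"), c(0, 50000, 0),
                     c(40000, 90000, 80000))
  pc <- per_chromosome_index(m, hp)
  expect_setequal(names(pc), c("chr1", "chr2"))
  for (ch in names(pc)) {
    expect_equal(pc[[ch]],
                 compute_index(m, hp[hp$chrom == ch, ])$index)
  }
  # a set confined to one chromosome reproduces the global index
  hp1 <- hp[hp$chrom == "chr1", ]
  expect_equal(unname(per_chromosome_index(m, hp1)),
               compute_index(m, hp1)$index)
})

test_that("uniform methylation gives a flat per-chromosome map", {
  m <- make_meth(rep(c("chr1", "chr2"), each = 50),
                 rep(1:50 * 100, 2), beta = rep(0.5, 100))
  hp <- make_regions(c("chr1", "chr2"), c(0, 0), c(6000, 6000))
  pc <- per_chromosome_index(m, hp)
  expect_true(all(abs(pc - 0.5) < 1e-12))
})

test_that("ranked profile reduces to per-region means at window 1", {
  set.seed(73)
  m <- make_meth("chr1", sort(sample.int(1e5, 400)), beta = runif(400))
  regions <- random_regions(30, span = 1e5, min_len = 500, max_len = 3000)
  regions$prc2_score <- runif(nrow(regions))
  regions$rank <- order(order(-regions$prc2_score))
  prof <- ranked_profile(m, regions, window = 1, step = 1)
  scored <- score_regions(regions, m)
  expect_equal(prof$values,
               scored$mean_level[order(regions$rank, decreasing = TRUE)])
})

test_that("ranked profile is flat on a constant methylome", {
  m <- make_meth("chr1", 1:500 * 100, beta = rep(0.5, 500))
  regions <- make_regions("chr1", (0:19) * 2000, (0:19) * 2000 + 1500)
  regions$rank <- sample(20)
  prof <- ranked_profile(m, regions, window = 5, step = 2)
  expect_true(all(abs(prof$values - 0.5) < 1e-12))
  expect_equal(length(prof$values), floor((20 - 5) / 2) + 1)
})

test_that("ranked profile matches brute-force windowed means", {
  set.seed(79)
  m <- make_meth("chr1", sort(sample.int(5e5, 2000)), beta = runif(2000))
  regions <- random_regions(120, span = 5e5, min_len = 300, max_len = 2000)
  regions$rank <- sample(nrow(regions))
  prof <- ranked_profile(m, regions, window = 50, step = 10)
  vals <- score_regions(regions, m)$mean_level
  vals <- vals[order(regions$rank, decreasing = TRUE)]
  n_win <- floor((nrow(regions) - 50) / 10) + 1
  oracle <- vapply(seq_len(n_win), function(i) {
    mean(vals[((i - 1) * 10 + 1):((i - 1) * 10 + 50)], na.rm = TRUE)
  }, numeric(1))
  expect_equal(prof$values, oracle, tolerance = 1e-12)
})

test_that("profile with window = step = N equals the region_mean index", {
  set.seed(83)
  m <- make_meth("chr1", sort(sample.int(1e5, 500)), beta = runif(500))
  regions <- random_regions(25, span = 1e5, min_len = 500, max_len = 2000)
  regions$rank <- sample(nrow(regions))
  prof <- ranked_profile(m, regions, window = nrow(regions),
                         step = nrow(regions))
  expect_equal(length(prof$values), 1)
  expect_equal(prof$values, compute_index(m, regions, "region_mean")$index)
})

test_that("profile rejects bad windows", {
  m <- make_meth("chr1", 1:50 * 100, beta = rep(0.5, 50))
  regions <- make_regions("chr1", c(0, 2000), c(1000, 3000), rank = 1:2)
  expect_error(ranked_profile(m, regions, window = 0, step = 1), "positive")
  expect_error(ranked_profile(m, regions, window = 1, step = -1), "positive")
  expect_error(ranked_profile(m, regions, window = 5, step = 1), "exceeds")
})

test_that("delta is zero for identical samples and additive otherwise", {
  regions <- make_regions("chr1", 0, 1000)
  m <- make_meth("chr1", c(100, 200), beta = c(0.3, 0.5))
  d <- delta_dnam(regions, m, m)
  expect_equal(d$delta, 0)

  young <- make_meth("chr1", 100, beta = 0.1)
  old <- make_meth("chr1", 100, beta = 0.3)
  d <- delta_dnam(regions, young, old)
  expect_equal(d$delta, 0.2)
})

test_that("regions covered in only one sample are dropped and counted", {
  regions <- make_regions("chr1", c(0, 5000), c(1000, 6000))
  young <- make_meth("chr1", c(100, 5100), beta = c(0.1, 0.2))
  old <- make_meth("chr1", 100, beta = 0.3)
  d <- delta_dnam(regions, young, old)
  expect_equal(nrow(d), 1)
  expect_equal(attr(d, "n_dropped"), 1)
})

test_that("planted target regions show positive deltas at coverage 30", {
  sim <- small_sim()
  young <- simulate_methylome(sim$layout, 20, seed = 201)
  old <- simulate_methylome(sim$layout, 80, seed = 202)
  targets <- sim$layout$lmrs[sim$layout$lmrs$is_target, ]
  d <- delta_dnam(targets, young, old)
  expect_gte(fraction_hypermethylated(d), 0.9)
})

test_that("hypermethylated fraction counts strictly positive deltas", {
  expect_equal(fraction_hypermethylated(c(0.1, -0.05, 0.2)), 2 / 3)
  expect_equal(fraction_hypermethylated(c(0, 0, 0)), 0)
  set.seed(89)
  d <- rnorm(1000)
  expect_equal(fraction_hypermethylated(d), sum(d > 0) / 1000)
  expect_equal(fraction_hypermethylated(d, subset = 1:100),
               sum(d[1:100] > 0) / 100)
  expect_error(fraction_hypermethylated(numeric(0)), "no deltas")
})

test_that("gain share hits its bounds in constructed scenarios", {
  hp <- make_regions("chr1", 0, 1000)
  lmrs <- make_regions("chr1", c(0, 5000), c(1000, 6000))
  # all gain inside the set
  young <- make_meth("chr1", c(100, 5100), beta = c(0.1, 0.5))
  old <- make_meth("chr1", c(100, 5100), beta = c(0.4, 0.5))
  gs <- gain_share(young, old, hp, lmrs)
  expect_equal(gs$share, 1.0)
  # no gain inside the set
  old2 <- make_meth("chr1", c(100, 5100), beta = c(0.1, 0.9))
  expect_equal(gain_share(young, old2, hp, lmrs)$share, 0.0)
  # losses everywhere -> error
  old3 <- make_meth("chr1", c(100, 5100), beta = c(0.0, 0.1))
  expect_error(gain_share(young, old3, hp, lmrs), "no methylation gain")
})

test_that("LMR scope restricts the gain denominator to the LMR complement", {
  hp <- make_regions("chr1", 0, 1000)
  lmrs <- make_regions("chr1", c(0, 5000), c(1000, 6000))
  young <- make_meth("chr1", c(100, 5100, 9000), beta = c(0.1, 0.2, 0.5))
  old <- make_meth("chr1", c(100, 5100, 9000), beta = c(0.3, 0.3, 0.8))
  genome <- gain_share(young, old, hp, lmrs, scope = "genome")
  lmr <- gain_share(young, old, hp, lmrs, scope = "lmrs")
  expect_equal(genome$share, 0.2 / 0.6)
  expect_equal(lmr$share, 0.2 / 0.3)
})
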