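# ChIP-signal aggregation, blacklist filtering, top-k selection and the
# site-level LMC variant.

test_that("aggregate_binding reproduces constant and multi-factor means", {
  r <- make_regions("chr1", 100, 200)
  tr <- make_track("chr1", 0, 1000, 2.5)
  scored <- aggregate_binding(r, tr)
  expect_equal(scored$score_factor1, 2.5)
  expect_equal(scored$prc2_score, 2.5)

  two <- list(ezh2 = make_track("chr1", 0, 1000, 1.0),
              suz12 = make_track("chr1", 0, 1000, 3.0))
  scored <- aggregate_binding(r, two)
  expect_equal(scored$score_ezh2, 1.0)
  expect_equal(scored$score_suz12, 3.0)
  expect_equal(scored$prc2_score, 2.0)
})

test_that("uncovered bases pad with 0 (fold change) or 1 (p-value)", {
  r <- make_regions("chr1", 0, 100)
  half_fc <- make_track("chr1", 0, 50, 2)
  expect_equal(aggregate_binding(r, half_fc)$prc2_score, 1.0)
  half_p <- make_track("chr1", 0, 50, 0.2, semantics = "p_value")
  expect_equal(aggregate_binding(r, half_p)$prc2_score, (0.2 * 50 + 50) / 100)
})

test_that("aggregate_binding matches the per-base oracle on random input", {
  set.seed(23)
  n_iv <- 300
  starts <- sort(sample.int(1e6, n_iv))
  ends <- pmin(starts + sample(20:500, n_iv, TRUE), c(starts[-1], Inf))
  keep <- starts < ends
  tr <- make_track("chr1", starts[keep], ends[keep],
                   runif(sum(keep), 0, 5))
  regions <- random_regions(100)
  scored <- aggregate_binding(regions, tr)
  for (i in seq_len(nrow(regions))) {
    expect_equal(scored$score_factor1[i],
                 oracle_track_mean(tr, regions$chrom[i], regions$start[i],
                                   regions$end[i]),
                 tolerance = 1e-9)
  }
})

test_that("aggregate_binding is linear in a fold-change track", {
  set.seed(29)
  tr <- make_track("chr1", c(0, 500, 2000), c(400, 1500, 2600),
                   c(1.2, 3.4, 0.7))
  tr_scaled <- tr
  tr_scaled$intervals$value <- tr$intervals$value * 3
  regions <- random_regions(20, span = 3000, min_len = 50, max_len = 500)
  s1 <- aggregate_binding(regions, tr)$prc2_score
  s3 <- aggregate_binding(regions, tr_scaled)$prc2_score
  expect_equal(s3, 3 * s1)
})

test_that("mixed semantics across tracks is an error", {
  r <- make_regions("chr1", 0, 100)
  expect_error(aggregate_binding(r, list(make_track("chr1", 0, 100, 2),
                                         make_track("chr1", 0, 100, 0.5,
                                                    semantics = "p_value"))),
               "semantics")
})

test_that("blacklist filtering removes any 1-bp overlap and keeps the rest", {
  r <- make_regions("chr1", c(100, 100), c(200, 200))
  expect_equal(nrow(filter_blacklist(r[1, ], make_regions("chr1", 300, 400))), 1)
  expect_equal(nrow(filter_blacklist(r[1, ], make_regions("chr1", 150, 160))), 0)

  set.seed(31)
  regions <- random_regions(200, span = 5e5)
  bl <- random_regions(50, span = 5e5)
  kept <- filter_blacklist(regions, bl)
  oracle_keep <- !oracle_overlaps_any(regions, bl)
  expect_equal(kept, regions[oracle_keep, ], ignore_attr = TRUE)
})

test_that("default selection keeps the top 1000 regions", {
  cfg <- selection_config()
  expect_equal(cfg$k, 1000L)
  set.seed(5)
  regions <- random_regions(1500, span = 5e6)
  regions$prc2_score <- runif(nrow(regions))
  regions$rank <- order(order(-regions$prc2_score))
  attr(regions, "semantics") <- "fold_change"
  hp <- select_top_k(regions, cfg)
  expect_equal(nrow(hp), 1000)
})

test_that("top-k selection follows the declared semantics and tie-break", {
  r <- make_regions("chr1", c(0, 100, 200), c(50, 150, 250))
  r$prc2_score <- c(5, 3, 9)
  attr(r, "semantics") <- "fold_change"
  hp <- select_top_k(r, selection_config(k = 2))
  expect_equal(hp$prc2_score, c(9, 5))

  attr(r, "semantics") <- "p_value"
  hp <- select_top_k(r, selection_config(k = 2, semantics = "p_value"))
  expect_equal(hp$prc2_score, c(3, 5))
})

test_that("top-k membership matches a full-sort oracle and ignores input order", {
  set.seed(37)
  regions <- random_regions(500, span = 2e6)
  regions$prc2_score <- round(runif(nrow(regions)), 2)  # forces ties
  attr(regions, "semantics") <- "fold_change"
  hp <- select_top_k(regions, selection_config(k = 100))

  o <- order(-regions$prc2_score, regions$chrom, regions$start)
  oracle <- regions[o[1:100], ]
  expect_equal(hp$start, oracle$start)

  shuffled <- regions[sample.int(nrow(regions)), ]
  attr(shuffled, "semantics") <- "fold_change"
  hp2 <- select_top_k(shuffled, selection_config(k = 100))
  expect_equal(hp2$start, hp$start)
})

test_that("select_top_k warns when k exceeds N and errors on empty input", {
  r <- make_regions("chr1", c(0, 100), c(50, 150))
  r$prc2_score <- c(1, 2)
  attr(r, "semantics") <- "fold_change"
  expect_warning(hp <- select_top_k(r, selection_config(k = 10)), "exceeds")
  expect_equal(nrow(hp), 2)
  expect_error(select_top_k(r[0, ], selection_config()), "empty")
})

test_that("LMC ranking filters by baseline beta and orders by signal", {
  ref <- make_meth("chr1", c(100, 200), beta = c(0.1, 0.6))
  tr <- make_track("chr1", 0, 1000, 2)
  rs <- rank_lmcs(ref, tr, low_threshold = 0.3)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$pos, 100L)

  ref <- make_meth("chr1", c(100, 200, 300), beta = c(0.1, 0.1, 0.1))
  tr <- make_track("chr1", c(50, 150, 250), c(150, 250, 350),
                   c(0.2, 5.0, 1.1))
  rs <- rank_lmcs(ref, tr, low_threshold = 0.3)
  expect_equal(rs$pos, c(200L, 300L, 100L))   # by decreasing signal
  expect_equal(rs$rank, 1:3)

  expect_error(rank_lmcs(make_meth("chr1", 1, beta = 0.9), tr, 0.3),
               "threshold")
})

test_that("LMC ranking matches a brute-force filter-and-sort oracle", {
  set.seed(41)
  n <- 1000
  pos <- sort(sample.int(5e5, n))
  ref <- make_meth("chr1", pos, beta = runif(n))
  n_iv <- 400
  ivs <- sort(sample.int(5e5, n_iv))
  ive <- pmin(ivs + sample(50:300, n_iv, TRUE), c(ivs[-1], Inf))
  keep <- ivs < ive
  tr <- make_track("chr1", ivs[keep], ive[keep], runif(sum(keep), 0, 4))
  rs <- rank_lmcs(ref, tr, low_threshold = 0.3)

  sig <- vapply(pos, function(p) {
    hit <- tr$intervals$start <= p & tr$intervals$end > p
    if (any(hit)) tr$intervals$value[hit][1] else 0
  }, numeric(1))
  o_keep <- ref$sites$beta < 0.3
  o <- order(-sig[o_keep], pos[o_keep])
  expect_equal(rs$pos, pos[o_keep][o])
  expect_equal(rs$signal, sig[o_keep][o])
})

test_that("baseline beta averages across multiple reference methylomes", {
  r1 <- make_meth("chr1", c(100, 200), beta = c(0.1, 0.5))
  r2 <- make_meth("chr1", c(100, 200), beta = c(0.3, 0.7))
  tr <- make_track("chr1", 0, 1000, 1)
  rs <- rank_lmcs(list(r1, r2), tr, low_threshold = 0.3)
  expect_equal(rs$pos, 100L)
  expect_equal(rs$ref_beta, 0.2)
})

test_that("density filtering keeps only CpG-dense elements", {
  r <- make_regions("chr1", c(0, 5000), c(3000, 8000),
                    n_cpgs = c(60L, 6L))
  kept <- density_filter(r, min_cpgs_per_kb = 10)
  expect_equal(kept$start, 0)

  set.seed(43)
  regions <- random_regions(50, span = 2e5)
  regions$n_cpgs <- sample(0:100, nrow(regions), TRUE)
  kept <- density_filter(regions, min_cpgs_per_kb = 10)
  oracle <- regions$n_cpgs / ((regions$end - regions$start) / 1000) >= 10
  expect_equal(kept, regions[oracle, ], ignore_attr = TRUE)
})

test_that("rank concordance is 1 for identical sets and 0 for disjoint sets", {
  set.seed(47)
  a <- random_regions(50, span = 2e5)
  a$rank <- seq_len(nrow(a))
  cc <- rank_concordance(a, a)
  expect_equal(cc$overlap, 1.0)
  expect_equal(cc$rank_cor, 1.0)

  b <- a
  b$start <- a$start + 3e5
  b$end <- a$end + 3e5
  expect_equal(rank_concordance(a, b)$overlap, 0.0)
})

test_that("rank concordance overlap matches an all-pairs oracle", {
  set.seed(53)
  base <- random_regions(80, span = 4e5)
  base$prc2_score <- runif(nrow(base), 1, 10)
  attr(base, "semantics") <- "fold_change"
  a <- select_top_k(base, selection_config(k = 40))
  noisy <- base
  noisy$prc2_score <- base$prc2_score + rnorm(nrow(base), 0, 1)
  noisy$prc2_score <- pmax(noisy$prc2_score, 0)
  attr(noisy, "semantics") <- "fold_change"
  b <- select_top_k(noisy, selection_config(k = 40))
  cc <- rank_concordance(a, b)
  expect_equal(cc$overlap, mean(oracle_overlaps_any(a, b)))
})
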