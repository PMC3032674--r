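pairs_df <- function(deep, bulk, coverage = 200) {
  data.frame(sample = "S1", locus = "L1", cpg_index = seq_along(deep),
             level_deep = deep, level_bulk = bulk,
             coverage_deep = rep_len(coverage, length(deep)))
}

test_that("pairing joins on shared keys and logs exclusions", {
  deep <- data.frame(sample = rep(c("S1", "S2"), each = 3),
                     locus = "L1", cpg_index = rep(1:3, 2),
                     level_pct = c(10, 20, 30, NA, 50, 60),
                     coverage = c(100, 100, 100, 0, 80, 80),
                     low_coverage = rep(c(FALSE, TRUE), each = 3))
  bulk <- data.frame(sample = rep(c("S1", "S2"), each = 3),
                     locus = "L1", cpg_index = rep(1:3, 2),
                     level_pct = c(12, 18, 33, 40, 52, 61))
  pr <- pair_measurements(deep, bulk)
  expect_identical(nrow(pr), 3L)            # S2 bin is low-coverage
  expect_identical(pr$level_deep, c(10, 20, 30))
  excl <- attr(pr, "excluded")
  expect_identical(nrow(excl), 3L)
  expect_true(all(excl$reason == "low_coverage"))
  # keeping low-coverage bins still drops the no-coverage site
  pr2 <- pair_measurements(deep, bulk, drop_low_coverage = FALSE)
  expect_identical(nrow(pr2), 5L)
  expect_identical(attr(pr2, "excluded")$reason, "no_coverage")
  # order-independence of the join
  pr3 <- pair_measurements(deep[sample(6), ], bulk[sample(6), ])
  expect_equal(pr, pr3, ignore_attr = TRUE)
  # disjoint keys
  bulk2 <- transform(bulk, locus = "other")
  expect_error(pair_measurements(deep, bulk2), "no overlapping")
})

test_that("Bland-Altman statistics match closed forms", {
  p0 <- pairs_df(c(10, 20, 30), c(10, 20, 30))
  ba0 <- bland_altman(p0)
  expect_identical(ba0$mean_diff, 0)
  expect_identical(ba0$lower_95, 0)
  expect_identical(ba0$upper_95, 0)
  ba <- bland_altman(c(-2, 0, 2))
  expect_identical(ba$mean_diff, 0)
  expect_identical(ba$sd_diff, 2)
  expect_equal(ba$lower_95, -3.92)
  expect_equal(ba$upper_95, 3.92)
  expect_error(bland_altman(c(1, 2)), "at least 3")
  # the tolerance-interval variant is wider than the plug-in band
  bt <- bland_altman(pairs_df(c(1, 5, 9, 2), c(2, 3, 8, 1)),
                     method = "tolerance")
  bl <- bland_altman(pairs_df(c(1, 5, 9, 2), c(2, 3, 8, 1)))
  expect_gt(bt$upper_95, bl$upper_95)
})

test_that("regression matches hand-computed normal equations", {
  x <- c(0, 25, 50, 75, 100)
  p <- pairs_df(x, x)
  r <- regression(p)
  expect_equal(r$slope, 1)
  expect_equal(r$r2, 1)
  # five-point toy set, coefficients from the normal equations
  xb <- c(10, 20, 40, 60, 90)
  yd <- c(8, 25, 35, 66, 84)
  sxx <- sum((xb - mean(xb))^2)
  sxy <- sum((xb - mean(xb)) * (yd - mean(yd)))
  slope <- sxy / sxx
  intercept <- mean(yd) - slope * mean(xb)
  r2 <- sxy^2 / (sxx * sum((yd - mean(yd))^2))
  rt <- regression(pairs_df(yd, xb))
  expect_equal(rt$slope, slope)
  expect_equal(rt$intercept, intercept)
  expect_equal(rt$r2, r2)
  expect_true(rt$slope_ci_low < slope && slope < rt$slope_ci_high)
  # through-origin mode: slope = sum(xy) / sum(x^2)
  ro <- regression(pairs_df(yd, xb), through_origin = TRUE)
  expect_equal(ro$slope, sum(xb * yd) / sum(xb^2))
  expect_true(is.na(ro$intercept))
  expect_error(regression(pairs_df(yd, rep(50, 5))), "zero variance")
})

test_that("congruence fractions count strict deviation thresholds", {
  cf <- congruence_fractions(c(1, -4, 6, -11))
  expect_identical(cf$n_within, c(1L, 2L, 3L))
  expect_identical(cf$pct_within, c(25.0, 50.0, 75.0))
  cf0 <- congruence_fractions(rep(0, 8))
  expect_true(all(cf0$pct_within == 100))
  # monotone in the threshold for arbitrary inputs
  set.seed(1)
  for (i in 1:20) {
    d <- rnorm(50, 0, runif(1, 1, 15))
    f <- congruence_fractions(d)$pct_within
    expect_true(all(diff(f) >= 0))
  }
  expect_error(congruence_fractions(numeric()), "at least 1")
})

test_that("coverage threshold is the lowest coverage with all pairs in band", {
  # all pairs inside the band -> threshold is the minimum coverage
  # (uniform differences never stray past 1.96 sample SDs from the mean)
  set.seed(2)
  p <- pairs_df(50 + runif(40, -1, 1), rep(50, 40),
                coverage = sample(100:500, 40))
  cc <- coverage_vs_congruence(p)
  expect_identical(cc$coverage_threshold, min(p$coverage_deep))
  # one wild pair at coverage 170, everything at >= 175 inside
  p2 <- pairs_df(c(50 + rnorm(30, 0, 1), 80), rep(50, 31),
                 coverage = c(seq(175, 465, 10), 170))
  cc2 <- coverage_vs_congruence(p2)
  expect_identical(cc2$coverage_threshold, 175)
  expect_false(all(cc2$table$in_band))
  # out-of-band point at the maximum coverage -> no threshold exists
  p3 <- pairs_df(c(50 + rnorm(30, 0, 1), 90), rep(50, 31),
                 coverage = c(seq(100, 390, 10), 400))
  expect_true(is.na(coverage_vs_congruence(p3)$coverage_threshold))
})

test_that("yield correlation follows the Pearson formula", {
  anti <- data.frame(length = c(100, 150, 200, 250),
                     mean_reads = c(400, 300, 200, 100))
  expect_equal(correlate_yield(anti)$r, -1)
  expect_error(correlate_yield(data.frame(length = c(1, 2, 3),
                                          mean_reads = c(5, 5, 5))),
               "zero variance")
  expect_error(correlate_yield(anti[1:2, ]), "at least 3")
  # six-point toy table against the explicit formula
  tab <- data.frame(length = c(120, 150, 180, 210, 250, 312),
                    mean_reads = c(420, 380, 350, 260, 170, 2))
  n <- nrow(tab)
  num <- sum(tab$length * tab$mean_reads) -
    n * mean(tab$length) * mean(tab$mean_reads)
  den <- sqrt((sum(tab$length^2) - n * mean(tab$length)^2) *
              (sum(tab$mean_reads^2) - n * mean(tab$mean_reads)^2))
  expect_equal(correlate_yield(tab)$r, num / den)
})

test_that("the concordance report assembles coherent statistics", {
  set.seed(9)
  x <- runif(120, 0, 100)
  p <- pairs_df(0.95 * x + rnorm(120, 0, 2), x,
                coverage = sample(150:400, 120, TRUE))
  rep <- concordance_report(p)
  expect_identical(rep$n_pairs, 120L)
  expect_true(rep$bland_altman$lower_95 <= rep$bland_altman$mean_diff)
  expect_true(rep$bland_altman$mean_diff <= rep$bland_altman$upper_95)
  expect_true(all(diff(rep$congruence$pct_within) >= 0))
  expect_gt(rep$regression$r2, 0.9)
})
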