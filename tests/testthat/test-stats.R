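test_that("AHA 16-segment labelling follows the standard geometry", {
  n <- 81
  g <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(g^2, g^2, "+"))
  ring <- r >= 12 & r <= 20
  lab <- aha16_labels(ring, slice_level = "basal", rv_insertion_deg = 0)
  tab <- table(lab)
  expect_setequal(as.integer(names(tab)), 1:6)
  # symmetric ring: six equal sectors (up to rasterization of the boundary)
  expect_lt(diff(range(tab)) / mean(tab), 0.1)
  # rotating the insertion by 60 degrees permutes labels cyclically
  lab2 <- aha16_labels(ring, slice_level = "basal", rv_insertion_deg = 60)
  shifted <- ifelse(is.na(lab), NA, (lab - 1 - 1) %% 6 + 1)
  expect_equal(lab2[!is.na(lab2)], shifted[!is.na(shifted)])
  # apical level has 4 sectors labelled 13..16
  lab3 <- aha16_labels(ring, slice_level = "apical")
  expect_setequal(unique(lab3[!is.na(lab3)]), 13:16)
  # a wedge at known angle lands in the predicted segment
  ang <- atan2(outer(rep(1, n), g), outer(g, rep(1, n))) * 180 / pi
  wedge <- ring & ((ang - 10) %% 360) < 20
  labw <- aha16_labels(ring, slice_level = "mid", rv_insertion_deg = 0)
  expect_true(all(labw[wedge] == 7))
  # a filled disk is rejected
  expect_error(aha16_labels(r <= 20), "not annular")
})

test_that("ICC(A,1) matches an independent aov mean-squares oracle", {
  # identity
  expect_equal(icc_two_way(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # constant offset: absolute agreement below consistency
  x <- c(10, 12, 15, 20, 24)
  y <- x + 50
  expect_lt(icc_two_way(x, y), icc_consistency(x, y))
  # worked table vs the aov decomposition
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(8, 100, 15)
    y <- x + rnorm(8, 2, 3)
    n <- length(x)
    df <- data.frame(val = c(x, y),
                     subj = factor(rep(seq_len(n), 2)),
                     meth = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(val ~ subj + meth, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    oracle <- (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
    expect_equal(icc_two_way(x, y), oracle, tolerance = 1e-10)
  }
  expect_error(icc_two_way(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("Bland-Altman limits follow the 1.96 sd convention", {
  x <- c(1, 2, 3, 4)
  expect_equal(unname(bland_altman(x, x)), c(0, 0, 0))
  # differences {-1, 1}: bias 0, LoA at +-1.96*sqrt(2)
  ba <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(unname(ba["bias"]), 0)
  expect_equal(unname(ba["loa_high"]), 1.96 * sqrt(2))
  # antisymmetric under argument swap
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(unname(bland_altman(a, b)["bias"]),
               -unname(bland_altman(b, a)["bias"]))
})

test_that("CoV uses two-point sd, RMS aggregation, and is scale invariant", {
  expect_equal(cov_rms(c(1000, 1200), c(1000, 1200)), 0)
  # single subject with global means 1000 and 1100:
  # sd = 100/sqrt(2) = 70.71, mean 1050 -> 6.73%
  cv <- cov_rms(1000, 1100)
  expect_equal(cv, 100 * (100 / sqrt(2)) / 1050, tolerance = 1e-12)
  expect_equal(round(cv, 2), 6.73)
  set.seed(5)
  s1 <- matrix(rnorm(40, 1200, 50), 5)
  s2 <- s1 + rnorm(40, 0, 30)
  expect_equal(cov_rms(2 * s1, 2 * s2, "segmentwise"),
               cov_rms(s1, s2, "segmentwise"), tolerance = 1e-12)
  expect_equal(cov_rms(2 * s1[, 1], 2 * s2[, 1]), cov_rms(s1[, 1], s2[, 1]),
               tolerance = 1e-12)
  # subject permutation invariance
  p <- sample(5)
  expect_equal(cov_rms(s1[p, ], s2[p, ], "segmentwise"),
               cov_rms(s1, s2, "segmentwise"), tolerance = 1e-12)
  expect_error(cov_rms(s1, s2[, 1:3], "segmentwise"), "mismatch")
})

test_that("SNR efficiency reproduces the worked values", {
  expect_equal(round(snr_efficiency(11.9, 3), 1), 6.9)
  expect_equal(round(snr_efficiency(6.0, 4.5), 1), 2.8)
  # zero-variance segment is flagged and excluded
  n <- 81
  g <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(g^2, g^2, "+"))
  ring <- r >= 12 & r <= 20
  lab <- aha16_labels(ring, slice_level = "basal")
  set.seed(1)
  map <- matrix(rnorm(n * n, 1200, 60), n)
  map[!is.na(lab) & lab == 3] <- 1200       # constant segment
  expect_warning(st <- snr_stats(map, lab, 3), "zero variance")
  expect_true(st$segments$flagged[st$segments$segment == 3])
  expect_false(any(st$segments$flagged[st$segments$segment != 3]))
  expect_true(is.finite(st$mean_snr_eff))
})

test_that("linear_fit matches the closed-form least squares", {
  # exact line
  lf <- linear_fit(1:10, 2 * (1:10) + 3)
  expect_equal(unname(lf), c(2, 3, 1))
  # 5-point worked set vs closed form
  x <- c(1, 2, 4, 7, 9); y <- c(2.1, 3.9, 8.3, 13.8, 18.2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(unname(linear_fit(x, y)), c(b, a, r2), tolerance = 1e-12)
  # r2 invariant to axis scaling
  expect_equal(unname(linear_fit(10 * x, 0.1 * y)["r2"]), r2,
               tolerance = 1e-12)
})
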