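# build complex voxel curves from known tissue parameters
synth_curves <- function(dict, tissues, phase = 0.7, noise_sd = 0,
                         seed = 1) {
  nn <- length(dict$n_grid); nk <- nrow(dict$combos)
  cv <- array(0i, dim = c(length(tissues), nn, nk))
  for (v in seq_along(tissues)) {
    tis <- tissues[[v]]
    s <- unlist(lapply(seq_len(nk), function(k)
      signal_curve(tis, dict$combos$prep_ms[k], dict$combos$flip_deg[k],
                   dict$combos$prev_flip_deg[k], dict$tr_ms,
                   n = dict$n_grid)))
    cv[v, , ] <- s * exp(1i * phase)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    cv <- cv + complex(real = rnorm(length(cv), sd = noise_sd),
                       imaginary = rnorm(length(cv), sd = noise_sd))
  }
  cv
}

fit_dict <- function() {
  if (is.null(.sim_cache$fit_dict)) {
    sch <- build_schedule(seq_config(n_periods = 10))
    .sim_cache$fit_dict <- build_dictionary(sch, grids = list(
      t1_ms = exp(seq(log(100), log(3000), length.out = 15)),
      t2_ms = exp(seq(log(10), log(3000), length.out = 15)),
      b1 = seq(0.7, 1.3, length.out = 5),
      eff = seq(-1, -0.7, length.out = 4)))
  }
  .sim_cache$fit_dict
}

test_that("noiseless grid-point curves are matched exactly", {
  d <- fit_dict()
  g <- d$grid
  picks <- list(c(8, 5, 3, 1), c(10, 4, 2, 4), c(5, 7, 5, 2))
  tissues <- lapply(picks, function(p)
    tissue_params(amp = 1.3, eff = g$eff[p[4]], b1 = g$b1[p[3]],
                  t1_ms = g$t1_ms[p[1]], t2_ms = g$t2_ms[p[2]]))
  cv <- synth_curves(d, tissues)
  s1 <- fit_step1(cv, d, refine = FALSE)
  for (i in seq_along(picks)) {
    expect_equal(s1$t2_ms[i], g$t2_ms[picks[[i]][2]], tolerance = 1e-10)
    expect_equal(s1$b1[i], g$b1[picks[[i]][3]], tolerance = 1e-10)
    expect_equal(s1$eff[i], g$eff[picks[[i]][4]], tolerance = 1e-10)
  }
  # all-zero curve flagged unfittable
  cv0 <- cv; cv0[1, , ] <- 0i
  s0 <- fit_step1(cv0, d, refine = FALSE)
  expect_true(s0$flag[1])
  expect_true(is.na(s0$t2_ms[1]))
})

test_that("off-grid tissue is refined to within 1% and T1 recovered", {
  d <- fit_dict()
  tis <- tissue_params(amp = 0.9, eff = -0.9, b1 = 1.1, t1_ms = 1200,
                       t2_ms = 42)
  cv <- synth_curves(d, list(tis))
  s1 <- fit_step1(cv, d, refine = TRUE)
  expect_lt(abs(s1$t2_ms[1] - 42) / 42, 0.01)
  expect_lt(abs(s1$b1[1] - 1.1), 0.02)
  t1 <- fit_step2(cv, s1, d)
  expect_lt(abs(t1[1] - 1200) / 1200, 0.01)
})

test_that("step 2 is exact at a grid point with ideal preparation", {
  d <- fit_dict()
  g <- d$grid
  tis <- tissue_params(amp = 1, eff = -1, b1 = 1,
                       t1_ms = g$t1_ms[8], t2_ms = g$t2_ms[6])
  cv <- synth_curves(d, list(tis))
  s1 <- fit_step1(cv, d, refine = TRUE)
  t1 <- fit_step2(cv, s1, d)
  expect_lt(abs(t1[1] - g$t1_ms[8]) / g$t1_ms[8], 1e-3)
})

test_that("medians stay within tolerance at curve SNR 20 (Monte-Carlo)", {
  d <- fit_dict()
  set.seed(55)
  tissues <- replicate(100, tissue_params(
    amp = 1, eff = runif(1, -1, -0.85), b1 = runif(1, 0.85, 1.15),
    t1_ms = 1200 * runif(1, 0.9, 1.1), t2_ms = 42 * runif(1, 0.9, 1.1)),
    simplify = FALSE)
  clean <- synth_curves(d, tissues)
  # curve SNR: mean curve magnitude over the noise standard deviation
  snr <- 20
  sd20 <- stats::median(apply(Mod(clean), 1, mean)) / snr
  cv <- clean + complex(real = rnorm(length(clean), sd = sd20),
                        imaginary = rnorm(length(clean), sd = sd20))
  cv <- array(cv, dim(clean))
  s1 <- fit_step1(cv, d, refine = TRUE)
  t1 <- fit_step2(cv, s1, d)
  t1_true <- vapply(tissues, function(t) t$t1_ms, numeric(1))
  t2_true <- vapply(tissues, function(t) t$t2_ms, numeric(1))
  expect_lt(stats::median(abs(t1 - t1_true) / t1_true), 0.05)
  expect_lt(stats::median(abs(s1$t2_ms - t2_true) / t2_true), 0.10)
  .sim_cache$mc_snr20 <- list(
    t1_med = stats::median(abs(t1 - t1_true) / t1_true),
    t2_med = stats::median(abs(s1$t2_ms - t2_true) / t2_true))
})

test_that("a global complex scale changes only the amplitude", {
  d <- fit_dict()
  tis <- tissue_params(amp = 1, eff = -0.92, b1 = 1.05, t1_ms = 1100,
                       t2_ms = 50)
  cv <- synth_curves(d, list(tis))
  s1a <- fit_step1(cv, d, refine = TRUE)
  cvs <- cv * (3.7 * exp(1i * 1.1))
  s1b <- fit_step1(cvs, d, refine = TRUE)
  expect_equal(s1b$t2_ms, s1a$t2_ms, tolerance = 1e-3)
  expect_equal(s1b$b1, s1a$b1, tolerance = 1e-3)
  expect_equal(s1b$amp / s1a$amp, 3.7, tolerance = 1e-3)
  t1a <- fit_step2(cv, s1a, d); t1b <- fit_step2(cvs, s1b, d)
  expect_equal(t1b, t1a, tolerance = 1e-3)
})

test_that("T1 error degrades monotonically with decreasing SNR", {
  d <- fit_dict()
  set.seed(66)
  tissues <- replicate(40, tissue_params(
    amp = 1, eff = -0.95, b1 = runif(1, 0.9, 1.1),
    t1_ms = 1200 * runif(1, 0.95, 1.05), t2_ms = 42), simplify = FALSE)
  clean <- synth_curves(d, tissues)
  t1_true <- vapply(tissues, function(t) t$t1_ms, numeric(1))
  meds <- vapply(c(Inf, 40, 20, 10), function(snr) {
    cv <- clean
    if (is.finite(snr)) {
      set.seed(100 + round(snr))
      sdv <- stats::median(apply(Mod(clean), 1, mean)) / snr
      cv <- array(clean + complex(real = rnorm(length(clean), sd = sdv),
                                  imaginary = rnorm(length(clean), sd = sdv)),
                  dim(clean))
    }
    s1 <- fit_step1(cv, d, refine = TRUE)
    t1 <- fit_step2(cv, s1, d)
    stats::median(abs(t1 - t1_true) / t1_true)
  }, numeric(1))
  expect_true(all(diff(meds) >= -1e-4))
})
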