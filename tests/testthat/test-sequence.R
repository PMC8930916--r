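deg2rad_test <- function(x) x * pi / 180

test_that("the prep/flip interleave yields a 10-combination cycle", {
  sch <- build_schedule(seq_config(n_periods = 25))
  per <- sch$periods
  first10 <- per[1:10, c("prep_ms", "flip_deg")]
  expect_equal(nrow(unique(first10)), 10L)
  # both flip angles visit every preparation duration
  expect_setequal(interaction(first10$prep_ms, first10$flip_deg),
                  interaction(rep(c(0, 30, 40, 50, 60), 2),
                              rep(c(3, 10), each = 5)))
  # cycle repeats with period 10
  expect_equal(per$combo, (per$period) %% 10L)
  expect_equal(per$prep_ms[11:20], per$prep_ms[1:10])
  # previous flip angle is the executed predecessor (cycle end for period 0)
  expect_equal(per$prev_flip_deg[1], 10)
  expect_equal(per$prev_flip_deg[-1], per$flip_deg[-nrow(per)])
})

test_that("readout count, roles and timing follow the configuration", {
  sch <- build_schedule(seq_config(recovery_ms = 2500, tr_ms = 3.5,
                                   n_periods = 3))
  expect_equal(sch$periods$n_readouts[1], 714L)  # floor(2500/3.5)
  rd <- sch$readouts
  # roles alternate 1:1, training first
  expect_equal(rd$role[1:4], c("training", "imaging", "training", "imaging"))
  expect_equal(sum(rd$role == "training"), sum(rd$role == "imaging"))
  expect_error(build_schedule(seq_config(recovery_ms = 5, tr_ms = 3.5)),
               "period too short")
})

test_that("one full cycle covers every combination exactly once", {
  sch <- build_schedule(seq_config(n_periods = 10))
  expect_equal(sort(sch$periods$combo), 0:9)
})

test_that("golden-angle counter advances on imaging lines only", {
  sch <- build_schedule(seq_config(n_periods = 1))
  rd <- sch$readouts
  img <- rd[rd$role == "imaging", ]
  expect_equal(img$radial_angle_deg[1:5],
               c(0, 111.24, 222.48, 333.72, 84.96))
  expect_true(all(rd$radial_angle_deg[rd$role == "training"] == 0))
  expect_true(all(rd$phase_step[rd$role == "training"] == 0L))
  expect_equal(img$phase_step[1:7], c(0L, 1L, 2L, 0L, 1L, 2L, 0L))
})

test_that("q_factor matches its closed form and limits", {
  expect_equal(q_factor(1200, 1, 5, 5, 3.5), 1.0)
  expect_equal(q_factor(1200, 1, 3, 10, 3.5), 0.2369209, tolerance = 1e-6)
  # TR/T1 -> infinity: E1 -> 0 so the ratio -> 1
  expect_equal(q_factor(1e-6, 1, 3, 10, 3.5), 1.0)
  expect_error(q_factor(1e9, 1, 0, 0, 1e-9), "degenerate")
})

test_that("signal_curve reproduces hand-computed values and limits", {
  tis <- tissue_params(amp = 1, eff = -1, b1 = 1, t1_ms = 1200, t2_ms = 50)
  s1 <- signal_curve(tis, 30, 3, 10, 3.5, n = 1)
  expect_equal(s1, -0.00445955, tolerance = 1e-5)
  # bracketed term equal to 1 gives a flat curve at the steady state
  q <- q_factor(1200, 1, 3, 10, 3.5)
  tis2 <- tissue_params(amp = 1, eff = exp(30 / 50) / q, b1 = 1,
                        t1_ms = 1200, t2_ms = 50)
  s <- signal_curve(tis2, 30, 3, 10, 3.5, n = 1:50)
  expect_lt(diff(range(s)), 1e-12)
  e1 <- exp(-3.5 / 1200)
  ss <- (1 - e1) / (1 - e1 * cos(deg2rad_test(3))) * sin(deg2rad_test(3))
  expect_equal(s[1], ss, tolerance = 1e-12)
  # geometric term vanishes at large n
  sl <- signal_curve(tis, 30, 3, 10, 3.5, n = 5000)
  expect_equal(sl, ss, tolerance = 1e-9)
  # |s(n) - s(inf)| strictly decreasing
  sn <- signal_curve(tis, 30, 3, 10, 3.5, n = 1:100)
  expect_true(all(diff(abs(sn - ss)) < 0))
})

test_that("closed form agrees with the per-TR Bloch recursion", {
  sch <- build_schedule(seq_config(n_periods = 10))
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    tis <- random_tissue()
    s1 <- signal_schedule(tis, sch)
    s2 <- bloch_oracle(tis, sch)
    worst <- max(worst, max(abs(s1 - s2)) / max(abs(s1)))
  }
  expect_lt(worst, 1e-9)
})

test_that("Bloch recursion special cases", {
  sch <- build_schedule(seq_config(n_periods = 10))
  # zero B1 scale: no excitation, zero signal
  tis0 <- tissue_params(amp = 1, eff = -1, b1 = 0, t1_ms = 800, t2_ms = 40)
  expect_true(all(bloch_oracle(tis0, sch) == 0))
  # eff = 0 with tau = 0: saturation recovery from Mz = 0
  cfg <- seq_config(prep_ms = c(0, 0, 0, 0, 0), n_periods = 1)
  sch0 <- build_schedule(cfg)
  tis <- tissue_params(amp = 1, eff = 0, b1 = 1, t1_ms = 800, t2_ms = 40)
  s <- bloch_oracle(tis, sch0)
  expect_gt(s[2], s[1])            # recovering from zero
  expect_true(all(diff(s) >= -1e-12))
})
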