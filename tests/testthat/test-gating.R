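test_that("zero respiratory amplitude collapses the respiratory bins", {
  sch <- build_schedule(seq_config(n_periods = 10))
  ph <- make_phantom(phantom_config(grid_n = 32, n_coils = 4, seed = 14,
                                    resp_amp_mm = 0, n_card_frames = 32,
                                    resp_drift = FALSE))
  raw <- simulate_scan(ph, sch)
  gs <- gating_sim()
  bins <- assign_bins(raw, gs$dict, gs$sub, seed = 2)
  expect_equal(length(unique(bins$lines$resp_bin)), 1L)
})

test_that("cardiac bins track the truth phase as a cyclic monotone map", {
  gs <- gating_sim()
  ln <- gs$bins$lines
  cc <- circular_corr(ln$card_bin, 20, ln$truth_card_phase)
  expect_gte(cc, 0.8)
  # per-bin circular-mean truth phases are cyclically ordered
  tp <- tapply(ln$truth_card_phase, ln$card_bin, function(p)
    (atan2(mean(sin(2 * pi * p)), mean(cos(2 * pi * p))) / (2 * pi)) %% 1)
  d <- diff(c(tp, tp[1] + 1))
  wraps <- sum(d < 0)
  expect_lte(wraps, 1)        # a single wrap: monotone on the circle
})

test_that("respiratory bins order along the displacement axis", {
  gs <- gating_sim()
  ln <- gs$bins$lines
  disp <- resp_wave(ln$truth_resp_phase)
  m <- tapply(disp, ln$resp_bin, mean)
  expect_gt(stats::cor(as.numeric(names(m)), m), 0.9)
  # bin 0 is the end-expiratory extreme: smallest mean displacement
  expect_equal(unname(which.min(m)), 1L)
})

test_that("contrast removal leaves under 1% residual on a static phantom", {
  ss <- static_sim()
  gs <- gating_sim()
  meta <- ss$raw$training_meta
  nl <- nrow(meta)
  feats <- t(matrix(aperm(ss$raw$training, c(3, 1, 2)), nrow = nl))
  res <- mtsms:::contrast_residual(feats, meta, gs$dict, gs$sub)
  expect_lt(sum(Mod(res)^2) / sum(Mod(feats)^2), 0.01)
})

test_that("assignments are invariant to line order and global phase", {
  gs <- gating_sim()
  raw <- gs$raw
  set.seed(77)
  perm <- sample(dim(raw$training)[3])
  raw2 <- raw
  raw2$training <- raw$training[, , perm, drop = FALSE]
  raw2$training_meta <- raw$training_meta[perm, ]
  b2 <- assign_bins(raw2, gs$dict, gs$sub, seed = 2)
  expect_equal(b2$lines$card_bin[order(perm)], gs$bins$lines$card_bin)
  expect_equal(b2$lines$resp_bin[order(perm)], gs$bins$lines$resp_bin)
  raw3 <- raw
  raw3$training <- raw$training * exp(1i * 0.83)
  b3 <- assign_bins(raw3, gs$dict, gs$sub, seed = 2)
  expect_equal(b3$lines$card_bin, gs$bins$lines$card_bin)
  expect_equal(b3$lines$resp_bin, gs$bins$lines$resp_bin)
})

test_that("undersampled training rate triggers a Nyquist error", {
  gs <- gating_sim()
  raw <- gs$raw
  keep <- seq(1, dim(raw$training)[3], by = 40)   # ~3.6 Hz sampling
  raw$training <- raw$training[, , keep, drop = FALSE]
  raw$training_meta <- raw$training_meta[keep, ]
  expect_error(assign_bins(raw, gs$dict, gs$sub), "Nyquist")
})

test_that("real-time reconstruction tracks the respiratory motion", {
  gs <- gating_sim()
  raw <- gs$raw
  rt <- realtime_reconstruct(raw, L_rt = 4, iters = 8)
  # render frames at a subsample of training times and track the liver edge
  sel <- seq(1, nrow(raw$training_meta), by = 25)
  frames <- rt$render(raw$training_meta$time_ms[sel])
  n <- raw$grid_n
  # track the liver block: center of mass of the liver-side profile, which
  # translates with respiration while its contrast scales uniformly
  lx <- which(((seq_len(n) - 1 - n / 2 + 0.5) / n * 270) > 30)
  edge <- vapply(seq_along(sel), function(i) {
    img <- matrix(Mod(frames[(n * n) + seq_len(n * n), i]), n)  # mid slice
    prof <- rowSums(img)[lx]
    sum(seq_along(prof) * prof) / sum(prof)
  }, numeric(1))
  truth <- resp_wave(raw$training_meta$resp_phase[sel])
  expect_gt(abs(stats::cor(edge, truth)), 0.9)
})

test_that("real-time residual decreases with the temporal rank", {
  gs <- gating_sim()
  raw <- gs$raw
  sub_lines <- seq(1, dim(raw$imaging)[3], by = 4)
  raw$imaging <- raw$imaging[, , sub_lines, drop = FALSE]
  raw$imaging_meta <- raw$imaging_meta[sub_lines, ]
  traj <- make_trajectory(raw$grid_n)
  E <- make_operator(traj, raw$coils, raw$imaging_meta$radial_angle_deg,
                     raw$imaging_meta$phase_step)
  resid <- vapply(c(1, 3, 6), function(L) {
    rt <- realtime_reconstruct(raw, L_rt = L, iters = 8)
    tt <- raw$training_meta$time_ms
    phi <- t(vapply(seq_len(ncol(rt$v)), function(j) {
      re <- stats::approx(tt, Re(rt$v[, j]), xout = raw$imaging_meta$time_ms,
                          rule = 2)$y
      im <- stats::approx(tt, Im(rt$v[, j]), xout = raw$imaging_meta$time_ms,
                          rule = 2)$y
      complex(real = re, imaginary = im)
    }, complex(nrow(raw$imaging_meta))))
    d <- raw$imaging
    r <- E$forward_phi(rt$u, phi) - d
    sqrt(sum(Mod(r)^2) / sum(Mod(d)^2))
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
})
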