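make_synth_tensor <- function(dims = c(12, 10, 8, 8, 6),
                              ranks = c(4, 3, 3, 3, 2), seed = 42,
                              mask_frac = 0.3, mask_seed = 7) {
  set.seed(seed)
  rf <- function(n, r) {
    q <- qr.Q(qr(matrix(complex(real = rnorm(n * r),
                                imaginary = rnorm(n * r)), n)))
    q[, 1:r, drop = FALSE]
  }
  us <- Map(rf, dims, ranks)
  core <- array(complex(real = rnorm(prod(ranks)),
                        imaginary = rnorm(prod(ranks))), dim = ranks)
  x <- core
  for (i in 1:5) x <- ttm(x, us[[i]], i)
  set.seed(mask_seed)
  cellmask <- array(runif(prod(dims[-1])) < mask_frac, dims[-1])
  mask <- array(rep(cellmask, each = dims[1]), dims)
  list(x = x, us = us, core = core,
       st = list(data = x * mask, mask = mask, counts = cellmask * 1),
       sub = list(u_t1 = us[[2]], u_ta = us[[3]]))
}

test_that("tensor unfold/fold/ttm are mutually consistent", {
  set.seed(1)
  x <- array(rnorm(2 * 3 * 4 * 5), dim = c(2, 3, 4, 5))
  for (m in 1:4) expect_equal(fold(unfold(x, m), m, dim(x)), x)
  a <- matrix(rnorm(12), 4, 3)
  y <- ttm(x, a, 2)
  # oracle by explicit summation at a few entries
  for (trial in 1:5) {
    i <- c(sample(2, 1), sample(4, 1), sample(4, 1), sample(5, 1))
    expect_equal(y[i[1], i[2], i[3], i[4]],
                 sum(a[i[2], ] * x[i[1], , i[3], i[4]]), tolerance = 1e-12)
  }
})

test_that("training lines are deposited and averaged into the right cells", {
  # a toy raw/bins pair: 4 lines, 2 of them in the same cell
  sch <- build_schedule(seq_config(n_periods = 1))
  tr_rows <- which(sch$readouts$role == "training")[1:4]
  meta <- sch$readouts[tr_rows, ]
  meta$combo <- c(0L, 0L, 0L, 1L)
  meta$n <- c(1L, 1L, 9L, 9L)              # lines 1,2 share a cell
  nsamp <- 4; ncoil <- 1
  tr <- array(0i, dim = c(nsamp, ncoil, 4))
  tr[, , 1] <- 1 + 1i; tr[, , 2] <- 3 - 1i; tr[, , 3] <- 2; tr[, , 4] <- 5i
  raw <- list(training = tr, training_meta = meta)
  bins <- list(n_card = 2L, n_resp = 2L,
               lines = data.frame(card_bin = c(0L, 0L, 1L, 0L),
                                  resp_bin = c(0L, 0L, 0L, 1L)))
  dict <- list(n_grid = c(1L, 9L), combos = data.frame(combo = 0:1))
  st <- assemble_training_tensor(raw, bins, dict, feature_rank = 4)
  expect_equal(sum(st$counts), 4)
  expect_equal(st$counts[1, 1, 1, 1], 2)   # averaged cell
  # averaging: the deposited feature equals the mean of the two projections
  f1 <- crossprod(Conj(st$v_feat), matrix(tr[, , 1], ncol = 1))
  f2 <- crossprod(Conj(st$v_feat), matrix(tr[, , 2], ncol = 1))
  expect_equal(st$data[, 1, 1, 1, 1], as.vector((f1 + f2) / 2),
               tolerance = 1e-12)
})

test_that("completion is exact for fully observed data with no penalty", {
  ts <- make_synth_tensor(mask_frac = 1.01)
  res <- complete_tensor(ts$st, ts$sub, lambda = 0, lambda_c = 0,
                         lambda_r = 0, iters = 5, polish = FALSE)
  p2 <- ts$us[[2]] %*% Conj(t(ts$us[[2]]))
  p3 <- ts$us[[3]] %*% Conj(t(ts$us[[3]]))
  proj <- ttm(ttm(ts$x, p2, 2), p3, 3)
  expect_lt(max(Mod(res$data - proj)), 1e-10)
})

test_that("a seeded low-multilinear-rank tensor is recovered from 30% cells", {
  ts <- make_synth_tensor()
  res <- complete_tensor(ts$st, ts$sub, iters = 80)
  expect_equal(res$polish_ranks, c(4, 3, 2))
  expect_lt(rel_err(res$data, ts$x), 1e-3)
  # objective non-increasing on accepted steps
  tr <- res$trace$total
  expect_true(all(diff(tr) <= tr[-length(tr)] * 1e-9 + 1e-12))
})

test_that("entrywise-partial feature fibers are rejected", {
  ts <- make_synth_tensor()
  st <- ts$st
  st$mask[1, 1, 1, 1, 1] <- !st$mask[1, 1, 1, 1, 1]
  st$counts <- NULL
  expect_error(complete_tensor(st, ts$sub), "feature")
})

test_that("truncated HOSVD is exact at the true multilinear rank", {
  ts <- make_synth_tensor()
  h <- hosvd(ts$x, c(4, 3, 3, 3, 2))
  expect_lt(rel_err(hosvd_expand(h), ts$x), 1e-10)
  # factor orthonormality and core all-orthogonality
  for (f in h$factors)
    expect_lt(max(Mod(crossprod(Conj(f), f) - diag(ncol(f)))), 1e-8)
  g1 <- unfold(h$core, 1)
  gram <- g1 %*% Conj(t(g1))
  expect_lt(max(Mod(gram[upper.tri(gram)])) / max(Mod(diag(gram))), 1e-6)
})

test_that("rank-1 outer product gives a scalar core of the norm product", {
  set.seed(9)
  vs <- lapply(c(5, 4, 3, 6, 2), function(n) rnorm(n))
  x <- array(Reduce(`%o%`, vs), dim = lengths(vs))
  h <- hosvd(x, rep(1L, 5))
  expect_equal(abs(as.vector(h$core)),
               prod(vapply(vs, function(v) sqrt(sum(v^2)), numeric(1))),
               tolerance = 1e-10)
})

test_that("factored Phi evaluation equals brute-force contraction", {
  set.seed(17)
  dims <- c(8, 4, 2, 2, 2); ranks <- c(3, 2, 2, 2, 2)
  x <- array(complex(real = rnorm(prod(dims)),
                     imaginary = rnorm(prod(dims))), dims)
  h <- hosvd(x, ranks)
  fs <- structure(list(core = h$core, u_feat = h$factors[[1]],
                       u_t1 = h$factors[[2]], u_ta = h$factors[[3]],
                       u_c = h$factors[[4]], u_r = h$factors[[5]],
                       ranks = ranks), class = "mt_factors")
  phi <- build_phi(fs)
  # brute force: Phi = core x2 u2 x3 u3 x4 u4 x5 u5
  full <- h$core
  for (i in 2:5) full <- ttm(full, h$factors[[i]], i)
  for (trial in 1:10) {
    q <- c(sample(4, 1), sample(2, 1), sample(2, 1), sample(2, 1))
    got <- phi_eval(phi, h$factors[[2]][q[1], , drop = FALSE],
                    q[2], q[3], q[4])
    expect_equal(as.vector(got), as.vector(full[, q[1], q[2], q[3], q[4]]),
                 tolerance = 1e-10)
  }
  # identity core with canonical factors returns the spatial columns
  u_x <- matrix(complex(real = rnorm(12 * 3), imaginary = rnorm(12 * 3)), 12)
  got <- render_images(u_x, phi, h$factors[[2]][1, , drop = FALSE], 1, 1, 1)
  expect_equal(got, u_x %*% phi_eval(phi, h$factors[[2]][1, , drop = FALSE],
                                     1, 1, 1))
  # linearity in u_x
  a <- render_images(2 * u_x, phi, h$factors[[2]][2, , drop = FALSE], 2, 1, 2)
  b <- render_images(u_x, phi, h$factors[[2]][2, , drop = FALSE], 2, 1, 2)
  expect_equal(a, 2 * b, tolerance = 1e-12)
  expect_error(render_images(u_x, phi, h$factors[[2]][1, , drop = FALSE],
                             9, 1, 1), "out of range")
})
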