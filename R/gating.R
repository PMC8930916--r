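#' SVD coil compression
#'
#' Rotates the physical coils into virtual coils ordered by signal energy and
#' keeps the leading ones. The same unitary is applied to the stored
#' sensitivity maps so truth-coil bypass remains consistent.
#'
#' @param raw an \code{mt_raw}.
#' @param n_virtual number of virtual coils to keep.
#' @return the compressed \code{mt_raw}.
#' @export
compress_coils <- function(raw, n_virtual = 4L) {
  nc <- dim(raw$imaging)[2]
  if (n_virtual >= nc) return(raw)
  m1 <- matrix(aperm(raw$training, c(1, 3, 2)), ncol = nc)
  cc <- crossprod(Conj(m1), m1)
  v <- eigen(cc, symmetric = TRUE)$vectors[, seq_len(n_virtual), drop = FALSE]
  rot <- function(a) {
    d <- dim(a)
    out <- array(0i, dim = c(d[1], n_virtual, d[3]))
    for (l in seq_len(d[3])) out[, , l] <- a[, , l] %*% v
    out
  }
  raw$imaging <- rot(raw$imaging)
  raw$training <- rot(raw$training)
  cs <- array(0i, dim = c(dim(raw$coils)[1], n_virtual, dim(raw$coils)[3]))
  for (s in seq_len(dim(raw$coils)[3])) cs[, , s] <- raw$coils[, , s] %*% v
  raw$coils <- cs
  raw$coil_rotation <- v
  raw
}

# Frequency-domain filter with raised-cosine edges; x is a numeric matrix,
# one trace per column, sampled uniformly every dt_s seconds.
filter_fft <- function(x, dt_s, low_hz = NULL, high_hz = NULL, soft_hz = 0.1,
                       notch_hz = NULL, notch_width_hz = 0.06) {
  x <- as.matrix(x)
  nl <- nrow(x)
  f <- abs(c(0:(floor(nl / 2)), -(ceiling(nl / 2) - 1):-1)) / (nl * dt_s)
  mask <- rep(1, nl)
  edge <- function(d) 0.5 * (1 + cos(pi * pmin(pmax(d / soft_hz, 0), 1)))
  if (!is.null(high_hz)) mask <- mask * edge(f - high_hz)
  if (!is.null(low_hz)) mask <- mask * (1 - edge(f - low_hz))
  for (fn in notch_hz) mask[abs(f - fn) < notch_width_hz] <- 0
  apply(x, 2, function(col) Re(stats::fft(stats::fft(col) * mask,
                                          inverse = TRUE)) / nl)
}

analytic_phase <- function(x) {
  nl <- length(x)
  h <- numeric(nl); h[1] <- 1
  if (nl %% 2 == 0) { h[nl / 2 + 1] <- 1; h[2:(nl / 2)] <- 2 }
  else h[2:((nl + 1) / 2)] <- 2
  Arg(stats::fft(stats::fft(x) * h, inverse = TRUE) / nl)
}

# Contrast-removal: regress training-line features onto the relaxation
# subspace predicted at each line's (combination, excitation index).
contrast_residual <- function(feats, meta, dict, sub, l_t1 = 5L, l_ta = 5L) {
  l1 <- min(l_t1, ncol(sub$u_t1)); l2 <- min(l_ta, ncol(sub$u_ta))
  ut <- apply(sub$u_t1[, seq_len(l1), drop = FALSE], 2, function(col)
    stats::approx(dict$n_grid, col, xout = meta$n, rule = 2)$y)
  ua <- sub$u_ta[meta$combo + 1L, seq_len(l2), drop = FALSE]
  x <- matrix(0, nrow(meta), l1 * l2)
  for (j in seq_len(l2)) x[, (j - 1L) * l1 + seq_len(l1)] <- ut * ua[, j]
  # least squares per feature row via the (real) normal equations of x;
  # ridge-stabilized: a short schedule spans few combinations and the
  # combination basis columns become collinear
  xtx <- crossprod(x)
  xtx <- xtx + 1e-8 * mean(diag(xtx)) * diag(ncol(x))
  coef <- solve(xtx, t(x) %*% t(feats))
  feats - t(x %*% coef)
}

#' Assign training lines to cardiac and respiratory bins
#'
#' Self-gating on the repeatedly acquired 0-degree training projections:
#' (1) the contrast weighting predicted by the relaxation subspaces at each
#' line's (combination, excitation) coordinate is regressed out of the
#' feature vectors; (2) the leading principal components of the motion
#' residual are low-pass filtered (respiration) and clustered by k-means
#' into \code{n_resp} bins ordered along the dominant component with the
#' modal bin (end-expiration) first; (3) a band-passed cardiac component is
#' converted to instantaneous phase by the analytic signal and partitioned
#' into \code{n_card} phase bins, refined by k-means on the unit circle.
#'
#' @param raw an \code{mt_raw}.
#' @param dict the dictionary the subspaces came from.
#' @param sub an \code{mt_subspaces}.
#' @param n_card,n_resp bin counts.
#' @param resp_cut_hz respiratory low-pass cutoff.
#' @param card_band_hz cardiac band-pass (length 2).
#' @param n_pc principal components retained from the motion residual.
#' @param seed k-means seed.
#' @return class \code{mt_bins}: per-line data.frame (time_ms, card_bin,
#'   resp_bin and truth phases when present), occupancy tables, and
#'   diagnostic feature traces.
#' @export
assign_bins <- function(raw, dict, sub, n_card = 20L, n_resp = 6L,
                        resp_cut_hz = 0.7, card_band_hz = c(0.5, 2.5),
                        n_pc = 6L, seed = 1L) {
  meta <- raw$training_meta
  nl <- nrow(meta)
  # features are time-explicit: process in time order, then map assignments
  # back to the storage order so results do not depend on how lines are held
  ord <- order(meta$time_ms)
  meta <- meta[ord, , drop = FALSE]
  raw$training <- raw$training[, , ord, drop = FALSE]
  inv <- integer(nl); inv[ord] <- seq_len(nl)
  dt <- stats::median(diff(meta$time_ms)) / 1000
  if (1 / (2 * dt) < card_band_hz[2])
    stop(sprintf(
      "training sampling rate %.1f Hz cannot resolve the cardiac band (Nyquist %.1f Hz < %.1f Hz)",
      1 / dt, 1 / (2 * dt), card_band_hz[2]))
  feats <- t(matrix(aperm(raw$training, c(3, 1, 2)), nrow = nl)) # feature x line
  res <- contrast_residual(feats, meta, dict, sub)
  # principal component traces of the motion residual (left-side eigen since
  # the feature dimension is much smaller than the line count)
  np <- min(n_pc, nl - 1L, nrow(res))
  g <- tcrossprod(res, Conj(res))
  ev <- eigen((g + Conj(t(g))) / 2, symmetric = TRUE)
  scores <- crossprod(Conj(res), ev$vectors[, seq_len(np), drop = FALSE])
  # anchor each component's global phase so assignments are invariant to a
  # global complex phase of the data
  for (j in seq_len(np)) {
    a <- scores[which.max(Mod(scores[, j])), j]
    scores[, j] <- scores[, j] * Conj(a) / Mod(a)
  }
  chans <- cbind(Re(scores), Im(scores))
  keep <- apply(chans, 2, stats::sd) > 1e-12 * max(apply(chans, 2, stats::sd))
  chans <- chans[, keep, drop = FALSE]

  # --- respiration ---
  lo <- filter_fft(chans, dt, high_hz = resp_cut_hz)
  lo <- sweep(lo, 2, colMeans(lo))
  v <- apply(lo, 2, stats::var)
  ord <- order(v, decreasing = TRUE)
  lead <- lo[, ord[1]]
  # genuine breathing dominates the residual's low band; the alternative
  # content there is contrast-cycle leakage at the ~8% level
  resp_present <- stats::var(lead) > 0.2 * max(apply(chans, 2, stats::var))
  if (!resp_present) {
    resp_bin <- rep(0L, nl)
  } else {
    rfeat <- lo[, ord[seq_len(min(3, length(ord)))], drop = FALSE]
    rfeat <- sweep(rfeat, 2, pmax(apply(rfeat, 2, stats::sd), 1e-300), "/")
    set.seed(seed)
    km <- stats::kmeans(rfeat, centers = n_resp, nstart = 50, iter.max = 100)
    pos <- tapply(lead, km$cluster, mean)
    occ <- tabulate(km$cluster, n_resp)
    # the expiratory plateau of the asymmetric respiratory waveform makes the
    # end-expiration extreme the denser one: orient so it sits at bin 0
    ordpos <- order(pos)
    if (occ[ordpos[n_resp]] > occ[ordpos[1]]) pos <- -pos
    relab <- integer(n_resp)
    relab[order(pos)] <- seq_len(n_resp) - 1L
    resp_bin <- relab[km$cluster]
  }

  # --- cardiac ---
  # remove respiratory-phase-locked content before the cardiac analysis:
  # the nonlinear feature response to breathing (k-space phase ramps of the
  # translation) carries overtones of the respiratory fundamental throughout
  # the cardiac band, and for typical rhythm ratios (e.g. 4 breaths : 1 beat)
  # an overtone can coincide with the cardiac line itself. Regressing on a
  # harmonic basis of the measured respiratory phase removes exactly the
  # respiration-locked energy at any frequency, while the (incommensurate)
  # cardiac signal survives.
  chans_c <- chans
  overtones <- numeric(0)
  fax <- (seq_len(nl) - 1) / (nl * dt)
  if (resp_present) {
    psi <- analytic_phase(lead)
    rb <- do.call(cbind, lapply(1:8, function(k)
      cbind(cos(k * psi), sin(k * psi))))
    beta <- solve(crossprod(rb) + 1e-9 * diag(ncol(rb)), crossprod(rb, chans))
    chans_c <- chans - rb %*% beta
    # remaining respiration-locked lines (the phase basis is imperfect over
    # the expiratory plateau): locate the respiratory fundamental and mark
    # its overtone frequencies for masking below
    spec_r <- Mod(stats::fft(lead - mean(lead)))^2
    sel_r <- fax > 0.08 & fax < resp_cut_hz
    f_r <- fax[sel_r][which.max(spec_r[sel_r])]
    overtones <- f_r * seq(2, ceiling(card_band_hz[2] / f_r))
    overtones <- overtones[overtones > card_band_hz[1] - 0.1 &
                             overtones < card_band_hz[2] + 0.1]
  }
  notch_w <- max(0.04, 2 / (nl * dt))
  mask_ot <- function(s) {
    for (fo in overtones) s[abs(fax - fo) < notch_w] <- 0
    s
  }
  # channel selection and f0 detection with overtone bins masked
  bp <- filter_fft(chans_c, dt, low_hz = card_band_hz[1],
                   high_hz = card_band_hz[2], notch_hz = overtones,
                   notch_width_hz = notch_w)
  tot <- apply(chans_c, 2, function(c) sum((c - mean(c))^2))
  band <- colSums(bp^2)
  csel <- which.max(band / pmax(tot, 1e-300))
  spec <- mask_ot(Mod(stats::fft(bp[, csel]))^2)
  inband <- fax >= card_band_hz[1] & fax <= card_band_hz[2]
  f0 <- fax[inband][which.max(spec[inband])]
  # isolate the cardiac fundamental; notch overtones unless one coincides
  # with the cardiac line itself (then it cannot be separated spectrally and
  # the regression residual is the best available)
  safe_ot <- overtones[abs(overtones - f0) > notch_w + 0.02]
  ctrace <- filter_fft(chans_c[, csel, drop = FALSE], dt,
                       low_hz = 0.6 * f0, high_hz = 1.45 * f0,
                       notch_hz = safe_ot, notch_width_hz = notch_w)[, 1]
  phase <- analytic_phase(ctrace)
  # light smoothing of the unwrapped phase (cardiac phase evolves smoothly)
  dphi <- diff(phase); dphi <- (dphi + pi) %% (2 * pi) - pi
  up <- cumsum(c(phase[1], dphi))
  k <- max(3L, round(0.15 / dt)); k <- k + (1L - k %% 2L)
  sm <- stats::filter(up, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- up[is.na(sm)]
  phase <- as.numeric(sm) %% (2 * pi)
  set.seed(seed + 1L)
  km2 <- stats::kmeans(cbind(cos(phase), sin(phase)), centers = n_card,
                       nstart = 50, iter.max = 100)
  cang <- atan2(km2$centers[, 2], km2$centers[, 1])
  # bin 0 anchored at the contraction extremum, then cyclic phase order
  bmean <- tapply(ctrace, km2$cluster, mean)
  anchor <- which.max(abs(bmean - stats::median(bmean)))
  ang0 <- cang[anchor]
  relab2 <- integer(n_card)
  relab2[order((cang - ang0) %% (2 * pi))] <- seq_len(n_card) - 1L
  card_bin <- relab2[km2$cluster]

  lines <- data.frame(time_ms = meta$time_ms, card_bin = card_bin,
                      resp_bin = resp_bin)
  if (!is.null(meta$combo)) lines$combo <- meta$combo
  if (!is.null(meta$card_phase)) {
    lines$truth_card_phase <- meta$card_phase
    lines$truth_resp_phase <- meta$resp_phase
  }
  lines <- lines[inv, , drop = FALSE]          # back to storage order
  rownames(lines) <- NULL
  card_bin <- lines$card_bin; resp_bin <- lines$resp_bin
  occ <- table(factor(card_bin, levels = 0:(n_card - 1)),
               factor(resp_bin, levels = 0:(n_resp - 1)))
  if (any(rowSums(occ) == 0))
    warning("empty cardiac bin(s): ",
            paste(which(rowSums(occ) == 0) - 1L, collapse = ", "))
  structure(list(lines = lines, occupancy = occ, n_card = n_card,
                 n_resp = n_resp,
                 diagnostics = list(resp_trace = lead, card_trace = ctrace,
                                    card_phase = phase)),
            class = "mt_bins")
}

#' Circular correlation between bin indices and a reference phase
#'
#' Fisher-Lee circular correlation between the bin centers (as angles) and
#' the reference phase (in cycles).
#'
#' @param bin integer bins 0..n_bins-1. @param n_bins total bins.
#' @param phase_ref reference phase in [0,1).
#' @export
circular_corr <- function(bin, n_bins, phase_ref) {
  a <- 2 * pi * (bin + 0.5) / n_bins
  b <- 2 * pi * phase_ref
  sa <- sin(a); ca <- cos(a); sb <- sin(b); cb <- cos(b)
  num <- sum(sa * sb) * sum(ca * cb) - sum(sa * cb) * sum(ca * sb)
  da <- sum(sa^2) * sum(ca^2) - sum(sa * ca)^2
  db <- sum(sb^2) * sum(cb^2) - sum(sb * cb)^2
  num / sqrt(da * db)
}

#' Real-time (ungated) subspace reconstruction
#'
#' Low-rank matrix image model: the temporal basis is taken from the SVD of
#' the training data; spatial coefficients are solved by (conjugate-gradient)
#' least squares against the imaging lines through the encoding operator,
#' with the temporal functions linearly interpolated from training to
#' imaging timestamps.
#'
#' @param raw an \code{mt_raw} (coil-compress first for speed).
#' @param L_rt temporal rank.
#' @param iters CG iterations. @param lambda Tikhonov stabilizer.
#' @param use_truth_coils take sensitivities from the truth sidecar.
#' @return class \code{mt_realtime} with spatial coefficients \code{u}
#'   (nvox*nslice x L), training temporal basis \code{v} and a
#'   \code{render(times_ms)} closure returning image frames.
#' @export
realtime_reconstruct <- function(raw, L_rt = 4L, iters = 10L, lambda = 1e-3,
                                 use_truth_coils = TRUE) {
  nl <- dim(raw$training)[3]
  if (L_rt > nl) stop("L_rt exceeds the number of training lines")
  feats <- matrix(aperm(raw$training, c(3, 1, 2)), nrow = nl)  # line x feat
  sv <- svd(feats, nu = L_rt, nv = 0)
  rk <- sum(sv$d > sv$d[1] * 1e-10)
  if (rk < L_rt) {
    warning("rank-deficient training data; reducing L_rt to ", rk)
    L_rt <- rk
  }
  v <- sv$u[, seq_len(L_rt), drop = FALSE]       # temporal basis at train times
  tt <- raw$training_meta$time_ms
  ti <- raw$imaging_meta$time_ms
  phi_img <- sapply(seq_len(L_rt), function(j) {
    re <- stats::approx(tt, Re(v[, j]), xout = ti, rule = 2)$y
    im <- stats::approx(tt, Im(v[, j]), xout = ti, rule = 2)$y
    complex(real = re, imaginary = im)
  })
  phi_img <- t(phi_img)                           # L x nlines
  traj <- make_trajectory(raw$grid_n, raw$oversample)
  coils <- if (use_truth_coils) raw$coils else estimate_coils(raw)
  E <- make_operator(traj, coils, raw$imaging_meta$radial_angle_deg,
                     raw$imaging_meta$phase_step)
  d <- raw$imaging
  u <- cg_solve_phi(E, phi_img, d, iters = iters, lambda = lambda)
  out <- list(u = u, v = v, time_train_ms = tt, grid_n = raw$grid_n,
              nslice = dim(coils)[3])
  out$render <- function(times_ms) {
    phi <- sapply(seq_len(ncol(v)), function(j) {
      re <- stats::approx(tt, Re(v[, j]), xout = times_ms, rule = 2)$y
      im <- stats::approx(tt, Im(v[, j]), xout = times_ms, rule = 2)$y
      complex(real = re, imaginary = im)
    })
    u %*% t(matrix(phi, ncol = ncol(v)))
  }
  class(out) <- "mt_realtime"
  out
}

# Conjugate gradient on the normal equations of the factored model
# d ~ E(U phi): solves (A'A + lambda I) U = A'd.
cg_solve_phi <- function(E, phi, d, iters = 10L, lambda = 0, x0 = NULL,
                         tol = 1e-8, verbose = FALSE) {
  aty <- E$adjoint_phi(d, phi)
  amul <- function(u) E$adjoint_phi(E$forward_phi(u, phi), phi) + lambda * u
  x <- if (is.null(x0)) matrix(0i, nrow(aty), ncol(aty)) else x0
  r <- aty - if (is.null(x0)) 0 else amul(x)
  p <- r
  rs <- sum(Mod(r)^2)
  rs0 <- rs
  for (i in seq_len(iters)) {
    ap <- amul(p)
    alpha <- rs / Re(sum(Conj(p) * ap))
    x <- x + alpha * p
    r <- r - alpha * ap
    rs_new <- sum(Mod(r)^2)
    if (verbose) message("cg iter ", i, " relres ", sqrt(rs_new / rs0))
    if (rs_new < tol^2 * rs0) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}
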