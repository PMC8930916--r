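#' Per-line radial angles of a schedule
#'
#' Imaging line m (0-based global imaging counter) is acquired at
#' (m * 111.24) mod 360 degrees; training lines always sample the 0-degree
#' projection.
#'
#' @param schedule an \code{mt_schedule}.
#' @return data.frame with columns role, angle_deg, phase_step.
#' @export
radial_angles <- function(schedule) {
  rd <- schedule$readouts
  data.frame(role = rd$role, angle_deg = rd$radial_angle_deg,
             phase_step = rd$phase_step)
}

#' CAIPIRINHA band phasors
#'
#' Per phase step j and band, the unit phasor exp(i j delta_b) with
#' increments +2pi/3 (basal), 0 (mid), -2pi/3 (apical). The phase step
#' advances by one per imaging readout (mod 3); training lines use step 0,
#' i.e. all bands in phase.
#'
#' @param n_bands multiband factor; only 3 is supported.
#' @param slice_order character vector naming the bands in storage order.
#' @return complex matrix (3 steps x n_bands); rows j = 0,1,2.
#' @export
band_phases <- function(n_bands = 3L,
                        slice_order = c("apical", "mid", "basal")) {
  if (n_bands != 3L) stop("unsupported multiband factor: only 3 bands")
  incr <- c(apical = -2 * pi / 3, mid = 0, basal = 2 * pi / 3)[slice_order]
  outer(0:2, incr, function(j, d) exp(1i * j * d))
}

#' Radial SMS trajectory
#'
#' Sampling geometry shared by all lines: symmetric readout through k = 0
#' with 2x readout oversampling (sample spacing 0.5 cycles/FOV), voxel-center
#' coordinates in FOV fractions, and ramp density-compensation weights
#' (|k|, used for gridded previews only).
#'
#' @param grid_n reconstruction matrix size.
#' @param oversample readout oversampling factor.
#' @return class \code{mt_traj}.
#' @export
make_trajectory <- function(grid_n, oversample = 2L) {
  m <- as.integer(grid_n * oversample)
  dk <- 1 / oversample
  kr <- (seq_len(m) - 1L - m / 2) * dk          # cycles/FOV
  g <- ((seq_len(grid_n) - 1L) - grid_n / 2 + 0.5) / grid_n  # voxel centers
  xy <- expand.grid(x = g, y = g)
  dcw <- pmax(abs(kr), dk / 4)
  structure(list(grid_n = as.integer(grid_n), oversample = oversample,
                 n_samp = m, dk = dk, kr0 = kr[1], kr = kr,
                 tx = xy$x, ty = xy$y, dcw = dcw), class = "mt_traj")
}

#' SMS radial encoding operator
#'
#' Linear map from a slice-stack image (or a spatial factor matrix paired
#' with per-line temporal weights) to radial k-space samples: per-slice coil
#' weighting, per-band CAIPIRINHA phasor, band summation, and exact
#' non-uniform Fourier evaluation along each line. The adjoint is the exact
#' conjugate transpose; density compensation never enters the pair.
#'
#' @param traj an \code{mt_traj}.
#' @param coils complex array (nvox, ncoil, nslice) of sensitivities.
#' @param angles per-line angle in degrees.
#' @param psteps per-line integer phase step in 0..2.
#' @param shift optional per-line translation (FOV fractions, along +x).
#' @param nufft use the Kaiser-Bessel NUFFT fast path (exact-transpose pair);
#'   \code{FALSE} evaluates the non-uniform DFT directly.
#' @return class \code{mt_operator} with fields \code{forward(x)} /
#'   \code{adjoint(y)} for a fixed image x (nvox x nslice), and
#'   \code{forward_phi(Ux, Phi)} / \code{adjoint_phi(y, Phi)} for a spatial
#'   factor Ux (nvox*nslice x L) with temporal weights Phi (L x nlines).
#' @export
make_operator <- function(traj, coils, angles, psteps, shift = NULL,
                          nufft = TRUE) {
  nvox <- length(traj$tx)
  dc <- dim(coils)
  if (dc[1] != nvox) stop("shape mismatch: coils vs trajectory")
  ncoil <- dc[2]; ns <- dc[3]
  nl <- length(angles)
  if (length(psteps) != nl) stop("shape mismatch: angles vs phase steps")
  if (is.null(shift)) shift <- numeric(nl)
  ph <- if (ns == 1L) matrix(1 + 0i, 3, 1) else band_phases(ns)
  cvec <- as.vector(coils)
  ones <- matrix(1 + 0i, 1, nl)
  op <- list(
    nvox = nvox, ncoil = ncoil, nslice = ns, nlines = nl,
    n_samp = traj$n_samp, traj = traj, angles = angles, psteps = psteps,
    shift = shift, phasors = ph, coils = coils,
    forward_phi = function(Ux, Phi) {
      y <- cpp_sms_forward(Ux, Phi, cvec, traj$tx, traj$ty, traj$kr0,
                           traj$dk, traj$n_samp, ncoil, ns, angles,
                           as.integer(psteps), ph, shift, nufft)
      array(y, dim = c(traj$n_samp, ncoil, ncol(Phi)))
    },
    adjoint_phi = function(y, Phi) {
      cpp_sms_adjoint(as.complex(y), Phi, cvec, traj$tx, traj$ty, traj$kr0,
                      traj$dk, traj$n_samp, ncoil, ns, angles,
                      as.integer(psteps), ph, shift, nufft)
    })
  op$forward <- function(x) {
    op$forward_phi(matrix(as.complex(x), ncol = 1L), ones)
  }
  op$adjoint <- function(y) {
    matrix(op$adjoint_phi(y, ones), nvox, ns)
  }
  class(op) <- "mt_operator"
  op
}

#' Numerical adjointness probe
#'
#' Checks |<Ex, y> - <x, E'y>| on seeded random inputs, relative to
#' ||Ex|| ||y||.
#'
#' @param op an \code{mt_operator}.
#' @param seed RNG seed for the probe vectors.
#' @return the relative adjointness defect (numeric scalar).
#' @export
adjointness_defect <- function(op, seed = 1L) {
  set.seed(seed)
  nx <- op$nvox * op$nslice
  x <- matrix(complex(real = rnorm(nx), imaginary = rnorm(nx)), op$nvox)
  ny <- op$n_samp * op$ncoil * op$nlines
  y <- array(complex(real = rnorm(ny), imaginary = rnorm(ny)),
             dim = c(op$n_samp, op$ncoil, op$nlines))
  ex <- op$forward(x)
  aty <- op$adjoint(y)
  ip1 <- sum(ex * Conj(y))
  ip2 <- sum(x * Conj(aty))
  Mod(ip1 - ip2) / (sqrt(sum(Mod(ex)^2)) * sqrt(sum(Mod(y)^2)))
}

#' Operator norm by power iteration
#'
#' @param op an \code{mt_operator}.
#' @param iters power iterations.
#' @param seed RNG seed.
#' @export
operator_norm <- function(op, iters = 10L, seed = 1L) {
  set.seed(seed)
  nx <- op$nvox * op$nslice
  x <- matrix(complex(real = rnorm(nx), imaginary = rnorm(nx)), op$nvox)
  lam <- 0
  for (i in seq_len(iters)) {
    z <- op$adjoint(op$forward(x))
    lam <- sqrt(sum(Mod(z)^2)) / sqrt(sum(Mod(x)^2))
    x <- z / sqrt(sum(Mod(z)^2))
  }
  sqrt(lam)
}

smooth_cx <- function(img, sigma_vox) {
  n <- nrow(img)
  f <- c(0:(n / 2), (-n / 2 + 1):(-1)) / n
  h <- exp(-2 * pi^2 * sigma_vox^2 * outer(f^2, f^2, "+"))
  stats::fft(stats::fft(img) * h, inverse = TRUE) / n^2
}

#' Coil-sensitivity estimation from imaging lines
#'
#' Time-averaged gridded reconstruction per kz bucket: lines are grouped by
#' CAIPIRINHA phase step, combined with the 3-point inverse DFT weights that
#' separate the three bands, density-compensated, and gridded per coil.
#' Sensitivities are the smoothed per-coil images divided by the
#' root-sum-of-squares image. With \code{use_truth = TRUE} (simulation mode)
#' the stored ground-truth maps are returned unchanged.
#'
#' @param raw an \code{mt_raw} simulated/acquired dataset.
#' @param smooth_sigma Gaussian smoothing sigma in voxels.
#' @param use_truth bypass estimation with the truth coil maps.
#' @return complex array (nvox, ncoil, nslice) plus attribute \code{rss}.
#' @export
estimate_coils <- function(raw, smooth_sigma = 2.5, use_truth = FALSE) {
  if (use_truth) return(raw$coils)
  traj <- make_trajectory(raw$grid_n, raw$oversample)
  meta <- raw$imaging_meta
  if (nrow(meta) < 3 * raw$grid_n) stop("too few imaging lines for coil estimation")
  # calibrate on the steady-state half of each recovery period: early
  # post-inversion lines carry signed, near-nulled contrast that partially
  # cancels the averaged calibration image
  late <- meta$n > max(meta$n) / 2
  if (sum(late) >= 3 * raw$grid_n) {
    meta <- meta[late, , drop = FALSE]
    raw$imaging <- raw$imaging[, , late, drop = FALSE]
  }
  ns <- dim(raw$coils)[3]; ncoil <- dim(raw$coils)[2]
  ph <- band_phases(ns)
  n <- raw$grid_n
  sens <- array(0i, dim = dim(raw$coils))
  imgs <- vector("list", ns)
  for (s in seq_len(ns)) {
    wline <- Conj(ph[meta$phase_step + 1L, s]) / ns
    x <- cpp_nudft_adjoint_percoil(as.complex(raw$imaging), traj$tx, traj$ty,
                                   traj$kr0, traj$dk, traj$n_samp, ncoil,
                                   meta$radial_angle_deg, as.complex(wline),
                                   traj$dcw, meta$shift %||% numeric(nrow(meta)),
                                   TRUE)
    imgs[[s]] <- array(x, dim = c(n, n, ncoil))
  }
  for (s in seq_len(ns)) {
    sm <- imgs[[s]]
    for (c in seq_len(ncoil)) sm[, , c] <- smooth_cx(sm[, , c], smooth_sigma)
    rss <- sqrt(apply(Mod(sm)^2, c(1, 2), sum))
    rss[rss < 0.05 * max(rss)] <- Inf      # suppress empty background
    for (c in seq_len(ncoil)) sens[, c, s] <- as.vector(sm[, , c] / rss)
  }
  sens
}
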