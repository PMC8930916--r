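#' Digital phantom configuration
#'
#' A dynamic three-slice short-axis left-ventricle phantom: a myocardial
#' annulus with a blood pool, plus a liver block whose edge acts as the
#' respiratory navigator structure. Cardiac contraction modulates the
#' annulus radii periodically; respiration translates the whole frame
#' rigidly along x (the head-foot direction of the 0-degree projection).
#'
#' @param grid_n in-plane matrix size (>= 32).
#' @param fov_mm field of view in mm.
#' @param tissues named list of \code{mt_tissue} for classes
#'   myocardium, blood, liver (background has zero amplitude).
#' @param cardiac_period_ms,resp_period_ms motion periods (ms).
#' @param resp_amp_mm peak respiratory displacement (mm).
#' @param contraction_frac fractional systolic reduction of the endocardial
#'   radius.
#' @param b1_range range of the smooth multiplicative B1+ map.
#' @param b1_levels number of quantization levels of the B1+ map.
#' @param n_card_frames cached cardiac frames used by the simulator.
#' @param partial_volume area-weighted anti-aliasing at class boundaries.
#' @param resp_drift modulate respiratory period/amplitude by +-10% over the
#'   scan (seeded) to exercise binning robustness.
#' @param n_coils number of receive coils.
#' @param seed generator seed; everything downstream is deterministic in it.
#' @export
phantom_config <- function(grid_n = 160L, fov_mm = 270,
                           tissues = list(
                             myocardium = tissue_params(amp = 0.8, t1_ms = 1200, t2_ms = 42),
                             blood = tissue_params(amp = 1.0, t1_ms = 1900, t2_ms = 250),
                             liver = tissue_params(amp = 0.9, t1_ms = 800, t2_ms = 34)),
                           cardiac_period_ms = 920, resp_period_ms = 3800,
                           resp_amp_mm = 12, contraction_frac = 0.25,
                           b1_range = c(0.85, 1.15), b1_levels = 21L,
                           n_card_frames = 64L, partial_volume = TRUE,
                           resp_drift = TRUE, n_coils = 8L, seed = 1L) {
  stopifnot(grid_n >= 32, cardiac_period_ms > 0, resp_period_ms > 0,
            resp_amp_mm >= 0, contraction_frac >= 0, contraction_frac < 1)
  structure(list(grid_n = as.integer(grid_n), fov_mm = fov_mm,
                 tissues = tissues, cardiac_period_ms = cardiac_period_ms,
                 resp_period_ms = resp_period_ms, resp_amp_mm = resp_amp_mm,
                 contraction_frac = contraction_frac, b1_range = b1_range,
                 b1_levels = as.integer(b1_levels),
                 n_card_frames = as.integer(n_card_frames),
                 partial_volume = isTRUE(partial_volume),
                 resp_drift = isTRUE(resp_drift),
                 n_coils = as.integer(n_coils), seed = as.integer(seed)),
            class = "mt_phantom_config")
}

#' Cardiac contraction waveform (0 at diastole, 1 at peak systole)
#' @param phase cardiac phase in [0, 1).
#' @export
contraction_wave <- function(phase) ((1 - cos(2 * pi * phase)) / 2)^2

#' Respiratory displacement waveform (0 at end-expiration, 1 at peak
#' inspiration); asymmetric with a long expiratory plateau.
#' @param phase respiratory phase in [0, 1).
#' @export
resp_wave <- function(phase) sin(pi * phase)^4

slice_geometry <- function() {
  # mm; slices stored apical, mid, basal (matching the band phase order)
  data.frame(slice = c("apical", "mid", "basal"),
             cx = -22, cy = 8,
             r_in = c(12, 16, 19), r_out = c(24, 30, 33))
}

#' Construct the dynamic phantom
#'
#' Deterministic in the seed: geometry, the quantized smooth B1+ maps, the
#' coil sensitivities and the (optional) respiratory drift realization are
#' all drawn from it.
#'
#' @param cfg an \code{mt_phantom_config}.
#' @return class \code{mt_phantom}.
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "mt_phantom_config"))
  geo <- slice_geometry()
  liver <- list(x0 = 32, x1 = 118, y0 = -85, y1 = 85, round = 25)
  if (liver$x0 <= max(geo$cx + geo$r_out) + 2)
    stop("overlapping geometry: liver intersects the ventricle")
  set.seed(cfg$seed)
  ns <- nrow(geo)
  n <- cfg$grid_n
  g <- ((seq_len(n) - 1) - n / 2 + 0.5) / n * cfg$fov_mm
  xy <- expand.grid(x = g, y = g)
  lv <- cfg$b1_range
  levels <- seq(lv[1], lv[2], length.out = cfg$b1_levels)
  b1idx <- matrix(0L, n * n, ns)
  for (s in seq_len(ns)) {
    co <- stats::runif(3, -1, 1)
    raw <- (co[1] * xy$x + co[2] * xy$y) / cfg$fov_mm +
      co[3] * ((xy$x / cfg$fov_mm)^2 - (xy$y / cfg$fov_mm)^2)
    raw <- mean(lv) + raw * diff(lv) * 0.45     # smooth, centered
    raw <- pmin(pmax(raw, lv[1]), lv[2])
    b1idx[, s] <- as.integer(round((raw - lv[1]) / diff(lv) *
                                     (cfg$b1_levels - 1)))
  }
  drift <- list(period_mod = 0, amp_mod = 0, phase = 0)
  if (cfg$resp_drift)
    drift <- list(period_mod = 0.1, amp_mod = 0.1,
                  phase = stats::runif(2, 0, 2 * pi),
                  cycle_ms = stats::runif(1, 25e3, 40e3))
  coils <- make_coil_maps(n, cfg$n_coils, ns, cfg$fov_mm, seed = cfg$seed + 1L)
  structure(list(cfg = cfg, geo = geo, liver = liver,
                 b1_levels = levels, b1idx = b1idx, b1_map =
                   matrix(levels[b1idx + 1L], n * n, ns),
                 coils = coils, drift = drift, xy = xy),
            class = "mt_phantom")
}

#' Smooth loop-like coil sensitivity maps
#'
#' Complex sensitivities with loop-element magnitude fall-off and a low-order
#' phase, normalized so the coil root-sum-of-squares is exactly 1 at every
#' voxel. Seeded.
#'
#' @param grid_n matrix size. @param n_coils coils. @param ns slices.
#' @param fov_mm field of view. @param seed RNG seed.
#' @return complex array (grid_n^2, n_coils, ns).
#' @export
make_coil_maps <- function(grid_n, n_coils, ns, fov_mm = 270, seed = 1L) {
  set.seed(seed)
  n <- grid_n
  g <- ((seq_len(n) - 1) - n / 2 + 0.5) / n * fov_mm
  xy <- expand.grid(x = g, y = g)
  out <- array(0i, dim = c(n * n, n_coils, ns))
  r0 <- 0.62 * fov_mm
  for (s in seq_len(ns)) {
    for (c in seq_len(n_coils)) {
      th <- 2 * pi * (c - 1) / n_coils + 0.15 * s + stats::runif(1, -0.1, 0.1)
      cx <- r0 * cos(th); cy <- r0 * sin(th)
      d2 <- ((xy$x - cx)^2 + (xy$y - cy)^2) / fov_mm^2
      mag <- 1 / (0.18 + d2)
      phs <- 2 * pi * (stats::runif(1, -0.4, 0.4) * xy$x +
                       stats::runif(1, -0.4, 0.4) * xy$y) / fov_mm +
        stats::runif(1, 0, 2 * pi)
      out[, c, s] <- mag * exp(1i * phs)
    }
    rss <- sqrt(rowSums(Mod(out[, , s, drop = FALSE][, , 1])^2))
    out[, , s] <- out[, , s] / rss
  }
  out
}

class_names <- function() c("background", "myocardium", "blood", "liver")

# Area-weighted class fraction maps for one slice at one motion state.
frame_fractions <- function(phantom, card_phase, resp_mm, slice_i) {
  cfg <- phantom$cfg
  n <- cfg$grid_n
  geo <- phantom$geo[slice_i, ]
  w <- contraction_wave(card_phase)
  r_in <- geo$r_in * (1 - cfg$contraction_frac * w)
  r_out <- geo$r_out * (1 - 0.4 * cfg$contraction_frac * w)
  lv <- phantom$liver
  ss <- if (cfg$partial_volume) 3L else 1L
  vox <- cfg$fov_mm / n
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss * vox
  frac <- matrix(0, n * n, 4L)
  x0 <- phantom$xy$x + resp_mm
  y0 <- phantom$xy$y
  for (ox in offs) for (oy in offs) {
    x <- x0 + ox; y <- y0 + oy
    r2 <- (x - geo$cx)^2 + (y - geo$cy)^2
    cls <- rep(1L, n * n)
    inliv <- x > lv$x0 & x < lv$x1 & y > lv$y0 & y < lv$y1
    cls[inliv] <- 4L
    cls[r2 < r_out^2] <- 2L
    cls[r2 < r_in^2] <- 3L
    ix <- cbind(seq_len(n * n), cls)
    frac[ix] <- frac[ix] + 1 / ss^2
  }
  frac
}

#' Rasterize per-voxel tissue-parameter images at one motion state
#'
#' @param phantom an \code{mt_phantom}.
#' @param card_phase,resp_phase phases in [0, 1).
#' @param slice slice index (1 apical, 2 mid, 3 basal).
#' @return list of grid_n x grid_n matrices: amp, t1_ms, t2_ms, eff, b1,
#'   class (dominant class index) and the fraction matrix.
#' @export
phantom_frame <- function(phantom, card_phase, resp_phase, slice = 2L) {
  stopifnot(card_phase >= 0, card_phase < 1, resp_phase >= 0, resp_phase < 1)
  cfg <- phantom$cfg
  resp_mm <- cfg$resp_amp_mm * resp_wave(resp_phase)
  fr <- frame_fractions(phantom, card_phase, resp_mm, slice)
  n <- cfg$grid_n
  cls <- max.col(fr, ties.method = "first")
  get <- function(field, bgval) {
    v <- c(bgval, vapply(cfg$tissues, function(t) t[[field]], numeric(1)))
    matrix(v[cls], n, n)
  }
  amp <- matrix(rowSums(fr %*% diag(c(0, vapply(cfg$tissues, function(t) t$amp,
                                                numeric(1))))), n, n)
  list(amp = amp, t1_ms = get("t1_ms", NA_real_), t2_ms = get("t2_ms", NA_real_),
       eff = get("eff", NA_real_),
       b1 = matrix(phantom$b1_map[, slice], n, n),
       class = matrix(cls, n, n), fractions = fr)
}

#' Motion phases and respiratory displacement at given times
#'
#' @param phantom an \code{mt_phantom}.
#' @param time_ms numeric vector of times.
#' @return data.frame with card_phase, resp_phase, resp_mm.
#' @export
motion_phases <- function(phantom, time_ms) {
  cfg <- phantom$cfg
  card <- (time_ms / cfg$cardiac_period_ms) %% 1
  if (cfg$resp_drift && length(time_ms) > 1) {
    d <- phantom$drift
    p_t <- cfg$resp_period_ms *
      (1 + d$period_mod * sin(2 * pi * time_ms / d$cycle_ms + d$phase[1]))
    a_t <- cfg$resp_amp_mm *
      (1 + d$amp_mod * sin(2 * pi * time_ms / d$cycle_ms + d$phase[2]))
    dt <- diff(c(0, time_ms))
    resp <- (cumsum(dt / p_t)) %% 1
  } else {
    resp <- (time_ms / cfg$resp_period_ms) %% 1
    a_t <- rep(cfg$resp_amp_mm, length(time_ms))
  }
  data.frame(card_phase = card, resp_phase = resp,
             resp_mm = a_t * resp_wave(resp))
}

#' Simulate an SMS radial scan of the phantom
#'
#' Runs the exact forward model line by line: the per-voxel recovery signal
#' of each line's (combination, excitation index) is taken from the
#' closed-form signal model at the line's cardiac frame, coil sensitivities
#' and per-band CAIPIRINHA phasors are applied, bands summed, the radial
#' line evaluated by exact non-uniform Fourier transform, the rigid
#' respiratory translation applied as its exact k-space phase ramp, and
#' seeded complex Gaussian noise added.
#'
#' @param phantom an \code{mt_phantom}.
#' @param schedule an \code{mt_schedule}.
#' @param noise_sigma standard deviation of the complex Gaussian noise per
#'   real/imaginary component, in units of the k-space samples.
#' @param seed noise seed (defaults to the phantom seed).
#' @param nufft use the fast NUFFT evaluation of the radial lines.
#' @return class \code{mt_raw}: imaging/training sample arrays
#'   (n_samp x n_coil x n_lines) with per-line metadata, truth sidecar, coil
#'   maps, and acquisition descriptors.
#' @export
simulate_scan <- function(phantom, schedule, noise_sigma = 0, seed = NULL,
                          nufft = TRUE) {
  cfg <- phantom$cfg
  if (is.null(seed)) seed <- cfg$seed + 2L
  n <- cfg$grid_n
  traj <- make_trajectory(n)
  rd <- schedule$readouts
  per <- schedule$periods
  mot <- motion_phases(phantom, rd$time_ms)
  nf <- cfg$n_card_frames
  f_idx <- pmin(as.integer(floor(mot$card_phase * nf)), nf - 1L)
  ns <- 3L; ncls <- 4L
  # cached class-fraction maps per cardiac frame per slice (end-expiration)
  frac <- array(0, dim = c(n * n, ncls, nf, ns))
  for (s in seq_len(ns)) for (f in seq_len(nf))
    frac[, , f, s] <- frame_fractions(phantom, (f - 0.5) / nf, 0, s)
  # signal lookup over (n, combo, class, b1 level)
  nlvl <- cfg$b1_levels
  N <- per$n_readouts[1]
  cc <- cycle_combos(schedule$cfg)
  cyc <- nrow(cc)
  stab <- array(0, dim = c(N, cyc, ncls, nlvl))
  for (k in seq_len(cyc)) for (ci in 2:4) for (q in seq_len(nlvl)) {
    t0 <- cfg$tissues[[ci - 1L]]
    tis <- tissue_params(amp = t0$amp, eff = t0$eff, b1 = phantom$b1_levels[q],
                         t1_ms = t0$t1_ms, t2_ms = t0$t2_ms)
    stab[, k, ci, q] <- signal_curve(tis, cc$prep_ms[k], cc$flip_deg[k],
                                     cc$prev_flip_deg[k], schedule$cfg$tr_ms,
                                     n = seq_len(N))
  }
  shift_frac <- mot$resp_mm / cfg$fov_mm
  ph <- band_phases(ns)
  y <- cpp_sim_scan(as.vector(frac), as.integer(phantom$b1idx), as.vector(stab),
                    as.integer(rd$n), as.integer(rd$period %% cyc),
                    f_idx, shift_frac, rd$radial_angle_deg,
                    as.integer(rd$phase_step), as.complex(phantom$coils), ph,
                    traj$tx, traj$ty, traj$kr0, traj$dk, traj$n_samp,
                    cfg$n_coils, ns, ncls, nf, N, cyc, nlvl, nufft)
  if (noise_sigma > 0) {
    set.seed(seed)
    y <- y + complex(real = stats::rnorm(length(y), sd = noise_sigma),
                     imaginary = stats::rnorm(length(y), sd = noise_sigma))
  }
  y <- array(y, dim = c(traj$n_samp, cfg$n_coils, nrow(rd)))
  meta <- cbind(rd, combo = rd$period %% cyc,
                card_phase = mot$card_phase, resp_phase = mot$resp_phase,
                shift = shift_frac)
  is_img <- rd$role == "imaging"
  truth_maps <- lapply(seq_len(ns), function(s)
    phantom_frame(phantom, 0, 0, s))
  raw <- list(imaging = y[, , is_img, drop = FALSE],
              imaging_meta = meta[is_img, ],
              training = y[, , !is_img, drop = FALSE],
              training_meta = meta[!is_img, ],
              coils = phantom$coils,
              truth = list(maps = truth_maps, b1_map = phantom$b1_map,
                           line_motion = mot, tissues = cfg$tissues,
                           phantom_seed = cfg$seed),
              grid_n = n, oversample = traj$oversample, fov_mm = cfg$fov_mm,
              noise_sigma = noise_sigma, seed = seed, schedule = schedule)
  class(raw) <- "mt_raw"
  raw
}

#' @export
print.mt_raw <- function(x, ...) {
  cat("<mt_raw>", x$grid_n, "x", x$grid_n, "grid,",
      dim(x$imaging)[3], "imaging +", dim(x$training)[3], "training lines,",
      dim(x$imaging)[2], "coils, noise sd", x$noise_sigma, "\n")
  invisible(x)
}
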