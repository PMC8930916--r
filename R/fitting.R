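#' Render per-voxel recovery curves at a fixed motion state
#'
#' Evaluates the reconstructed image at every (excitation-grid, combination)
#' coordinate for one (cardiac, respiratory) bin pair.
#'
#' @param u_x spatial factor (nvox*nslice x L1).
#' @param phi an \code{mt_phi}. @param sub the subspaces (supplies the
#'   recovery-basis rows on the excitation grid).
#' @param c_star,r_star 1-based cardiac/respiratory bin.
#' @return complex array (nvox*nslice, n_grid, n_combos).
#' @export
extract_curves <- function(u_x, phi, sub, c_star, r_star) {
  nn <- nrow(sub$u_t1); l2 <- ncol(phi$u_t1)
  nk <- nrow(phi$u_ta)
  u2 <- sub$u_t1[, seq_len(l2), drop = FALSE]
  u2rep <- u2[rep(seq_len(nn), nk), , drop = FALSE]
  krep <- rep(seq_len(nk), each = nn)
  pl <- phi_eval(phi, u2rep, krep, c_star, r_star)
  array(u_x %*% pl, dim = c(nrow(u_x), nn, nk))
}

# phase-correct complex curves using the late-excitation (steady-state)
# samples, and return the signed real part
signed_real_curves <- function(curves) {
  d <- dim(curves)
  nn <- d[2]
  late <- curves[, max(1L, round(0.8 * nn)):nn, , drop = FALSE]
  ph <- Arg(apply(late, 1, sum))
  out <- Re(curves * exp(-1i * ph))    # recycles along dim 1
  array(out, d)
}

model_curves <- function(t1, t2, b1, eff, combos, n_grid, tr_ms) {
  nn <- length(n_grid)
  out <- numeric(nn * nrow(combos))
  e1 <- exp(-tr_ms / t1)
  for (k in seq_len(nrow(combos))) {
    th <- deg2rad(b1 * combos$flip_deg[k])
    g <- e1 * cos(th)
    q <- (1 - g) / (1 - e1 * cos(deg2rad(b1 * combos$prev_flip_deg[k])))
    pref <- (1 - e1) / (1 - g) * sin(th)
    cc <- eff * q * exp(-combos$prep_ms[k] / t2)
    out[(k - 1L) * nn + seq_len(nn)] <- pref * (1 + (cc - 1) * g^n_grid)
  }
  out
}

#' Step 1: dictionary matching plus local refinement of (A, B, beta, T2)
#'
#' Maximum normalized inner product over the dictionary, followed by
#' Nelder-Mead refinement of (T1', T2, beta, B) with the amplitude profiled
#' out linearly; T1' is estimated but discarded (step 2 re-fits it from the
#' low-flip-angle curve).
#'
#' @param curves complex array from \code{extract_curves} (already subset to
#'   the voxels to fit).
#' @param dict an \code{mt_dict} (matching grid).
#' @param refine run the local refinement.
#' @param chunk voxels per matching block.
#' @return data.frame with amp, eff, b1, t2_ms, t1_step1_ms, resid, flag.
#' @export
fit_step1 <- function(curves, dict, refine = TRUE, chunk = 512L) {
  y <- signed_real_curves(curves)
  nv <- dim(y)[1]
  ym <- matrix(y, nv)                      # voxel x (n*combo), combo-major
  rn <- sqrt(rowSums(ym^2))
  flag <- rn <= 0
  out <- data.frame(amp = numeric(nv), eff = NA_real_, b1 = NA_real_,
                    t2_ms = NA_real_, t1_step1_ms = NA_real_,
                    resid = NA_real_, flag = flag)
  if (all(flag)) return(out)
  # the dictionary rows are (combo, n) stacked combo-major like ym's columns
  map <- dict$grid$map
  best <- integer(nv); bscore <- numeric(nv)
  for (i0 in seq.int(1L, nv, by = chunk)) {
    ix <- i0:min(i0 + chunk - 1L, nv)
    sc <- (ym[ix, , drop = FALSE] / pmax(rn[ix], 1e-300)) %*% dict$atoms_norm
    best[ix] <- max.col(sc)
    bscore[ix] <- sc[cbind(seq_along(ix), best[ix])]
  }
  g <- dict$grid
  t1g <- g$t1_ms[map$t1[best]]; t2g <- g$t2_ms[map$t2[best]]
  b1g <- g$b1[map$b1[best]]; efg <- g$eff[map$eff[best]]
  combos <- dict$combos; ngr <- dict$n_grid; tr <- dict$tr_ms
  lo <- c(log(100), log(10), 0, -1.5); hi <- c(log(3000), log(3000), 1.5, 0)
  for (v in which(!flag)) {
    yv <- ym[v, ]
    if (refine) {
      fn <- function(p) {
        if (any(p < lo) || any(p > hi)) return(1e12)
        m <- model_curves(exp(p[1]), exp(p[2]), p[3], p[4], combos, ngr, tr)
        den <- sum(m^2)
        if (den < 1e-300) return(1e12)
        a <- sum(yv * m) / den
        sum((yv - a * m)^2)
      }
      p0 <- c(log(t1g[v]), log(t2g[v]), b1g[v], efg[v])
      opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                          control = list(maxit = 250, reltol = 1e-9))
      p <- opt$par
      t1g[v] <- exp(p[1]); t2g[v] <- exp(p[2]); b1g[v] <- p[3]; efg[v] <- p[4]
      m <- model_curves(t1g[v], t2g[v], b1g[v], efg[v], combos, ngr, tr)
      a <- sum(yv * m) / sum(m^2)
      out$amp[v] <- a
      out$resid[v] <- sqrt(opt$value) / max(rn[v], 1e-300)
    } else {
      m <- dict$atoms[, best[v]]
      out$amp[v] <- sum(yv * m) / sum(m^2)
      out$resid[v] <- sqrt(max(0, 1 - bscore[v]^2))
    }
  }
  out$eff <- efg; out$b1 <- b1g; out$t2_ms <- t2g; out$t1_step1_ms <- t1g
  out$eff[flag] <- NA; out$b1[flag] <- NA; out$t2_ms[flag] <- NA
  out
}

#' Step 2: T1 from the low-flip-angle recovery curves
#'
#' One-dimensional bounded search for T1 on the combinations acquired with
#' the smaller flip angle (reduced Look-Locker perturbation), holding
#' (beta, B, T2) from step 1 fixed and profiling the amplitude linearly.
#'
#' @param curves complex array from \code{extract_curves} (same voxels as
#'   \code{step1}).
#' @param step1 data.frame from \code{fit_step1}.
#' @param dict an \code{mt_dict}.
#' @param t1_bounds_ms search interval.
#' @return numeric vector of T1 estimates (ms).
#' @export
fit_step2 <- function(curves, step1, dict, t1_bounds_ms = c(100, 3000)) {
  combos <- dict$combos
  ksel <- which(combos$flip_deg == min(combos$flip_deg))
  if (length(ksel) == 0) stop("no low-flip-angle combinations in the schedule")
  y <- signed_real_curves(curves)
  nv <- dim(y)[1]
  ngr <- dict$n_grid; tr <- dict$tr_ms
  csub <- combos[ksel, , drop = FALSE]
  t1 <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    if (isTRUE(step1$flag[v]) || is.na(step1$t2_ms[v])) next
    yv <- as.vector(y[v, , ksel])
    fn <- function(lt1) {
      m <- model_curves(exp(lt1), step1$t2_ms[v], step1$b1[v], step1$eff[v],
                        csub, ngr, tr)
      den <- sum(m^2)
      if (den < 1e-300) return(1e12)
      a <- sum(yv * m) / den
      sum((yv - a * m)^2)
    }
    opt <- stats::optimize(fn, log(t1_bounds_ms), tol = 1e-6)
    t1[v] <- exp(opt$minimum)
  }
  t1
}

#' Voxelwise multiparametric mapping
#'
#' Orchestrates curve extraction at the chosen (diastolic, end-expiration)
#' motion state, support masking, step-1 (A, B, beta, T2) and step-2 (T1)
#' fitting, and map assembly.
#'
#' @param u_x spatial factor. @param phi an \code{mt_phi}.
#' @param dict_fit matching dictionary. @param sub subspaces.
#' @param bins an \code{mt_bins} (used to pick default motion state).
#' @param grid_n,nslice image geometry.
#' @param c_star,r_star 1-based bins; defaults: cardiac bin with the least
#'   contraction (diastole, from the truth phases when available, else bin 1)
#'   and the respiratory bin with the most complete contrast coverage - the
#'   bin maximizing the minimum per-combination training-line count, ties
#'   broken toward end-expiration. Every contrast weighting must actually be
#'   sampled at the fitted motion state; a bin missing a combination entirely
#'   leaves those cells to pure extrapolation by the completion, which
#'   degrades the rendered recovery curves there.
#' @param support_frac voxels with curve RMS below this fraction of the
#'   maximum are not fitted.
#' @param refine run step-1 local refinement.
#' @return class \code{mt_maps}: per-slice parameter maps and diagnostics.
#' @export
map_volume <- function(u_x, phi, dict_fit, sub, bins, grid_n, nslice = 3L,
                       c_star = NULL, r_star = NULL, support_frac = 0.08,
                       refine = TRUE) {
  if (is.null(r_star)) {
    if (!is.null(bins$lines$combo)) {
      cov <- table(factor(bins$lines$combo),
                   factor(bins$lines$resp_bin, levels = 0:(bins$n_resp - 1)))
      r_star <- which.max(apply(cov, 2, min))  # ties: lowest label wins
    } else r_star <- 1L
  }
  if (is.null(c_star)) {
    if (!is.null(bins$lines$truth_card_phase)) {
      w <- tapply(contraction_wave(bins$lines$truth_card_phase),
                  bins$lines$card_bin, mean)
      c_star <- as.integer(names(w)[which.min(w)]) + 1L
    } else c_star <- 1L
  }
  curves <- extract_curves(u_x, phi, sub, c_star, r_star)
  nv <- dim(curves)[1]
  rms <- sqrt(rowMeans(Mod(matrix(curves, nv))^2))
  support <- rms > support_frac * max(rms)
  s1 <- fit_step1(curves[support, , , drop = FALSE], dict_fit, refine = refine)
  t1 <- fit_step2(curves[support, , , drop = FALSE], s1, dict_fit)
  fill <- function(vals) {
    m <- rep(NA_real_, nv); m[support] <- vals
    array(m, dim = c(grid_n, grid_n, nslice))
  }
  structure(list(t1_ms = fill(t1), t2_ms = fill(s1$t2_ms),
                 amp = fill(s1$amp), eff = fill(s1$eff), b1 = fill(s1$b1),
                 resid = fill(s1$resid),
                 support = array(support, dim = c(grid_n, grid_n, nslice)),
                 c_star = c_star, r_star = r_star,
                 grid_n = grid_n, nslice = nslice),
            class = "mt_maps")
}

#' Write parameter maps as NIfTI files
#'
#' One float32 NIfTI per parameter per slice plus a JSON sidecar of the fit
#' settings.
#'
#' @param maps an \code{mt_maps}. @param dir output directory.
#' @param fov_mm field of view for the voxel dimensions.
#' @param slice_names names used in filenames.
#' @export
write_maps_nifti <- function(maps, dir, fov_mm = 270,
                             slice_names = c("apical", "mid", "basal")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- fov_mm / maps$grid_n
  for (p in c("t1_ms", "t2_ms", "amp", "eff", "b1")) {
    for (s in seq_len(maps$nslice)) {
      img <- maps[[p]][, , s]
      img[is.na(img)] <- 0
      f <- file.path(dir, sprintf("%s_%s.nii.gz", p, slice_names[s]))
      RNifti::writeNifti(RNifti::asNifti(img, pixdim = c(vox, vox, 1)), f)
    }
  }
  side <- list(c_star = maps$c_star, r_star = maps$r_star,
               grid_n = maps$grid_n, fov_mm = fov_mm,
               parameters = c("t1_ms", "t2_ms", "amp", "eff", "b1"))
  jsonlite::write_json(side, file.path(dir, "fit_settings.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
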