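#' Tissue parameter set
#'
#' Voxel- or class-level parameters of the spoiled gradient-echo recovery
#' signal: amplitude \code{amp}, signed preparation efficiency \code{eff}
#' (-1 for a perfect inversion), transmit-field scale \code{b1} multiplying
#' nominal flip angles, and the relaxation times in ms.
#'
#' @param amp signal amplitude (arbitrary units).
#' @param eff signed inversion / T2prep-IR pulse efficiency.
#' @param b1 B1+ transmit scale, >= 0.
#' @param t1_ms,t2_ms longitudinal / transverse relaxation times (ms), > 0.
#' @return an object of class \code{mt_tissue}.
#' @export
tissue_params <- function(amp = 1, eff = -1, b1 = 1, t1_ms, t2_ms) {
  stopifnot(t1_ms > 0, t2_ms > 0, b1 >= 0)
  structure(list(amp = amp, eff = eff, b1 = b1,
                 t1_ms = t1_ms, t2_ms = t2_ms), class = "mt_tissue")
}

deg2rad <- function(x) x * pi / 180

#' FLASH steady-state ratio between successive recovery periods
#'
#' Ratio of the spoiled-FLASH longitudinal steady states reached with the
#' previous and the current flip angle,
#' \deqn{Q_k = (1 - E_1\cos\beta\alpha_k) / (1 - E_1\cos\beta\alpha_{k-1})}
#' with \eqn{E_1 = \exp(-TR/T_1)}. It carries the memory of the previous
#' period's steady state into the preparation of period \eqn{k}.
#'
#' @param t1_ms T1 in ms (vectorized).
#' @param b1 B1+ scale.
#' @param alpha_k_deg current flip angle (degrees).
#' @param alpha_prev_deg previous period's flip angle (degrees).
#' @param tr_ms repetition time (ms).
#' @export
q_factor <- function(t1_ms, b1, alpha_k_deg, alpha_prev_deg, tr_ms) {
  stopifnot(all(t1_ms > 0))
  e1 <- exp(-tr_ms / t1_ms)
  num <- 1 - e1 * cos(deg2rad(b1 * alpha_k_deg))
  den <- 1 - e1 * cos(deg2rad(b1 * alpha_prev_deg))
  if (any(abs(den) < 1e-15)) stop("degenerate flip angle: steady-state denominator ~ 0")
  num / den
}

#' Closed-form T2prep-IR FLASH recovery signal
#'
#' Signal at the n-th excitation of a recovery period that starts from the
#' previous period's steady state, is inverted (and T2-prepared for
#' \code{prep_ms} > 0) with efficiency \code{eff}, and is then read out by a
#' spoiled FLASH train with flip angle \code{flip_deg}:
#' \deqn{s(n) = A\,\frac{1-E_1}{1-E_1\cos\beta\alpha_k}
#'   \left[1 + \left(B Q_k e^{-\tau/T_2} - 1\right)(E_1\cos\beta\alpha_k)^n\right]
#'   \sin\beta\alpha_k.}
#'
#' @param tissue an \code{mt_tissue} (or list with the same fields).
#' @param prep_ms preparation duration tau (ms) of this period.
#' @param flip_deg flip angle alpha_k (degrees) of this period.
#' @param prev_flip_deg flip angle of the previous period.
#' @param tr_ms repetition time (ms).
#' @param n integer vector of excitation indices (1-based).
#' @return numeric vector of signals, one per entry of \code{n}.
#' @export
signal_curve <- function(tissue, prep_ms, flip_deg, prev_flip_deg, tr_ms,
                         n = seq_len(attr(prep_ms, "n_readouts") %||% 1L)) {
  e1 <- exp(-tr_ms / tissue$t1_ms)
  th <- deg2rad(tissue$b1 * flip_deg)
  q <- q_factor(tissue$t1_ms, tissue$b1, flip_deg, prev_flip_deg, tr_ms)
  g <- e1 * cos(th)
  pref <- tissue$amp * (1 - e1) / (1 - g) * sin(th)
  cc <- tissue$eff * q * exp(-prep_ms / tissue$t2_ms) - 1
  pref * (1 + cc * g^n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the closed form over a whole schedule
#'
#' Convenience wrapper: one signal value per readout row of the schedule,
#' using each period's (prep, flip, previous flip) and the readout's n index.
#'
#' @param tissue an \code{mt_tissue}.
#' @param schedule an \code{mt_schedule}.
#' @export
signal_schedule <- function(tissue, schedule) {
  per <- schedule$periods
  rd <- schedule$readouts
  out <- numeric(nrow(rd))
  for (p in seq_len(nrow(per))) {
    idx <- which(rd$period == per$period[p])
    out[idx] <- signal_curve(tissue, per$prep_ms[p], per$flip_deg[p],
                             per$prev_flip_deg[p], schedule$cfg$tr_ms,
                             n = rd$n[idx])
  }
  out
}

#' Per-TR Bloch recursion over a schedule
#'
#' Independent iterative evaluation of the recovery signal: the longitudinal
#' magnetization is propagated excitation by excitation
#' (\code{Mz <- Mz*cos(beta*alpha)}, then \code{Mz <- M0 + (Mz - M0)*E1} over
#' each TR, signal recorded as \code{Mz*sin(beta*alpha)}), with the
#' preparation applied at each period start as
#' \code{Mz <- eff * Mz_pre * exp(-prep/T2)}.
#'
#' With \code{steady_prep = TRUE} (default) the magnetization entering each
#' preparation is the FLASH steady state of the previous period's flip angle
#' - the same assumption the closed form makes - so the two evaluations agree
#' to machine precision. With \code{steady_prep = FALSE} the recursion runs
#' continuously across periods, which is the physically exact behaviour; for
#' long T1 the two differ because a single recovery period does not fully
#' reach steady state.
#'
#' @param tissue an \code{mt_tissue}.
#' @param schedule an \code{mt_schedule}.
#' @param steady_prep reset to the previous period's steady state at each
#'   preparation (matches the closed form's assumption).
#' @return numeric vector, one signal per readout.
#' @export
bloch_oracle <- function(tissue, schedule, steady_prep = TRUE) {
  per <- schedule$periods
  rd <- schedule$readouts
  tr <- schedule$cfg$tr_ms
  e1 <- exp(-tr / tissue$t1_ms)
  m0 <- tissue$amp
  ss <- function(flip) {
    th <- deg2rad(tissue$b1 * flip)
    m0 * (1 - e1) / (1 - e1 * cos(th))
  }
  out <- numeric(nrow(rd))
  # start at the steady state appropriate to the flip angle that nominally
  # precedes the first executed period
  mz <- ss(per$prev_flip_deg[1])
  row <- 1L
  for (p in seq_len(nrow(per))) {
    if (steady_prep) mz <- ss(per$prev_flip_deg[p])
    mz <- tissue$eff * mz * exp(-per$prep_ms[p] / tissue$t2_ms)
    th <- deg2rad(tissue$b1 * per$flip_deg[p])
    cth <- cos(th); sth <- sin(th)
    nr <- per$n_readouts[p]
    for (i in seq_len(nr)) {
      mz <- mz * cth
      mz <- m0 + (mz - m0) * e1
      out[row] <- mz * sth
      row <- row + 1L
    }
  }
  out
}

default_dict_grids <- function() {
  list(t1_ms = exp(seq(log(100), log(3000), length.out = 21)),
       t2_ms = exp(seq(log(10), log(3000), length.out = 21)),
       b1 = seq(0, 1.5, length.out = 7),
       eff = seq(-1, -0.7, length.out = 7))
}

#' Build the training dictionary of recovery signal curves
#'
#' One column per combination of the four parameter grids (T1, T2, B1+ scale,
#' preparation efficiency), rows stacked over the schedule's cycle of
#' preparation/flip combinations at a decimated excitation grid
#' (every \code{n_stride}-th excitation). The default grids are 21
#' log-spaced T1 in [100, 3000] ms, 21 log-spaced T2 in [10, 3000] ms,
#' 7 B1+ values in [0, 1.5] and 7 efficiencies in [-1, -0.7].
#'
#' @param schedule an \code{mt_schedule}.
#' @param grids list with numeric vectors \code{t1_ms}, \code{t2_ms},
#'   \code{b1}, \code{eff}; defaults to \code{default_dict_grids()}.
#' @param n_stride decimation stride of the excitation index (atoms are
#'   stored at full resolution when the period has at most 256 readouts).
#' @return an object of class \code{mt_dict}: \code{atoms} (raw columns),
#'   \code{atoms_norm} (l2-normalized columns), \code{grid} (the parameter
#'   grids and the per-column grid index map), \code{n_grid}, \code{combos}.
#' @export
build_dictionary <- function(schedule, grids = default_dict_grids(),
                             n_stride = 8L) {
  if (any(lengths(grids) == 0)) stop("empty dictionary grid")
  per <- cycle_combos(schedule$cfg)
  cyc <- nrow(per)
  n_read <- schedule$periods$n_readouts[1]
  if (n_read <= 256L) n_stride <- 1L
  n_grid <- seq.int(1L, n_read, by = n_stride)
  map <- expand.grid(t1 = seq_along(grids$t1_ms), t2 = seq_along(grids$t2_ms),
                     b1 = seq_along(grids$b1), eff = seq_along(grids$eff))
  t1 <- grids$t1_ms[map$t1]; t2 <- grids$t2_ms[map$t2]
  b1 <- grids$b1[map$b1]; ef <- grids$eff[map$eff]
  na <- length(t1); nn <- length(n_grid)
  tr <- schedule$cfg$tr_ms
  atoms <- matrix(0, nrow = cyc * nn, ncol = na)
  e1 <- exp(-tr / t1)
  for (k in seq_len(cyc)) {
    th <- deg2rad(b1 * per$flip_deg[k])
    thp <- deg2rad(b1 * per$prev_flip_deg[k])
    g <- e1 * cos(th)
    q <- (1 - g) / (1 - e1 * cos(thp))
    pref <- (1 - e1) / (1 - g) * sin(th)
    cc <- ef * q * exp(-per$prep_ms[k] / t2)
    # s(n, a) = pref_a + pref_a * (cc_a - 1) * g_a^n
    gp <- exp(outer(n_grid, log(pmax(g, .Machine$double.xmin))))
    blk <- gp * rep(pref * (cc - 1), each = nn) + rep(pref, each = nn)
    atoms[(k - 1L) * nn + seq_len(nn), ] <- blk
  }
  atoms[!is.finite(atoms)] <- 0
  nrm <- sqrt(colSums(atoms^2))
  atoms_norm <- sweep(atoms, 2, ifelse(nrm > 0, nrm, 1), "/")
  structure(list(atoms = atoms, atoms_norm = atoms_norm,
                 grid = c(grids, list(map = map)),
                 n_grid = n_grid, combos = per, tr_ms = tr),
            class = "mt_dict")
}

#' Relaxation subspaces from the dictionary SVD
#'
#' Left singular vectors of the dictionary's excitation-index unfolding give
#' the within-period recovery basis; left singular vectors of its
#' combination-index unfolding give the basis over the cycle of
#' preparation/flip combinations.
#'
#' @param dict an \code{mt_dict}.
#' @param L_t1 rank of the excitation (recovery) basis.
#' @param L_ta rank of the combination basis.
#' @return class \code{mt_subspaces}: orthonormal \code{u_t1}
#'   (length(n_grid) x L_t1) and \code{u_ta} (n_combos x L_ta), singular
#'   values, and the relative Frobenius reconstruction errors of the
#'   dictionary under each truncation.
#' @export
fit_subspaces <- function(dict, L_t1 = 6L, L_ta = 6L) {
  nn <- length(dict$n_grid); nk <- nrow(dict$combos)
  na <- ncol(dict$atoms)
  if (L_t1 > nn || L_t1 > nk * na) stop("L_t1 exceeds matrix dimension")
  if (L_ta > nk) stop("L_ta exceeds number of combinations")
  arr <- array(dict$atoms, dim = c(nn, nk, na))
  u1 <- matrix(arr, nn)                       # n x (combo*atom)
  c1 <- tcrossprod(u1)
  e1 <- eigen(c1, symmetric = TRUE)
  u2 <- matrix(aperm(arr, c(2, 1, 3)), nk)    # combo x (n*atom)
  c2 <- tcrossprod(u2)
  e2 <- eigen(c2, symmetric = TRUE)
  relerr <- function(ev, L) {
    tot <- sum(pmax(ev$values, 0))
    sqrt(max(0, 1 - sum(pmax(ev$values[seq_len(L)], 0)) / tot))
  }
  structure(list(
    u_t1 = e1$vectors[, seq_len(L_t1), drop = FALSE],
    u_ta = e2$vectors[, seq_len(L_ta), drop = FALSE],
    sv_t1 = sqrt(pmax(e1$values, 0)), sv_ta = sqrt(pmax(e2$values, 0)),
    err_t1 = relerr(e1, L_t1), err_ta = relerr(e2, L_ta),
    n_grid = dict$n_grid), class = "mt_subspaces")
}

#' Evaluate the recovery basis at arbitrary excitation indices
#'
#' The stored basis lives on the dictionary's decimated excitation grid. For
#' arbitrary n the basis functions are evaluated exactly through the SVD
#' relation U(n, :) = D(n, :) V S^{-1}: the dictionary row at excitation n is
#' regenerated from the closed-form signal model and projected through the
#' stored decomposition. At grid points this reproduces the stored rows.
#'
#' @param dict the \code{mt_dict} the subspaces were fitted from.
#' @param sub the \code{mt_subspaces}.
#' @param n_values integer vector of excitation indices.
#' @param chunk number of atoms per evaluation block.
#' @return matrix length(n_values) x L_t1.
#' @export
eval_u_t1 <- function(dict, sub, n_values, chunk = 4000L) {
  L <- ncol(sub$u_t1)
  nn <- length(dict$n_grid); nk <- nrow(dict$combos)
  na <- ncol(dict$atoms)
  sv2 <- sub$sv_t1[seq_len(L)]^2
  # W = D1' U S^-2, with D1 the n x (combo*atom) unfolding
  arr <- array(dict$atoms, dim = c(nn, nk, na))
  d1 <- matrix(arr, nn)
  w <- crossprod(d1, sub$u_t1) %*% diag(1 / sv2, L)
  g <- dict$grid
  map <- g$map
  t1 <- g$t1_ms[map$t1]; t2 <- g$t2_ms[map$t2]
  b1 <- g$b1[map$b1]; ef <- g$eff[map$eff]
  tr <- dict$tr_ms
  out <- matrix(0, length(n_values), L)
  e1a <- exp(-tr / t1)
  for (k in seq_len(nk)) {
    th <- deg2rad(b1 * dict$combos$flip_deg[k])
    thp <- deg2rad(b1 * dict$combos$prev_flip_deg[k])
    gg <- e1a * cos(th)
    q <- (1 - gg) / (1 - e1a * cos(thp))
    pref <- (1 - e1a) / (1 - gg) * sin(th)
    cc <- ef * q * exp(-dict$combos$prep_ms[k] / t2)
    for (a0 in seq.int(1L, na, by = chunk)) {
      a1 <- min(a0 + chunk - 1L, na)
      ix <- a0:a1
      gp <- exp(outer(n_values, log(pmax(gg[ix], .Machine$double.xmin))))
      blk <- gp * rep(pref[ix] * (cc[ix] - 1), each = length(n_values)) +
        rep(pref[ix], each = length(n_values))
      blk[!is.finite(blk)] <- 0
      out <- out + blk %*% w[(ix - 1L) * nk + k, , drop = FALSE]
    }
  }
  out
}
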