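db4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)
  list(h = h, g = g)
}

# one periodic analysis step along the rows of x (n x m), n even
dwt_step <- function(x) {
  f <- db4_filters()
  n <- nrow(x); n2 <- n / 2
  idx <- outer(2 * (seq_len(n2) - 1), 1:4, "+")
  idx <- (idx - 1) %% n + 1
  a <- f$h[1] * x[idx[, 1], , drop = FALSE] + f$h[2] * x[idx[, 2], , drop = FALSE] +
    f$h[3] * x[idx[, 3], , drop = FALSE] + f$h[4] * x[idx[, 4], , drop = FALSE]
  d <- f$g[1] * x[idx[, 1], , drop = FALSE] + f$g[2] * x[idx[, 2], , drop = FALSE] +
    f$g[3] * x[idx[, 3], , drop = FALSE] + f$g[4] * x[idx[, 4], , drop = FALSE]
  rbind(a, d)
}

idwt_step <- function(y) {
  f <- db4_filters()
  n <- nrow(y); n2 <- n / 2
  a <- y[seq_len(n2), , drop = FALSE]
  d <- y[n2 + seq_len(n2), , drop = FALSE]
  x <- matrix(0, n, ncol(y))
  if (is.complex(y)) x <- matrix(0i, n, ncol(y))
  for (i in 1:4) {
    rows <- (2 * (seq_len(n2) - 1) + i - 1) %% n + 1
    contrib <- f$h[i] * a + f$g[i] * d
    x[rows, ] <- x[rows, ] + contrib
  }
  x
}

#' Orthogonal Daubechies-4 2-D wavelet transform (periodic)
#'
#' @param img square matrix (side divisible by 2^levels).
#' @param levels decomposition levels.
#' @return coefficient matrix of the same size.
#' @export
dwt2 <- function(img, levels = 3L) {
  n <- nrow(img)
  out <- img
  sz <- n
  for (j in seq_len(levels)) {
    blk <- out[seq_len(sz), seq_len(sz), drop = FALSE]
    blk <- dwt_step(blk)
    blk <- t(dwt_step(t(blk)))
    out[seq_len(sz), seq_len(sz)] <- blk
    sz <- sz / 2
  }
  out
}

#' Inverse of \code{dwt2}
#' @param coef coefficient matrix. @param levels decomposition levels.
#' @export
idwt2 <- function(coef, levels = 3L) {
  n <- nrow(coef)
  out <- coef
  sz <- n / 2^(levels - 1)
  for (j in seq_len(levels)) {
    blk <- out[seq_len(sz), seq_len(sz), drop = FALSE]
    blk <- t(idwt_step(t(blk)))
    blk <- idwt_step(blk)
    out[seq_len(sz), seq_len(sz)] <- blk
    sz <- sz * 2
  }
  out
}

soft <- function(x, tau) sign(x) * pmax(abs(x) - tau, 0)

# soft-threshold the db4 coefficients of every spatial basis image,
# separately on real and imaginary parts
wavelet_shrink <- function(u, grid_n, ns, tau, levels = 3L) {
  for (j in seq_len(ncol(u))) for (s in seq_len(ns)) {
    ix <- (s - 1L) * grid_n^2 + seq_len(grid_n^2)
    img <- matrix(u[ix, j], grid_n, grid_n)
    wr <- soft(dwt2(Re(img), levels), tau)
    wi <- soft(dwt2(Im(img), levels), tau)
    u[ix, j] <- as.vector(idwt2(wr, levels) + 1i * idwt2(wi, levels))
  }
  u
}

wavelet_l1 <- function(u, grid_n, ns, levels = 3L) {
  tot <- 0
  for (j in seq_len(ncol(u))) for (s in seq_len(ns)) {
    ix <- (s - 1L) * grid_n^2 + seq_len(grid_n^2)
    img <- matrix(u[ix, j], grid_n, grid_n)
    tot <- tot + sum(abs(dwt2(Re(img), levels))) +
      sum(abs(dwt2(Im(img), levels)))
  }
  tot
}

#' Temporal weights of the imaging lines
#'
#' Places every imaging line in the temporal factor tensor: (excitation,
#' combination) come from the schedule; (cardiac, respiratory) bins are
#' inherited from the temporally nearest training line (at most one TR away
#' with the 1:1 interleave). The recovery basis is evaluated exactly at each
#' line's excitation index.
#'
#' @param raw an \code{mt_raw}. @param bins an \code{mt_bins}.
#' @param dict,sub dictionary and subspaces. @param phi an \code{mt_phi}.
#' @return list: \code{phi_lines} (L1 x n_imaging), per-line \code{c}/\code{r}.
#' @export
imaging_phi <- function(raw, bins, dict, sub, phi) {
  meta <- raw$imaging_meta
  tt <- bins$lines$time_ms
  nearest <- findInterval(meta$time_ms, tt)
  nearest <- pmin(pmax(nearest, 1L), length(tt))
  lo_ok <- nearest < length(tt) &
    abs(tt[pmin(nearest + 1L, length(tt))] - meta$time_ms) <
      abs(tt[nearest] - meta$time_ms)
  nearest[lo_ok] <- nearest[lo_ok] + 1L
  cb <- bins$lines$card_bin[nearest] + 1L
  rb <- bins$lines$resp_bin[nearest] + 1L
  nv <- sort(unique(meta$n))
  u2full <- eval_u_t1(dict, sub, nv)
  u2rows <- u2full[match(meta$n, nv), , drop = FALSE]
  u2rows <- u2rows[, seq_len(ncol(phi$u_t1)), drop = FALSE]
  list(phi_lines = phi_eval(phi, u2rows, meta$combo + 1L, cb, rb),
       card = cb - 1L, resp = rb - 1L)
}

#' Recover the spatial factor from imaging data
#'
#' Solves
#' \deqn{\min_{U_x} \|d - \Omega(\Phi \times_1 F S U_x)\|_2^2 +
#'   \lambda_w \|W U_x\|_1}
#' with W an orthogonal Daubechies-4 wavelet transform applied per spatial
#' basis image. With \code{lambda_w = 0} conjugate gradient on the normal
#' equations is used; otherwise FISTA with restart, the step size taken from
#' a power-iteration Lipschitz estimate.
#'
#' @param raw an \code{mt_raw}.
#' @param E an \code{mt_operator} bound to the imaging lines.
#' @param phi_lines complex matrix (L1 x n_imaging) of temporal weights.
#' @param lambda_w wavelet weight (relative to the data scale; must be >= 0).
#' @param iters iterations.
#' @param init optional initial factor; default adjoint of the data.
#' @param levels wavelet levels.
#' @param sv_tol relative singular-value cutoff for the temporal weights:
#'   temporal directions whose presence in the acquired lines falls below
#'   this fraction of the dominant one are excluded from the solve (they are
#'   unobservable at meaningful signal level and would otherwise be
#'   amplified by the inverse mapping).
#' @param dc_weight precondition the least-squares problem with ramp
#'   (density-compensation) sample weights. This speeds up k-space residual
#'   convergence but also accelerates semiconvergent overfitting of model
#'   mismatch (binning discretization), trading parameter-map quality for
#'   residual; the default keeps the unweighted normal equations, where a
#'   modest CG iteration count acts as implicit regularization.
#' @return class \code{mt_spatial}: \code{u_x} (nvox*nslice x L1) and a
#'   diagnostic \code{trace}.
#' @export
solve_spatial <- function(raw, E, phi_lines, lambda_w = 0, iters = 12L,
                          init = NULL, levels = 3L, dc_weight = FALSE,
                          sv_tol = 0.01) {
  if (lambda_w < 0) stop("lambda_w must be non-negative")
  d <- raw$imaging
  ns <- E$nslice
  n <- raw$grid_n
  if (lambda_w == 0) {
    Es <- E
    ds <- d
    if (dc_weight) {
      w <- sqrt(E$traj$dcw / max(E$traj$dcw))
      ds <- d * as.vector(w)
      Es <- list(forward_phi = function(U, P) E$forward_phi(U, P) *
                   as.vector(w),
                 adjoint_phi = function(y, P) E$adjoint_phi(y * as.vector(w),
                                                            P))
    }
    # orthonormalize the temporal weights over the acquired lines: the raw
    # weights carry the core tensor's singular values, whose orders-of-
    # magnitude spread makes CG converge last in exactly the weak contrast
    # directions. Solve in rotated coordinates, map the factor back.
    # Directions with negligible presence in the acquired lines are
    # truncated rather than divided by: amplifying them by 1/S injects
    # unconstrained noise into every rendered state that expresses them.
    sv <- svd(phi_lines)
    keep <- sv$d > sv_tol * sv$d[1]
    phi_o <- t(Conj(sv$v[, keep, drop = FALSE]))        # orthonormal rows
    init_o <- if (is.null(init)) NULL else
      init %*% (sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep],
                                                    sum(keep)))
    ut <- cg_solve_phi(Es, phi_o, ds, iters = iters, x0 = init_o)
    u <- ut %*% (diag(1 / sv$d[keep], sum(keep)) %*%
                   Conj(t(sv$u[, keep, drop = FALSE])))
    res <- E$forward_phi(u, phi_lines) - d
    tr <- data.frame(iter = iters,
                     relres = sqrt(sum(Mod(res)^2) / sum(Mod(d)^2)))
    return(structure(list(u_x = u, trace = tr, lambda_w = lambda_w),
                     class = "mt_spatial"))
  }
  # Lipschitz estimate of A'A by power iteration
  set.seed(1)
  nx <- E$nvox * ns
  L1 <- nrow(phi_lines)
  z <- matrix(complex(real = stats::rnorm(nx * L1),
                      imaginary = stats::rnorm(nx * L1)), nx, L1)
  for (i in 1:6) {
    z <- E$adjoint_phi(E$forward_phi(z, phi_lines), phi_lines)
    lam <- sqrt(sum(Mod(z)^2)); z <- z / lam
  }
  if (!is.finite(lam) || lam <= 0) stop("Lipschitz estimation failed")
  step <- 1 / (1.05 * lam)
  tau <- lambda_w * step
  x <- if (is.null(init))
    E$adjoint_phi(d, phi_lines) / lam else init
  y <- x; t_k <- 1
  objfun <- function(u) {
    r <- E$forward_phi(u, phi_lines) - d
    sum(Mod(r)^2) + lambda_w * wavelet_l1(u, n, ns, levels)
  }
  obj <- objfun(x)
  tr <- data.frame(iter = 0, obj = obj)
  for (it in seq_len(iters)) {
    g <- E$adjoint_phi(E$forward_phi(y, phi_lines) - d, phi_lines)
    xn <- wavelet_shrink(y - step * g, n, ns, tau, levels)
    on <- objfun(xn)
    if (on > obj) {           # restart momentum
      y <- x; t_k <- 1
      g <- E$adjoint_phi(E$forward_phi(y, phi_lines) - d, phi_lines)
      xn <- wavelet_shrink(y - step * g, n, ns, tau, levels)
      on <- objfun(xn)
    }
    tn <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    y <- xn + ((t_k - 1) / tn) * (xn - x)
    x <- xn; t_k <- tn; obj <- on
    tr <- rbind(tr, data.frame(iter = it, obj = obj))
  }
  structure(list(u_x = x, trace = tr, lambda_w = lambda_w),
            class = "mt_spatial")
}
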