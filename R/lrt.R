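#' Assemble the sampled 5-way training tensor
#'
#' Each training line's feature vector (readout samples x coils, compressed
#' to \code{feature_rank} principal components by a unitary rotation) is
#' deposited at its (feature, excitation-grid, combination, cardiac bin,
#' respiratory bin) cell; multiple lines per cell are averaged and the
#' sampling mask records coverage. The excitation index is decimated to the
#' dictionary's subspace grid.
#'
#' @param raw an \code{mt_raw}. @param bins an \code{mt_bins}.
#' @param dict the \code{mt_dict} defining the excitation grid.
#' @param feature_rank retained feature-space rank.
#' @return class \code{mt_ttensor}: \code{data} (complex 5-way array),
#'   \code{mask}, \code{counts}, the feature rotation \code{v_feat}, and the
#'   cell coordinates per line.
#' @export
assemble_training_tensor <- function(raw, bins, dict, feature_rank = 16L) {
  meta <- raw$training_meta
  nl <- nrow(meta)
  feats <- t(matrix(aperm(raw$training, c(3, 1, 2)), nrow = nl)) # feat x line
  fr <- min(feature_rank, nrow(feats), nl)
  sv <- top_left_sv(feats, fr)
  v_feat <- sv$u
  scores <- crossprod(Conj(v_feat), feats)                       # fr x line
  n_grid <- dict$n_grid
  ni <- vapply(meta$n, function(n) which.min(abs(n_grid - n)), integer(1))
  nk <- nrow(dict$combos)
  nc <- bins$n_card
  # a collapsed respiratory axis (still breathing) keeps only its occupied
  # bins: structurally empty bins would otherwise be pure extrapolation
  nr <- max(bins$n_resp * (max(bins$lines$resp_bin) > 0), 
            max(bins$lines$resp_bin) + 1L)
  ki <- meta$combo + 1L
  ci <- bins$lines$card_bin + 1L
  ri <- bins$lines$resp_bin + 1L
  dims <- c(fr, length(n_grid), nk, nc, nr)
  cell <- ((ri - 1L) * nc + (ci - 1L)) * nk * length(n_grid) +
    (ki - 1L) * length(n_grid) + ni                      # 1-based cell id
  ncell <- prod(dims[-1])
  acc <- matrix(0i, fr, ncell)
  cnt <- numeric(ncell)
  for (l in seq_len(nl)) {
    acc[, cell[l]] <- acc[, cell[l]] + scores[, l]
    cnt[cell[l]] <- cnt[cell[l]] + 1
  }
  obs <- cnt > 0
  acc[, obs] <- sweep(acc[, obs, drop = FALSE], 2, cnt[obs], "/")
  data <- array(acc, dim = dims)
  mask <- array(rep(obs, each = fr), dim = dims)
  structure(list(data = data, mask = mask,
                 counts = array(cnt, dim = dims[-1]), v_feat = v_feat,
                 n_grid = n_grid, cells = data.frame(n = ni, k = ki, c = ci,
                                                     r = ri)),
            class = "mt_ttensor")
}

#' Low-rank tensor completion of the training tensor
#'
#' Minimizes
#' \deqn{\|d - \Omega(D)\|_2^2 + \lambda(\|D_{(1)}\|_* + \|D_{(4)}\|_* +
#'   \|D_{(5)}\|_*) + \lambda_c\|\Delta_c D_{(4)}\|_1 +
#'   \lambda_r\|\Delta_r D_{(5)}\|_1}
#' subject to the mode-2/3 unfoldings lying in the ranges of the relaxation
#' subspaces, by a proximal alternating scheme: data-consistency gradient
#' step, projection onto the mode-2/3 subspaces, singular-value thresholding
#' of unfoldings 1/4/5, and a 1-D total-variation prox along the cardiac
#' (cyclic) and respiratory (one-sided) bin dimensions. The regularization
#' weight follows a geometric continuation schedule; the objective is
#' recorded every iteration and each accepted step is non-increasing
#' (the step size is backtracked otherwise).
#'
#' @param st an \code{mt_ttensor}.
#' @param sub an \code{mt_subspaces} (modes 2 and 3).
#' @param lambda nuclear-norm weight; default 0.01 * sigma_max of the
#'   zero-filled mode-1 unfolding.
#' @param lambda_c,lambda_r temporal TV weights; default 0.1 * lambda.
#' @param iters maximum iterations.
#' @param continuation geometric decay factor applied to lambda every
#'   \code{cont_every} iterations (1 disables).
#' @param cont_every iterations between continuation steps.
#' @param lambda_floor smallest lambda as a fraction of the initial one.
#' @param tol relative objective change for early stopping.
#' @param polish run a rank-constrained alternating-projection refinement
#'   after the prox phase (data consistency + truncated HOSVD + subspace
#'   projection), removing the shrinkage bias of the thresholding.
#' @param ranks optional multilinear ranks (modes 1, 4, 5) for the polish
#'   phase; detected from the singular spectra when NULL.
#' @param rank_thr relative singular-value threshold for rank detection.
#' @param polish_iters maximum polish iterations.
#' @return list: \code{data} (completed tensor), \code{trace} (data.frame of
#'   per-iteration objective terms), \code{lambda}, \code{polish_ranks},
#'   \code{trace_polish}.
#' @export
complete_tensor <- function(st, sub, lambda = NULL, lambda_c = NULL,
                            lambda_r = NULL, iters = 150L,
                            continuation = 0.7, cont_every = 10L,
                            lambda_floor = 1e-3, tol = 1e-7,
                            polish = TRUE, ranks = NULL, rank_thr = 0.05,
                            polish_iters = 100L) {
  d <- st$data
  dims <- dim(d)
  u2 <- sub$u_t1; u3 <- sub$u_ta
  stopifnot(nrow(u2) == dims[2], nrow(u3) == dims[3])
  L2 <- ncol(u2); L3 <- ncol(u3)
  nf <- dims[1]; nc <- dims[4]; nr <- dims[5]
  # the iterate lives in the mode-2/3 subspace coefficients: D = C x2 u2 x3 u3.
  # Nuclear norms of unfoldings 1/4/5 are invariant under the orthonormal
  # factors; data consistency acts per observed cell through the basis rows.
  fib <- colSums(matrix(st$mask, nf))
  if (!all(fib %in% c(0L, nf)))
    stop("sampling mask must be constant along the feature mode: training ",
         "lines observe whole feature fibers")
  cnt <- if (!is.null(st$counts)) st$counts else array(fib / nf, dims[-1])
  obs <- which(cnt > 0)
  coord <- arrayInd(obs, dims[-1])
  dobs <- matrix(d, nf)[, obs, drop = FALSE]
  w <- matrix(0i, length(obs), L2 * L3)
  for (j3 in seq_len(L3))
    w[, (j3 - 1L) * L2 + seq_len(L2)] <-
      u2[coord[, 1], , drop = FALSE] * u3[coord[, 2], j3]
  gid <- coord[, 3] + nc * (coord[, 4] - 1L)
  groups <- split(seq_along(obs), gid)
  goff <- (as.integer(names(groups)) - 1L) * L2 * L3
  cdims <- c(nf, L2, L3, nc, nr)
  fwd_obs <- function(cm) {
    out <- matrix(0i, nf, length(obs))
    for (g in seq_along(groups)) {
      ix <- groups[[g]]
      out[, ix] <- cm[, goff[g] + seq_len(L2 * L3), drop = FALSE] %*%
        t(w[ix, , drop = FALSE])
    }
    out
  }
  adj_obs <- function(r) {
    gm <- matrix(0i, nf, L2 * L3 * nc * nr)
    for (g in seq_along(groups)) {
      ix <- groups[[g]]
      gm[, goff[g] + seq_len(L2 * L3)] <-
        r[, ix, drop = FALSE] %*% Conj(w[ix, , drop = FALSE])
    }
    gm
  }
  # exact proximal map of the data-consistency term: per (cardiac,
  # respiratory) group, C <- (C0 + 2 eta d Wbar)(I + 2 eta W^T Wbar)^-1
  gram <- lapply(groups, function(ix)
    t(w[ix, , drop = FALSE]) %*% Conj(w[ix, , drop = FALSE]))
  prox_cache <- new.env(parent = emptyenv())
  dc_prox <- function(carr, eta) {
    key <- format(eta, digits = 12)
    inv <- prox_cache[[key]]
    if (is.null(inv)) {
      inv <- lapply(gram, function(m)
        solve(diag(1, nrow(m)) + 2 * eta * m))
      prox_cache[[key]] <- inv
    }
    cm <- matrix(carr, nf)
    for (g in seq_along(groups)) {
      ix <- groups[[g]]
      cols <- goff[g] + seq_len(L2 * L3)
      rhs <- cm[, cols, drop = FALSE] +
        2 * eta * (dobs[, ix, drop = FALSE] %*% Conj(w[ix, , drop = FALSE]))
      cm[, cols] <- rhs %*% inv[[g]]
    }
    array(cm, cdims)
  }
  if (is.null(lambda)) lambda <- 0.01 * top_left_sv(dobs, 1)$d[1]
  if (is.null(lambda_c)) lambda_c <- 0.1 * lambda
  if (is.null(lambda_r)) lambda_r <- 0.1 * lambda
  lam0 <- lambda
  objective <- function(carr, lam, lc, lr) {
    dc <- sum(Mod(fwd_obs(matrix(carr, nf)) - dobs)^2)
    nuc <- nuclear_mode(carr, 1) + nuclear_mode(carr, 4) +
      nuclear_mode(carr, 5)
    tvc <- tv_norm_mode(carr, 4, cyclic = TRUE)
    tvr <- tv_norm_mode(carr, 5, cyclic = FALSE)
    c(total = dc + lam * nuc + lc * tvc + lr * tvr, dc = dc, nuc = nuc,
      tvc = tvc, tvr = tvr)
  }
  x <- array(adj_obs(dobs), cdims)
  eta <- 1
  lam <- lambda; lc <- lambda_c; lr <- lambda_r
  obj <- objective(x, lam, lc, lr)
  trace <- list(c(iter = 0, eta = eta, lambda = lam, obj))
  rises <- 0L
  for (it in seq_len(iters)) {
    if (continuation < 1 && it %% cont_every == 0L) {
      lam <- max(lam * continuation, lam0 * lambda_floor)
      lc <- max(lc * continuation, lambda_c * lambda_floor)
      lr <- max(lr * continuation, lambda_r * lambda_floor)
      obj <- objective(x, lam, lc, lr)
    }
    repeat {
      g <- dc_prox(x, eta)
      g <- svt_mode(g, 1, eta * lam)$x
      g <- svt_mode(g, 4, eta * lam)$x
      g <- svt_mode(g, 5, eta * lam)$x
      g <- tv_prox_mode(g, 4, eta * lc, cyclic = TRUE)
      g <- tv_prox_mode(g, 5, eta * lr, cyclic = FALSE)
      cand <- objective(g, lam, lc, lr)
      if (cand["total"] <= obj["total"] * (1 + 1e-9) || eta < 1e-4) break
      eta <- eta / 2
    }
    if (cand["total"] > obj["total"] * (1 + 1e-6)) rises <- rises + 1L
    else rises <- 0L
    if (rises >= 10L)
      stop("tensor completion failed to converge; objective trace attached",
           call. = FALSE)
    delta <- abs(obj["total"] - cand["total"]) / max(obj["total"], 1e-300)
    x <- g; obj <- cand
    trace[[length(trace) + 1L]] <- c(iter = it, eta = eta, lambda = lam, obj)
    if (delta < tol && it > cont_every) break
  }
  tr <- as.data.frame(do.call(rbind, trace))
  polish_ranks <- NULL
  tr_pol <- NULL
  if (polish) {
    if (is.null(ranks)) {
      detect <- function(mode) {
        s <- top_left_sv(unfold(x, mode), dim(x)[mode])$d
        max(1L, sum(s > rank_thr * s[1]))
      }
      ranks <- c(detect(1), detect(4), detect(5))
    }
    polish_ranks <- pmin(ranks, cdims[c(1, 4, 5)])
    rk5 <- c(polish_ranks[1], L2, L3, polish_ranks[2], polish_ranks[3])
    dnorm <- max(sum(Mod(dobs)^2), 1e-300)
    rr <- numeric(0)
    prev <- Inf
    for (it in seq_len(polish_iters)) {
      x <- dc_prox(x, 20)
      x <- hosvd_expand(hosvd(x, rk5))
      rr[it] <- sqrt(sum(Mod(fwd_obs(matrix(x, nf)) - dobs)^2) / dnorm)
      if (prev - rr[it] < 1e-13) break
      prev <- rr[it]
    }
    tr_pol <- data.frame(iter = seq_along(rr), dc_relative = rr)
  }
  dhat <- ttm(ttm(x, u2, 2), u3, 3)
  list(data = dhat, coeff = x, trace = tr,
       lambda = c(lambda = lam, lambda_c = lc, lambda_r = lr),
       polish_ranks = polish_ranks, trace_polish = tr_pol)
}

#' Extract factor set from the completed training tensor
#'
#' Truncated HOSVD with the relaxation modes fixed to the dictionary-derived
#' bases.
#'
#' @param dhat completed tensor (complex 5-way array).
#' @param ranks integer vector of 5 multilinear ranks.
#' @param sub an \code{mt_subspaces} supplying the fixed mode-2/3 factors.
#' @return class \code{mt_factors}: core and the five factors.
#' @export
hosvd_factors <- function(dhat, ranks, sub = NULL) {
  fixed <- NULL
  if (!is.null(sub)) fixed <- list(`2` = sub$u_t1, `3` = sub$u_ta)
  h <- hosvd(dhat, ranks, fixed = fixed)
  structure(list(core = h$core, u_feat = h$factors[[1]],
                 u_t1 = h$factors[[2]], u_ta = h$factors[[3]],
                 u_c = h$factors[[4]], u_r = h$factors[[5]],
                 ranks = vapply(h$factors, ncol, integer(1))),
            class = "mt_factors")
}

#' Combined temporal factor tensor
#'
#' Stores the core contracted with the four temporal factor matrices in
#' factored form; queries evaluate the L x 1 temporal weight vector at any
#' (excitation, combination, cardiac bin, respiratory bin) tuple without
#' materializing the full array.
#'
#' @param fs an \code{mt_factors}.
#' @return class \code{mt_phi}.
#' @export
build_phi <- function(fs) {
  structure(list(core1 = unfold(fs$core, 1), ranks = fs$ranks,
                 u_t1 = fs$u_t1, u_ta = fs$u_ta, u_c = fs$u_c, u_r = fs$u_r),
            class = "mt_phi")
}

#' Evaluate temporal weight vectors of Phi
#'
#' @param phi an \code{mt_phi}.
#' @param u2rows matrix (nq x L2) of recovery-basis rows (e.g. rows of the
#'   stored basis for training timestamps, or the exact full-resolution
#'   evaluation for imaging lines).
#' @param k,c,r 1-based combination / cardiac / respiratory indices (vectors
#'   of length nq or scalars).
#' @return complex matrix (L1 x nq).
#' @export
phi_eval <- function(phi, u2rows, k, c, r) {
  nq <- nrow(u2rows)
  a3 <- phi$u_ta[k, , drop = FALSE]
  a4 <- phi$u_c[c, , drop = FALSE]
  a5 <- phi$u_r[r, , drop = FALSE]
  if (nrow(a3) == 1L) a3 <- a3[rep(1, nq), , drop = FALSE]
  if (nrow(a4) == 1L) a4 <- a4[rep(1, nq), , drop = FALSE]
  if (nrow(a5) == 1L) a5 <- a5[rep(1, nq), , drop = FALSE]
  # row-wise Kronecker in mode order (5,4,3,2), matching vec(col-major)
  kr <- function(a, b) {            # rows: a[i,] kron b[i,]
    out <- matrix(0i, nrow(a), ncol(a) * ncol(b))
    for (j in seq_len(ncol(a)))
      out[, (j - 1L) * ncol(b) + seq_len(ncol(b))] <- a[, j] * b
    out
  }
  w <- kr(kr(kr(a5, a4), a3), u2rows)   # nq x (L2 L3 L4 L5)
  phi$core1 %*% t(w)
}

#' Render images from the spatial factor and Phi
#'
#' A = Phi x1 Ux evaluated lazily at the queried motion/contrast states.
#'
#' @param u_x complex matrix (nvox*nslice x L1).
#' @param phi an \code{mt_phi}.
#' @param u2rows,k,c,r as in \code{phi_eval}.
#' @return complex matrix (nvox*nslice x nq).
#' @export
render_images <- function(u_x, phi, u2rows, k, c, r) {
  if (max(k) > nrow(phi$u_ta) || max(c) > nrow(phi$u_c) ||
      max(r) > nrow(phi$u_r) || min(k) < 1 || min(c) < 1 || min(r) < 1)
    stop("query index out of range")
  u_x %*% phi_eval(phi, u2rows, k, c, r)
}
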