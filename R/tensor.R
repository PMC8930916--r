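#' Mode-n unfolding of an array
#'
#' Rows index the chosen mode; columns run over the remaining modes in
#' increasing order (column-major), the standard unfolding convention.
#'
#' @param x array. @param mode mode index.
#' @export
unfold <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, seq_along(d)[-mode])
  matrix(aperm(x, perm), nrow = d[mode])
}

#' Inverse of \code{unfold}
#' @param m matrix. @param mode mode index. @param dims target array dims.
#' @export
fold <- function(m, mode, dims) {
  perm <- c(mode, seq_along(dims)[-mode])
  x <- array(m, dim = dims[perm])
  aperm(x, order(perm))
}

#' Mode-n product of a tensor with a matrix
#' @param x array. @param mat matrix (new_dim x dims[mode]). @param mode mode.
#' @export
ttm <- function(x, mat, mode) {
  d <- dim(x)
  m <- mat %*% unfold(x, mode)
  d[mode] <- nrow(mat)
  fold(m, mode, d)
}

# top-L left singular vectors of a (possibly complex) matrix via the small
# Gram eigenproblem; returns list(u, d)
top_left_sv <- function(m, L) {
  g <- tcrossprod(m, Conj(m))
  ev <- eigen((g + Conj(t(g))) / 2, symmetric = TRUE)
  list(u = ev$vectors[, seq_len(L), drop = FALSE],
       d = sqrt(pmax(Re(ev$values), 0)))
}

#' Truncated higher-order SVD
#'
#' Per-mode left singular vectors of the unfoldings, with optional fixed
#' factors for chosen modes; the core is the tensor contracted by all factor
#' conjugate-transposes. The core of a full (untruncated) HOSVD is
#' all-orthogonal.
#'
#' @param x array. @param ranks integer vector, one per mode.
#' @param fixed optional named list mode -> factor matrix to use unchanged.
#' @return list(core, factors, ranks).
#' @export
hosvd <- function(x, ranks, fixed = NULL) {
  d <- dim(x)
  stopifnot(length(ranks) == length(d), all(ranks <= d))
  factors <- vector("list", length(d))
  for (i in seq_along(d)) {
    fx <- fixed[[as.character(i)]]
    if (!is.null(fx)) {
      factors[[i]] <- fx[, seq_len(min(ranks[i], ncol(fx))), drop = FALSE]
    } else {
      factors[[i]] <- top_left_sv(unfold(x, i), ranks[i])$u
    }
  }
  core <- x
  for (i in seq_along(d)) core <- ttm(core, Conj(t(factors[[i]])), i)
  list(core = core, factors = factors, ranks = ranks)
}

#' Reconstruct a tensor from HOSVD factors
#' @param h result of \code{hosvd}.
#' @export
hosvd_expand <- function(h) {
  x <- h$core
  for (i in seq_along(h$factors)) x <- ttm(x, h$factors[[i]], i)
  x
}

# singular-value thresholding of the mode-m unfolding
svt_mode <- function(x, mode, tau) {
  d <- dim(x)
  m <- unfold(x, mode)
  sv <- top_left_sv(m, nrow(m))
  s <- sv$d
  keep <- s > tau
  if (!any(keep)) return(list(x = array(0i, d), nuc = 0))
  u <- sv$u[, keep, drop = FALSE]
  # rows of V^H scaled: V^H = S^-1 U^H M ; thresholded M = U (S - tau) S^-1 U^H M
  w <- Conj(t(u)) %*% m
  shrink <- (s[keep] - tau) / s[keep]
  m2 <- u %*% (shrink * w)
  list(x = fold(m2, mode, d), nuc = sum(pmax(s - tau, 0)))
}

nuclear_mode <- function(x, mode) sum(top_left_sv(unfold(x, mode), 1)$d)

# prox of tau * ||D x||_1 along the rows of the mode-m unfolding, where D is
# the (cyclic or one-sided) first difference; Chambolle-style dual projection
tv_prox_mode <- function(x, mode, tau, cyclic = TRUE, iters = 30L) {
  if (tau <= 0) return(x)
  d <- dim(x)
  y <- unfold(x, mode)
  nm <- nrow(y)
  diffop <- function(v) if (cyclic) v[c(2:nm, 1), , drop = FALSE] - v else
    v[2:nm, , drop = FALSE] - v[1:(nm - 1), , drop = FALSE]
  diffadj <- function(p) {
    if (cyclic) p[c(nm, 1:(nm - 1)), , drop = FALSE] - p
    else rbind(-p[1, , drop = FALSE],
               p[1:(nm - 2), , drop = FALSE] - p[2:(nm - 1), , drop = FALSE],
               p[nm - 1, , drop = FALSE])
  }
  p <- diffop(y) * 0
  for (i in seq_len(iters)) {
    g <- diffop(y - diffadj(p))
    p <- p + 0.25 * g
    mag <- Mod(p)
    p <- p * ifelse(mag > tau, tau / mag, 1)
  }
  fold(y - diffadj(p), mode, d)
}

tv_norm_mode <- function(x, mode, cyclic = TRUE) {
  y <- unfold(x, mode)
  nm <- nrow(y)
  d <- if (cyclic) y[c(2:nm, 1), , drop = FALSE] - y else
    y[2:nm, , drop = FALSE] - y[1:(nm - 1), , drop = FALSE]
  sum(Mod(d))
}
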