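# Low-level array operations for the segmentation network.
#
# Feature maps are arrays with dim (H, W, C). Every operation here works on
# both double and complex arrays: complex inputs carry infinitesimal
# perturbations for complex-step differentiation of the gradient itself
# (exact Hessian-vector products), so branching decisions always use Re().

.im2col_cache <- new.env(parent = emptyenv())

#' im2col gather indices for a conv configuration, cached per shape
#' @noRd
im2col_idx <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  # linear offsets (1-based) of window top-left corners within one channel plane
  corner <- outer(seq(1L, by = stride, length.out = Ho),
                  seq(0L, by = stride * Hp, length.out = Wo), `+`)
  # offsets of the k*k taps relative to the corner (row fastest, then col)
  tap <- outer(0:(k - 1L), seq(0L, by = Hp, length.out = k), `+`)
  idx1 <- outer(as.vector(corner), as.vector(tap), `+`) # (Ho*Wo) x (k*k)
  if (C > 1L) {
    idx <- do.call(cbind, lapply(0:(C - 1L), function(ch) idx1 + ch * Hp * Wp))
  } else {
    idx <- idx1
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

zeros_like_type <- function(template, dims) {
  if (is.complex(template)) array(0 + 0i, dims) else array(0, dims)
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- zeros_like_type(x, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  out
}

unpad_array <- function(x, pad, H, W) {
  if (pad == 0L) return(x)
  x[(pad + 1L):(pad + H), (pad + 1L):(pad + W), , drop = FALSE]
}

#' Sum values into a vector of length n at (possibly repeated) indices
#' @noRd
scatter_add <- function(values, idx, n) {
  if (is.complex(values)) {
    return(complex(real = scatter_add(Re(values), idx, n),
                   imaginary = scatter_add(Im(values), idx, n)))
  }
  s <- rowsum(values, idx)
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s
  out
}

#' 2-D convolution forward pass (im2col + GEMM)
#'
#' @param x array (H, W, Cin); w array (k, k, Cin, Cout); b length-Cout vector
#' @return list(y, cache) where cache holds what backward needs
#' @noRd
conv2d_forward <- function(x, w, b, stride = 1L, pad = 1L) {
  d <- dim(x)
  k <- dim(w)[1]
  Cin <- dim(w)[3]
  Cout <- dim(w)[4]
  stopifnot(d[3] == Cin)
  ic <- im2col_idx(d[1], d[2], Cin, k, stride, pad)
  xp <- pad_array(x, pad)
  cols <- matrix(xp[as.vector(ic$idx)], nrow = nrow(ic$idx))
  wm <- matrix(w, ncol = Cout)
  ym <- cols %*% wm
  ym <- ym + matrix(b, nrow(ym), Cout, byrow = TRUE)
  y <- array(ym, c(ic$Ho, ic$Wo, Cout))
  list(y = y, cache = list(cols = cols, wm = wm, ic = ic, dims = d,
                           k = k, Cin = Cin, Cout = Cout,
                           stride = stride, pad = pad))
}

conv2d_backward <- function(dy, cache) {
  ic <- cache$ic
  dym <- matrix(dy, ic$Ho * ic$Wo, cache$Cout)
  # plain transpose (no conjugation): backward must stay holomorphic in the
  # parameters so complex-step Hessian-vector products are exact
  dw <- array(t(cache$cols) %*% dym, c(cache$k, cache$k, cache$Cin, cache$Cout))
  db <- colSums(dym)
  dcols <- dym %*% t(cache$wm)
  n_pad <- ic$Hp * ic$Wp * cache$Cin
  dxp <- array(scatter_add(as.vector(dcols), as.vector(ic$idx), n_pad),
               c(ic$Hp, ic$Wp, cache$Cin))
  dx <- unpad_array(dxp, cache$pad, cache$dims[1], cache$dims[2])
  list(dx = dx, dw = dw, db = db)
}

#' Group normalization forward (population variance, per-group over H,W,Cg)
#' @noRd
group_norm_forward <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  stopifnot(C %% groups == 0)
  cg <- C %/% groups
  xm <- matrix(x, d[1] * d[2], C)
  grp <- rep(seq_len(groups), each = cg)
  n_per <- d[1] * d[2] * cg
  xhat <- xm
  mu <- sd_inv <- vector(if (is.complex(x)) "complex" else "numeric", groups)
  for (g in seq_len(groups)) {
    sel <- which(grp == g)
    xs <- xm[, sel, drop = FALSE]
    m <- sum(xs) / n_per
    v <- sum((xs - m)^2) / n_per
    si <- 1 / sqrt(v + eps)
    xhat[, sel] <- (xs - m) * si
    mu[g] <- m
    sd_inv[g] <- si
  }
  gm <- matrix(gamma, d[1] * d[2], C, byrow = TRUE)
  bm <- matrix(beta, d[1] * d[2], C, byrow = TRUE)
  y <- array(xhat * gm + bm, d)
  list(y = y,
       cache = list(xhat = xhat, sd_inv = sd_inv, grp = grp, gamma = gamma,
                    dims = d, groups = groups, n_per = n_per))
}

group_norm_backward <- function(dy, cache) {
  d <- cache$dims
  C <- d[3]
  dym <- matrix(dy, d[1] * d[2], C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  gm <- matrix(cache$gamma, d[1] * d[2], C, byrow = TRUE)
  dxhat <- dym * gm
  dxm <- dxhat
  for (g in seq_len(cache$groups)) {
    sel <- which(cache$grp == g)
    dxh <- dxhat[, sel, drop = FALSE]
    xh <- cache$xhat[, sel, drop = FALSE]
    n <- cache$n_per
    # dx = sd_inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
    dxm[, sel] <- cache$sd_inv[g] *
      (dxh - sum(dxh) / n - xh * (sum(dxh * xh) / n))
  }
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- Re(x) > 0
  list(y = x * mask, cache = mask)
}

relu_backward <- function(dy, mask) dy * mask

#' Nearest-neighbour 2x upsampling and its adjoint
#' @noRd
upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  a <- dy[seq(1L, d[1], 2L), , , drop = FALSE] + dy[seq(2L, d[1], 2L), , , drop = FALSE]
  a[, seq(1L, d[2], 2L), , drop = FALSE] + a[, seq(2L, d[2], 2L), , drop = FALSE]
}

sigmoid_c <- function(z) 1 / (1 + exp(-z))

#' Numerically stable softplus, complex-safe
#' @noRd
softplus_c <- function(z) {
  pos <- Re(z) > 0
  out <- z
  if (is.complex(z)) {
    out[pos] <- z[pos] + log(1 + exp(-z[pos]))
    out[!pos] <- log(1 + exp(z[!pos]))
  } else {
    out[pos] <- z[pos] + log1p(exp(-z[pos]))
    out[!pos] <- log1p(exp(z[!pos]))
  }
  out
}
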