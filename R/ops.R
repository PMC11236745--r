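# Tensor operations, each with a tape-recorded backward pass.
#
# Internal layout is (H, W, N, C): with channels last, every per-channel
# matrix view (rows = pixels x batch, cols = channels) is a free `dim<-`
# reshape, and convolutions reduce to one gather plus one BLAS matrix
# product. Gather index tables for the 3x3 im2col are cached per shape.

.idx_cache <- new.env(parent = emptyenv())

# gather index: one HWN x 9C integer matrix into the zero-padded
# (H+2, W+2, N, C) array; column blocks enumerate the 9 kernel offsets
# dj-major / di-minor (channel within block) to match the kernel matrix
# layout.
.conv_idx <- function(H, W, N, C) {
  key <- paste(H, W, N, C, sep = "x")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  ph <- rep(seq_len(H), times = W * N)
  pw <- rep(rep(seq_len(W), each = H), times = N)
  pn <- rep(seq_len(N), each = H * W)
  strideC <- (H + 2L) * (W + 2L) * N
  cshift <- (seq_len(C) - 1L) * strideC
  blocks <- vector("list", 9L); k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    base <- (ph + di) + (H + 2L) * (pw + dj - 1L) + (H + 2L) * (W + 2L) * (pn - 1L)
    blocks[[k]] <- outer(as.integer(base), as.integer(cshift), `+`)
  }
  idx <- do.call(cbind, blocks)
  storage.mode(idx) <- "integer"
  .idx_cache[[key]] <- idx
  idx
}

# forward 3x3 conv primitive: returns list(out, M) where M is the
# im2col matrix (kept for the weight gradient).
.conv3_fwd <- function(X, Kmat, bb) {
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  idx <- .conv_idx(H, W, N, C)
  Xp <- .pad1(X)
  M <- Xp[idx]
  dim(M) <- dim(idx)
  Ymat <- M %*% Kmat
  if (!is.null(bb)) Ymat <- .coladd(Ymat, bb)
  list(out = .as_arr(Ymat, H, W, N, ncol(Kmat)), M = M)
}

# kernel array (3,3,Cin,Cout) -> (9 Cin) x Cout matrix in gather order
.kmat <- function(K) {
  d <- dim(K)
  matrix(aperm(K, c(3, 1, 2, 4)), 9L * d[3], d[4])
}

# spatially flipped, in/out-transposed kernel for the input gradient:
# dX = conv3(dY, flip(K)^T)
.kflip <- function(K) {
  Kf <- K[3:1, 3:1, , , drop = FALSE]
  aperm(Kf, c(1, 2, 4, 3))
}

.pad1 <- function(X) {
  d <- dim(X)
  Xp <- array(0, d + c(2L, 2L, 0L, 0L))
  Xp[2:(d[1] + 1), 2:(d[2] + 1), , ] <- X
  Xp
}

.as_mat <- function(X) { d <- dim(X); dim(X) <- c(d[1] * d[2] * d[3], d[4]); X }
.as_arr <- function(M, H, W, N, C) { dim(M) <- c(H, W, N, C); M }

# column-recycled arithmetic (much cheaper than sweep())
.colmul <- function(M, v) M * rep(v, each = nrow(M))
.coladd <- function(M, v) M + rep(v, each = nrow(M))

#' 3x3 convolution, stride 1, zero padding 1
#'
#' @param tape tape or NULL.
#' @param x input node/array (H, W, N, Cin).
#' @param W kernel node/array (3, 3, Cin, Cout).
#' @param b bias node/array length Cout.
#' @keywords internal
op_conv3 <- function(tape, x, W, b) {
  X <- nd_val(x); K <- nd_val(W); bb <- nd_val(b)
  d <- dim(X); C <- d[4]; Cout <- dim(K)[4]
  fw <- .conv3_fwd(X, .kmat(K), bb)
  tp_node(tape, fw$out, ins = c(nd_id(x), nd_id(W), nd_id(b)), back = function(g) {
    gmat <- .as_mat(g)
    dK <- aperm(array(crossprod(fw$M, gmat), c(C, 3, 3, Cout)), c(2, 3, 1, 4))
    db <- colSums(gmat)
    dX <- .conv3_fwd(g, .kmat(.kflip(K)), NULL)$out
    list(dX, dK, db)
  })
}

#' 1x1 convolution (channel mixing)
#' @keywords internal
op_conv1 <- function(tape, x, W, b) {
  X <- nd_val(x); K <- nd_val(W); bb <- nd_val(b)   # K: (Cin, Cout)
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  Cout <- ncol(K)
  M <- .as_mat(X)
  Ymat <- .coladd(M %*% K, bb)
  out <- .as_arr(Ymat, H, Wd, N, Cout)
  tp_node(tape, out, ins = c(nd_id(x), nd_id(W), nd_id(b)), back = function(g) {
    gmat <- .as_mat(g)
    list(.as_arr(gmat %*% t(K), H, Wd, N, C), crossprod(M, gmat), colSums(gmat))
  })
}

#' Transposed convolution, 2x2 kernel, stride 2 (doubles H and W)
#'
#' Non-overlapping: output pixel (2i-2+a, 2j-2+b) receives tap (a, b) of
#' input pixel (i, j).
#' @param W kernel (2, 2, Cin, Cout).
#' @keywords internal
op_tconv2 <- function(tape, x, W, b) {
  X <- nd_val(x); K <- nd_val(W); bb <- nd_val(b)
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  Cout <- dim(K)[4]
  M <- .as_mat(X)
  out <- array(0, c(2L * H, 2L * Wd, N, Cout))
  for (a in 1:2) for (bidx in 1:2) {
    Ymat <- M %*% matrix(K[a, bidx, , ], C, Cout)
    out[seq(a, 2L * H, 2L), seq(bidx, 2L * Wd, 2L), , ] <- .as_arr(Ymat, H, Wd, N, Cout)
  }
  dim(out) <- c(4L * H * Wd * N, Cout)
  out <- .coladd(out, bb)
  dim(out) <- c(2L * H, 2L * Wd, N, Cout)
  tp_node(tape, out, ins = c(nd_id(x), nd_id(W), nd_id(b)), back = function(g) {
    dX <- matrix(0, H * Wd * N, C)
    dK <- array(0, dim(K))
    for (a in 1:2) for (bidx in 1:2) {
      gsub <- .as_mat(g[seq(a, 2L * H, 2L), seq(bidx, 2L * Wd, 2L), , , drop = FALSE])
      dX <- dX + gsub %*% t(matrix(K[a, bidx, , ], C, Cout))
      dK[a, bidx, , ] <- crossprod(M, gsub)
    }
    db <- colSums(.as_mat(g))
    list(.as_arr(dX, H, Wd, N, C), dK, db)
  })
}

#' Batch normalization over (H, W, N) per channel
#'
#' In training mode uses batch statistics and updates the running
#' mean/variance stored in `stats_env[[name]]` (momentum 0.1); in
#' inference mode uses the stored running statistics.
#' @keywords internal
op_bn <- function(tape, x, gamma, beta, training, stats_env, name, eps = 1e-5) {
  X <- nd_val(x); gm <- nd_val(gamma); be <- nd_val(beta)
  d <- dim(X); C <- d[4]
  M <- .as_mat(X)
  m_rows <- nrow(M)
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M * M) - mu * mu
    va[va < 0] <- 0
    st <- stats_env[[name]]
    if (is.null(st) || !isTRUE(st$init)) {
      st <- list(mean = mu, var = va, init = TRUE)
    } else {
      st$mean <- 0.9 * st$mean + 0.1 * mu
      st$var  <- 0.9 * st$var + 0.1 * va
    }
    stats_env[[name]] <- st
  } else {
    st <- stats_env[[name]]
    if (is.null(st)) st <- list(mean = numeric(C), var = rep(1, C))
    mu <- st$mean; va <- st$var
  }
  inv_sd <- 1 / sqrt(va + eps)
  a <- gm * inv_sd
  out <- .as_arr(.coladd(.colmul(M, a), be - mu * a), d[1], d[2], d[3], C)
  tp_node(tape, out, ins = c(nd_id(x), nd_id(gamma), nd_id(beta)), back = function(g) {
    gmat <- .as_mat(g)
    dbeta <- colSums(gmat)
    Xhat <- .coladd(.colmul(M, inv_sd), -mu * inv_sd)
    dgamma <- colSums(gmat * Xhat)
    if (training) {
      dX <- .colmul(gmat - .coladd(.colmul(Xhat, dgamma / m_rows), dbeta / m_rows), a)
    } else {
      dX <- .colmul(gmat, a)
    }
    list(.as_arr(dX, d[1], d[2], d[3], C), dgamma, dbeta)
  })
}

#' Rectified linear activation
#' @keywords internal
op_relu <- function(tape, x) {
  X <- nd_val(x)
  mask <- X > 0
  tp_node(tape, X * mask, ins = nd_id(x), back = function(g) list(g * mask))
}

#' Elementwise logistic
#' @keywords internal
op_sigmoid <- function(tape, x) {
  X <- nd_val(x)
  s <- 1 / (1 + exp(-X))
  tp_node(tape, s, ins = nd_id(x), back = function(g) list(g * s * (1 - s)))
}

#' 2x2 max pooling, stride 2
#' @keywords internal
op_maxpool2 <- function(tape, x) {
  X <- nd_val(x)
  d <- dim(X); H <- d[1]; Wd <- d[2]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  a1 <- X[i1, , , , drop = FALSE]; a2 <- X[i2, , , , drop = FALSE]
  mh <- a1 >= a2
  mrow <- pmax(a1, a2)
  j1 <- seq(1L, Wd, 2L); j2 <- seq(2L, Wd, 2L)
  b1 <- mrow[, j1, , , drop = FALSE]; b2 <- mrow[, j2, , , drop = FALSE]
  mw <- b1 >= b2
  out <- pmax(b1, b2)
  tp_node(tape, out, ins = nd_id(x), back = function(g) {
    gr <- array(0, dim(mrow))
    gr[, j1, , ] <- g * mw
    gr[, j2, , ] <- g * !mw
    gx <- array(0, d)
    gx[i1, , , ] <- gr * mh
    gx[i2, , , ] <- gr * !mh
    list(gx)
  })
}

#' Concatenate along the channel (last) dimension
#' @keywords internal
op_concat <- function(tape, xs) {
  vals <- lapply(xs, nd_val)
  chs <- vapply(vals, function(v) dim(v)[4], integer(1))
  d1 <- dim(vals[[1]])
  out <- array(0, c(d1[1], d1[2], d1[3], sum(chs)))
  at <- 0L
  for (v in vals) {
    cc <- dim(v)[4]
    out[, , , at + seq_len(cc)] <- v
    at <- at + cc
  }
  tp_node(tape, out, ins = vapply(xs, nd_id, integer(1)), back = function(g) {
    res <- vector("list", length(chs)); at2 <- 0L
    for (k in seq_along(chs)) {
      res[[k]] <- g[, , , at2 + seq_len(chs[k]), drop = FALSE]
      at2 <- at2 + chs[k]
    }
    res
  })
}

#' Elementwise sum of a list of same-shaped tensors
#' @keywords internal
op_add <- function(tape, xs) {
  out <- Reduce(`+`, lapply(xs, nd_val))
  n <- length(xs)
  tp_node(tape, out, ins = vapply(xs, nd_id, integer(1)),
          back = function(g) rep(list(g), n))
}

#' Soft Dice loss between a probability map and a binary target
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`. Scalar output.
#' @keywords internal
op_dice <- function(tape, p, truth, eps = 1e-6) {
  P <- nd_val(p); tt <- nd_val(truth)
  S <- sum(P * tt)
  D <- sum(P) + sum(tt) + eps
  L <- 1 - (2 * S + eps) / D
  tp_node(tape, L, ins = nd_id(p), back = function(g) {
    list(g * (-2 * tt / D + (2 * S + eps) / D^2))
  })
}

#' Channel-wise softmax (over the last dimension)
#' @keywords internal
op_softmax <- function(tape, x) {
  X <- nd_val(x)
  d <- dim(X)
  M <- .as_mat(X)
  mx <- M[, 1L]
  for (j in seq_len(d[4])[-1L]) mx <- pmax(mx, M[, j])
  M <- M - mx
  E <- exp(M)
  P <- E / rowSums(E)
  out <- .as_arr(P, d[1], d[2], d[3], d[4])
  tp_node(tape, out, ins = nd_id(x), back = function(g) {
    gmat <- .as_mat(g)
    dX <- P * (gmat - rowSums(gmat * P))
    list(.as_arr(dX, d[1], d[2], d[3], d[4]))
  })
}

#' Weighted sum of scalar nodes (loss aggregation)
#' @keywords internal
op_wsum <- function(tape, xs, w) {
  out <- sum(vapply(xs, nd_val, numeric(1)) * w)
  tp_node(tape, out, ins = vapply(xs, nd_id, integer(1)),
          back = function(g) as.list(g * w))
}
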