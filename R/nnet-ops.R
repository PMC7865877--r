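# Neural-network primitives on base-R arrays.  Activations are (L, C, N)
# arrays: temporal length x channels x batch (batch = all segments in the
# minibatch).  Convolutions are evaluated as im2col matrix products so the
# heavy lifting happens in BLAS.  Every op has a forward returning
# list(out, cache) and a backward returning the input gradient plus parameter
# gradients.  No framework is available in this environment, so training
# (backprop + Adam) is implemented here as well.

conv1d_fw <- function(A, W, b, stride = 1L) {
  dims <- dim(A)
  L <- dims[1]; Cin <- dims[2]; N <- dims[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  pad_l <- (K - 1L) %/% 2L
  pad_r <- K - 1L - pad_l
  Lp <- L + pad_l + pad_r
  L_out <- if (stride == 1L) L else L %/% 2L
  Apad <- array(0, c(Lp, Cin, N))
  Apad[(pad_l + 1L):(pad_l + L), , ] <- A
  starts <- seq.int(1L, by = stride, length.out = L_out)
  tidx <- outer(starts, 0:(K - 1L), "+")                    # (L_out, K)
  I <- outer(tidx, (0:(Cin - 1L)) * Lp, "+")                # (L_out, K, Cin)
  I <- outer(I, (0:(N - 1L)) * (Lp * Cin), "+")             # (L_out, K, Cin, N)
  Xc <- Apad[I]
  dim(Xc) <- c(L_out, K, Cin, N)
  Xm <- aperm(Xc, c(1, 4, 2, 3))
  dim(Xm) <- c(L_out * N, K * Cin)
  Wm <- W; dim(Wm) <- c(K * Cin, Cout)
  Ym <- Xm %*% Wm
  Ym <- Ym + rep(b, each = L_out * N)
  dim(Ym) <- c(L_out, N, Cout)
  Y <- aperm(Ym, c(1, 3, 2))
  list(out = Y,
       cache = list(Xm = Xm, starts = starts, pad_l = pad_l, Lp = Lp,
                    L = L, Cin = Cin, N = N, K = K, Cout = Cout,
                    L_out = L_out, W = W))
}

conv1d_bw <- function(dY, cache) {
  c0 <- cache
  dYm <- aperm(dY, c(1, 3, 2))
  dim(dYm) <- c(c0$L_out * c0$N, c0$Cout)
  dW <- crossprod(c0$Xm, dYm)
  dim(dW) <- c(c0$K, c0$Cin, c0$Cout)
  db <- colSums(dYm)
  Wm <- c0$W; dim(Wm) <- c(c0$K * c0$Cin, c0$Cout)
  dXm <- tcrossprod(dYm, Wm)
  dim(dXm) <- c(c0$L_out, c0$N, c0$K, c0$Cin)
  dXc <- aperm(dXm, c(1, 3, 4, 2))                          # (L_out, K, Cin, N)
  dApad <- array(0, c(c0$Lp, c0$Cin, c0$N))
  for (k in seq_len(c0$K)) {
    tpos <- c0$starts + k - 1L
    dApad[tpos, , ] <- dApad[tpos, , ] + dXc[, k, , ]
  }
  dA <- dApad[(c0$pad_l + 1L):(c0$pad_l + c0$L), , , drop = FALSE]
  list(dA = dA, dW = dW, db = db)
}

bn_fw <- function(A, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  dims <- dim(A)
  L <- dims[1]; C <- dims[2]; N <- dims[3]
  Am <- aperm(A, c(1, 3, 2))
  dim(Am) <- c(L * N, C)
  if (train) {
    mu <- colMeans(Am)
    v <- colMeans(Am^2) - mu^2
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * v
  } else {
    mu <- state$rm
    v <- state$rv
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- (Am - rep(mu, each = L * N)) * rep(inv_std, each = L * N)
  Ym <- xhat * rep(gamma, each = L * N) + rep(beta, each = L * N)
  dim(Ym) <- c(L, N, C)
  Y <- aperm(Ym, c(1, 3, 2))
  list(out = Y, state = state,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma,
                    L = L, C = C, N = N))
}

bn_bw <- function(dY, cache) {
  c0 <- cache
  M <- c0$L * c0$N
  dYm <- aperm(dY, c(1, 3, 2))
  dim(dYm) <- c(M, c0$C)
  dgamma <- colSums(dYm * c0$xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(c0$gamma, each = M)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * c0$xhat)
  dXm <- (dxhat - rep(s1 / M, each = M) - c0$xhat * rep(s2 / M, each = M)) *
    rep(c0$inv_std, each = M)
  dim(dXm) <- c(c0$L, c0$N, c0$C)
  dA <- aperm(dXm, c(1, 3, 2))
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(A) {
  mask <- A > 0
  list(out = A * mask, cache = mask)
}
relu_bw <- function(dY, mask) dY * mask

dropout_fw <- function(A, rate, train) {
  if (!train || rate <= 0) return(list(out = A, cache = NULL))
  mask <- array((stats::runif(length(A)) >= rate) / (1 - rate), dim(A))
  list(out = A * mask, cache = mask)
}
dropout_bw <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# temporal max pooling by a factor of 2 (used on residual shortcuts)
maxpool2_fw <- function(A) {
  L <- dim(A)[1]
  i1 <- seq.int(1L, L, by = 2L)
  A1 <- A[i1, , , drop = FALSE]
  A2 <- A[i1 + 1L, , , drop = FALSE]
  mask <- A1 >= A2
  list(out = pmax(A1, A2), cache = list(mask = mask, L = L))
}
maxpool2_bw <- function(dY, cache) {
  L <- cache$L
  d <- dim(dY)
  dA <- array(0, c(L, d[2], d[3]))
  i1 <- seq.int(1L, L, by = 2L)
  dA[i1, , ] <- dY * cache$mask
  dA[i1 + 1L, , ] <- dY * !cache$mask
  dA
}

# global average over the temporal dimension: (L, C, N) -> (C, N)
gap_fw <- function(A) {
  d <- dim(A)
  list(out = colMeans(array(A, c(d[1], d[2] * d[3]))), cache = d)
}
gap_bw <- function(dY, dims) {
  # dY is (C, N) possibly as matrix (C*N values)
  dA <- array(rep(as.vector(dY), each = dims[1]) / dims[1], dims)
  dA
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- GRU over a sequence of per-segment embeddings -------------------------
# X: (C, S, R) embeddings, h: (H, R).  Standard gated recurrent unit:
#   z = sigm(Wz x + Uz h + bz); r = sigm(Wr x + Ur h + br)
#   n = tanh(Wn x + r * (Un h) + bn); h' = (1 - z) * n + z * h

gru_fw <- function(X, p) {
  d <- dim(X)
  C <- d[1]; S <- d[2]; R <- d[3]
  H <- length(p$bz)
  h <- matrix(0, H, R)
  steps <- vector("list", S)
  for (t in seq_len(S)) {
    x <- matrix(X[, t, ], C, R)
    z <- sigmoid(p$Wz %*% x + p$Uz %*% h + p$bz)
    r <- sigmoid(p$Wr %*% x + p$Ur %*% h + p$br)
    Unh <- p$Un %*% h
    n <- tanh(p$Wn %*% x + r * Unh + p$bn)
    h_new <- (1 - z) * n + z * h
    steps[[t]] <- list(x = x, h_prev = h, z = z, r = r, n = n, Unh = Unh)
    h <- h_new
  }
  list(out = h, cache = list(steps = steps, C = C, S = S, R = R, H = H, p = p))
}

gru_bw <- function(dh, cache) {
  p <- cache$p
  S <- cache$S
  g <- list(Wz = 0 * p$Wz, Uz = 0 * p$Uz, bz = 0 * p$bz,
            Wr = 0 * p$Wr, Ur = 0 * p$Ur, br = 0 * p$br,
            Wn = 0 * p$Wn, Un = 0 * p$Un, bn = 0 * p$bn)
  dX <- array(0, c(cache$C, S, cache$R))
  for (t in rev(seq_len(S))) {
    st <- steps <- cache$steps[[t]]
    z <- st$z; r <- st$r; n <- st$n; h_prev <- st$h_prev
    dz <- dh * (h_prev - n) * z * (1 - z)
    dn <- dh * (1 - z) * (1 - n^2)
    dr <- dn * st$Unh * r * (1 - r)
    # accumulate parameter gradients
    g$Wz <- g$Wz + tcrossprod(dz, st$x)
    g$Uz <- g$Uz + tcrossprod(dz, h_prev)
    g$bz <- g$bz + rowSums(dz)
    g$Wr <- g$Wr + tcrossprod(dr, st$x)
    g$Ur <- g$Ur + tcrossprod(dr, h_prev)
    g$br <- g$br + rowSums(dr)
    g$Wn <- g$Wn + tcrossprod(dn, st$x)
    g$Un <- g$Un + tcrossprod(dn * r, h_prev)
    g$bn <- g$bn + rowSums(dn)
    dX[, t, ] <- crossprod(p$Wz, dz) + crossprod(p$Wr, dr) + crossprod(p$Wn, dn)
    dh <- dh * z + crossprod(p$Uz, dz) + crossprod(p$Ur, dr) +
      crossprod(p$Un, dn * r)
  }
  list(dX = dX, grads = g)
}

# --- parameter-tree helpers (Adam) -----------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- if (is.null(a[[i]])) NULL else tree_map2(f, a[[i]], b[[i]])
    }
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, function(e) if (is.null(e)) NULL else tree_zero(e))
  else a * 0
}

adam_init <- function(params) list(m = tree_zero(params), v = tree_zero(params), t = 0L)

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, st$v, grads)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), st$m, st$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = st)
}
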