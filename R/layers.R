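# Internal 2-D layer primitives for the encoder-decoder segmenter.
#
# Feature maps are 4-D arrays (H, W, C, N). Convolutions are 3x3 stride-1
# "same" (zero padded) implemented as im2col + GEMM so the heavy lifting is
# done by BLAS. Backward-data passes reuse the forward kernel with
# 180-degree-flipped, channel-transposed weights, which is exact for
# zero-padded stride-1 convolution. Gather indices are precomputed per
# feature-map shape; reshapes use `dim<-` and grouped sums use .rowSums /
# .colSums to keep per-call overhead low.

conv_big_idx <- function(H, W, C, N) {
  key <- paste(H, W, C, N, sep = "x")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  kh <- rep(0:2, times = 3); kw <- rep(0:2, each = 3)
  pix <- rep(seq_len(H), times = W) + (rep(seq_len(W), each = H) - 1L) * Hp
  A <- outer(kh + kw * Hp, pix, "+")                       # 9 x HW
  idx <- A[rep(1:9, C), , drop = FALSE] +
    rep((0:(C - 1L)) * Hp * Wp, each = 9L)
  big <- rep.int(as.vector(idx), N) +
    rep((0:(N - 1L)) * (Hp * Wp * C), each = length(idx))
  storage.mode(big) <- "integer"
  .conv_cache[[key]] <- big
  big
}

im2col3 <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Xp <- array(0, c(H + 2L, W + 2L, C, N))
  Xp[2:(H + 1L), 2:(W + 1L), , ] <- X
  M <- Xp[conv_big_idx(H, W, C, N)]
  dim(M) <- c(9L * C, H * W * N)
  M
}

# X: (H,W,C,N); Wk: (3,3,C,Cout); b: length Cout
conv3_fwd <- function(X, Wk, b) {
  d <- dim(X); Cout <- dim(Wk)[4]
  M <- im2col3(X)
  Wm <- Wk; dim(Wm) <- c(9L * d[3], Cout)
  Y <- crossprod(Wm, M) + b
  dim(Y) <- c(Cout, d[1], d[2], d[4])
  list(Y = aperm(Y, c(2, 3, 1, 4)), M = M)
}

conv3_bwd <- function(X, Wk, M, dY) {
  d <- dim(X); Cout <- dim(Wk)[4]
  Dm <- aperm(dY, c(3, 1, 2, 4))
  dim(Dm) <- c(Cout, d[1] * d[2] * d[4])
  dWk <- tcrossprod(M, Dm)
  dim(dWk) <- dim(Wk)
  db <- .rowSums(Dm, Cout, ncol(Dm))
  Wf <- aperm(Wk[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  dX <- conv3_fwd(dY, Wf, numeric(d[3]))$Y
  list(dX = dX, dW = dWk, db = db)
}

# 1x1 convolution; Wm: (C x Cout)
conv1_fwd <- function(X, Wm, b) {
  d <- dim(X)
  Xm <- aperm(X, c(3, 1, 2, 4))
  dim(Xm) <- c(d[3], d[1] * d[2] * d[4])
  Y <- crossprod(Wm, Xm) + b
  dim(Y) <- c(ncol(Wm), d[1], d[2], d[4])
  list(Y = aperm(Y, c(2, 3, 1, 4)), Xm = Xm)
}

conv1_bwd <- function(X, Wm, Xm, dY) {
  d <- dim(X); Cout <- ncol(Wm)
  Dm <- aperm(dY, c(3, 1, 2, 4))
  dim(Dm) <- c(Cout, d[1] * d[2] * d[4])
  dWm <- tcrossprod(Xm, Dm)
  db <- .rowSums(Dm, Cout, ncol(Dm))
  dXm <- Wm %*% Dm
  dim(dXm) <- c(d[3], d[1], d[2], d[4])
  list(dX = aperm(dXm, c(2, 3, 1, 4)), dW = dWm, db = db)
}

# depthwise 3x3; Wd: (9 x C)
dw3_fwd <- function(X, Wd, b) {
  d <- dim(X); C <- d[3]; n <- d[1] * d[2] * d[4]
  M <- im2col3(X)
  Mw <- M * as.vector(Wd)
  Y <- .colSums(Mw, 9L, C * n)           # sums each 9-row group
  dim(Y) <- c(C, n)
  Y <- Y + b
  dim(Y) <- c(C, d[1], d[2], d[4])
  list(Y = aperm(Y, c(2, 3, 1, 4)), M = M)
}

dw3_bwd <- function(X, Wd, M, dY) {
  d <- dim(X); C <- d[3]; n <- d[1] * d[2] * d[4]
  Dm <- aperm(dY, c(3, 1, 2, 4))
  dim(Dm) <- c(C, n)
  tmp <- M * Dm[rep(seq_len(C), each = 9L), , drop = FALSE]
  dWd <- .rowSums(tmp, 9L * C, n)
  dim(dWd) <- c(9L, C)
  db <- .rowSums(Dm, C, n)
  dim(dY) <- c(d[1], d[2], C, d[4])
  dX <- dw3_fwd(dY, Wd[9:1, , drop = FALSE], numeric(C))$Y
  list(dX = dX, dW = dWd, db = db)
}

pool_fwd <- function(X) {
  d <- dim(X)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  a <- X[i1, j1, , , drop = FALSE]; b <- X[i2, j1, , , drop = FALSE]
  cc <- X[i1, j2, , , drop = FALSE]; e <- X[i2, j2, , , drop = FALSE]
  Y <- pmax(a, b, cc, e)
  list(Y = Y, a = a, b = b, cc = cc, e = e)
}

pool_bwd <- function(cache, dY, dimX) {
  Y <- cache$Y
  m1 <- cache$a == Y
  m2 <- (cache$b == Y) & !m1
  m3 <- (cache$cc == Y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  dX <- array(0, dimX)
  i1 <- seq(1L, dimX[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, dimX[2], 2L); j2 <- j1 + 1L
  dX[i1, j1, , ] <- dY * m1
  dX[i2, j1, , ] <- dY * m2
  dX[i1, j2, , ] <- dY * m3
  dX[i2, j2, , ] <- dY * m4
  dX
}

up_fwd <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

up_bwd <- function(dY) {
  d <- dim(dY)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  dY[i1, j1, , , drop = FALSE] + dY[i2, j1, , , drop = FALSE] +
    dY[i1, j2, , , drop = FALSE] + dY[i2, j2, , , drop = FALSE]
}

cat_channels <- function(A, B) {
  dA <- dim(A); dB <- dim(B)
  Y <- array(0, c(dA[1], dA[2], dA[3] + dB[3], dA[4]))
  Y[, , seq_len(dA[3]), ] <- A
  Y[, , dA[3] + seq_len(dB[3]), ] <- B
  Y
}

# softmax over the class axis; Zm is (K x n)
softmax_cols <- function(Zm) {
  K <- nrow(Zm)
  mx <- Zm[1, ]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, Zm[k, ])
  E <- exp(Zm - rep(mx, each = K))
  E * rep(1 / .colSums(E, K, ncol(E)), each = K)
}

# combined cross-entropy + soft-Jaccard loss and its gradient wrt logits.
# Pm, Tm: (K x n) column-stochastic prediction and one-hot target.
softmax_loss_grad <- function(Pm, Tm, eps = 1e-7) {
  n <- ncol(Pm); K <- nrow(Pm)
  ce <- -mean(.colSums(Tm * log(Pm + eps), K, n))
  p2 <- Pm[K, ]; t2 <- Tm[K, ]
  I <- sum(p2 * t2); U <- sum(p2) + sum(t2) - I
  jac <- if (U > 0) 1 - I / U else 0
  G <- -(Tm / (Pm + eps)) / n
  if (U > 0) G[K, ] <- G[K, ] - (t2 * U - I * (1 - t2)) / U^2
  s <- .colSums(G * Pm, K, n)
  dZ <- Pm * (G - rep(s, each = K))
  list(loss = ce + jac, ce = ce, jaccard = jac, dZ = dZ)
}
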