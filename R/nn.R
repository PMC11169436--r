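## Minimal dense/conv neural-network layers with hand-derived backward
## passes, vectorized over the batch. Batch activations are stored as
## arrays of dim (H, W, N, C) so that reshaping to (H*W*N, C) matrices is a
## zero-copy reinterpretation and every convolution is nine BLAS matrix
## products (one per 3x3 tap).

nn_init_conv <- function(cin, cout) {
  list(W = array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                 c(3, 3, cin, cout)),
       b = numeric(cout))
}

nn_init_dense <- function(din, dout) {
  list(W = matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

## 3x3 same-padding convolution, stride 1 (compiled hot loop).
conv_fwd <- function(X, W, b) {
  conv3_fwd_cpp(X, dim(X), W, b)
}

conv_bwd <- function(dOut, X, W) {
  res <- conv3_bwd_cpp(dOut, X, dim(X), W, dim(W)[4])
  res$dW <- array(res$dW, dim(W))
  res
}

## 2x2 average pooling, stride 2 (even dims required).
pool2_fwd <- function(X) {
  d <- dim(X)
  r1 <- seq(1, d[1], 2); r2 <- seq(2, d[1], 2)
  c1 <- seq(1, d[2], 2); c2 <- seq(2, d[2], 2)
  (X[r1, c1, , , drop = FALSE] + X[r2, c1, , , drop = FALSE] +
     X[r1, c2, , , drop = FALSE] + X[r2, c2, , , drop = FALSE]) / 4
}

pool2_bwd <- function(dOut, in_dim) {
  dX <- array(0, in_dim)
  r1 <- seq(1, in_dim[1], 2); r2 <- seq(2, in_dim[1], 2)
  c1 <- seq(1, in_dim[2], 2); c2 <- seq(2, in_dim[2], 2)
  q <- dOut / 4
  dX[r1, c1, , ] <- q; dX[r2, c1, , ] <- q
  dX[r1, c2, , ] <- q; dX[r2, c2, , ] <- q
  dX
}

## Global average pooling (H, W, N, C) -> (N, C).
gap_fwd <- function(X) {
  d <- dim(X)
  M <- X; dim(M) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colMeans(M), d[3], d[4])
}

gap_bwd <- function(dF, in_dim) {
  array(rep(as.vector(dF) / (in_dim[1] * in_dim[2]), each = in_dim[1] * in_dim[2]),
        in_dim)
}

## Batch normalization over columns of an (N, D) matrix.
bn_fwd <- function(X, gamma, beta, running, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean; v <- running$var
    xc <- sweep(X, 2, mu)
  }
  ivstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivstd, `*`)
  list(out = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`),
       xhat = xhat, ivstd = ivstd, running = running)
}

bn_bwd <- function(dOut, cache, gamma) {
  N <- nrow(dOut)
  dxhat <- sweep(dOut, 2, gamma, `*`)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  ## dX in the batch-statistics regime
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dX <- sweep(t1 - t2, 2, cache$ivstd, `*`)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## Block-mean downsampling of a (H, W, N) stack by integer factor(s)
## k = c(row_factor, col_factor) (a scalar applies to both axes).
input_pool <- function(X, k) {
  if (length(k) == 1) k <- c(k, k)
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[3]
  stopifnot(H %% k[1] == 0, W %% k[2] == 0)
  s1 <- if (k[1] == 1) X else colMeans(array(X, c(k[1], H / k[1], W, N)))
  if (k[2] == 1) return(s1)
  colMeans(aperm(array(s1, c(H / k[1], k[2], W / k[2], N)), c(2, 1, 3, 4)))
}

## Row L2-normalization and its backward pass.
norm_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  list(out = X / n, norms = n)
}

norm_rows_bwd <- function(dYn, Yn, norms) {
  (dYn - Yn * rowSums(dYn * Yn)) / norms
}
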