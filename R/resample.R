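## Separable cubic-convolution ("bicubic") resampling, Keys kernel a = -0.5,
## plus a bilinear inverse-map sampler used by the geometric warps.

cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  w <- numeric(length(x))
  i1 <- x <= 1
  i2 <- x > 1 & x < 2
  w[i1] <- (a + 2) * x[i1]^3 - (a + 3) * x[i1]^2 + 1
  w[i2] <- a * (x[i2]^3 - 5 * x[i2]^2 + 8 * x[i2] - 4)
  w
}

## Resample one axis of a matrix at fractional input positions `pos`
## (1-based; pos[j] = input coordinate of output sample j). Edge-clamped.
resample_axis <- function(X, pos, axis = 1L) {
  if (axis == 2L) return(t(resample_axis(t(X), pos, 1L)))
  n <- nrow(X)
  i0 <- floor(pos)
  t_ <- pos - i0
  cl <- function(i) pmin(pmax(i, 1L), n)
  w1 <- cubic_kernel(1 + t_); w2 <- cubic_kernel(t_)
  w3 <- cubic_kernel(1 - t_); w4 <- cubic_kernel(2 - t_)
  ws <- w1 + w2 + w3 + w4   # renormalize (guards clamped edges)
  out <- X[cl(i0 - 1), , drop = FALSE] * w1 + X[cl(i0), , drop = FALSE] * w2 +
    X[cl(i0 + 1), , drop = FALSE] * w3 + X[cl(i0 + 2), , drop = FALSE] * w4
  out / ws
}

#' Resize a pixel matrix with bicubic interpolation
#'
#' Separable cubic-convolution resampling (Keys kernel, a = -0.5), the
#' classical "bicubic" interpolator. Output sample centers are aligned with
#' input pixel centers through the physical scale `ratio` per axis
#' (input pixels per output pixel).
#'
#' @param X Numeric matrix (rows x cols).
#' @param out_dim Integer `c(rows, cols)` of the output.
#' @param ratio Numeric length-2: input pixels per output pixel on each axis.
#'   Defaults to `dim(X) / out_dim`.
#' @return Numeric matrix of dimension `out_dim`.
#' @export
resize_bicubic <- function(X, out_dim, ratio = dim(X) / out_dim) {
  stopifnot(length(out_dim) == 2, all(out_dim >= 1))
  pos_r <- (seq_len(out_dim[1]) - 0.5) * ratio[1] + 0.5
  pos_c <- (seq_len(out_dim[2]) - 0.5) * ratio[2] + 0.5
  Y <- resample_axis(X, pos_r, 1L)
  resample_axis(Y, pos_c, 2L)
}

## Bilinear sampling of X at fractional (rpos, cpos); out-of-range -> fill.
sample_bilinear <- function(X, rpos, cpos, fill = 0) {
  bilinear_cpp(X, rpos, cpos, fill)
}
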