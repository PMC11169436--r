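#' Training augmentation configuration
#'
#' Four sequential geometric layers applied to each training image: random
#' perspective, random rotation, random transversal (width-only) scaling,
#' and center cropping. No flips of any kind are ever applied — mirrored
#' anatomy would be an undesirable, error-promoting transformation of a
#' clinical image. The transversal defaults (factor 1.04, probability 0.25)
#' are the settings found to maximize cross-vendor identification accuracy;
#' a factor of 1.04 corresponds to a table offset of about 23 mm at a
#' 600 mm source-to-isocenter distance. Perspective and rotation magnitudes
#' are conservative defaults; all fields are configurable.
#'
#' @param perspective_distortion Corner displacement fraction.
#' @param perspective_prob Probability of applying the perspective layer.
#' @param rotation_degrees Maximum absolute rotation, degrees.
#' @param rotation_prob Probability of applying the rotation layer.
#' @param transversal_factor Width scale factor `f >= 1`.
#' @param transversal_prob Probability `p` that an image's width is
#'   rescaled.
#' @param transversal_range `"reciprocal"` samples the scale from
#'   `Uniform[1/f, f]` (symmetric in magnification — tables sit above or
#'   below isocenter); `"linear"` samples from `Uniform[2 - f, f]`.
#' @param crop_rows,crop_cols Final center-crop grid.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(perspective_distortion = 0.1, perspective_prob = 0.5,
                           rotation_degrees = 3, rotation_prob = 0.5,
                           transversal_factor = 1.04, transversal_prob = 0.25,
                           transversal_range = c("reciprocal", "linear"),
                           crop_rows = 384, crop_cols = 256) {
  transversal_range <- match.arg(transversal_range)
  if (transversal_factor < 1) stop("`transversal_factor` must be >= 1")
  if (transversal_prob < 0 || transversal_prob > 1)
    stop("`transversal_prob` must be in [0, 1]")
  structure(list(perspective_distortion = perspective_distortion,
                 perspective_prob = perspective_prob,
                 rotation_degrees = rotation_degrees,
                 rotation_prob = rotation_prob,
                 transversal_factor = transversal_factor,
                 transversal_prob = transversal_prob,
                 transversal_range = transversal_range,
                 crop_rows = as.integer(crop_rows),
                 crop_cols = as.integer(crop_cols)),
            class = "augment_config")
}

#' Random transversal (width-only) scaling
#'
#' With probability `p`, resizes the image width to `round(W * s)` with
#' bicubic interpolation — `s` drawn from `Uniform[1/f, f]` — leaving the
#' height untouched, then center-crops/pads back to the original width.
#' This emulates the change in transversal magnification caused by a
#' different patient-table height at each examination. With probability
#' `1 - p`, or when `f = 1`, the image passes through unchanged. Draws
#' come from the caller's RNG stream; seed the stream (or use
#' [augment_pipeline()]) for reproducibility.
#'
#' @param x Numeric pixel matrix or [scout_image()].
#' @param f Scale factor `>= 1`.
#' @param p Application probability.
#' @param range `"reciprocal"` (`Uniform[1/f, f]`) or `"linear"`
#'   (`Uniform[2 - f, f]`).
#' @param force_scale Bypass randomness and apply exactly this scale
#'   (used by tests and previews).
#' @return Same type as `x`, same dimensions.
#' @export
random_transversal_scaling <- function(x, f = 1.04, p = 0.25,
                                       range = c("reciprocal", "linear"),
                                       force_scale = NULL) {
  range <- match.arg(range)
  if (f < 1) stop("`f` must be >= 1")
  px <- as_pixels(x)
  s <- if (!is.null(force_scale)) force_scale
       else if (stats::runif(1) >= p) 1
       else if (range == "reciprocal") stats::runif(1, 1 / f, f)
       else stats::runif(1, 2 - f, f)
  W <- ncol(px)
  W2 <- as.integer(round(W * s))
  if (W2 != W || s != 1) {
    pos <- (seq_len(W2) - 0.5) * (W / W2) + 0.5
    px <- crop_pad_matrix(resample_axis(px, pos, 2L), nrow(px), W)
  }
  if (inherits(x, "scout_image")) { x$pixels <- px; x } else px
}

## Homography mapping the unit rectangle corners to displaced corners,
## solved by direct linear transform; returns the 3x3 inverse map.
perspective_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Random perspective distortion
#'
#' Displaces each image corner inward by an independent uniform draw up to
#' `distortion` times the half-size, warps through the implied homography
#' (bilinear sampling, zero fill), with probability `p`.
#'
#' @inheritParams random_transversal_scaling
#' @param distortion Maximum corner displacement fraction.
#' @return Same type as `x`, same dimensions.
#' @export
random_perspective <- function(x, distortion = 0.1, p = 0.5) {
  px <- as_pixels(x)
  if (distortion > 0 && stats::runif(1) < p) {
    H <- nrow(px); W <- ncol(px)
    dx <- stats::runif(4, 0, distortion * W / 2)
    dy <- stats::runif(4, 0, distortion * H / 2)
    ## corners (col, row): TL, TR, BR, BL displaced inward
    src <- rbind(c(1, 1), c(W, 1), c(W, H), c(1, H))
    dst <- rbind(c(1 + dx[1], 1 + dy[1]), c(W - dx[2], 1 + dy[2]),
                 c(W - dx[3], H - dy[3]), c(1 + dx[4], H - dy[4]))
    ## inverse map: output pixel -> source location in the original
    Hm <- perspective_homography(src, dst)
    grid_c <- rep(seq_len(W), each = H)
    grid_r <- rep(seq_len(H), W)
    den <- Hm[3, 1] * grid_c + Hm[3, 2] * grid_r + 1
    sc <- (Hm[1, 1] * grid_c + Hm[1, 2] * grid_r + Hm[1, 3]) / den
    sr <- (Hm[2, 1] * grid_c + Hm[2, 2] * grid_r + Hm[2, 3]) / den
    px <- matrix(sample_bilinear(px, sr, sc), H, W)
  }
  if (inherits(x, "scout_image")) { x$pixels <- px; x } else px
}

#' Random small rotation
#'
#' Rotates about the image center by an angle drawn from
#' `Uniform[-degrees, degrees]` (bilinear sampling, zero fill), with
#' probability `p`.
#'
#' @inheritParams random_transversal_scaling
#' @param degrees Maximum absolute angle.
#' @return Same type as `x`, same dimensions.
#' @export
random_rotation <- function(x, degrees = 3, p = 0.5) {
  px <- as_pixels(x)
  if (degrees > 0 && stats::runif(1) < p) {
    th <- stats::runif(1, -degrees, degrees) * pi / 180
    H <- nrow(px); W <- ncol(px)
    cr <- (H + 1) / 2; cc <- (W + 1) / 2
    gc <- rep(seq_len(W), each = H) - cc
    gr <- rep(seq_len(H), W) - cr
    sr <- cos(th) * gr - sin(th) * gc + cr
    sc <- sin(th) * gr + cos(th) * gc + cc
    px <- matrix(sample_bilinear(px, sr, sc), H, W)
  }
  if (inherits(x, "scout_image")) { x$pixels <- px; x } else px
}

#' Full training augmentation pipeline
#'
#' Applies, in order: random perspective, random rotation, random
#' transversal scaling, and a final center crop/pad to
#' `(crop_rows, crop_cols)`. Fully reproducible from `seed`; with all
#' probabilities zero the output is the plain center crop of the input.
#'
#' @param x Numeric pixel matrix or [scout_image()] (preprocessed to the
#'   working size).
#' @param config An [augment_config()].
#' @param seed Integer seed for this draw.
#' @return Same type as `x`, shape `(crop_rows, crop_cols)`.
#' @export
augment_pipeline <- function(x, config = augment_config(), seed = 0L) {
  stopifnot(inherits(config, "augment_config"))
  px <- as_pixels(x)
  px <- with_seed(seed, {
    y <- random_perspective(px, config$perspective_distortion,
                            config$perspective_prob)
    y <- random_rotation(y, config$rotation_degrees, config$rotation_prob)
    random_transversal_scaling(y, config$transversal_factor,
                               config$transversal_prob,
                               config$transversal_range)
  })
  px <- crop_pad_matrix(px, config$crop_rows, config$crop_cols)
  if (inherits(x, "scout_image")) { x$pixels <- px; x } else px
}
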