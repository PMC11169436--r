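#' Preprocessing configuration
#'
#' Defaults implement the standard network-input chain: resample to
#' 2.0 x 2.0 mm pixels with bicubic interpolation, crop/pad to the central
#' 256 x 384 (columns x rows) window, and rescale the bit depth linearly to
#' 8 bits.
#'
#' @param target_spacing Target pixel spacing `c(row_mm, col_mm)`.
#' @param crop_rows,crop_cols Output grid size (rows x cols).
#' @param out_depth Output bit depth; only 8 is supported.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = c(2.0, 2.0), crop_rows = 384,
                              crop_cols = 256, out_depth = 8) {
  stopifnot(length(target_spacing) == 2, all(target_spacing > 0),
            crop_rows >= 1, crop_cols >= 1, out_depth == 8)
  structure(list(target_spacing = as.numeric(target_spacing),
                 crop_rows = as.integer(crop_rows),
                 crop_cols = as.integer(crop_cols),
                 out_depth = as.integer(out_depth)),
            class = "preprocess_config")
}

#' Resample a scout image to a target pixel spacing
#'
#' Bicubic (cubic-convolution) resampling onto a grid with the requested
#' physical spacing. Output dimensions are
#' `round(dim_in * spacing_in / spacing_target)` per axis; sample positions
#' are aligned by physical pixel-center coordinates, so the physical extent
#' is preserved to within one target pixel per axis. An image already at the
#' target spacing passes through unchanged.
#'
#' @param img A [scout_image()].
#' @param target Target spacing `c(row_mm, col_mm)`.
#' @return A [scout_image()] at the target spacing.
#' @export
resample_to_spacing <- function(img, target = c(2.0, 2.0)) {
  stopifnot(inherits(img, "scout_image"))
  target <- as.numeric(target)
  if (length(target) != 2 || any(!is.finite(target)) || any(target <= 0))
    stop("`target` spacing must be two positive numbers")
  d_in <- dim(img$pixels)
  s_in <- img$spacing
  d_out <- pmax(1L, as.integer(round(d_in * s_in / target)))
  pos_r <- ((seq_len(d_out[1]) - 0.5) * target[1]) / s_in[1] + 0.5
  pos_c <- ((seq_len(d_out[2]) - 0.5) * target[2]) / s_in[2] + 0.5
  px <- resample_axis(resample_axis(img$pixels, pos_r, 1L), pos_c, 2L)
  out <- img
  out$pixels <- px
  out$spacing <- target
  out
}

## Crop/pad a plain matrix to (rows, cols): crop window centered with the
## left/top bias of floor() on odd excess; deficits zero-padded symmetrically
## (extra pixel goes after, mirroring the crop bias).
crop_pad_matrix <- function(x, rows, cols, fill = 0) {
  take <- function(n, target) {
    if (n >= target) {
      off <- (n - target) %/% 2L
      list(src = seq.int(off + 1L, off + target), dst = seq_len(target))
    } else {
      off <- (target - n) %/% 2L
      list(src = seq_len(n), dst = seq.int(off + 1L, off + n))
    }
  }
  r <- take(nrow(x), rows); c_ <- take(ncol(x), cols)
  out <- matrix(fill, rows, cols)
  out[r$dst, c_$dst] <- x[r$src, c_$src]
  out
}

#' Center-crop (and zero-pad) a scout image to a fixed grid
#'
#' Crops the central `rows` x `cols` window; when an axis is smaller than
#' the target, the deficit is zero-padded symmetrically. On odd excess the
#' crop origin is biased left/top by `floor()`.
#'
#' @param img A [scout_image()].
#' @param rows,cols Target grid (defaults 384 x 256).
#' @return A [scout_image()] of exactly `rows` x `cols` pixels.
#' @export
center_crop_pad <- function(img, rows = 384, cols = 256) {
  stopifnot(inherits(img, "scout_image"), rows >= 1, cols >= 1)
  out <- img
  out$pixels <- crop_pad_matrix(img$pixels, rows, cols)
  out
}

#' Linearly rescale intensities to 8-bit range
#'
#' Per-image min-max rescale: `round(255 * (x - min) / (max - min))`.
#' A constant image maps to all zeros (the documented degenerate choice).
#'
#' @param img A [scout_image()].
#' @return A [scout_image()] with integer pixel values in `[0, 255]`.
#' @export
rescale_8bit <- function(img) {
  stopifnot(inherits(img, "scout_image"))
  x <- img$pixels
  rng <- range(x)
  out <- img
  out$pixels <- if (rng[2] > rng[1])
    round(255 * (x - rng[1]) / (rng[2] - rng[1]))
  else matrix(0, nrow(x), ncol(x))
  out
}

#' Full preprocessing chain
#'
#' Composition `resample_to_spacing()` then `center_crop_pad()` then
#' [rescale_8bit()], in that order. Every output is exactly
#' `crop_rows` x `crop_cols` (default 384 x 256) with values in `[0, 255]`,
#' whatever the native vendor spacing of the input.
#'
#' @param img A [scout_image()].
#' @param config A [preprocess_config()].
#' @return A network-ready [scout_image()].
#' @export
preprocess <- function(img, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  img <- resample_to_spacing(img, config$target_spacing)
  img <- center_crop_pad(img, config$crop_rows, config$crop_cols)
  rescale_8bit(img)
}
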