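#' Scout image container
#'
#' A `scout_image` bundles a 2D pixel grid (rows x columns, row-major
#' indexing `[row, col]`) with its physical pixel spacing and acquisition
#' metadata. It is the unit of enrollment and query throughout the package.
#'
#' @param pixels Numeric matrix of intensities (rows x cols), finite.
#' @param spacing Numeric length-2, physical pixel spacing in mm as
#'   `c(row_mm, col_mm)`; must be positive.
#' @param patient_id Patient identifier, or `NA` if unknown.
#' @param vendor Scanner vendor tag (e.g. `"S-like"`, `"G-like"`), or `NA`.
#' @param table_height Table height in mm, or `NA`.
#' @param exam_role One of `"baseline"`, `"follow-up"`, `"unknown"`.
#' @return An object of class `scout_image`.
#' @export
scout_image <- function(pixels, spacing, patient_id = NA_character_,
                        vendor = NA_character_, table_height = NA_real_,
                        exam_role = c("unknown", "baseline", "follow-up")) {
  exam_role <- match.arg(exam_role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stop("`pixels` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be two positive numbers (row_mm, col_mm)")
  structure(list(pixels = pixels, spacing = spacing,
                 patient_id = as.character(patient_id),
                 vendor = as.character(vendor),
                 table_height = as.numeric(table_height),
                 exam_role = exam_role),
            class = "scout_image")
}

#' @export
print.scout_image <- function(x, ...) {
  cat(sprintf("<scout_image> %d x %d px, spacing %.3g x %.3g mm", nrow(x$pixels),
              ncol(x$pixels), x$spacing[1], x$spacing[2]))
  if (!is.na(x$patient_id)) cat(", patient", x$patient_id)
  if (!is.na(x$vendor)) cat(", vendor", x$vendor)
  cat("\n")
  invisible(x)
}

#' @export
dim.scout_image <- function(x) dim(x$pixels)

as_pixels <- function(x) if (inherits(x, "scout_image")) x$pixels else x

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a scout image to disk
#'
#' Writes the pixel grid as a 16-bit grayscale TIFF and the metadata (pixel
#' spacing, patient id, vendor, table height, exam role, intensity scale) as
#' a JSON sidecar next to it. Pixels are stored as `pixels / scale_max` on
#' the 16-bit grid; because 65535 is divisible by 255, 8-bit integer images
#' round-trip exactly, and images quantized to the 16-bit grid (as the
#' phantom renderer produces) round-trip bit-identically.
#'
#' @param img A [scout_image()].
#' @param path Output file path (`.tif`/`.tiff`).
#' @param scale_max Intensity that maps to the top of the 16-bit range.
#'   Defaults to 255 for 8-bit-range images, 1 otherwise.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, scale_max = NULL) {
  stopifnot(inherits(img, "scout_image"))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unsupported container: ", path, " (expected .tif/.tiff)")
  if (is.null(scale_max))
    scale_max <- if (max(img$pixels) > 1 + 1e-9) 255 else 1
  px <- img$pixels / scale_max
  if (min(px) < -1e-9 || max(px) > 1 + 1e-9)
    stop("pixels exceed [0, scale_max]; pass an explicit `scale_max`")
  tiff::writeTIFF(pmin(pmax(px, 0), 1), path, bits.per.sample = 16L)
  meta <- list(pixel_spacing_mm = img$spacing, patient_id = img$patient_id,
               vendor = img$vendor, table_height_mm = img$table_height,
               exam_role = img$exam_role, scale_max = scale_max)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a scout image from disk
#'
#' Reads a 16-bit TIFF written by [write_image()] together with its JSON
#' metadata sidecar. A missing sidecar or a sidecar without pixel spacing is
#' an error: spacing is never silently assumed.
#'
#' @param path Path to the `.tif`/`.tiff` file.
#' @return A [scout_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unsupported container: ", path, " (expected .tif/.tiff)")
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("metadata sidecar not found: ", sc,
         " (pixel_spacing_mm is required; it is never assumed)")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$pixel_spacing_mm))
    stop("sidecar ", sc, " is missing required field `pixel_spacing_mm`")
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  scale_max <- if (is.null(meta$scale_max)) 1 else meta$scale_max
  px <- px * scale_max
  if (scale_max == 255) px <- round(px)
  scout_image(px, meta$pixel_spacing_mm,
              patient_id = meta$patient_id %||% NA_character_,
              vendor = meta$vendor %||% NA_character_,
              table_height = meta$table_height_mm %||% NA_real_,
              exam_role = meta$exam_role %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
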