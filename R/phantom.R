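#' Scout-geometry model
#'
#' Projective geometry of a CT scout acquisition: an X-ray source at
#' distance `d0` from the isocenter and a detector at source-to-image
#' distance `sid` (clinical devices sit near 100 cm). Raising or lowering
#' the patient table by `dh` moves the patient relative to the source and
#' changes the transversal (width-direction) magnification by
#' `s(dh) = d0 / (d0 - dh)`; the height direction, swept by table motion,
#' is unaffected.
#'
#' @param sid Source-to-image-receptor distance, mm.
#' @param d0 Source-to-isocenter distance, mm; `0 < d0 < sid`.
#' @return A list of class `geometry_model`.
#' @export
#' @examples
#' g <- geometry_model()
#' transversal_scale(g, 23)   # ~1.04
geometry_model <- function(sid = 1000, d0 = 600) {
  if (!(d0 > 0 && d0 < sid)) stop("geometry requires 0 < d0 < sid")
  structure(list(sid = sid, d0 = d0), class = "geometry_model")
}

#' @rdname geometry_model
#' @param geometry A `geometry_model`.
#' @param dh Signed table offset from centered position, mm.
#' @export
transversal_scale <- function(geometry, dh) {
  stopifnot(inherits(geometry, "geometry_model"))
  if (any(abs(dh) >= geometry$d0))
    stop("degenerate geometry: |dh| must be < d0 = ", geometry$d0, " mm")
  geometry$d0 / (geometry$d0 - dh)
}

#' Vendor acquisition profiles for the phantom
#'
#' Two synthetic vendor profiles emulating the appearance differences
#' between scanner makes: native pixel spacing and field of view, plus a
#' vendor-specific monotone contrast curve. `"S-like"` uses logarithmic
#' dynamic-range compression at 2.0 x 2.0 mm spacing over a 560 mm field;
#' `"G-like"` uses a sigmoid contrast curve at 0.55 x 0.60 mm (row x col)
#' spacing over a 530 mm field. Both curves are identity below the tissue
#' threshold `t = 0.12`: vendors disagree about midtone/highlight
#' rendering, not about air being black. Any two distinct monotone curves
#' would serve; these are fixed so renders are reproducible.
#'
#' @param vendor `"S-like"` or `"G-like"`.
#' @return List with `spacing` (row_mm, col_mm), `fov` (mm) and `contrast`
#'   (a monotone function on `[0, 1]`).
#' @export
vendor_config <- function(vendor) {
  t0 <- 0.12
  upper <- function(x, f) {       # apply f to the rescaled tissue range
    z <- pmax(x - t0, 0) / (1 - t0)
    ifelse(x <= t0, x, t0 + (1 - t0) * f(z))
  }
  switch(vendor,
    "S-like" = list(
      vendor = "S-like", spacing = c(2.0, 2.0), fov = 560,
      contrast = function(x) upper(x, function(z) log(1 + 5 * z) / log(6))),
    "G-like" = list(
      vendor = "G-like", spacing = c(0.55, 0.60), fov = 530,
      contrast = function(x) upper(x, function(z) {
        lo <- stats::plogis(7 * (0 - 0.45)); hi <- stats::plogis(7 * (1 - 0.45))
        (stats::plogis(7 * (z - 0.45)) - lo) / (hi - lo)
      })),
    stop("unknown vendor: ", vendor, " (expected \"S-like\" or \"G-like\")"))
}

phantom_vendors <- c("S-like", "G-like")

#' Deterministically generate a phantom patient's stable anatomy
#'
#' Maps `(master_seed, patient_id)` to a latent anatomy: torso half-widths
#' at shoulder/waist/pelvis, torso height, baseline lung area, spine
#' periodicity, pelvis aspect, an implant flag and a texture seed. The
#' mapping is a pure function of its arguments; distinct ids (or seeds)
#' give distinct latents with probability ~1.
#'
#' @param master_seed Integer master seed.
#' @param patient_id Nonempty string.
#' @return A list of class `patient_latent`.
#' @export
make_patient <- function(master_seed, patient_id) {
  if (!is.character(patient_id) || length(patient_id) != 1 || !nzchar(patient_id))
    stop("`patient_id` must be a nonempty string")
  with_seed(derive_seed(master_seed, "patient", patient_id), {
    shoulder <- runif(1, 150, 215)
    structure(list(
      patient_id = patient_id,
      torso_half_widths = c(shoulder = shoulder,
                            waist = runif(1, 120, min(200, shoulder)),
                            pelvis = runif(1, 135, 205)),
      torso_height = runif(1, 380, 480),
      lung_area_base = runif(1, 0.25, 0.45),
      spine_period = runif(1, 22, 30),
      pelvis_aspect = runif(1, 0.45, 0.70),
      implant_flag = runif(1) < 0.10,
      texture_seed = sample.int(.Machine$integer.max - 1, 1)),
      class = "patient_latent")
  })
}

#' Per-exam nuisance and geometry sampling rates
#'
#' Rates and magnitudes for the intra-patient nuisance factors the phantom
#' emulates (the dominant causes of re-identification errors in clinical
#' scout images): differing scan range, lung condition, intestinal gas and
#' arm position, plus the table-height offset driving transversal
#' magnification. The default occurrence rates 0.50 / 0.40 / 0.325 / 0.225
#' follow the reported relative frequencies of those factors, and the
#' table-offset SD of 14 mm matches reported clinical table-height spread.
#'
#' @param scan_range_prob,scan_range_sd Probability and SD (mm) of a
#'   vertical scan-range shift.
#' @param lung_prob,lung_range Probability and multiplier range of a lung
#'   inflation change.
#' @param gas_prob,gas_max Probability of intestinal gas and maximum number
#'   of gas pockets.
#' @param arms_prob Probability that arms are raised out of the field.
#' @param table_sd SD (mm) of the signed table offset `dh`.
#' @param table_mean_split Difference (mm) between the vendors' nominal
#'   table heights: `dh` centers at `+split/2` for S-like and `-split/2`
#'   for G-like scanners, reflecting the reported per-device means (about
#'   144 vs 135 mm). This makes transversal magnification a systematic
#'   cross-vendor nuisance on top of the per-exam spread; set 0 for a
#'   vendor-free `Normal(0, table_sd)` offset.
#' @param noise_sigma Additive Gaussian noise SD on the unit intensity scale.
#' @return A list of class `nuisance_rates`.
#' @export
nuisance_rates <- function(scan_range_prob = 0.5, scan_range_sd = 25,
                           lung_prob = 0.4, lung_range = c(0.85, 1.15),
                           gas_prob = 0.325, gas_max = 3,
                           arms_prob = 0.225, table_sd = 14,
                           table_mean_split = 9, noise_sigma = 0.01) {
  structure(as.list(environment()), class = "nuisance_rates")
}

#' Construct exam parameters directly (neutral defaults)
#'
#' Mostly useful in tests and geometry experiments; [sample_exam_params()]
#' is the stochastic path used by the cohort generator.
#'
#' @param vendor `"S-like"` or `"G-like"`.
#' @param table_offset_dh Signed table offset, mm.
#' @param scan_range_shift Vertical anatomy shift, mm.
#' @param lung_inflation Lung area multiplier.
#' @param gas `NULL`, or a list with `x` (mm), `u` (relative height) and
#'   `r` (radius, mm) vectors of gas pockets.
#' @param arms_raised Logical.
#' @param noise_sigma Additive noise SD.
#' @param exam_index Integer exam index.
#' @param seed Integer seed used for the render's noise stream.
#' @return A list of class `exam_params`.
#' @export
exam_params <- function(vendor = "S-like", table_offset_dh = 0,
                        scan_range_shift = 0, lung_inflation = 1,
                        gas = NULL, arms_raised = FALSE, noise_sigma = 0,
                        exam_index = 1L, seed = 0L) {
  if (!vendor %in% phantom_vendors)
    stop("unknown vendor: ", vendor)
  structure(list(vendor = vendor, table_offset_dh = table_offset_dh,
                 scan_range_shift = scan_range_shift,
                 lung_inflation = lung_inflation, gas = gas,
                 arms_raised = arms_raised, noise_sigma = noise_sigma,
                 exam_index = as.integer(exam_index), seed = as.integer(seed)),
            class = "exam_params")
}

#' Sample per-exam nuisance and geometry parameters
#'
#' Draws the exam-to-exam variation for one acquisition: a table offset
#' `dh ~ Normal(0, table_sd)` (independent between baseline and follow-up —
#' the table is not returned to the same height across visits), and the
#' nuisance toggles at their configured rates. Fully reproducible from
#' `(latent, vendor, exam_index, seed)`.
#'
#' @param latent A [make_patient()] latent.
#' @param vendor `"S-like"` or `"G-like"`.
#' @param exam_index Integer exam counter for this patient.
#' @param seed Integer seed (typically the cohort master seed).
#' @param rates A [nuisance_rates()].
#' @return An [exam_params()] object.
#' @export
sample_exam_params <- function(latent, vendor, exam_index, seed,
                               rates = nuisance_rates()) {
  stopifnot(inherits(latent, "patient_latent"), inherits(rates, "nuisance_rates"))
  if (!vendor %in% phantom_vendors)
    stop("unknown vendor: ", vendor)
  sd_ <- derive_seed(seed, "exam", latent$patient_id, vendor, exam_index)
  with_seed(sd_, {
    offset <- if (vendor == "S-like") rates$table_mean_split / 2
              else -rates$table_mean_split / 2
    dh <- offset + rnorm(1, 0, rates$table_sd)
    shift <- if (runif(1) < rates$scan_range_prob)
      rnorm(1, 0, rates$scan_range_sd) else 0
    lung <- if (runif(1) < rates$lung_prob)
      runif(1, rates$lung_range[1], rates$lung_range[2]) else 1
    gas <- NULL
    if (runif(1) < rates$gas_prob && rates$gas_max >= 1) {
      ng <- sample.int(rates$gas_max, 1)
      gas <- list(x = runif(ng, -60, 60), u = runif(ng, 0.55, 0.78),
                  r = runif(ng, 8, 20))
    }
    arms <- runif(1) < rates$arms_prob
    exam_params(vendor = vendor, table_offset_dh = dh, scan_range_shift = shift,
                lung_inflation = lung, gas = gas, arms_raised = arms,
                noise_sigma = rates$noise_sigma, exam_index = exam_index,
                seed = sd_)
  })
}

#' Rendering configuration for the phantom
#'
#' @param spacing Override of the vendor-native pixel spacing
#'   `c(row_mm, col_mm)`, or `NULL` for the vendor default.
#' @param fov Override of the field of view (mm), or `NULL`.
#' @param background Background intensity on the unit scale.
#' @param edge_mm Soft-edge width of the body silhouette, mm.
#' @param quantize Quantize output to the 16-bit grid (makes renders
#'   bit-exact through disk round trips).
#' @return A list of class `render_config`.
#' @export
render_config <- function(spacing = NULL, fov = NULL, background = 0.02,
                          edge_mm = 1.5, quantize = TRUE) {
  structure(list(spacing = spacing, fov = fov, background = background,
                 edge_mm = edge_mm, quantize = quantize),
            class = "render_config")
}

soft_gt <- function(a, b, w) stats::plogis((a - b) / w)

#' Render one synthetic scout exam
#'
#' Renders an anterior-view trunk projection from soft-edged geometric
#' primitives: the body silhouette with patient-specific half-width profile,
#' two lung fields, a periodic spine band, a pelvic ring, optional arms,
#' implant and gas pockets, and a faint patient-specific texture. The whole
#' width is scaled by the projective factor `s(dh) = d0 / (d0 - dh)` before
#' discretization at the vendor's native spacing; the vendor's monotone
#' contrast curve and additive Gaussian noise are applied afterwards. This
#' anatomy model is deliberately schematic — built for a controllable
#' identity signal and speed, not radiographic realism.
#'
#' @param latent A [make_patient()] latent.
#' @param params An [exam_params()] object.
#' @param geometry A [geometry_model()].
#' @param config A [render_config()].
#' @param exam_role Metadata tag: `"baseline"`, `"follow-up"` or `"unknown"`.
#' @return A [scout_image()] at the vendor's native spacing.
#' @export
render_exam <- function(latent, params, geometry = geometry_model(),
                        config = render_config(), exam_role = "unknown") {
  stopifnot(inherits(latent, "patient_latent"), inherits(params, "exam_params"),
            inherits(config, "render_config"))
  vc <- vendor_config(params$vendor)
  spacing <- config$spacing %||% vc$spacing
  fov <- config$fov %||% vc$fov
  s <- transversal_scale(geometry, params$table_offset_dh)

  H <- as.integer(round(fov / spacing[1]))
  W <- as.integer(round(fov / spacing[2]))
  ## detector coordinates (mm), demagnified into object coordinates
  x_det <- (seq_len(W) - (W + 1) / 2) * spacing[2]
  y_det <- (seq_len(H) - (H + 1) / 2) * spacing[1]
  x <- x_det / s
  y <- y_det + params$scan_range_shift
  th <- latent$torso_height
  u <- y / th + 0.5                       # 0 = shoulders, 1 = pelvis floor
  hw <- latent$torso_half_widths

  ## torso half-width profile along the height
  prof <- stats::splinefun(
    x = c(-0.06, 0.10, 0.50, 0.85, 1.04),
    y = c(0.30 * hw[["shoulder"]], hw[["shoulder"]], hw[["waist"]],
          hw[["pelvis"]], 0.55 * hw[["pelvis"]]),
    method = "natural")
  halfw <- pmax(prof(pmin(pmax(u, -0.06), 1.04)), 1)
  cap <- stats::plogis(u / 0.02) * stats::plogis((1.02 - u) / 0.02)

  ax <- abs(x)
  body <- soft_gt(halfw, rep(ax, each = H), config$edge_mm)
  dim(body) <- c(H, W)
  body <- body * cap

  ## arms alongside the torso unless raised out of the field
  arm <- 0
  if (!params$arms_raised) {
    inner <- halfw + 8
    armu <- stats::plogis((u - 0.12) / 0.03) * stats::plogis((0.78 - u) / 0.03)
    axm <- rep(ax, each = H); dim(axm) <- c(H, W)
    arm <- soft_gt(axm, inner, 2) * soft_gt(inner + 26, axm, 2) * armu
  }

  ## lung fields
  k <- sqrt((latent$lung_area_base / 0.35) * params$lung_inflation)
  la <- 0.30 * hw[["shoulder"]] * k
  lb <- 0.16 * th * k
  cy <- (0.22 - 0.5) * th
  lung <- 0
  for (sx in c(-1, 1)) {
    cx <- sx * 0.40 * hw[["shoulder"]]
    q <- sqrt(outer(((y - cy) / lb)^2, ((x - cx) / la)^2, "+"))
    lung <- lung + soft_gt(1, q, 0.08)
  }

  ## periodic spine band
  bandu <- stats::plogis((u - 0.04) / 0.03) * stats::plogis((0.92 - u) / 0.03)
  vert <- 0.55 + 0.45 * sin(2 * pi * y / latent$spine_period)
  spine <- outer(bandu * vert, soft_gt(14, ax, 3))

  ## pelvic ring
  pw <- 0.72 * hw[["pelvis"]]
  ph <- pw * latent$pelvis_aspect
  y0 <- (0.84 - 0.5) * th
  q <- sqrt(outer(((y - y0) / ph)^2, (x / pw)^2, "+"))
  ring <- exp(-((q - 1) / 0.12)^2)

  ## implant and gas pockets
  implant <- 0
  if (latent$implant_flag) {
    r <- sqrt(outer((y - (0.76 - 0.5) * th)^2, (x - 24)^2, "+"))
    implant <- soft_gt(11, r, 2)
  }
  gas <- 0
  if (!is.null(params$gas)) {
    for (i in seq_along(params$gas$x)) {
      r <- sqrt(outer((y - (params$gas$u[i] - 0.5) * th)^2,
                      (x - params$gas$x[i])^2, "+"))
      gas <- gas + soft_gt(params$gas$r[i], r, 2)
    }
    gas <- pmin(gas, 1)
  }

  ## stable per-patient texture (low-frequency interference pattern)
  tex <- with_seed(derive_seed(latent$texture_seed, "texture"), {
    tt <- 0
    for (i in 1:3) {
      fx <- runif(1, 1 / 180, 1 / 60); fy <- runif(1, 1 / 180, 1 / 60)
      phi <- runif(1, 0, 2 * pi)
      tt <- tt + sin(2 * pi * outer(fy * y, fx * x, "+") + phi)
    }
    tt / 3
  })

  img <- config$background +
    body * (0.50 + 0.18 * spine + 0.16 * ring + 0.45 * implant -
              0.26 * lung - 0.22 * gas + 0.05 * tex) +
    0.32 * arm
  img <- pmin(pmax(img, 0), 1)
  img <- vc$contrast(img)
  if (params$noise_sigma > 0) {
    img <- img + with_seed(derive_seed(params$seed, "noise"),
                           matrix(rnorm(H * W, 0, params$noise_sigma), H, W))
    img <- pmin(pmax(img, 0), 1)
  }
  if (config$quantize) img <- round(img * 65535) / 65535
  scout_image(img, spacing, patient_id = latent$patient_id,
              vendor = params$vendor,
              table_height = 140 + params$table_offset_dh,
              exam_role = exam_role)
}

#' Measure the body-silhouette width on one image row
#'
#' Thresholds the row slightly above the background level (a small
#' fraction of the image's intensity range) and returns the distance
#' between the outer threshold crossings, with subpixel linear
#' interpolation at each crossing. The threshold sits in the low intensity
#' band where all vendor contrast curves are identity, so the same
#' physical silhouette is recovered whichever vendor processing was
#' applied. Used by the geometry-recovery checks: the ratio of widths
#' between two renders that differ only in table offset equals the ratio
#' of their transversal scale factors, to within one pixel.
#'
#' @param img A [scout_image()].
#' @param row Row index; defaults to the central row (the waist for a
#'   centered phantom).
#' @param frac Threshold as a fraction of the intensity range above the
#'   minimum; keep below the tissue threshold of the contrast curves.
#' @return List with `px` (fractional pixel width) and `mm` (physical
#'   width).
#' @export
silhouette_width <- function(img, row = NULL, frac = 0.08) {
  stopifnot(inherits(img, "scout_image"))
  if (is.null(row)) row <- as.integer(round(nrow(img$pixels) / 2))
  v <- img$pixels[row, ]
  thr <- min(img$pixels) + frac * diff(range(img$pixels))
  above <- which(v > thr)
  if (!length(above)) return(list(px = 0, mm = 0))
  i1 <- above[1]; i2 <- above[length(above)]
  cross_left <- if (i1 > 1)
    (i1 - 1) + (thr - v[i1 - 1]) / (v[i1] - v[i1 - 1]) else 1
  cross_right <- if (i2 < length(v))
    i2 + (thr - v[i2]) / (v[i2 + 1] - v[i2]) else length(v)
  px <- cross_right - cross_left
  list(px = px, mm = px * img$spacing[2])
}
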