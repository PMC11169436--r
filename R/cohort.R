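#' Cohort specification for the phantom generator
#'
#' Describes a synthetic study population. Patients are split into a
#' training pool and a test pool. Training-pool patients contribute
#' `exams_per_patient` (>= 3) exams, the last of which is held out as the
#' validation image (images are used either for training or for validation,
#' never both). Test-pool patients contribute at most two exams: a baseline
#' (the enrollment image) and, for a declared fraction, a follow-up (the
#' query image) — mirroring a clinical archive where every enrolled patient
#' has one trusted baseline and only some return.
#'
#' @param n_patients Number of patients.
#' @param exams_per_patient Exams per training-pool patient (>= 3).
#' @param vendor_policy `"random"` (vendor drawn per exam) or `"fixed"`
#'   (one vendor per patient). The assignment process is exposed as policy
#'   because archives differ; `"random"` produces cross-vendor pairs.
#' @param split Named fractions `c(train = ..., test = ...)` summing to 1.
#' @param followup_fraction Fraction of test patients with a follow-up exam.
#' @param master_seed Integer; all randomness flows from it.
#' @param rates A [nuisance_rates()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, exams_per_patient = 3,
                        vendor_policy = c("random", "fixed"),
                        split = c(train = 0.5, test = 0.5),
                        followup_fraction = 1, master_seed = 1,
                        rates = nuisance_rates()) {
  vendor_policy <- match.arg(vendor_policy)
  if (!setequal(names(split), c("train", "test")) ||
      abs(sum(split) - 1) > 1e-8)
    stop("`split` must be named fractions c(train=, test=) summing to 1")
  if (exams_per_patient < 3)
    stop("training-pool patients need >= 3 exams (train + held-out validation)")
  n_train <- round(n_patients * split[["train"]])
  n_test <- n_patients - n_train
  if (n_train < 1 || n_test < 1)
    stop("n_patients = ", n_patients, " is too small for split (",
         "train pool ", n_train, ", test pool ", n_test,
         "); each pool needs at least one patient")
  structure(list(n_patients = as.integer(n_patients),
                 exams_per_patient = as.integer(exams_per_patient),
                 vendor_policy = vendor_policy, split = split,
                 followup_fraction = followup_fraction,
                 master_seed = as.integer(master_seed), rates = rates),
            class = "cohort_spec")
}

#' Generate a phantom cohort
#'
#' Renders every exam of a [cohort_spec()] and returns (or writes) the
#' images together with a manifest table. The manifest records patient id,
#' exam index, vendor, table offset, split (`train`/`val`/`test`), role
#' (`train`/`val`/`baseline`/`follow-up`) and, when `out_dir` is given, the
#' image file path. No patient appears in more than one split; running the
#' same spec twice yields identical manifests and images.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Directory to write TIFF+sidecar images and
#'   `manifest.csv`, or `NULL` to keep images in memory.
#' @param geometry A [geometry_model()].
#' @param config A [render_config()]; pass a coarse spacing override for
#'   fast experimentation.
#' @return List with `manifest` (data.frame) and `images` (named list of
#'   [scout_image()], names matching `manifest$key`).
#' @export
generate_cohort <- function(spec, out_dir = NULL, geometry = geometry_model(),
                            config = render_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ms <- spec$master_seed
  ids <- sprintf("P%03d", seq_len(spec$n_patients))
  n_train <- round(spec$n_patients * spec$split[["train"]])
  ord <- with_seed(derive_seed(ms, "split"), sample(ids))
  train_ids <- sort(ord[seq_len(n_train)])
  test_ids <- sort(setdiff(ids, train_ids))
  n_fu <- round(length(test_ids) * spec$followup_fraction)
  fu_ids <- sort(with_seed(derive_seed(ms, "followup"),
                           sample(test_ids, n_fu)))

  rows <- list()
  for (pid in ids) {
    is_train <- pid %in% train_ids
    n_ex <- if (is_train) spec$exams_per_patient
            else if (pid %in% fu_ids) 2L else 1L
    fixed_vendor <- with_seed(derive_seed(ms, "vendor", pid),
                              sample(phantom_vendors, 1))
    for (e in seq_len(n_ex)) {
      vendor <- if (spec$vendor_policy == "fixed") fixed_vendor
                else with_seed(derive_seed(ms, "vendor", pid, e),
                               sample(phantom_vendors, 1))
      role <- if (is_train) {
        if (e == n_ex) "val" else "train"
      } else if (e == 1L) "baseline" else "follow-up"
      rows[[length(rows) + 1]] <- data.frame(
        key = sprintf("%s_e%d", pid, e), patient_id = pid, exam_index = e,
        vendor = vendor, split = if (is_train) {
          if (role == "val") "val" else "train"
        } else "test",
        role = role, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)

  images <- vector("list", nrow(manifest))
  names(images) <- manifest$key
  dh <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    latent <- make_patient(ms, r$patient_id)
    params <- sample_exam_params(latent, r$vendor, r$exam_index, ms,
                                 rates = spec$rates)
    dh[i] <- params$table_offset_dh
    images[[i]] <- render_exam(latent, params, geometry, config,
                               exam_role = if (r$role %in% c("baseline", "follow-up"))
                                 r$role else "unknown")
  }
  manifest$table_offset_dh <- dh
  manifest$path <- NA_character_

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      p <- file.path(out_dir, paste0(manifest$key[i], ".tif"))
      write_image(images[[i]], p, scale_max = 1)
      manifest$path[i] <- p
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, images = images)
}

#' Read a written cohort back from disk
#'
#' Loads `manifest.csv` and the TIFF+sidecar images written by
#' [generate_cohort()] with an `out_dir`.
#'
#' @param dir Cohort directory.
#' @return List with `manifest` and `images`, as [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  images <- lapply(manifest$path, read_image)
  names(images) <- manifest$key
  list(manifest = manifest, images = images)
}
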