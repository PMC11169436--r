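# Shared fixtures. Everything is generated in code; heavy objects are
# built once per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Coarse, fast render settings for unit tests (native-spacing rendering is
# exercised in the preprocessing and acceptance tests).
fast_render <- function() render_config(spacing = c(4, 4), fov = 512)

tiny_cohort <- function() memo("tiny_cohort", {
  generate_cohort(cohort_spec(n_patients = 8, exams_per_patient = 3,
                              split = c(train = 0.5, test = 0.5),
                              master_seed = 11),
                  config = fast_render())
})

tiny_dataset <- function() memo("tiny_dataset", {
  prepare_reid_dataset(tiny_cohort())
})

# A quickly trained extractor shared by embedder/matcher tests (coarse
# input resolution keeps unit tests fast).
tiny_model <- function() memo("tiny_model", {
  train_extractor(tiny_dataset(), desk_backbone(input_pool = 4),
                  train_config(epochs = 8, batch_size = 8, augment = NULL,
                               track_history = TRUE, seed = 5))
})

# An asymmetric test image: bright L-shape, off-center.
asym_image <- function(rows = 384, cols = 256) {
  x <- matrix(0, rows, cols)
  x[40:200, 30:60] <- 200
  x[180:200, 30:180] <- 255
  x
}
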