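test_that("patient latents are deterministic in (seed, id) and distinct otherwise", {
  a <- make_patient(42, "P001")
  b <- make_patient(42, "P001")
  expect_identical(a, b)

  differs <- function(x, y) {
    any(vapply(setdiff(names(x), "patient_id"), function(f)
      !identical(x[[f]], y[[f]]), TRUE))
  }
  expect_true(differs(make_patient(42, "P001"), make_patient(42, "P002")))
  expect_true(differs(make_patient(41, "P001"), make_patient(42, "P001")))

  expect_error(make_patient(1, ""), "nonempty")

  lat <- make_patient(7, "P010")
  expect_true(all(lat$torso_half_widths >= 120 & lat$torso_half_widths <= 220))
  expect_gte(lat$lung_area_base, 0.2)
  expect_lte(lat$lung_area_base, 0.5)
})

test_that("exam parameter sampling is reproducible and matches its distribution", {
  lat <- make_patient(42, "P001")
  p1 <- sample_exam_params(lat, "S-like", 1, 99)
  p2 <- sample_exam_params(lat, "S-like", 1, 99)
  expect_identical(p1, p2)
  expect_error(sample_exam_params(lat, "X-like", 1, 1), "unknown vendor")

  # table offset ~ Normal(vendor offset, 14): Monte-Carlo check
  dh <- vapply(seq_len(10000), function(i)
    sample_exam_params(lat, "S-like", i, 1)$table_offset_dh, 0)
  expect_lt(abs(sd(dh) - 14), 0.5)
  expect_lt(abs(mean(dh) - 4.5), 0.5)
  dh0 <- vapply(seq_len(5000), function(i)
    sample_exam_params(lat, "G-like", i, 1,
                       rates = nuisance_rates(table_mean_split = 0))$table_offset_dh, 0)
  expect_lt(abs(mean(dh0)), 0.7)

  # all nuisance toggles neutral when rates are zero
  r0 <- nuisance_rates(scan_range_prob = 0, lung_prob = 0, gas_prob = 0,
                       arms_prob = 0)
  pn <- sample_exam_params(lat, "G-like", 3, 5, rates = r0)
  expect_identical(pn$scan_range_shift, 0)
  expect_identical(pn$lung_inflation, 1)
  expect_null(pn$gas)
  expect_false(pn$arms_raised)
})

test_that("transversal scale follows the projective geometry model", {
  g <- geometry_model()
  expect_equal(transversal_scale(g, 0), 1)
  expect_equal(transversal_scale(g, 23), 600 / 577)
  expect_equal(transversal_scale(g, -23), 600 / 623)
  expect_error(transversal_scale(g, 600), "degenerate")
  expect_error(geometry_model(sid = 500, d0 = 600), "0 < d0 < sid")
})

test_that("renders are deterministic and table offset scales the silhouette width", {
  lat <- make_patient(42, "P001")
  g <- geometry_model()
  im1 <- render_exam(lat, exam_params("S-like"), g, fast_render())
  im2 <- render_exam(lat, exam_params("S-like"), g, fast_render())
  expect_identical(im1$pixels, im2$pixels)

  # width ratio tracks d0 / (d0 - dh) within one pixel across offsets
  w0 <- silhouette_width(im1)$px
  for (dh in c(-50, -23, 23, 50)) {
    im <- render_exam(lat, exam_params("S-like", table_offset_dh = dh), g,
                      fast_render())
    expect_lt(abs(silhouette_width(im)$px - w0 * 600 / (600 - dh)), 1)
  }
  expect_error(render_exam(lat, exam_params("S-like", table_offset_dh = 700), g),
               "degenerate")
})

test_that("vendors share geometry but differ in intensity rendition", {
  lat <- make_patient(3, "P019")
  g <- geometry_model()
  imS <- render_exam(lat, exam_params("S-like", table_offset_dh = 10), g)
  imG <- render_exam(lat, exam_params("G-like", table_offset_dh = 10), g)
  # silhouette widths in mm agree within one (2 mm) pixel
  expect_lt(abs(silhouette_width(imS)$mm - silhouette_width(imG)$mm), 2)
  # intensity histograms differ clearly
  br <- seq(0, 1, by = 0.05)
  hS <- hist(imS$pixels, breaks = br, plot = FALSE)$density
  hG <- hist(imG$pixels, breaks = br, plot = FALSE)$density
  expect_gt(sum(abs(hS - hG)), 1)
  # native vendor rasters
  expect_identical(imS$spacing, c(2, 2))
  expect_identical(imG$spacing, c(0.55, 0.60))
})

test_that("same-patient renders correlate more than different-patient renders", {
  # the identity signal the extractor must learn, at the pixel level
  n <- 10
  imgs <- lapply(seq_len(n), function(i) {
    lat <- make_patient(21, sprintf("P%03d", i))
    lapply(1:2, function(e) {
      pr <- sample_exam_params(lat, "S-like", e, 21,
                               rates = nuisance_rates(noise_sigma = 0.005))
      preprocess(render_exam(lat, pr, config = fast_render()))$pixels
    })
  })
  same <- vapply(imgs, function(p) cor(c(p[[1]]), c(p[[2]])), 0)
  diff <- unlist(lapply(1:(n - 1), function(i)
    vapply((i + 1):n, function(j)
      cor(c(imgs[[i]][[1]]), c(imgs[[j]][[1]])), 0)))
  expect_gt(mean(same), mean(diff))
})

test_that("cohort generation is deterministic, conserving and split-disjoint", {
  spec <- cohort_spec(n_patients = 12, exams_per_patient = 3, master_seed = 7)
  c1 <- generate_cohort(spec, config = fast_render())
  c2 <- generate_cohort(spec, config = fast_render())
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$images, c2$images)

  man <- c1$manifest
  n_train_pat <- length(unique(man$patient_id[man$split != "test"]))
  n_test_pat <- length(unique(man$patient_id[man$split == "test"]))
  expect_equal(nrow(man), n_train_pat * 3 + n_test_pat * 2)

  # no patient id in two splits (train/val share patients by design; the
  # disjointness contract is train-pool vs test-pool)
  expect_length(intersect(man$patient_id[man$split %in% c("train", "val")],
                          man$patient_id[man$split == "test"]), 0)
  # images are unique across roles
  expect_false(anyDuplicated(man$key) > 0)
  # every test patient has a baseline
  tst <- man[man$split == "test", ]
  expect_setequal(tst$patient_id[tst$role == "baseline"], unique(tst$patient_id))

  expect_error(generate_cohort(cohort_spec(1)), "too small")
  expect_error(cohort_spec(10, split = c(train = 0.7, test = 0.2)), "summing to 1")
  expect_error(cohort_spec(10, exams_per_patient = 2), ">= 3 exams")
})
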