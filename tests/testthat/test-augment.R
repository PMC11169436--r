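test_that("transversal scaling degenerates to identity and rejects bad factors", {
  x <- asym_image()
  set.seed(1)
  expect_identical(random_transversal_scaling(x, f = 1.0, p = 1), x)
  expect_identical(random_transversal_scaling(x, f = 1.2, p = 0), x)
  expect_error(random_transversal_scaling(x, f = 0.9), ">= 1")
  expect_error(augment_config(transversal_factor = 0.9), ">= 1")
  expect_error(augment_config(transversal_prob = 1.2), "\\[0, 1\\]")
})

test_that("forced transversal scale resizes the width and crops back", {
  x <- asym_image(384, 256)
  y <- random_transversal_scaling(x, force_scale = 1.04)
  expect_identical(dim(y), dim(x))    # round(256 * 1.04) = 266, cropped to 256
  # column extent of the bright object scales by ~1.04; rows untouched
  col_extent <- function(m) {
    cs <- colSums(m > 50)
    range(which(cs > 0))
  }
  e0 <- col_extent(x); e1 <- col_extent(y)
  w0 <- diff(e0) + 1; w1 <- diff(e1) + 1
  expect_lt(abs(w1 - 1.04 * w0), 3)
  expect_identical(range(which(rowSums(y > 50) > 0)), range(which(rowSums(x > 50) > 0)))

  # row-wise center of mass of a symmetric pattern is preserved
  s <- matrix(0, 100, 100); s[40:60, 30:70] <- 1
  z <- random_transversal_scaling(s, force_scale = 1.1)
  com <- function(m) sum(col(m) * m) / sum(m)
  expect_lt(abs(com(z) - com(s)), 0.2)
})

test_that("the applied fraction matches the configured probability", {
  x <- matrix(runif(40 * 40), 40, 40)
  p <- 0.25; n <- 2000
  set.seed(42)
  applied <- vapply(seq_len(n), function(i)
    !identical(random_transversal_scaling(x, f = 1.5, p = p), x), TRUE)
  # binomial 3-sigma band
  expect_lt(abs(mean(applied) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the pipeline is ordered, seeded and shape-stable", {
  x <- asym_image()
  cfg0 <- augment_config(perspective_prob = 0, rotation_prob = 0,
                         transversal_prob = 0)
  expect_identical(augment_pipeline(x, cfg0, seed = 1), x)

  cfg <- augment_config()
  a <- augment_pipeline(x, cfg, seed = 7)
  b <- augment_pipeline(x, cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, augment_pipeline(x, cfg, seed = 8)))
  for (seed in 1:5)
    expect_identical(dim(augment_pipeline(x, cfg, seed = seed)), c(384L, 256L))

  # scout_image in, scout_image out
  im <- scout_image(x, c(2, 2))
  out <- augment_pipeline(im, cfg, seed = 7)
  expect_s3_class(out, "scout_image")
  expect_identical(out$pixels, a)
})

test_that("no augmentation draw ever mirrors the image", {
  # an augmented asymmetric pattern must stay closer to the original than
  # to its left-right or top-bottom mirror
  x <- asym_image()
  xm_lr <- x[, ncol(x):1]
  xm_tb <- x[nrow(x):1, ]
  cfg <- augment_config()
  for (seed in 1:25) {
    y <- augment_pipeline(x, cfg, seed = seed)
    d0 <- mean((y - x)^2)
    expect_lt(d0, mean((y - xm_lr)^2))
    expect_lt(d0, mean((y - xm_tb)^2))
  }
})
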