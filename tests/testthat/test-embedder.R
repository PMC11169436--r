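test_that("the adaptive cosine scale follows its closed forms", {
  # initial scale: s0 = sqrt(2) * log(C - 1)
  expect_equal(adacos_init(3, 8)$s, sqrt(2) * log(2), tolerance = 1e-12)
  expect_equal(adacos_init(101, 8)$s, sqrt(2) * log(100), tolerance = 1e-12)
  expect_error(adacos_init(2, 8), "at least 3 classes")

  # samples exactly on their class weights: theta_med = 0, s = ln(B_avg)
  C <- 4
  st <- adacos_init(C, C)
  st$weights <- diag(C)
  E <- diag(C)
  out <- adacos_logits(E, 1:C, st)
  # cosines are the identity matrix, so B_avg = (C - 1) * exp(0) and the
  # update reduces to s = ln(C - 1)
  expect_equal(out$state$s, log(C - 1), tolerance = 1e-12)

  # orthogonal embeddings: theta_med = pi/2 clamps to pi/4
  st2 <- adacos_init(3, 3)
  st2$weights <- diag(3)
  E2 <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  s0 <- st2$s
  out2 <- adacos_logits(E2, 1:3, st2)
  expect_equal(out2$state$s, log(exp(s0) + 1) / cos(pi / 4), tolerance = 1e-12)

  # frozen at evaluation
  out3 <- adacos_logits(E2, 1:3, st2, update = FALSE)
  expect_equal(out3$state$s, s0)
  expect_equal(out3$logits, s0 * out3$cos)

  # non-normalized input is normalized with a warning
  expect_warning(adacos_logits(2 * E2, 1:3, st2), "normaliz")
})

test_that("label-smoothed cross entropy reduces, bounds and descends correctly", {
  set.seed(8)
  logits <- matrix(rnorm(5 * 4), 5, 4)
  y <- c(1L, 3L, 2L, 4L, 1L)

  # eps = 0 equals the plain cross entropy
  ce <- -mean(vapply(1:5, function(i) {
    z <- logits[i, ] - max(logits[i, ])
    z[y[i]] - log(sum(exp(z)))
  }, 0))
  expect_equal(smooth_ce_loss(logits, y, 0), ce, tolerance = 1e-12)

  # uniform logits: loss = ln C for any eps
  u <- matrix(1.7, 6, 5)
  for (eps in c(0, 0.05, 0.3))
    expect_equal(smooth_ce_loss(u, rep(2L, 6), eps), log(5), tolerance = 1e-12)

  # perfectly classified logits: loss decreases monotonically with scale
  oh <- diag(4)[c(1, 2, 3), ]
  losses <- vapply(c(1, 2, 5, 10, 20), function(s)
    smooth_ce_loss(s * oh, 1:3, 0), 0)
  expect_true(all(diff(losses) < 0))
  expect_error(smooth_ce_loss(logits, y, 1), "eps")

  # analytic gradient agrees with finite differences
  g <- scoutreid:::smooth_ce_grad(logits, y, 0.05)
  eps_ <- 1e-6
  for (i in sample(length(logits), 6)) {
    lp <- logits; lp[i] <- lp[i] + eps_
    lm <- logits; lm[i] <- lm[i] - eps_
    num <- (smooth_ce_loss(lp, y, 0.05) - smooth_ce_loss(lm, y, 0.05)) / (2 * eps_)
    expect_lt(abs(num - g[i]), 1e-6)
  }
})

test_that("training reduces the loss and widens the genuine/impostor gap", {
  m <- tiny_model()
  h <- m$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_true(all(is.finite(h$adacos_s)) && all(h$adacos_s > 0))
  gap <- h$genuine_mean - h$impostor_mean
  expect_gt(gap[nrow(h)], gap[1])
})

test_that("training is reproducible from its seed", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 2, batch_size = 8, augment = augment_config(),
                      track_history = FALSE, seed = 12)
  m1 <- train_extractor(ds, desk_backbone(input_pool = 4), cfg)
  m2 <- train_extractor(ds, desk_backbone(input_pool = 4), cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)
})

test_that("training rejects degenerate datasets", {
  ds <- tiny_dataset()
  two <- ds
  keep <- two$train$labels %in% unique(two$train$labels)[1:2]
  two$train <- lapply(two$train, function(v) v[keep])
  expect_error(train_extractor(two, desk_backbone(),
                               train_config(epochs = 1)), "3 training classes")
  leak <- ds
  leak$val$keys[1] <- leak$train$keys[1]
  expect_error(train_extractor(leak, desk_backbone(),
                               train_config(epochs = 1)), "share images")
})

test_that("embedding extraction is deterministic and batch-size invariant", {
  m <- tiny_model()
  ds <- tiny_dataset()
  imgs <- ds$test$x[1:5]
  E1 <- extract_embeddings(m, imgs, batch_size = 1)
  E8 <- extract_embeddings(m, imgs, batch_size = 8)
  expect_equal(E1, E8, tolerance = 1e-12)

  dup <- extract_embeddings(m, list(a = imgs[[1]], b = imgs[[1]]))
  expect_equal(dup[1, ], dup[2, ], tolerance = 1e-12)

  expect_equal(ncol(extract_embeddings(m, imgs[1])), m$config$embed_dim)
  expect_equal(ncol(extract_embeddings(m, imgs[1], use_head = FALSE)),
               m$backbone$feature_dim)
  expect_error(extract_embeddings(m, list(matrix(0, 10, 10))), "wrong shape")
})

test_that("the desk backbone can memorize its own small training set", {
  ds <- tiny_dataset()
  m <- train_extractor(ds, desk_backbone(input_pool = 4),
                       train_config(epochs = 100, batch_size = 8,
                                    augment = NULL, track_history = FALSE,
                                    seed = 2))
  tr <- ds$train
  gal_i <- match(unique(tr$labels), tr$labels)
  q_i <- setdiff(seq_along(tr$x), gal_i)
  S <- cosine_similarity_matrix(extract_embeddings(m, tr$x[q_i]),
                                extract_embeddings(m, tr$x[gal_i]))
  expect_equal(as.numeric(topk_accuracy(S, tr$labels[q_i], tr$labels[gal_i], 1)),
               1.0)
})
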