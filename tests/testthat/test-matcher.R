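test_that("cosine similarity hits its closed-form anchor cases", {
  q <- rbind(c(1, 0), c(0, 2), c(-3, 0))
  g <- rbind(c(2, 0), c(0, 1))
  S <- cosine_similarity_matrix(q, g)
  expect_equal(S[1, 1], 1)
  expect_equal(S[1, 2], 0)
  expect_equal(S[3, 1], -1)
  expect_true(all(S >= -1 & S <= 1))

  expect_error(cosine_similarity_matrix(rbind(c(0, 0), c(1, 1)), g),
               "zero query vector.*1")
  expect_error(cosine_similarity_matrix(q, rbind(c(1, 1), c(0, 0))),
               "zero gallery vector.*2")
})

test_that("similarity is invariant to positive rescaling", {
  set.seed(3)
  Q <- matrix(rnorm(5 * 8), 5, 8)
  G <- matrix(rnorm(7 * 8), 7, 8)
  expect_equal(cosine_similarity_matrix(3.7 * Q, G),
               cosine_similarity_matrix(Q, G), tolerance = 1e-12)
})

test_that("similarity matches the brute-force pairwise loop", {
  set.seed(9)
  for (rep in 1:5) {
    Q <- matrix(rnorm(10 * 6), 10, 6)
    G <- matrix(rnorm(7 * 6), 7, 6)
    S <- cosine_similarity_matrix(Q, G)
    for (i in 1:10) for (j in 1:7) {
      ref <- sum(Q[i, ] * G[j, ]) / sqrt(sum(Q[i, ]^2) * sum(G[j, ]^2))
      expect_lt(abs(S[i, j] - ref), 1e-6)
    }
  }
})

test_that("gallery ranking is descending with stable index tie-breaks", {
  S <- rbind(c(0.2, 0.9, 0.5), c(0.4, 0.4, 0.4))
  expect_identical(rank_gallery(S, 1), c(2L, 3L, 1L))
  expect_identical(rank_gallery(S, 2), c(1L, 2L, 3L))   # all-equal: identity
  expect_identical(rank_gallery(S, 1)[1], which.max(S[1, ]))
})

test_that("identify returns top-k ids with non-increasing scores", {
  set.seed(2)
  E <- matrix(rnorm(4 * 6), 4, 6)
  gal <- build_gallery(E, sprintf("P%d", 1:4), rep("S-like", 4))
  S <- rbind(c(0.2, 0.9, 0.5, 0.1))
  out <- identify(S, gal, k = 1)
  expect_identical(out[[1]]$patient_ids, "P2")
  all4 <- identify(S, gal, k = 4)[[1]]
  expect_setequal(all4$patient_ids, gal$patient_ids)
  expect_true(all(diff(all4$scores) <= 0))
  expect_identical(all4$top_score, 0.9)
  expect_error(identify(S, gal, k = 5), "out of range")
  expect_error(identify(S, gal, k = 0), "out of range")
})

test_that("gallery construction enforces the one-image-per-patient policy", {
  E <- matrix(rnorm(6), 3, 2)
  expect_error(build_gallery(E, c("A", "B", "A")), "duplicated ids: A")
  expect_error(build_gallery(rbind(E[1:2, ], 0), c("A", "B", "C")),
               "zero embedding")
  gal <- build_gallery(E * 10, c("A", "B", "C"))
  expect_equal(rowSums(gal$embeddings^2), rep(1, 3))
})

test_that("multi-image enrollment fuses scores by per-patient maximum", {
  set.seed(6)
  E <- matrix(rnorm(5 * 4), 5, 4)
  ids <- c("A", "A", "B", "C", "C")
  expect_error(build_gallery(E, ids), "duplicated")
  gal <- build_gallery(E, ids, multi = TRUE)
  Q <- matrix(rnorm(3 * 4), 3, 4)
  S <- cosine_similarity_matrix(Q, gal)
  fused <- fuse_gallery_scores(S, gal$patient_ids)
  expect_identical(fused$patient_ids, c("A", "B", "C"))
  expect_equal(fused$values[, "A"], pmax(S[, 1], S[, 2]))
  expect_equal(fused$values[, "B"], S[, 3])
  # fusion never lowers a patient's best score
  expect_true(all(fused$values >= S[, c(1, 3, 4)] - 1e-12))
})
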