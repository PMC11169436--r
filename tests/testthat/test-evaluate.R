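brute_topk <- function(S, ql, gl, k) {
  # independent oracle: full sort per query with the stable tie rule
  hits <- vapply(seq_len(nrow(S)), function(i) {
    ord <- order(-S[i, ])
    ql[i] %in% gl[ord[seq_len(k)]]
  }, TRUE)
  mean(hits)
}

test_that("top-K accuracy matches its anchor examples and the brute-force oracle", {
  l2 <- c("A", "B")
  expect_equal(as.numeric(topk_accuracy(rbind(c(0.9, 0.1), c(0.2, 0.8)),
                                        l2, l2, 1)), 1.0)
  S <- rbind(c(0.1, 0.9), c(0.2, 0.8))
  expect_equal(as.numeric(topk_accuracy(S, l2, l2, 1)), 0.5)
  expect_equal(as.numeric(topk_accuracy(S, l2, l2, 2)), 1.0)
  expect_error(topk_accuracy(S, l2, l2, 0), ">= 1")

  set.seed(31)
  for (rep in 1:20) {
    Sq <- matrix(runif(8 * 6), 8, 6)
    gl <- sprintf("P%d", 1:6)
    ql <- sample(gl, 8, replace = TRUE)
    for (k in c(1, 2, 4, 6))
      expect_equal(as.numeric(topk_accuracy(Sq, ql, gl, k)),
                   brute_topk(Sq, ql, gl, k))
    # exhaustion: every enrolled query is found at K = N_g
    expect_equal(as.numeric(topk_accuracy(Sq, ql, gl, 6)), 1.0)
  }

  # non-enrolled queries are excluded and reported; the remaining query
  # ("A", scores 0.1 vs 0.9) ranks its own gallery entry second
  expect_warning(a <- topk_accuracy(S, c("A", "Z"), l2, 1), "no enrolled")
  expect_equal(as.numeric(a), 0.0)
  expect_identical(attr(a, "n_excluded"), 1L)
  expect_warning(a2 <- topk_accuracy(S, c("A", "Z"), l2, 2), "no enrolled")
  expect_equal(as.numeric(a2), 1.0)
})

test_that("CMC curves are monotone, exhaustive and consistent with acc@K", {
  set.seed(17)
  S <- matrix(runif(10 * 7), 10, 7)
  gl <- sprintf("P%d", 1:7)
  ql <- sample(gl, 10, replace = TRUE)
  cmc <- cmc_curve(S, ql, gl)
  expect_true(all(diff(cmc) >= 0))
  expect_equal(cmc[length(cmc)], 1.0)
  expect_equal(cmc[1], as.numeric(topk_accuracy(S, ql, gl, 1)))
  expect_equal(cmc[3], as.numeric(topk_accuracy(S, ql, gl, 3)))
  expect_error(cmc_curve(S, ql, gl, 8), "k_max")
})

test_that("score distributions separate genuine from impostor pairs", {
  # identical embedding per patient, distinct across patients
  E <- diag(4)
  S <- cosine_similarity_matrix(E, E)
  sd_ <- score_distributions(S, sprintf("P%d", 1:4), sprintf("P%d", 1:4))
  expect_equal(sd_$genuine_mean, 1.0)
  expect_true(sd_$separated)
  expect_identical(sd_$genuine_n + sd_$impostor_n, 16L)

  # random unit directions in D = 64: impostor similarities center on zero
  set.seed(5)
  Q <- matrix(rnorm(50 * 64), 50, 64)
  S2 <- cosine_similarity_matrix(Q, Q)
  sd2 <- score_distributions(S2, sprintf("q%d", 1:50), sprintf("q%d", 1:50))
  expect_lt(abs(sd2$impostor_mean), 3 / sqrt(64))
  expect_identical(sd2$genuine_n + sd2$impostor_n, 2500L)

  expect_error(score_distributions(S, rep("P1", 4), rep("P1", 4)), "impostor")
  expect_error(score_distributions(S, rep("X", 4), sprintf("P%d", 1:4)),
               "genuine")
})

test_that("stratified evaluation conserves counts and pools consistently", {
  set.seed(23)
  n_g <- 12; n_q <- 18
  gl <- sprintf("P%02d", 1:n_g)
  gv <- rep(c("S-like", "G-like"), length.out = n_g)
  ql <- sample(gl, n_q, replace = TRUE)
  qv <- sample(c("S-like", "G-like"), n_q, replace = TRUE)
  S <- matrix(runif(n_q * n_g), n_q, n_g)
  rep_ <- stratified_eval(S, ql, gl, qv, gv, ks = c(1, 3))

  expect_equal(sum(rep_$cells[, "n"]), n_q)
  expect_equal(sum(rep_$groups[, "n"]), n_q)

  # pooled group accuracy equals the directly computed subset accuracy
  bv <- gv[match(ql, gl)]
  same <- which(bv == qv)
  expect_equal(unname(rep_$groups["same vendor", "acc1"]),
               brute_topk(S[same, , drop = FALSE], ql[same], gl, 1))
  diffv <- which(bv != qv)
  expect_equal(unname(rep_$groups["different vendors", "acc3"]),
               brute_topk(S[diffv, , drop = FALSE], ql[diffv], gl, 3))

  # single-vendor cohort: the different-vendor group is empty, reported as such
  rep1 <- stratified_eval(S, ql, gl, rep("S-like", n_q), rep("S-like", n_g))
  expect_equal(unname(rep1$groups["different vendors", "n"]), 0)
  expect_true(is.na(rep1$groups["different vendors", "acc1"]))

  # missing vendor tags are grouped under "untagged", never dropped
  qv_na <- qv; qv_na[1:3] <- NA
  rep2 <- stratified_eval(S, ql, gl, qv_na, gv)
  expect_equal(unname(rep2$groups["untagged", "n"]), 3)
  expect_equal(sum(rep2$groups[, "n"]), n_q)
})

test_that("the two-proportion Z-test matches its closed form and prop.test", {
  t1 <- two_proportion_ztest(824, 887, 347, 404)
  p1 <- 824 / 887; p2 <- 347 / 404; ph <- (824 + 347) / (887 + 404)
  z_ref <- (p1 - p2) / sqrt(ph * (1 - ph) * (1 / 887 + 1 / 404))
  expect_equal(t1$statistic, z_ref, tolerance = 1e-10)
  expect_equal(t1$p_value, 2 * pnorm(-abs(z_ref)), tolerance = 1e-10)

  # independent route: Z^2 equals the uncorrected chi-squared of prop.test
  pt <- prop.test(c(824, 347), c(887, 404), correct = FALSE)
  expect_equal(t1$statistic^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(t1$p_value, pt$p.value, tolerance = 1e-10)

  # symmetry and antisymmetry
  expect_equal(two_proportion_ztest(5, 10, 10, 20)$statistic, 0)
  expect_equal(two_proportion_ztest(5, 10, 10, 20)$p_value, 1)
  t_ab <- two_proportion_ztest(30, 50, 20, 60)
  t_ba <- two_proportion_ztest(20, 60, 30, 50)
  expect_equal(t_ab$statistic, -t_ba$statistic, tolerance = 1e-12)
  expect_equal(t_ab$p_value, t_ba$p_value, tolerance = 1e-12)

  expect_warning(z0 <- two_proportion_ztest(0, 10, 0, 5), "zero variance")
  expect_equal(z0$p_value, 1)
  expect_error(two_proportion_ztest(11, 10, 1, 5), "k1 <= n1")
})

test_that("McNemar's test matches its closed form and stats::mcnemar.test", {
  m1 <- mcnemar_test(10, 10)
  expect_equal(m1$statistic, 0.05, tolerance = 1e-12)

  m2 <- mcnemar_test(5, 15)
  expect_equal(m2$statistic, (abs(5 - 15) - 1)^2 / 20, tolerance = 1e-12)
  expect_equal(m2$statistic, 4.05, tolerance = 1e-12)
  expect_equal(m2$p_value, pchisq(4.05, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(abs(m2$p_value - 0.044), 5e-4)

  # independent route: stats::mcnemar.test on the equivalent 2x2 table
  ref <- mcnemar.test(matrix(c(40, 5, 15, 40), 2, 2))
  expect_equal(m2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(m2$p_value, ref$p.value, tolerance = 1e-10)

  # b = c attains the maximal p among fixed b + c (ties with |b - c| = 2
  # under the continuity correction)
  ps <- vapply(0:10, function(b) mcnemar_test(b, 20 - b)$p_value, 0)
  expect_equal(ps[11], max(ps))

  # exact-binomial option for small discordant counts
  m3 <- mcnemar_test(3, 9)
  expect_equal(m3$p_value_exact, binom.test(3, 12, 0.5)$p.value,
               tolerance = 1e-12)
  expect_error(mcnemar_test(0, 0), "no discordant")
})
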