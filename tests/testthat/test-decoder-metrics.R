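# Hand-built decoders with known outputs: a linear softmax decoder whose
# logits are `scale * x %*% M` produces controlled prediction tables.
manual_decoder <- function(M, scale = 1, bias = NULL) {
  k <- ncol(M)
  rine:::new_fitted_decoder(
    weights = list(scale * M),
    biases = list(if (is.null(bias)) rep(0, k) else bias),
    activation = "relu", n_classes = k
  )
}

test_that("cross-entropy hits the uniform and perfect-predictor endpoints", {
  k <- 4
  d <- onehot_copy_dataset(200, k, seed = 1, n_sources = 1)
  uniform <- manual_decoder(matrix(0, k, k))
  expect_equal(cross_entropy_bits(uniform, d, 1), log2(k))
  # saturated softmax on the true label: loss bounded by the 1e-12 floor
  perfect <- manual_decoder(diag(k), scale = 200)
  expect_lt(cross_entropy_bits(perfect, d, 1), 1e-6)
  wrong_dim <- manual_decoder(matrix(0, 2, 4))
  expect_error(cross_entropy_bits(wrong_dim, d, 1), "input feature")
})

test_that("cross-entropy of the true conditional converges to H(Y|X)", {
  pmf <- make_canonical("AND")
  d <- sample_dataset(pmf, 50000, seed = 9)
  # linear decoder realizing p(y | x1): x1 = 0 -> (1, 0), x1 = 1 -> (0.5, 0.5)
  dec <- rine:::new_fitted_decoder(
    weights = list(matrix(c(-25, 25), nrow = 1)),
    biases = list(c(25, -25)),
    activation = "relu", n_classes = 2
  )
  expect_equal(predict_probs(dec, matrix(0))[1, 1], 1, tolerance = 1e-8)
  expect_equal(predict_probs(dec, matrix(1))[1, 1], 0.5, tolerance = 1e-8)
  h_cond <- entropy_bits(pmf, c("x1", "y")) - entropy_bits(pmf, "x1") # 0.5 bits
  expect_equal(cross_entropy_bits(dec, d, 1), h_cond, tolerance = 0.02)
})

test_that("prediction distance spans its [0, 2] range as expected", {
  k <- 2
  d <- onehot_copy_dataset(100, k, seed = 2, n_sources = 2)
  same <- manual_decoder(diag(k), scale = 100)
  expect_equal(prediction_distance(same, same, d), 0)
  # disjoint one-hots on every row: f2 predicts the flipped class
  flip <- manual_decoder(diag(k)[, c(2, 1)], scale = 100)
  expect_equal(prediction_distance(same, flip, d), 2, tolerance = 1e-8)
  # agreement on half the rows: average of 0 and 2
  half <- labeled_dataset(
    list(diag(2)[c(1, 1, 2, 2), ], diag(2)[c(1, 2, 2, 1), ]),
    c(0L, 0L, 1L, 1L), 2
  )
  expect_equal(prediction_distance(same, same, half), 1, tolerance = 1e-8)
})

test_that("the penalized objective matches its hand computation", {
  k <- 2
  d <- onehot_copy_dataset(64, k, seed = 3, n_sources = 2)
  f1 <- manual_decoder(diag(k), scale = 100)
  f2 <- manual_decoder(matrix(0, k, k))
  ce1 <- cross_entropy_bits(f1, d, 1)
  ce2 <- cross_entropy_bits(f2, d, 2)
  D <- prediction_distance(f1, f2, d)
  expect_equal(lagrangian_bits(f1, f2, d, 0), (ce1 + ce2) / 2)
  expect_equal(lagrangian_bits(f1, f2, d, 3), (ce1 + ce2) / 2 + 3 * D)
  expect_equal(lagrangian_bits(f1, f1, d, 7), ce1, tolerance = 1e-10)
  expect_error(lagrangian_bits(f1, f2, d, -1), "non-negative")
})

test_that("the beta schedule ramps linearly then plateaus", {
  s <- beta_schedule(beta_start = 2, beta_final = 12, ramp_fraction = 0.5)
  expect_equal(beta_at(s, 0), 2)
  expect_equal(beta_at(s, 0.25), 7) # midpoint of the ramp
  expect_equal(beta_at(s, 0.5), 12)
  expect_equal(beta_at(s, 1), 12)
  expect_error(beta_at(s, 1.5), "progress")
  expect_error(beta_schedule(beta_start = 5, beta_final = 1), "beta_start")
  expect_error(beta_schedule(ramp_fraction = 0), "ramp_fraction")
})

test_that("cosine similarity handles parallel, orthogonal and shared columns", {
  m <- matrix(rnorm(60), 20, 3)
  expect_equal(cosine_similarity_mean(m, m), 1)
  a <- cbind(1, 0)[rep(1, 10), ]
  b <- cbind(0, 1)[rep(1, 10), ]
  expect_equal(cosine_similarity_mean(a, b), 0)
  # appending identical shared columns strictly increases the similarity
  m2 <- matrix(rnorm(60), 20, 3)
  base <- cosine_similarity_mean(m, m2)
  shared <- matrix(rnorm(40), 20, 2)
  expect_gt(cosine_similarity_mean(cbind(m, shared), cbind(m2, shared)), base)
  expect_error(cosine_similarity_mean(m, m2[, 1:2]), "column count")
  expect_error(cosine_similarity_mean(rbind(a, 0), rbind(b, 0)), "zero-norm")
})
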