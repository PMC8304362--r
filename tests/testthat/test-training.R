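test_that("clean shared one-hot sources recover the full label entropy", {
  train <- onehot_copy_dataset(2000, 2, seed = 1)
  test <- onehot_copy_dataset(2000, 2, seed = 2)
  fit <- train_rine(train, test, decoder_family(), quick_config(seeds = 1),
                    seed = 1, h_y_bits = 1)
  expect_equal(fit$i_cap_v_bits, 1, tolerance = 0.02)
  expect_lt(fit$final_distance, 0.02)
})

test_that("labels independent of both sources yield no redundancy", {
  set.seed(4)
  mk <- function(seed) {
    set.seed(seed)
    labeled_dataset(list(matrix(rnorm(1000 * 3), ncol = 3),
                         matrix(rnorm(1000 * 3), ncol = 3)),
                    sample(0:1, 1000, replace = TRUE), 2)
  }
  fit <- train_rine(mk(10), mk(11), decoder_family(), quick_config(seeds = 1),
                    seed = 1, h_y_bits = 1)
  expect_lt(abs(fit$i_cap_v_bits), 0.06)
})

test_that("training is reproducible given the seed and leaves the RNG alone", {
  td <- quick_task_data("RDNXOR", n = 600)
  cfg <- quick_config(seeds = 1, epochs = 10)
  set.seed(77)
  snapshot <- .Random.seed
  f1 <- train_rine(td$train, td$test, decoder_family(), cfg, seed = 3,
                   h_y_bits = 2)
  expect_identical(snapshot, .Random.seed)
  f2 <- train_rine(td$train, td$test, decoder_family(), cfg, seed = 3,
                   h_y_bits = 2)
  expect_identical(f1$i_cap_v_bits, f2$i_cap_v_bits)
  expect_identical(f1$decoders[[1]]$weights, f2$decoders[[1]]$weights)
})

test_that("usable information matches the task structure", {
  # UNQ: each source alone decodes exactly 1 of the 2 label bits
  td <- quick_task_data("UNQ", n = 4000)
  iu <- usable_information_bits(td$train, td$test, decoder_family(),
                                quick_config(seeds = 1), source_index = 1,
                                seed = 5, h_y_bits = 2)
  expect_equal(iu, 1, tolerance = 0.05)
  # identity source with 4 classes: perfect decoding of 2 bits
  train <- onehot_copy_dataset(3000, 4, seed = 6, n_sources = 1)
  test <- onehot_copy_dataset(3000, 4, seed = 7, n_sources = 1)
  iu2 <- usable_information_bits(train, test, decoder_family(),
                                 quick_config(seeds = 1), seed = 2, h_y_bits = 2)
  expect_equal(iu2, 2, tolerance = 0.05)
  # independent label: nothing decodable
  set.seed(8)
  noise <- function(seed) {
    set.seed(seed)
    labeled_dataset(list(matrix(rnorm(2000), ncol = 2)),
                    sample(0:1, 1000, replace = TRUE), 2)
  }
  iu3 <- usable_information_bits(noise(1), noise(2), decoder_family(),
                                 quick_config(seeds = 1), seed = 2, h_y_bits = 1)
  expect_lt(abs(iu3), 0.06)
})

test_that("multi-seed aggregation reports means, sds and degenerate cases", {
  td <- quick_task_data("IMPERFECTRDN", n = 2000)
  est <- estimate_redundancy(td$train, td$test, decoder_family(),
                             quick_config(seeds = 1:3),
                             h_y_bits = entropy_bits(td$pmf, "y"))
  expect_length(est$per_seed_bits, 3)
  expect_equal(est$mean_bits, mean(est$per_seed_bits))
  expect_equal(est$sd_bits, sd(est$per_seed_bits))
  expect_equal(dim(est$per_seed_cross_entropies), c(3, 2))
  # single seed: sd undefined, reported as absent
  est1 <- estimate_redundancy(td$train, td$test, decoder_family(),
                              quick_config(seeds = 9),
                              h_y_bits = entropy_bits(td$pmf, "y"))
  expect_true(is.na(est1$sd_bits))
  expect_length(est1$per_seed_bits, 1)
})

test_that("the n-source extension reduces to and extends the pairwise case", {
  td <- quick_task_data("RDNXOR", n = 2000)
  cfg <- quick_config(seeds = 1:2)
  h_y <- 2
  two <- estimate_redundancy(td$train, td$test, decoder_family(), cfg,
                             h_y_bits = h_y)
  two_ms <- estimate_redundancy_multisource(td$train, td$test,
                                            decoder_family(), cfg,
                                            h_y_bits = h_y)
  expect_identical(two$per_seed_bits, two_ms$per_seed_bits)

  # three identical clean copies: agreement is free, estimate ~ usable info
  tri_train <- onehot_copy_dataset(2000, 2, seed = 21, n_sources = 3)
  tri_test <- onehot_copy_dataset(2000, 2, seed = 22, n_sources = 3)
  tri <- estimate_redundancy_multisource(tri_train, tri_test,
                                         decoder_family(),
                                         quick_config(seeds = 1),
                                         h_y_bits = 1)
  expect_equal(tri$mean_bits, 1, tolerance = 0.05)

  # appending a pure-noise third source destroys attainable agreement
  with_noise <- function(ds, seed) {
    set.seed(seed)
    labeled_dataset(c(ds$sources,
                      list(matrix(rnorm(n_obs <- nrow(ds$sources[[1]])), ncol = 1))),
                    ds$labels, ds$n_classes)
  }
  noisy <- suppressWarnings(estimate_redundancy_multisource(
    with_noise(td$train, 31), with_noise(td$test, 32),
    decoder_family(), quick_config(beta_final = 30, seeds = 1), h_y_bits = 2
  ))
  expect_lt(noisy$mean_bits, 0.15)
})

test_that("pathological inputs fail with informative errors", {
  td <- quick_task_data("AND", n = 200)
  expect_error(train_rine(td$train, quick_task_data("UNQ", n = 200)$test,
                          decoder_family(), quick_config(seeds = 1), 1),
               "class count")
  one_source <- labeled_dataset(td$train$sources[1], td$train$labels, 2)
  expect_error(train_rine(one_source, one_source, decoder_family(),
                          quick_config(seeds = 1), 1), "2 sources")
  expect_error(estimate_redundancy(one_source, one_source, decoder_family(),
                                   quick_config(seeds = 1)), "two-source")
  expect_error(
    train_rine(td$train, td$test, decoder_family(kind = "convolutional"),
               quick_config(seeds = 1), 1),
    "fully-connected"
  )
})

test_that("decoder checkpoints round-trip through disk", {
  td <- quick_task_data("AND", n = 500)
  fit <- train_rine(td$train, td$test, decoder_family(),
                    quick_config(seeds = 1, epochs = 5), seed = 1,
                    h_y_bits = entropy_bits(td$pmf, "y"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_decoder(fit$decoders[[1]], path, info = list(seed = 1))
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_decoder(path)
  x <- td$test$sources[[1]]
  expect_equal(predict_probs(back, x), predict_probs(fit$decoders[[1]], x))
})
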