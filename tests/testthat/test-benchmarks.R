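test_that("overlap task construction follows its bookkeeping invariants", {
  # no noise or shared units: columns = informative units exactly
  spec <- overlap_task_spec(5, n_informative_units = 10, seed = 3)
  ds <- make_overlap_task(spec)
  expect_equal(ncol(ds$train$sources[[1]]), 10)
  expect_equal(ncol(ds$train$sources[[2]]), 10)
  expect_equal(nrow(ds$train$sources[[1]]), 800)
  expect_equal(ds$train$n_classes, 8)
  # balanced classes
  expect_true(all(table(ds$train$labels) == 100))
  # extra units appended
  spec2 <- overlap_task_spec(5, n_informative_units = 10, n_noise_units = 7,
                             n_shared_nontask_units = 3, seed = 3)
  ds2 <- make_overlap_task(spec2)
  expect_equal(ncol(ds2$train$sources[[1]]), 20)
  # shared non-task units are identical across the two sources
  shared1 <- ds2$train$sources[[1]][, 18:20]
  shared2 <- ds2$train$sources[[2]][, 18:20]
  expect_identical(shared1, shared2)
  # encoded-class overlap must be non-negative
  expect_error(overlap_task_spec(3), "\\[4, 8\\]")
})

test_that("informative units are class-selective only for encoded classes", {
  spec <- overlap_task_spec(4, n_informative_units = 8,
                            samples_per_class = 400, seed = 11)
  ds <- make_overlap_task(spec)
  x1 <- ds$train$sources[[1]]
  lab <- ds$train$labels
  # source 1 encodes classes 0..3: unit 1 prefers class 0
  m_pref <- mean(x1[lab == 0, 1])
  m_other <- mean(x1[lab == 5, 1])
  expect_gt(m_pref, 1.5)
  expect_lt(abs(m_other), 0.3)
  # classes not encoded by source 1 (4..7) leave all its units at baseline
  for (cl in 4:7) {
    expect_lt(max(abs(colMeans(x1[lab == cl, ]))), 0.3)
  }
})

test_that("cosine similarity of informative units ignores the noise seed only through noise columns", {
  s1 <- overlap_task_spec(6, n_noise_units = 0, n_shared_nontask_units = 0,
                          seed = 5)
  ds <- make_overlap_task(s1)
  c0 <- cosine_similarity_mean(ds$train$sources[[1]], ds$train$sources[[2]])
  expect_true(c0 > -1 && c0 < 1)
})

test_that("redundancy endpoints bracket the overlap sweep", {
  cfg <- train_config(epochs = 150, batch_size = 128, learning_rate = 2e-3,
                      beta = beta_schedule(0, 50, 0.8), seeds = 1)
  # full overlap, clean: estimate approaches H(Y) = 3 bits
  full <- make_overlap_task(overlap_task_spec(8, samples_per_class = 100, seed = 2))
  est_full <- estimate_redundancy(full$train, full$test, decoder_family(), cfg,
                                  h_y_bits = 3)
  expect_gt(est_full$mean_bits, 2.4)
  # disjoint encoded sets: no redundancy
  disj <- make_overlap_task(overlap_task_spec(4, samples_per_class = 100, seed = 2))
  est_disj <- suppressWarnings(
    estimate_redundancy(disj$train, disj$test, decoder_family(), cfg,
                        h_y_bits = 3)
  )
  expect_lt(abs(est_disj$mean_bits), 0.35)
  expect_gt(est_full$mean_bits, est_disj$mean_bits)
})

test_that("the sweep returns a complete long-format grid", {
  res <- run_overlap_sweep(
    n_encoded_values = c(4L, 8L), noise_unit_counts = c(0L, 5L),
    shared_unit_counts = 0L, seeds = 1L,
    config = quick_config(beta_final = 50, seeds = 1, epochs = 25,
                          batch_size = 128),
    samples_per_class = 50
  )
  expect_setequal(unique(res$metric), c("redundancy_bits", "cosine_similarity"))
  expect_equal(nrow(res), 2 * 2 * 2) # cells x metrics
  expect_false(any(is.na(res$value)))
})

test_that("benchmark report aggregation contract holds on a miniature run", {
  rep <- suppressWarnings(run_canonical_suite(
    beta_final = 15, n_seeds = 1, base_seed = 4, n_train = 400, n_test = 400,
    epochs = 8, tasks = c("UNQ", "RDNXOR")
  ))
  expect_equal(nrow(rep), 2)
  expect_true(all(is.na(rep$sd_bits))) # one seed: sd absent
  expect_equal(rep$oracle_wedge_bits, c(0, 1))
  # bit-reproducible given the same base seed
  rep2 <- suppressWarnings(run_canonical_suite(
    beta_final = 15, n_seeds = 1, base_seed = 4, n_train = 400, n_test = 400,
    epochs = 8, tasks = c("UNQ", "RDNXOR")
  ))
  expect_identical(rep$mean_bits, rep2$mean_bits)
})
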