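canonical_true_value <- function(task) {
  switch(task,
    UNQ = "0", AND = "[0, 0.311]", RDNXOR = "1", IMPERFECTRDN = "0.99")
}

#' Run the canonical benchmark suite
#'
#' For each of the four canonical tasks (UNQ, AND, RDNXOR, IMPERFECTRDN):
#' samples train/test datasets from the exact pmf, runs the multi-seed
#' constrained estimate, and attaches the exact common-variable redundancy
#' oracle and the literature reference value. All sampling and training
#' seeds derive deterministically from `base_seed`.
#'
#' @param beta_final final agreement-penalty coefficient (15 matches the
#'   canonical benchmark configuration).
#' @param n_seeds number of training initializations per task.
#' @param base_seed integer master seed.
#' @param n_train,n_test samples drawn for training and held-out evaluation.
#' @param epochs,batch_size,learning_rate training configuration defaults
#'   chosen for the canonical tasks.
#' @param family decoder family shared by both sources.
#' @param tasks subset of tasks to run (default all four).
#' @return a `benchmark_report` data frame with columns `task`, `beta_final`,
#'   `mean_bits`, `sd_bits`, `oracle_wedge_bits`, `true_value`,
#'   `mean_final_distance`, `n_seeds_ok`, `error`; the full per-task
#'   [estimate_redundancy()] objects are attached as `attr(, "estimates")`.
#' @export
run_canonical_suite <- function(beta_final = 15, n_seeds = 5, base_seed = 1,
                                n_train = 10000, n_test = 10000,
                                epochs = 150, batch_size = 256,
                                learning_rate = 1e-3,
                                family = decoder_family(),
                                tasks = canonical_task_names()) {
  stopifnot(n_seeds >= 1)
  tasks <- match.arg(tasks, canonical_task_names(), several.ok = TRUE)
  rows <- list()
  estimates <- list()
  for (t_idx in seq_along(tasks)) {
    task <- tasks[t_idx]
    pmf <- make_canonical(task)
    oracle <- i_cap_wedge_bits(pmf)
    est <- tryCatch({
      train <- sample_dataset(pmf, n_train, derive_seed(base_seed, t_idx, 1))
      test <- sample_dataset(pmf, n_test, derive_seed(base_seed, t_idx, 2))
      cfg <- train_config(
        epochs = epochs, batch_size = batch_size,
        learning_rate = learning_rate,
        beta = beta_schedule(0, beta_final, 0.8),
        seeds = vapply(seq_len(n_seeds), function(k) {
          derive_seed(base_seed, t_idx, 2 + k)
        }, 1L)
      )
      estimate_redundancy(train, test, family, cfg,
                          h_y_bits = entropy_bits(pmf, "y"))
    }, error = function(e) e)

    if (inherits(est, "error")) {
      rows[[task]] <- data.frame(
        task = task, beta_final = beta_final, mean_bits = NA_real_,
        sd_bits = NA_real_, oracle_wedge_bits = oracle,
        true_value = canonical_true_value(task),
        mean_final_distance = NA_real_, n_seeds_ok = 0L,
        error = conditionMessage(est), stringsAsFactors = FALSE
      )
    } else {
      estimates[[task]] <- est
      rows[[task]] <- data.frame(
        task = task, beta_final = beta_final, mean_bits = est$mean_bits,
        sd_bits = est$sd_bits, oracle_wedge_bits = oracle,
        true_value = canonical_true_value(task),
        mean_final_distance = mean(est$final_distances),
        n_seeds_ok = length(est$per_seed_bits),
        error = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "estimates") <- estimates
  class(report) <- c("benchmark_report", "data.frame")
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Canonical redundancy benchmarks (all quantities in bits)\n")
  df <- as.data.frame(x)
  df$mean_bits <- sprintf("%.3f", df$mean_bits)
  df$sd_bits <- ifelse(is.na(x$sd_bits), "-", sprintf("%.4f", x$sd_bits))
  print(df[, c("task", "true_value", "oracle_wedge_bits", "beta_final",
               "mean_bits", "sd_bits")], row.names = FALSE)
  invisible(x)
}

#' Specify the synthetic class-overlap task
#'
#' A population-decoding-style task with 8 balanced classes. Each source
#' carries class-selective informative units: unit `j` is tuned to class
#' `((j - 1) mod 8) + 1` and fires with mean +3 (unit-variance Gaussian
#' noise) when its tuned class is shown *and* that class belongs to the
#' source's encoded set; otherwise the unit is baseline noise. Each source
#' encodes a contiguous block of `n_encoded_per_source` classes, so the two
#' sources' encoded sets overlap in `2 * n_encoded_per_source - 8` classes,
#' which controls the redundant information. Because the unit-to-class
#' tuning is shared across sources, units tuned to jointly-encoded classes
#' respond identically in both sources, giving the inputs themselves a
#' similarity that grows with the overlap. Optional pure-noise units
#' (independent per source) and shared non-task units (identical across the
#' two sources, label-independent) carry no information about the label but
#' do move input-space similarity metrics.
#'
#' @param n_encoded_per_source classes encoded per source, in `[4, 8]`.
#' @param n_informative_units class-selective units per source (default 16,
#'   i.e. two units tuned to each of the 8 classes).
#' @param n_noise_units independent pure-noise units per source.
#' @param n_shared_nontask_units label-independent units appended identically
#'   to both sources.
#' @param noise_scale standard deviation of noise and shared units.
#' @param samples_per_class observations per class (per dataset).
#' @param seed integer master seed for the generator.
#' @return an object of class `overlap_task_spec`.
#' @export
overlap_task_spec <- function(n_encoded_per_source,
                              n_informative_units = 16,
                              n_noise_units = 0,
                              n_shared_nontask_units = 0,
                              noise_scale = 1,
                              samples_per_class = 100,
                              seed = 1) {
  n_encoded_per_source <- as.integer(n_encoded_per_source)
  if (n_encoded_per_source < 4 || n_encoded_per_source > 8) {
    stop("n_encoded_per_source must lie in [4, 8] so the overlap 2n - 8 is in [0, 8]")
  }
  stopifnot(n_informative_units >= 1, n_noise_units >= 0,
            n_shared_nontask_units >= 0, noise_scale > 0,
            samples_per_class >= 1)
  structure(
    list(
      n_classes_total = 8L,
      n_encoded_per_source = n_encoded_per_source,
      n_informative_units = as.integer(n_informative_units),
      n_noise_units = as.integer(n_noise_units),
      n_shared_nontask_units = as.integer(n_shared_nontask_units),
      noise_scale = noise_scale,
      samples_per_class = as.integer(samples_per_class),
      seed = as.integer(seed)
    ),
    class = "overlap_task_spec"
  )
}

overlap_encoded_sets <- function(spec) {
  n <- spec$n_encoded_per_source
  list(seq_len(n), seq(8L - n + 1L, 8L)) # 1-based class ids
}

generate_overlap_dataset <- function(spec, seed) {
  k <- spec$n_classes_total
  n <- k * spec$samples_per_class
  classes <- rep(seq_len(k), each = spec$samples_per_class) # 1-based
  enc <- overlap_encoded_sets(spec)
  # unit j is tuned to class ((j - 1) mod 8) + 1, identically in both sources
  pref <- (seq_len(spec$n_informative_units) - 1L) %% k + 1L
  selective_mean <- 3
  with_preserved_seed(seed, {
    shared <- matrix(rnorm(n * spec$n_shared_nontask_units, sd = spec$noise_scale),
                     nrow = n)
    sources <- lapply(1:2, function(s) {
      active <- pref %in% enc[[s]]
      mu <- selective_mean * outer(classes, pref, "==") *
        rep(as.numeric(active), each = n)
      informative <- mu + matrix(rnorm(n * spec$n_informative_units), nrow = n)
      noise <- matrix(rnorm(n * spec$n_noise_units, sd = spec$noise_scale),
                      nrow = n)
      cbind(informative, noise, shared)
    })
    labeled_dataset(sources, classes - 1L, k)
  })
}

#' Generate train/test datasets for the class-overlap task
#'
#' @param spec an [overlap_task_spec()].
#' @return list with elements `train` and `test`, both [labeled_dataset()]s
#'   drawn independently (the test draw uses a seed derived from
#'   `spec$seed`).
#' @export
make_overlap_task <- function(spec) {
  stopifnot(inherits(spec, "overlap_task_spec"))
  list(
    train = generate_overlap_dataset(spec, derive_seed(spec$seed, 91, 1)),
    test = generate_overlap_dataset(spec, derive_seed(spec$seed, 91, 2))
  )
}

#' Sweep the overlap task over class overlap, noise units and shared units
#'
#' Runs the redundancy estimator and the rowwise cosine similarity on every
#' cell of the factorial grid and returns a long-format table for plotting:
#' redundancy should grow with the class overlap and stay flat in the
#' label-independent unit counts, whereas cosine similarity falls with noise
#' units and rises with shared non-task units.
#'
#' @param n_encoded_values integer vector of classes-per-source values.
#' @param noise_unit_counts integer vector of pure-noise unit counts.
#' @param shared_unit_counts integer vector of shared non-task unit counts.
#' @param seeds integer vector of generator seeds (each seed is one
#'   replicate cell; the training seed derives from it).
#' @param config a [train_config()]; default is a light configuration sized
#'   for the 800-sample task.
#' @param family decoder family for both sources.
#' @param samples_per_class observations per class in each generated dataset.
#' @return long-format data frame with columns `n_encoded`, `n_noise_units`,
#'   `n_shared_units`, `seed`, `metric` (`"redundancy_bits"` or
#'   `"cosine_similarity"`), `value`.
#' @export
run_overlap_sweep <- function(n_encoded_values = c(4L, 6L, 8L),
                              noise_unit_counts = c(0L, 10L, 20L),
                              shared_unit_counts = 0L,
                              seeds = 1L,
                              config = NULL,
                              family = decoder_family(),
                              samples_per_class = 250) {
  stopifnot(length(n_encoded_values) > 0, length(noise_unit_counts) > 0,
            length(shared_unit_counts) > 0, length(seeds) > 0)
  if (is.null(config)) {
    config <- train_config(epochs = 150, batch_size = 128,
                           learning_rate = 2e-3,
                           beta = beta_schedule(0, 50, 0.8), seeds = 1L)
  }
  grid <- expand.grid(
    n_encoded = as.integer(n_encoded_values),
    n_noise_units = as.integer(noise_unit_counts),
    n_shared_units = as.integer(shared_unit_counts),
    seed = as.integer(seeds)
  )
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    row <- tryCatch({
      spec <- overlap_task_spec(
        n_encoded_per_source = cell$n_encoded,
        n_noise_units = cell$n_noise_units,
        n_shared_nontask_units = cell$n_shared_units,
        samples_per_class = samples_per_class,
        seed = cell$seed
      )
      ds <- make_overlap_task(spec)
      cfg <- config
      cfg$seeds <- derive_seed(cell$seed, g, 7)
      est <- estimate_redundancy(ds$train, ds$test, family, cfg,
                                 h_y_bits = log2(8))
      cs <- cosine_similarity_mean(ds$train$sources[[1]], ds$train$sources[[2]])
      data.frame(
        cell[rep(1, 2), c("n_encoded", "n_noise_units", "n_shared_units", "seed")],
        metric = c("redundancy_bits", "cosine_similarity"),
        value = c(est$mean_bits, cs),
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(
        cell[, c("n_encoded", "n_noise_units", "n_shared_units", "seed")],
        metric = "error", value = NA_real_, stringsAsFactors = FALSE
      )
    })
    rows[[g]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
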