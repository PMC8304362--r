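# Shared fixtures: independent oracles, small training configurations, and a
# memoized full-scale canonical run reused by the acceptance tests.

ent2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Exhaustive-search oracle for the deterministic-common-variable redundancy:
# enumerates every labeling of the supported X1 symbols into blocks, keeps
# those expressible as a function of every other source on the support, and
# maximizes I(Y; Q). Any admissible Q is a function of X1, so this search is
# complete. Only feasible for <= 4 supported symbols per source.
brute_force_wedge <- function(pmf) {
  sup <- rine:::pmf_support(pmf)
  pts <- sup$points
  mass <- sup$mass
  n_src <- pmf$n_sources
  x1sym <- sort(unique(pts[, 1]))
  n1 <- length(x1sym)
  stopifnot(n1 <= 4)
  ny <- length(pmf$target_alphabet)
  grid <- expand.grid(rep(list(seq_len(n1)), n1))
  best <- 0
  for (g in seq_len(nrow(grid))) {
    lab <- as.integer(grid[g, ])
    q <- lab[match(pts[, 1], x1sym)]
    ok <- TRUE
    for (i in 2:n_src) {
      per_sym <- tapply(q, pts[, i], function(v) length(unique(v)))
      if (any(per_sym > 1)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    joint <- matrix(0, n1, ny)
    for (r in seq_len(nrow(pts))) {
      joint[q[r], pts[r, n_src + 1]] <- joint[q[r], pts[r, n_src + 1]] + mass[r]
    }
    best <- max(best, ent2(rowSums(joint)) + ent2(colSums(joint)) -
                  ent2(as.vector(joint)))
  }
  best
}

# Random small joint pmf over given alphabet sizes, sparse support.
random_pmf <- function(sizes, ny, seed) {
  set.seed(seed)
  dims <- c(sizes, ny)
  tab <- array(0, dim = dims)
  n_cells <- prod(dims)
  k <- sample(seq(2, min(n_cells, 8)), 1)
  cells <- sample.int(n_cells, k)
  tab[cells] <- stats::runif(k)
  tab <- tab / sum(tab)
  alphabets <- lapply(sizes, function(s) as.list(seq_len(s) - 1))
  joint_pmf(alphabets, as.list(seq_len(ny) - 1), tab)
}

# A light training configuration for property tests: sized so that the small
# canonical tasks converge while keeping each seed well under a second.
quick_config <- function(beta_final = 15, seeds = 1:3, epochs = 50,
                         batch_size = 256) {
  train_config(epochs = epochs, batch_size = batch_size,
               beta = beta_schedule(0, beta_final, 0.8), seeds = seeds)
}

quick_task_data <- function(task, n = 2000, seed = 1) {
  pmf <- make_canonical(task)
  list(
    pmf = pmf,
    train = sample_dataset(pmf, n, derive_seed_t(seed, 1)),
    test = sample_dataset(pmf, n, derive_seed_t(seed, 2))
  )
}

derive_seed_t <- function(base, k) (base * 1009 + k * 7919) %% 2147483647 + 1

# A one-hot "copy of the label" dataset: K classes, X = one-hot(Y).
onehot_copy_dataset <- function(n, k, seed, n_sources = 2) {
  set.seed(seed)
  y <- sample.int(k, n, replace = TRUE) - 1L
  x <- diag(k)[y + 1L, , drop = FALSE]
  labeled_dataset(rep(list(x), n_sources), y, k)
}

# Memoized full-scale canonical benchmark run shared by acceptance tests.
.rine_test_cache <- new.env(parent = emptyenv())

full_canonical_suite <- function() {
  if (is.null(.rine_test_cache$suite)) {
    .rine_test_cache$suite <- suppressWarnings(
      run_canonical_suite(beta_final = 15, n_seeds = 5, base_seed = 20260924)
    )
  }
  .rine_test_cache$suite
}
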