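check_dataset_pair <- function(train, test) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(test, "labeled_dataset"))
  if (length(train$sources) != length(test$sources)) {
    stop("train and test must have the same number of sources")
  }
  if (train$n_classes != test$n_classes) {
    stop("train and test must share the class count")
  }
  for (i in seq_along(train$sources)) {
    if (ncol(train$sources[[i]]) != ncol(test$sources[[i]])) {
      stop(sprintf("source %d differs in feature count between train and test", i))
    }
  }
  invisible(TRUE)
}

resolve_h_y <- function(h_y_bits, train, test) {
  if (!is.null(h_y_bits)) return(as.numeric(h_y_bits))
  label_entropy_bits(c(train$labels, test$labels), train$n_classes)
}

# Warn when a decoder's predictions are (near-)constant across inputs: the
# degenerate solution that satisfies the agreement constraint with zero
# information content.
warn_if_trivial <- function(probs, source_index) {
  v <- apply(probs, 2, var)
  if (max(v) < 1e-6) {
    warning(sprintf(
      "decoder %d predictions are near-constant across inputs (trivial solution); consider a slower beta ramp",
      source_index
    ), call. = FALSE)
  }
  invisible(NULL)
}

#' Train agreement-constrained decoders for one seed
#'
#' Jointly optimizes one softmax decoder per source by mini-batch gradient
#' descent on the penalized objective
#' `(1/n) sum_i Hf_i + beta * sum_{i<j} D(f_i, f_j)` (cross-entropies in
#' bits, `D` the expected L1 distance between predicted distributions), with
#' `beta` ramped by the reverse-annealing schedule in `config`. The reported
#' estimate is `H(Y) - (1/n) sum_i Hf_i` with every term evaluated on the
#' held-out `test` set.
#'
#' @param train,test [labeled_dataset()]s with the same structure; `train`
#'   must have at least two sources (use [usable_information_bits()] for a
#'   single source).
#' @param families a single [decoder_family()] shared by all sources, or a
#'   list with one per source.
#' @param config a [train_config()].
#' @param seed integer seed controlling initialization and batch order.
#' @param h_y_bits target entropy H(Y) in bits; when the generating
#'   distribution is known pass its exact entropy, otherwise (default) the
#'   plug-in entropy of the pooled train+test labels is used.
#' @return an object of class `rine_fit`: `i_cap_v_bits`, `h_y_bits`,
#'   `cross_entropy_bits` (per source), `final_distance` (mean pairwise L1 on
#'   test), `decoders`, `history` (per-epoch data frame), `seed`.
#' @export
train_rine <- function(train, test, families, config, seed,
                       h_y_bits = NULL) {
  check_dataset_pair(train, test)
  n_src <- length(train$sources)
  if (n_src < 2) {
    stop("train_rine needs >= 2 sources; use usable_information_bits for one")
  }
  fit_decoders(train, test, families, config, seed, h_y_bits)
}

# Shared engine for 1..n sources.
fit_decoders <- function(train, test, families, config, seed, h_y_bits) {
  stopifnot(inherits(config, "train_config"))
  n_src <- length(train$sources)
  families <- as_family_list(families, n_src)
  h_y <- resolve_h_y(h_y_bits, train, test)

  res <- with_preserved_seed(seed, {
    cpp_train_decoders(
      train$sources, train$labels, train$n_classes,
      lapply(families, function(f) f$hidden),
      families[[1]]$activation,
      config$epochs, config$batch_size, config$learning_rate,
      config$optimizer, config$sgd_momentum,
      config$beta$beta_start, config$beta$beta_final,
      config$beta$ramp_fraction
    )
  })
  if (!all(is.finite(res$history[, "objective_bits"]))) {
    stop("training diverged: non-finite objective; last finite epoch ",
         max(which(is.finite(res$history[, "objective_bits"])), 0))
  }

  decoders <- lapply(seq_len(n_src), function(i) {
    d <- res$decoders[[i]]
    new_fitted_decoder(d$weights, d$biases, families[[i]]$activation,
                      train$n_classes)
  })

  probs <- lapply(seq_len(n_src), function(i) {
    predict_probs(decoders[[i]], test$sources[[i]])
  })
  for (i in seq_len(n_src)) warn_if_trivial(probs[[i]], i)

  ce <- vapply(seq_len(n_src), function(i) {
    py <- probs[[i]][cbind(seq_len(nrow(probs[[i]])), test$labels + 1L)]
    mean(-log2(pmax(py, PROB_FLOOR)))
  }, 1.0)

  dist <- NA_real_
  if (n_src >= 2) {
    pairs <- utils::combn(n_src, 2)
    dist <- mean(apply(pairs, 2, function(ij) {
      l1_distance_rows(probs[[ij[1]]], probs[[ij[2]]])
    }))
  }

  structure(
    list(
      i_cap_v_bits = h_y - mean(ce),
      h_y_bits = h_y,
      cross_entropy_bits = ce,
      final_distance = dist,
      decoders = decoders,
      history = as.data.frame(res$history),
      seed = seed
    ),
    class = "rine_fit"
  )
}

#' @export
print.rine_fit <- function(x, ...) {
  cat(sprintf(
    "rine_fit (seed %s): estimate %.4f bits [H(Y) = %.4f, mean CE = %.4f, D = %s]\n",
    format(x$seed), x$i_cap_v_bits, x$h_y_bits, mean(x$cross_entropy_bits),
    ifelse(is.na(x$final_distance), "NA", sprintf("%.4f", x$final_distance))
  ))
  invisible(x)
}

#' Usable information of a single source about the target, in bits
#'
#' Fits one decoder from the chosen family by cross-entropy minimization on
#' `train` and returns `H(Y)` minus its test cross-entropy: the information
#' a decoder from family `V` can actually extract. With an unrestricted
#' family this recovers Shannon mutual information; with a single source the
#' agreement-constrained problem reduces to exactly this quantity
#' (self-redundancy).
#'
#' @inheritParams train_rine
#' @param family a [decoder_family()].
#' @param source_index which source to decode from.
#' @return usable information in bits (may be slightly negative on held-out
#'   data).
#' @export
usable_information_bits <- function(train, test, family, config,
                                    source_index = 1, seed = 1,
                                    h_y_bits = NULL) {
  check_dataset_pair(train, test)
  if (source_index < 1 || source_index > length(train$sources)) {
    stop("invalid source index")
  }
  sub <- function(ds) labeled_dataset(ds$sources[source_index], ds$labels,
                                      ds$n_classes)
  cfg <- config
  cfg$beta <- beta_schedule(0, 0, 1)
  fit <- fit_decoders(sub(train), sub(test), family, cfg, seed,
                      resolve_h_y(h_y_bits, train, test))
  fit$i_cap_v_bits
}

#' Multi-seed redundancy estimate with aggregation
#'
#' Runs [train_rine()] once per seed in `config$seeds` and aggregates the
#' per-seed estimates into a mean and sample standard deviation. A failing
#' seed is recorded and skipped; the aggregate covers the successes, and an
#' error is raised only if every seed fails.
#'
#' @inheritParams train_rine
#' @return an object of class `redundancy_estimate`: `per_seed_bits`,
#'   `mean_bits`, `sd_bits` (`NA` for a single seed), `h_y_bits`,
#'   `per_seed_cross_entropies` (matrix, seeds x sources),
#'   `final_distances`, `beta_final`, `seeds`, `errors`, `fits`.
#' @export
estimate_redundancy <- function(train, test, families, config,
                                h_y_bits = NULL) {
  if (length(train$sources) != 2) {
    stop("estimate_redundancy is the two-source interface; use estimate_redundancy_multisource for n > 2")
  }
  estimate_redundancy_multisource(train, test, families, config, h_y_bits)
}

#' @rdname estimate_redundancy
#' @export
estimate_redundancy_multisource <- function(train, test, families, config,
                                            h_y_bits = NULL) {
  check_dataset_pair(train, test)
  n_src <- length(train$sources)
  if (n_src < 2) stop("need at least two sources")
  stopifnot(inherits(config, "train_config"))

  fits <- list()
  errors <- list()
  for (s in config$seeds) {
    f <- tryCatch(
      fit_decoders(train, test, families, config, s, h_y_bits),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      errors[[as.character(s)]] <- conditionMessage(f)
    } else {
      fits[[as.character(s)]] <- f
    }
  }
  if (length(fits) == 0) {
    stop("all seeds failed: ", paste(unlist(errors), collapse = " | "))
  }

  per_seed <- vapply(fits, function(f) f$i_cap_v_bits, 1.0)
  ces <- do.call(rbind, lapply(fits, function(f) f$cross_entropy_bits))
  structure(
    list(
      per_seed_bits = unname(per_seed),
      mean_bits = mean(per_seed),
      sd_bits = if (length(per_seed) >= 2) sd(per_seed) else NA_real_,
      h_y_bits = fits[[1]]$h_y_bits,
      per_seed_cross_entropies = unname(ces),
      final_distances = unname(vapply(fits, function(f) f$final_distance, 1.0)),
      beta_final = config$beta$beta_final,
      seeds = as.integer(names(fits)),
      errors = errors,
      fits = fits
    ),
    class = "redundancy_estimate"
  )
}

#' @export
print.redundancy_estimate <- function(x, ...) {
  cat(sprintf(
    "redundancy_estimate: %.4f bits (sd %s) over %d seed(s), beta_final = %g\n",
    x$mean_bits,
    ifelse(is.na(x$sd_bits), "NA", sprintf("%.4f", x$sd_bits)),
    length(x$per_seed_bits), x$beta_final
  ))
  cat(sprintf("  H(Y) = %.4f bits, mean final distance = %.4f\n",
              x$h_y_bits, mean(x$final_distances)))
  if (length(x$errors) > 0) {
    cat(sprintf("  %d seed(s) failed\n", length(x$errors)))
  }
  invisible(x)
}

#' Serialize a redundancy estimate to JSON
#'
#' @param estimate a [estimate_redundancy()] result.
#' @param path output JSON path.
#' @param config_echo optional named list echoed under `"config"`.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(estimate, path, config_echo = NULL) {
  stopifnot(inherits(estimate, "redundancy_estimate"))
  obj <- list(
    units = "bits",
    per_seed_bits = estimate$per_seed_bits,
    mean_bits = estimate$mean_bits,
    sd_bits = estimate$sd_bits,
    h_y_bits = estimate$h_y_bits,
    per_seed_cross_entropies = estimate$per_seed_cross_entropies,
    final_distances = estimate$final_distances,
    beta_final = estimate$beta_final,
    seeds = estimate$seeds,
    errors = estimate$errors
  )
  if (!is.null(config_echo)) obj$config <- config_echo
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
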