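#' Bundle aligned source matrices with a discrete label vector
#'
#' The unit of training and evaluation: `n` real-valued observation matrices
#' (rows = samples, columns = features) that share row alignment, plus one
#' integer label vector in `{0, ..., K-1}`.
#'
#' @param sources list of numeric matrices with equal row counts.
#' @param labels integer vector of class labels in `[0, n_classes)`.
#' @param n_classes number of target classes `K`.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sources, labels, n_classes) {
  stopifnot(is.list(sources), length(sources) >= 1)
  sources <- lapply(sources, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  labels <- as.integer(labels)
  n <- nrow(sources[[1]])
  if (!all(vapply(sources, nrow, 1L) == n)) {
    stop("all source matrices must share the same row count")
  }
  if (length(labels) != n) {
    stop("label vector length must match the source row count")
  }
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 1)
  if (n > 0 && (min(labels) < 0 || max(labels) >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  structure(
    list(sources = sources, labels = labels, n_classes = n_classes),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "labeled_dataset: %d rows, %d source(s) with %s feature(s), K = %d classes\n",
    nrow(x$sources[[1]]), length(x$sources),
    paste(vapply(x$sources, ncol, 1L), collapse = "/"), x$n_classes
  ))
  invisible(x)
}

n_obs <- function(data) nrow(data$sources[[1]])

# Numeric feature encoding of an alphabet: one row per symbol. Tuple symbols
# expand to one column per element, in the symbol's own element order.
# Non-numeric alphabets fall back to 0-based symbol indices.
alphabet_features <- function(alphabet) {
  d <- max(vapply(alphabet, length, 1L))
  if (!all(vapply(alphabet, length, 1L) == d)) {
    stop("all symbols in one alphabet must have the same tuple length")
  }
  m <- matrix(NA_real_, nrow = length(alphabet), ncol = d)
  numeric_ok <- TRUE
  for (k in seq_along(alphabet)) {
    v <- suppressWarnings(as.numeric(alphabet[[k]]))
    if (anyNA(v)) {
      numeric_ok <- FALSE
      break
    }
    m[k, ] <- v
  }
  if (!numeric_ok) {
    m <- matrix(seq_along(alphabet) - 1, ncol = 1)
  }
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  m
}

#' Draw an iid sample dataset from a joint pmf
#'
#' Source symbols are encoded as numeric feature vectors (tuple symbols
#' expand to one column per element, in a fixed documented order); the target
#' is encoded as the 0-based index of its alphabet symbol. The same seed
#' always reproduces the same dataset, and the caller's RNG state is left
#' untouched.
#'
#' @param pmf a [joint_pmf()].
#' @param n number of observations (`n >= 0`).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a [labeled_dataset()] with one matrix per source.
#' @export
sample_dataset <- function(pmf, n, seed = NULL) {
  stopifnot(inherits(pmf, "joint_pmf"))
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("`n` must be a non-negative count")
  feats <- lapply(pmf$source_alphabets, alphabet_features)
  idx <- with_preserved_seed(seed, {
    if (n == 0) integer(0) else
      sample.int(length(pmf$table), n, replace = TRUE, prob = as.vector(pmf$table))
  })
  pts <- arrayInd(idx, dim(pmf$table))
  sources <- lapply(seq_len(pmf$n_sources), function(i) {
    m <- feats[[i]][pts[, i], , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  labels <- if (n == 0) integer(0) else pts[, pmf$n_sources + 1] - 1L
  labeled_dataset(sources, labels, length(pmf$target_alphabet))
}

#' Write a labeled dataset to CSV files
#'
#' One CSV per source (`<prefix>source_<i>.csv`, rows = observations,
#' columns = features) plus `<prefix>labels.csv` with a single `label`
#' column.
#'
#' @param data a [labeled_dataset()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix, default `""`.
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset_csv <- function(data, dir, prefix = "") {
  stopifnot(inherits(data, "labeled_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(data$sources)) {
    p <- file.path(dir, sprintf("%ssource_%d.csv", prefix, i))
    write.csv(as.data.frame(data$sources[[i]]), p, row.names = FALSE)
    paths[sprintf("source_%d", i)] <- p
  }
  lp <- file.path(dir, sprintf("%slabels.csv", prefix))
  write.csv(data.frame(label = data$labels), lp, row.names = FALSE)
  paths["labels"] <- lp
  invisible(paths)
}

#' Read a labeled dataset from CSV files
#'
#' @param source_paths character vector of per-source CSV paths (in source
#'   order).
#' @param labels_path CSV with a `label` column of 0-based integer classes.
#' @param n_classes number of classes; defaults to `max(label) + 1`.
#' @return a [labeled_dataset()].
#' @export
read_dataset_csv <- function(source_paths, labels_path, n_classes = NULL) {
  sources <- lapply(source_paths, function(p) as.matrix(read.csv(p)))
  labels <- read.csv(labels_path)
  if (!("label" %in% names(labels))) {
    stop("labels CSV must contain a `label` column")
  }
  labels <- as.integer(labels$label)
  bad <- which(vapply(sources, nrow, 1L) != length(labels))
  if (length(bad) > 0) {
    stop("source file(s) ", paste(bad, collapse = ", "),
         " have row counts that do not match the label file")
  }
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  labeled_dataset(sources, labels, n_classes)
}

# Plug-in entropy of the empirical label distribution, in bits.
label_entropy_bits <- function(labels, n_classes) {
  if (length(labels) == 0) return(0)
  p <- tabulate(labels + 1L, nbins = n_classes) / length(labels)
  entropy_from_masses(p)
}
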