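LOG2 <- log(2)
PROB_FLOOR <- 1e-12

#' Empirical cross-entropy of a decoder on a dataset, in bits
#'
#' Mean of `-log2 f(y | x)` over the dataset, with predicted probabilities
#' floored at `1e-12` before the log so that a saturated softmax yields a
#' finite loss.
#'
#' @param decoder a fitted decoder.
#' @param data a [labeled_dataset()].
#' @param source_index which source matrix the decoder reads.
#' @return cross-entropy in bits.
#' @export
cross_entropy_bits <- function(decoder, data, source_index = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  x <- data$sources[[source_index]]
  p <- predict_probs(decoder, x)
  if (ncol(p) != data$n_classes) {
    stop("decoder output classes do not match the dataset")
  }
  py <- p[cbind(seq_len(nrow(p)), data$labels + 1L)]
  mean(-log2(pmax(py, PROB_FLOOR)))
}

# Mean rowwise L1 distance between two probability matrices.
l1_distance_rows <- function(p1, p2) mean(rowSums(abs(p1 - p2)))

#' Expected L1 distance between two decoders' predictions
#'
#' `D(f1, f2) = E ||f1(y|x1) - f2(y|x2)||_1` estimated over jointly sampled
#' rows: `x1` and `x2` come from the same observation, matching the
#' expectation over the joint distribution. The value lies in `[0, 2]`.
#'
#' @param f1,f2 fitted decoders.
#' @param data a [labeled_dataset()] with at least two sources.
#' @param source_indices which sources feed `f1` and `f2` (default 1 and 2).
#' @return mean L1 distance between predicted distributions.
#' @export
prediction_distance <- function(f1, f2, data, source_indices = c(1, 2)) {
  stopifnot(inherits(data, "labeled_dataset"), length(source_indices) == 2)
  p1 <- predict_probs(f1, data$sources[[source_indices[1]]])
  p2 <- predict_probs(f2, data$sources[[source_indices[2]]])
  if (nrow(p1) != nrow(p2)) stop("paired sources must share row counts")
  if (ncol(p1) != ncol(p2)) {
    stop("both decoders must predict over the same number of classes")
  }
  l1_distance_rows(p1, p2)
}

#' Penalized objective: mean cross-entropy plus beta times disagreement
#'
#' `(Hf1 + Hf2) / 2 + beta * D(f1, f2)` with cross-entropies in bits. At
#' `beta = 0` this is the unconstrained decoding loss; as `beta` grows the
#' minimizer approaches the agreement-constrained solution.
#'
#' @param f1,f2 fitted decoders reading sources 1 and 2 of `data`.
#' @param data a [labeled_dataset()].
#' @param beta non-negative penalty coefficient.
#' @return the objective value (bits + beta * L1).
#' @export
lagrangian_bits <- function(f1, f2, data, beta) {
  if (beta < 0) stop("beta must be non-negative")
  0.5 * (cross_entropy_bits(f1, data, 1) + cross_entropy_bits(f2, data, 2)) +
    beta * prediction_distance(f1, f2, data)
}

#' Mean rowwise cosine similarity between two observation matrices
#'
#' The matrices must have the same shape; each row pair contributes the
#' cosine of the angle between the two observation vectors.
#'
#' @param d1,d2 numeric matrices with equal dimensions and no zero-norm rows.
#' @return mean cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity_mean <- function(d1, d2) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (nrow(d1) != nrow(d2)) stop("matrices must share the row count")
  if (ncol(d1) != ncol(d2)) stop("matrices must share the column count")
  n1 <- sqrt(rowSums(d1^2))
  n2 <- sqrt(rowSums(d2^2))
  if (any(n1 == 0) || any(n2 == 0)) stop("zero-norm rows are not allowed")
  mean(rowSums(d1 * d2) / (n1 * n2))
}
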