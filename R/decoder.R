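#' Declare a decoder family
#'
#' Describes the function family `V` over which the constrained optimization
#' runs: multilayer perceptrons whose final layer is a softmax over the `K`
#' target classes, so every member maps an observation to a probability
#' vector. Input and output dimensions are inferred from the data at fit
#' time.
#'
#' @param kind `"mlp"` (fully-connected). A `"convolutional"` kind is part of
#'   the declared interface but has no fitting backend in this package;
#'   requesting it is an error at fit time.
#' @param hidden integer vector of hidden-layer widths; `integer(0)` gives a
#'   linear softmax decoder.
#' @param activation `"relu"` or `"tanh"`.
#' @return an object of class `decoder_family`.
#' @examples
#' decoder_family()            # the default 2 x 64 ReLU MLP
#' decoder_family(hidden = integer(0))  # linear softmax decoder
#' @export
decoder_family <- function(kind = c("mlp", "fully_connected", "convolutional"),
                           hidden = c(64L, 64L),
                           activation = c("relu", "tanh")) {
  kind <- match.arg(kind)
  if (kind == "fully_connected") kind <- "mlp"
  activation <- match.arg(activation)
  hidden <- as.integer(hidden)
  if (length(hidden) > 0 && any(hidden < 1)) {
    stop("hidden widths must be positive")
  }
  structure(
    list(kind = kind, hidden = hidden, activation = activation),
    class = "decoder_family"
  )
}

#' @export
print.decoder_family <- function(x, ...) {
  h <- if (length(x$hidden) == 0) "linear" else paste(x$hidden, collapse = "-")
  cat(sprintf("decoder_family: %s (%s, %s)\n", x$kind, h, x$activation))
  invisible(x)
}

as_family_list <- function(families, n_sources) {
  if (inherits(families, "decoder_family")) {
    families <- rep(list(families), n_sources)
  }
  stopifnot(is.list(families))
  if (length(families) != n_sources) {
    stop("need one decoder family per source (or a single family to share)")
  }
  for (f in families) {
    if (!inherits(f, "decoder_family")) stop("not a decoder_family object")
    if (f$kind != "mlp") {
      stop("only the fully-connected (mlp) family has a fitting backend")
    }
  }
  families
}

new_fitted_decoder <- function(weights, biases, activation, n_classes) {
  structure(
    list(
      weights = lapply(weights, as.matrix),
      biases = lapply(biases, as.numeric),
      activation = activation,
      input_dim = nrow(weights[[1]]),
      n_classes = n_classes
    ),
    class = "rine_decoder"
  )
}

#' @export
print.rine_decoder <- function(x, ...) {
  widths <- vapply(x$weights, ncol, 1L)
  cat(sprintf("rine_decoder: %d -> %s (softmax over %d classes, %s)\n",
              x$input_dim, paste(widths, collapse = " -> "),
              x$n_classes, x$activation))
  invisible(x)
}

#' Predicted class distributions of a fitted decoder
#'
#' @param decoder a fitted decoder from [train_rine()] or
#'   [usable_information_bits()].
#' @param x numeric matrix of observations (rows = samples).
#' @return matrix of row-normalized class probabilities (rows = samples,
#'   columns = classes).
#' @export
predict_probs <- function(decoder, x) {
  stopifnot(inherits(decoder, "rine_decoder"))
  x <- as.matrix(x)
  if (ncol(x) != decoder$input_dim) {
    stop(sprintf("decoder expects %d input feature(s), got %d",
                 decoder$input_dim, ncol(x)))
  }
  h <- x
  L <- length(decoder$weights)
  for (l in seq_len(L)) {
    h <- h %*% decoder$weights[[l]]
    h <- sweep(h, 2, decoder$biases[[l]], "+")
    if (l < L) {
      h <- if (decoder$activation == "relu") pmax(h, 0) else tanh(h)
    }
  }
  h <- h - apply(h, 1, max)
  e <- exp(h)
  e / rowSums(e)
}

#' Save / load a fitted decoder checkpoint
#'
#' The checkpoint is an RDS file holding the weights; a JSON sidecar
#' (`<path>.json`) records the architecture and any metadata supplied in
#' `info` (seed, beta schedule, final metrics, ...).
#'
#' @param decoder a fitted decoder.
#' @param path checkpoint file path (conventionally `.rds`).
#' @param info named list of metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
save_decoder <- function(decoder, path, info = list()) {
  stopifnot(inherits(decoder, "rine_decoder"))
  saveRDS(unclass(decoder), path)
  sidecar <- c(
    list(
      format = "rine_decoder_checkpoint_v1",
      input_dim = decoder$input_dim,
      layer_widths = vapply(decoder$weights, ncol, 1L),
      activation = decoder$activation,
      n_classes = decoder$n_classes
    ),
    info
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  obj <- readRDS(path)
  new_fitted_decoder(obj$weights, obj$biases, obj$activation, obj$n_classes)
}
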