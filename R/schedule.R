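#' Reverse-annealing schedule for the agreement penalty coefficient
#'
#' Training starts with a low Lagrange coefficient `beta` so that the
#' decoders first learn informative predictions, then ramps `beta` up so the
#' agreement constraint is enforced; starting high risks collapse to a
#' constant ("trivial") decoder that satisfies the constraint with no
#' information content. The ramp is linear from `beta_start` at progress 0
#' to `beta_final` at progress `ramp_fraction`, constant afterwards.
#'
#' @param beta_start non-negative starting coefficient (default 0).
#' @param beta_final non-negative final coefficient; 50 is a robust general
#'   default, 15 matches the canonical-benchmark configuration.
#' @param ramp_fraction fraction of training over which the ramp runs, in
#'   `(0, 1]`.
#' @return an object of class `beta_schedule`.
#' @export
beta_schedule <- function(beta_start = 0, beta_final = 50, ramp_fraction = 0.8) {
  stopifnot(is.numeric(beta_start), is.numeric(beta_final),
            is.numeric(ramp_fraction))
  if (beta_start < 0 || beta_final < 0) stop("beta values must be non-negative")
  if (beta_start > beta_final) stop("beta_start must be <= beta_final")
  if (ramp_fraction <= 0 || ramp_fraction > 1) {
    stop("ramp_fraction must lie in (0, 1]")
  }
  structure(
    list(beta_start = beta_start, beta_final = beta_final,
         ramp_fraction = ramp_fraction),
    class = "beta_schedule"
  )
}

#' Evaluate a beta schedule at a training progress fraction
#'
#' @param schedule a [beta_schedule()].
#' @param progress fraction of training completed, in `[0, 1]`.
#' @return the coefficient beta at that point.
#' @examples
#' s <- beta_schedule(0, 50, 0.8)
#' beta_at(s, 0)    # 0
#' beta_at(s, 0.4)  # 25
#' beta_at(s, 0.9)  # 50
#' @export
beta_at <- function(schedule, progress) {
  stopifnot(inherits(schedule, "beta_schedule"))
  if (any(progress < 0 | progress > 1)) stop("progress must lie in [0, 1]")
  frac <- pmin(progress / schedule$ramp_fraction, 1)
  schedule$beta_start + (schedule$beta_final - schedule$beta_start) * frac
}

#' Training configuration for the constrained decoder optimization
#'
#' @param epochs number of passes over the training data (>= 1).
#' @param batch_size mini-batch size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate step size.
#' @param beta a [beta_schedule()].
#' @param seeds integer vector of initialization seeds (>= 1 seed); the
#'   reported estimate aggregates over them.
#' @param sgd_momentum momentum coefficient, used only by `"sgd"`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 150, batch_size = 256,
                         optimizer = c("adam", "sgd"),
                         learning_rate = 1e-3,
                         beta = beta_schedule(),
                         seeds = 1:5,
                         sgd_momentum = 0.9) {
  optimizer <- match.arg(optimizer)
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  seeds <- as.integer(seeds)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            inherits(beta, "beta_schedule"))
  if (length(seeds) < 1) stop("at least one seed is required")
  structure(
    list(epochs = epochs, batch_size = batch_size, optimizer = optimizer,
         learning_rate = learning_rate, beta = beta, seeds = seeds,
         sgd_momentum = sgd_momentum),
    class = "train_config"
  )
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(
    "train_config: %d epoch(s), batch %d, %s(lr=%g), beta %g -> %g over %g%%, %d seed(s)\n",
    x$epochs, x$batch_size, x$optimizer, x$learning_rate,
    x$beta$beta_start, x$beta$beta_final, 100 * x$beta$ramp_fraction,
    length(x$seeds)
  ))
  invisible(x)
}
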