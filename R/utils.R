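# Small numeric helpers shared across the network code. All activations are
# written for matrices and keep dims.

silu <- function(x) x / (1 + exp(-x))

silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

# multiply each column k of M by v[k]
colscale <- function(M, v) M * rep(v, each = nrow(M))

# row-permutation that reverses the sequence axis of a [B*L x d] matrix
# (rows ordered batch-fastest: row = b + B*(t-1))
flip_perm <- function(B, L) {
  rep(seq_len(B), times = L) + B * rep((L - 1):0, each = B)
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible sub-seed from a run seed and a label
#'
#' All randomness in the package flows from one integer run seed. Independent
#' random streams (parameter init, fold splits, noise, shuffling) use
#' sub-seeds derived deterministically from the run seed and a short label,
#' so that e.g. changing the number of epochs never perturbs the fold split.
#'
#' @param seed Integer run seed.
#' @param label Character label naming the stream.
#' @return An integer in `[0, 2^31)`.
#' @export
#' @examples
#' subseed(1, "folds")
subseed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

# uniform init in [-k, k] with k = 1/sqrt(fan_in), the usual linear-layer default
init_linear <- function(fan_in, fan_out) {
  k <- 1 / sqrt(fan_in)
  matrix(runif(fan_in * fan_out, -k, k), fan_in, fan_out)
}

init_bias <- function(fan_in, fan_out) {
  k <- 1 / sqrt(fan_in)
  runif(fan_out, -k, k)
}
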