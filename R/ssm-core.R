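#' Selective state-space (S6) parameters
#'
#' Creates a randomly initialised parameter set for a selective SSM over
#' sequences whose elements have `model_dim` channels, each channel carrying a
#' hidden state of size `state_dim`. The state matrix is diagonal and
#' log-parameterised, `A = -exp(A_log)`, so it is strictly negative and the
#' zero-order-hold transition `exp(delta * A)` lies in (0, 1) for any positive
#' step size. The input projection `B`, output projection `C` and step size
#' `delta` are input-dependent (the selection mechanism): linear maps of the
#' current sequence element, with `delta` passed through softplus to keep it
#' positive.
#'
#' `A_log` is initialised to `log(1..state_dim)` per channel; the step-size
#' bias is drawn so that softplus of it falls in `[0.001, 0.1]`, the standard
#' range for stable long-sequence memory. Draws come from the current RNG
#' state, so wrap calls in `withr::with_seed()` (or `set.seed`) for
#' reproducibility.
#'
#' @param model_dim Channels per sequence element (positive integer).
#' @param state_dim Hidden-state size per channel (positive integer).
#' @return An object of class `ssm_params`: a named list with `A_log`
#'   (`model_dim x state_dim`), `D_skip` (length `model_dim` feed-through),
#'   `W_B`, `b_B`, `W_C`, `b_C` (projections to `state_dim`), and `W_dt`,
#'   `b_dt` (step-size projection).
#' @export
#' @examples
#' set.seed(1)
#' p <- ssm_params(model_dim = 2, state_dim = 3)
#' u <- matrix(rnorm(16), 8, 2)
#' y <- selective_scan(u, p)
#' dim(y)
ssm_params <- function(model_dim, state_dim) {
  stopifnot(model_dim >= 1, state_dim >= 1)
  d <- as.integer(model_dim); n <- as.integer(state_dim)
  dt <- exp(runif(d, log(0.001), log(0.1)))
  structure(list(
    model_dim = d, state_dim = n,
    A_log  = matrix(log(seq_len(n)), d, n, byrow = TRUE),
    D_skip = rep(1, d),
    W_B = init_linear(d, n), b_B = rep(0, n),
    W_C = init_linear(d, n), b_C = rep(0, n),
    W_dt = init_linear(d, d),
    b_dt = dt + log(-expm1(-dt))  # inverse softplus
  ), class = "ssm_params")
}

#' Zero-order-hold discretization of a diagonal selective SSM
#'
#' Converts the continuous-time diagonal state matrix `A` (strictly negative)
#' and an input projection `B_t` into their discrete counterparts for step
#' size `delta_t`: the state path uses the exact zero-order hold
#' `Abar = exp(delta * A)`, the input path the simplified Euler rule
#' `Bbar = delta * B_t`.
#'
#' @param A Numeric scalar/array, strictly negative (diagonal state matrix).
#' @param B_t Numeric scalar/array, input projection at step t.
#' @param delta_t Numeric scalar/array, strictly positive step size
#'   (recycled against `A` / `B_t` by ordinary arithmetic rules).
#' @return A list with elements `Abar` (elementwise in (0,1)) and `Bbar`.
#' @export
#' @examples
#' discretize(A = -1, B_t = 1, delta_t = 0.1)$Abar  # exp(-0.1)
discretize <- function(A, B_t, delta_t) {
  if (any(delta_t <= 0)) {
    stop("delta_t must be strictly positive", call. = FALSE)
  }
  if (any(A >= 0)) {
    stop("A must be strictly negative (diagonal stable system)", call. = FALSE)
  }
  list(Abar = exp(delta_t * A), Bbar = delta_t * B_t)
}

# derive the per-step scan inputs (selection mechanism) from a [rows x d]
# matrix of sequence elements
.ssm_selection <- function(u, p) {
  delta_pre <- u %*% p$W_dt + rep(p$b_dt, each = nrow(u))
  list(
    delta_pre = delta_pre,
    delta = softplus(delta_pre),
    Bmat  = u %*% p$W_B + rep(p$b_B, each = nrow(u)),
    Cmat  = u %*% p$W_C + rep(p$b_C, each = nrow(u)),
    A     = -exp(p$A_log)
  )
}

#' Linear-time selective scan
#'
#' Evaluates the selective-SSM recurrence along a sequence: for each channel
#' `k` and hidden-state component `j`,
#' `h_t = exp(delta_t A) h_(t-1) + (delta_t B_t) u_t` and
#' `y_t = C_t . h_t + D u_t`, with `B_t`, `C_t`, `delta_t` generated from the
#' current input `u_t` by the projections in `params`. The hidden state starts
#' at zero and the cost is linear in the sequence length.
#'
#' @param u Numeric matrix `[L x model_dim]` (one sequence), or a 3-d array
#'   `[B x L x model_dim]` for a batch.
#' @param params An [ssm_params] object with matching `model_dim`.
#' @return Output of the same shape as `u`.
#' @seealso [selective_scan_reference()] for the brute-force per-step oracle.
#' @export
selective_scan <- function(u, params) {
  stopifnot(inherits(params, "ssm_params"))
  arr <- length(dim(u)) == 3
  if (arr) {
    B <- dim(u)[1]; L <- dim(u)[2]; d <- dim(u)[3]
    um <- matrix(u, B * L, d)
  } else {
    u <- as.matrix(u)
    B <- 1L; L <- nrow(u); d <- ncol(u)
    um <- u
  }
  if (L < 1) stop("empty sequence", call. = FALSE)
  check_finite(um, "selective_scan input")
  if (d != params$model_dim) {
    stop(sprintf("model_dim mismatch: input has %d channels, params expect %d",
                 d, params$model_dim), call. = FALSE)
  }
  sel <- .ssm_selection(um, params)
  y <- .scan_forward_cpp(um, sel$delta, sel$Bmat, sel$Cmat, sel$A,
                         params$D_skip, as.integer(B), as.integer(L))
  if (arr) array(y, dim(u)) else y
}

#' Brute-force reference scan (per-step loop oracle)
#'
#' A deliberately naive, literal evaluation of the same recurrence as
#' [selective_scan()], stepping through the sequence one element at a time in
#' plain R. It exists as an independent oracle for testing the optimized scan
#' and is far too slow for real use. The returned matrix carries an attribute
#' `recurrence_steps` (= L), the number of sequential recurrence evaluations,
#' which documents the linear-in-L operation count.
#'
#' @inheritParams selective_scan
#' @return `[L x model_dim]` output with attribute `recurrence_steps`.
#' @export
selective_scan_reference <- function(u, params) {
  stopifnot(inherits(params, "ssm_params"))
  u <- as.matrix(u)
  L <- nrow(u); d <- ncol(u); n <- params$state_dim
  if (L < 1) stop("empty sequence", call. = FALSE)
  check_finite(u, "selective_scan input")
  A <- -exp(params$A_log)
  y <- matrix(0, L, d)
  h <- matrix(0, d, n)
  steps <- 0L
  for (t in seq_len(L)) {
    ut <- u[t, ]
    delta_t <- softplus(drop(ut %*% params$W_dt) + params$b_dt)
    B_t <- drop(ut %*% params$W_B) + params$b_B
    C_t <- drop(ut %*% params$W_C) + params$b_C
    for (k in seq_len(d)) {
      dsc <- discretize(A[k, ], B_t, delta_t[k])
      h[k, ] <- dsc$Abar * h[k, ] + dsc$Bbar * ut[k]
      y[t, k] <- sum(C_t * h[k, ]) + params$D_skip[k] * ut[k]
    }
    steps <- steps + 1L
  }
  attr(y, "recurrence_steps") <- steps
  y
}

#' Gated Mamba block parameters
#'
#' The block wraps the selective SSM with the standard gated architecture:
#' an input projection that widens `model_dim` to `2 * expand * model_dim`
#' (value and gate paths), a short depthwise causal convolution plus SiLU on
#' the value path, the selective scan, a SiLU-gated elementwise product, and
#' an output projection back to `model_dim`.
#'
#' @param model_dim Channels of the block input/output.
#' @param state_dim Hidden-state size of the inner SSM (default 16).
#' @param expand Width multiplier for the inner channels (default 2).
#' @param conv_width Depthwise causal convolution length (default 4).
#' @return An object of class `mamba_block_params`.
#' @export
mamba_block_params <- function(model_dim, state_dim = 16, expand = 2,
                               conv_width = 4) {
  stopifnot(model_dim >= 1, state_dim >= 1, expand >= 1, conv_width >= 1)
  m <- as.integer(model_dim)
  di <- as.integer(expand * model_dim)
  kc <- 1 / sqrt(conv_width)
  structure(list(
    model_dim = m, d_inner = di, expand = as.integer(expand),
    conv_width = as.integer(conv_width),
    W_in = init_linear(m, 2L * di), b_in = init_bias(m, 2L * di),
    conv_w = matrix(runif(conv_width * di, -kc, kc), conv_width, di),
    conv_b = runif(di, -kc, kc),
    ssm = ssm_params(di, state_dim),
    W_out = init_linear(di, m), b_out = init_bias(di, m)
  ), class = "mamba_block_params")
}

# batched Mamba block forward on a [B*L x model_dim] matrix; returns the
# block output (same shape) and, optionally, the cache needed for backward.
# The heavy lifting (projections, conv, scan, gate) happens in the fused
# C++ kernel; the scan's state trajectory is cached there so the backward
# pass never replays the recurrence.
.block_forward <- function(X, p, B, L, keep_cache = FALSE) {
  A <- -exp(p$ssm$A_log)
  out <- .block_fwd_cpp(X, p$W_in, p$b_in, p$conv_w, p$conv_b, A,
                        p$ssm$D_skip, p$ssm$W_B, p$ssm$b_B, p$ssm$W_C,
                        p$ssm$b_C, p$ssm$W_dt, p$ssm$b_dt, p$W_out, p$b_out,
                        as.integer(B), as.integer(L), isTRUE(keep_cache))
  cache <- NULL
  if (keep_cache) {
    cache <- list(cache_ptr = out$cache_ptr, X = X, A = A, B = B, L = L)
  }
  list(y = out$y, cache = cache)
}

.block_backward <- function(gy, cache, p) {
  sb <- .block_bwd_cpp(gy, cache$X, p$W_in, p$conv_w, cache$A, p$ssm$D_skip,
                       p$ssm$W_B, p$ssm$W_C, p$ssm$W_dt, p$W_out,
                       cache$cache_ptr,
                       as.integer(cache$B), as.integer(cache$L))
  grads <- list(
    W_in = sb$W_in, b_in = drop(sb$b_in),
    conv_w = sb$conv_w, conv_b = drop(sb$conv_b),
    ssm = list(
      A_log = sb$A * cache$A,                  # A = -exp(A_log)
      D_skip = drop(sb$D_skip),
      W_B = sb$W_B, b_B = drop(sb$b_B),
      W_C = sb$W_C, b_C = drop(sb$b_C),
      W_dt = sb$W_dt, b_dt = drop(sb$b_dt)
    ),
    W_out = sb$W_out, b_out = drop(sb$b_out)
  )
  list(grads = grads, gX = sb$gX)
}

#' Apply a gated Mamba block to a sequence
#'
#' Runs the full gated block (input projection, causal depthwise convolution,
#' SiLU, selective scan, SiLU gate, output projection) on one sequence.
#' Output shape equals input shape.
#'
#' @param x Numeric matrix `[L x model_dim]`.
#' @param params A [mamba_block_params] object with matching `model_dim`.
#' @return Numeric matrix `[L x model_dim]`.
#' @export
mamba_block <- function(x, params) {
  stopifnot(inherits(params, "mamba_block_params"))
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("empty sequence", call. = FALSE)
  if (ncol(x) != params$model_dim) {
    stop(sprintf("model_dim mismatch: input has %d channels, params expect %d",
                 ncol(x), params$model_dim), call. = FALSE)
  }
  check_finite(x, "mamba_block input")
  .block_forward(x, params, B = 1L, L = nrow(x))$y
}
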